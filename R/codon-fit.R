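# Maximum-likelihood fitting of GY94 one-ratio and two-ratio branch models,
# the likelihood-ratio test, and profile-likelihood intervals for the
# foreground dN/dS.

.GY_BOUNDS <- list(logKappa = log(c(1e-2, 1e2)),
                   logOmega = log(c(1e-4, 50)),
                   logT     = log(c(1e-6, 20)))

# Core bounded quasi-Newton optimisation of the pruning likelihood on
# log-transformed (kappa, omega..., t...). Eigendecompositions are cached by
# (kappa, omega) so branch-length moves only pay for transition matrices.
.gyFitCore <- function(data, pi, model, start, fixOmegaFg = NULL,
                       fixT = NULL, maxit = 300, factr = 1e9) {
  twoRatio <- model == "two_ratio"
  freeT <- is.null(fixT)
  nEdge <- nrow(data$edge)
  classIdx <- if (twoRatio)
    ifelse(data$foreground, "foreground", "background") else
    rep("all", nEdge)
  classes <- unique(classIdx)

  theta0 <- c(log(start$kappa),
              log(if (twoRatio) start$omega[["background"]] else
                start$omega[[1L]]))
  lower <- c(.GY_BOUNDS$logKappa[1L], .GY_BOUNDS$logOmega[1L])
  upper <- c(.GY_BOUNDS$logKappa[2L], .GY_BOUNDS$logOmega[2L])
  freeFg <- twoRatio && is.null(fixOmegaFg)
  if (freeFg) {
    theta0 <- c(theta0, log(start$omega[["foreground"]]))
    lower <- c(lower, .GY_BOUNDS$logOmega[1L])
    upper <- c(upper, .GY_BOUNDS$logOmega[2L])
  }
  if (freeT) {
    theta0 <- c(theta0, log(pmin(pmax(start$t, 1.01e-6), 19.9)))
    lower <- c(lower, rep(.GY_BOUNDS$logT[1L], nEdge))
    upper <- c(upper, rep(.GY_BOUNDS$logT[2L], nEdge))
  }

  cache <- new.env(parent = emptyenv())
  getEigen <- function(kappa, omega) {
    key <- sprintf("%.14g_%.14g", kappa, omega)
    e <- cache[[key]]
    if (is.null(e)) {
      e <- .gyEigen(kappa, omega, pi)
      if (length(ls(cache)) > 8L) rm(list = ls(cache), envir = cache)
      cache[[key]] <- e
    }
    e
  }

  unpack <- function(theta) {
    kappa <- exp(theta[1L])
    om <- if (twoRatio)
      c(background = exp(theta[2L]),
        foreground = if (freeFg) exp(theta[3L]) else fixOmegaFg)
    else c(all = exp(theta[2L]))
    off <- 2L + freeFg
    t <- if (freeT) exp(theta[(off + 1L):(off + nEdge)]) else fixT
    list(kappa = kappa, omega = om, t = t)
  }

  neg <- function(theta) {
    p <- unpack(theta)
    eigs <- lapply(stats::setNames(classes, classes),
                   function(cl) getEigen(p$kappa, p$omega[[cl]]))
    lnL <- .pruneLogLik(data, eigs, classIdx, p$t, pi)
    if (!is.finite(lnL)) return(1e10)
    -lnL
  }

  res <- optim(theta0, neg, method = "L-BFGS-B", lower = lower,
               upper = upper,
               control = list(maxit = maxit, factr = factr))
  p <- unpack(res$par)
  list(lnL = -res$value, kappa = p$kappa, omega = p$omega, t = p$t,
       converged = res$convergence == 0L,
       iterations = unname(res$counts["function"]),
       message = if (is.null(res$message)) "" else res$message,
       par = res$par)
}

.defaultStart <- function(tree, model) {
  t0 <- tree@tree$edge.length
  if (is.null(t0) || any(!is.finite(t0)) || all(t0 <= 0))
    t0 <- rep(0.1, nrow(tree@tree$edge))
  t0 <- pmax(t0, 1e-4)
  om <- if (model == "two_ratio")
    c(background = 0.2, foreground = 0.2) else c(all = 0.2)
  list(kappa = 2, omega = om, t = t0)
}

#' Fit a GY94 branch model by maximum likelihood
#'
#' Jointly maximizes the pruning log-likelihood over `kappa`, the per-class
#' dN/dS values and (by default) all branch lengths, using bounded
#' quasi-Newton iterations on log-transformed parameters with multiple
#' starting points. The one-ratio model gives every branch the same dN/dS;
#' the two-ratio model gives the tree's foreground branch(es) their own.
#'
#' @param aln A [CodonAlignment-class].
#' @param tree A [LabeledTree-class]; `model = "two_ratio"` requires at least
#'   one foreground and one background branch.
#' @param model `"one_ratio"` or `"two_ratio"`.
#' @param pi Codon frequencies; default F3X4 from `aln`.
#' @param nStarts Number of optimisation starts (default 3): the first uses
#'   the supplied/heuristic start, the rest random log-scale perturbations of
#'   it run with a reduced iteration cap, after which the best is polished.
#' @param seed Optional seed for the random restarts.
#' @param fixBranchLengths Keep branch lengths at the tree's values.
#' @param dropGapped Drop codon columns containing gaps (default: gap as
#'   missing data).
#' @param start Optional warm start: list with `kappa`, `omega` (named as the
#'   model expects) and `t`.
#' @param maxit Iteration cap for the polishing run.
#' @return A [CodonModelFit-class]. Non-convergence is flagged in
#'   `convergence(fit)$converged`, not raised as an error.
#' @export
fitBranchModel <- function(aln, tree, model = c("one_ratio", "two_ratio"),
                           pi = NULL, nStarts = 3L, seed = NULL,
                           fixBranchLengths = FALSE, dropGapped = FALSE,
                           start = NULL, maxit = 300L) {
  model <- match.arg(model)
  stopifnot(methods::is(aln, "CodonAlignment"),
            methods::is(tree, "LabeledTree"))
  if (model == "two_ratio" &&
      (!any(tree@foreground) || all(tree@foreground)))
    stop("two-ratio model needs >= 1 foreground and >= 1 background branch")
  data <- .codonData(aln, tree, dropGapped)
  if (is.null(pi)) pi <- f3x4Frequencies(aln)
  if (is.null(start)) start <- .defaultStart(tree, model)
  if (model == "two_ratio" && is.null(names(start$omega)))
    start$omega <- c(background = start$omega[[1L]],
                     foreground = start$omega[[length(start$omega)]])
  fixT <- if (fixBranchLengths) tree@tree$edge.length else NULL
  if (!is.null(seed)) set.seed(seed)

  runs <- vector("list", nStarts)
  runs[[1L]] <- .gyFitCore(data, pi, model, start, fixT = fixT,
                           maxit = maxit)
  if (nStarts > 1L) {
    for (k in 2L:nStarts) {
      jitter <- start
      jitter$kappa <- start$kappa * exp(rnorm(1L, 0, 0.5))
      jitter$omega <- start$omega * exp(rnorm(length(start$omega), 0, 0.7))
      jitter$t <- start$t * exp(rnorm(length(start$t), 0, 0.5))
      runs[[k]] <- .gyFitCore(data, pi, model, jitter, fixT = fixT,
                              maxit = 40L)
    }
    best <- which.max(vapply(runs, `[[`, numeric(1L), "lnL"))
    if (best != 1L) {
      polish <- list(kappa = runs[[best]]$kappa, omega = runs[[best]]$omega,
                     t = runs[[best]]$t)
      runs[[best]] <- .gyFitCore(data, pi, model, polish, fixT = fixT,
                                 maxit = maxit)
    }
  }
  lnLs <- vapply(runs, `[[`, numeric(1L), "lnL")
  best <- runs[[which.max(lnLs)]]
  methods::new("CodonModelFit", lnL = best$lnL, kappa = best$kappa,
               omega = best$omega,
               branchLengths = if (fixBranchLengths) fixT else best$t,
               pi = pi, model = model,
               convergence = list(converged = best$converged,
                                  iterations = best$iterations,
                                  nStarts = as.integer(nStarts),
                                  startLnLs = lnLs,
                                  message = best$message),
               tree = tree)
}

#' Fitted log-likelihood
#' @param fit A [CodonModelFit-class].
#' @return Scalar log-likelihood.
#' @export
fitLogLik <- function(fit) fit@lnL

#' Fitted dN/dS per branch class
#' @param fit A [CodonModelFit-class].
#' @return Named numeric vector.
#' @export
omegaEstimates <- function(fit) fit@omega

#' Convergence record of a fit
#' @param fit A [CodonModelFit-class].
#' @return List with `converged`, `iterations`, `nStarts`, `startLnLs`.
#' @export
convergenceInfo <- function(fit) fit@convergence

#' Likelihood-ratio test of nested codon models
#'
#' `2dL = 2 (lnL_alt - lnL_null)` compared to the chi-square upper tail with
#' `df` degrees of freedom; the statistic is clipped at 0. A negative value
#' beyond numerical tolerance (alternative worse than its nested null)
#' triggers a refit warning.
#'
#' @param nullFit,altFit [CodonModelFit-class] objects (or numeric lnL
#'   values), the null nested in the alternative.
#' @param df Degrees of freedom (default 1, one extra dN/dS class).
#' @return An [LrtResult-class].
#' @export
lrTest <- function(nullFit, altFit, df = 1) {
  ln0 <- if (methods::is(nullFit, "CodonModelFit")) nullFit@lnL else nullFit
  ln1 <- if (methods::is(altFit, "CodonModelFit")) altFit@lnL else altFit
  stat <- 2 * (ln1 - ln0)
  if (stat < -1e-4)
    warning(sprintf(paste0("alternative lnL below null by %.4g: ",
                           "optimisation likely not converged; refit"),
                    -stat))
  stat <- max(stat, 0)
  methods::new("LrtResult", statistic = stat, df = df,
               pValue = pchisq(stat, df, lower.tail = FALSE),
               lnLNull = ln0, lnLAlt = ln1)
}

#' Profile-likelihood interval for the foreground dN/dS
#'
#' Re-optimizes all nuisance parameters (kappa, background dN/dS, branch
#' lengths) on a moving grid of fixed foreground dN/dS values, warm-started
#' from the MLE, and inverts the likelihood-ratio statistic at the
#' chi-square(1) quantile for `level`.
#'
#' @param fit A converged two-ratio [CodonModelFit-class].
#' @param aln The [CodonAlignment-class] the fit used.
#' @param level Confidence level (default 0.95).
#' @param nBisect Bisection iterations per bound (default 7).
#' @return Numeric `c(lower, upper)`; bounds that run into the parameter box
#'   are returned at the box edge.
#' @export
profileForegroundOmega <- function(fit, aln, level = 0.95, nBisect = 7L) {
  stopifnot(fit@model == "two_ratio")
  tree <- fit@tree
  data <- .codonData(aln, tree, dropGapped = FALSE)
  pi <- fit@pi
  crit <- stats::qchisq(level, df = 1)
  mle <- fit@omega[["foreground"]]
  mleStart <- list(kappa = fit@kappa, omega = fit@omega,
                   t = fit@branchLengths)
  boxLo <- exp(.GY_BOUNDS$logOmega[1L])
  boxHi <- exp(.GY_BOUNDS$logOmega[2L])
  findBound <- function(direction) {
    # continuation: each profile point warm-starts from the previous
    # point's solution, so the nuisance optimum tracks the moving omega
    warm <- mleStart
    profDev <- function(w) {
      st <- warm
      st$omega["foreground"] <- w
      r <- .gyFitCore(data, pi, "two_ratio", st, fixOmegaFg = w,
                      maxit = 200L)
      warm <<- list(kappa = r$kappa, omega = r$omega, t = r$t)
      2 * (fit@lnL - r$lnL)
    }
    w <- mle
    fac <- if (direction > 0) 1.4 else 1 / 1.4
    for (i in 1:40) {
      wNext <- w * fac
      if (wNext >= boxHi) return(boxHi)
      if (wNext <= boxLo) return(boxLo)
      if (profDev(wNext) > crit) {
        lo <- min(w, wNext); hi <- max(w, wNext)
        for (j in seq_len(nBisect)) {
          mid <- sqrt(lo * hi)
          if ((profDev(mid) > crit) == (direction > 0)) hi <- mid else
            lo <- mid
        }
        return(sqrt(lo * hi))
      }
      w <- wNext
    }
    if (direction > 0) boxHi else boxLo
  }
  c(lower = findBound(-1), upper = findBound(+1))
}

setMethod("show", "CodonModelFit", function(object) {
  cat(sprintf("CodonModelFit [%s]: lnL = %.4f%s\n", object@model,
              object@lnL,
              if (isTRUE(object@convergence$converged)) "" else
                "  (NOT converged)"))
  cat(sprintf("  kappa = %.4f\n", object@kappa))
  cat(sprintf("  omega: %s\n",
              paste(sprintf("%s = %.4f", names(object@omega), object@omega),
                    collapse = ", ")))
  cat(sprintf("  tree length = %.4f over %d branches\n",
              sum(object@branchLengths), length(object@branchLengths)))
})

setMethod("show", "LrtResult", function(object) {
  cat(sprintf("LRT: 2dL = %.3f, df = %g, p = %.4g\n", object@statistic,
              object@df, object@pValue))
})
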