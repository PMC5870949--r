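# Weighted kernel substitution-density profiles, the relative-density hotspot
# statistic, and its Monte-Carlo permutation threshold.

.scanKernel <- function(h) {
  K <- ceiling(6 * h)
  dnorm(seq.int(-K, K), sd = h)
}

.eventPositions <- function(map, includeIndels = FALSE) {
  ev <- map@events
  if (!includeIndels) ev <- ev[ev$type == "substitution", , drop = FALSE]
  lapply(stats::setNames(BRANCHES, BRANCHES),
         function(b) as.integer(ev$column[ev$branch == b]))
}

#' Weighted kernel substitution density for one branch
#'
#' A Gaussian kernel with standard deviation `h` (residues) is placed at every
#' event column, evaluated on integer columns `1..L`, normalized to unit mass
#' over the real line and weighted by the branch's share of all events,
#' `w_b = n_b / n_total`; equivalently `d_b(x) = (1/n_total) sum_i
#' phi_h(x - x_i)`. No boundary correction is applied (edge mass is lost,
#' matching the default kernel estimator).
#'
#' @param map A [BranchEventMap-class].
#' @param branch `"outgroup"`, `"paralog1"` or `"paralog2"`.
#' @param h Kernel standard deviation in residues (default 15).
#' @param includeIndels Count indel events as well as substitutions
#'   (default `FALSE`).
#' @return A [DensityProfile-class].
#' @export
substitutionDensity <- function(map, branch = BRANCHES, h = 15,
                                includeIndels = FALSE) {
  branch <- match.arg(branch)
  stopifnot(h > 0, map@L >= 1L)
  pos <- .eventPositions(map, includeIndels)
  nTotal <- sum(lengths(pos))
  p <- pos[[branch]]
  vals <- if (nTotal == 0L || !length(p)) numeric(map@L) else
    cpp_density_profile(p, map@L, .scanKernel(h), 1 / nTotal)
  methods::new("DensityProfile", branch = branch, values = vals,
               bandwidth = h,
               weight = if (nTotal) length(p) / nTotal else 0,
               nEvents = length(p))
}

#' Relative density of one branch over the other two
#'
#' `R_b(x) = d_b(x) / max(d_b'(x) + d_b''(x), eps)`: the branch's weighted
#' substitution density divided by the summed densities of the other two
#' branches, with a small floor `eps` keeping the ratio finite where the
#' other branches carry no density.
#'
#' @param profiles List of three [DensityProfile-class] objects (one per
#'   branch, any order), sharing `L` and `h`.
#' @param eps Denominator floor in events per residue (default `1e-8`).
#' @return Named list of three [RelativeDensityProfile-class] objects.
#' @export
relativeDensity <- function(profiles, eps = 1e-8) {
  stopifnot(length(profiles) == 3L, eps > 0)
  br <- vapply(profiles, function(p) p@branch, character(1L))
  if (!setequal(br, BRANCHES)) stop("need one profile per trio branch")
  names(profiles) <- br
  Ls <- vapply(profiles, function(p) length(p@values), integer(1L))
  hs <- vapply(profiles, function(p) p@bandwidth, numeric(1L))
  if (length(unique(Ls)) != 1L) stop("profiles disagree in L")
  if (length(unique(hs)) != 1L) stop("profiles disagree in bandwidth")
  out <- lapply(stats::setNames(BRANCHES, BRANCHES), function(b) {
    others <- Reduce(`+`, lapply(setdiff(BRANCHES, b),
                                 function(o) profiles[[o]]@values))
    den <- pmax(others, eps)
    methods::new("RelativeDensityProfile", branch = b,
                 values = profiles[[b]]@values / den, eps = eps,
                 bandwidth = hs[1L], floored = others < eps)
  })
  out
}

#' Monte-Carlo null distribution for the relative-density scan
#'
#' Each simulation places `n_b` events per branch uniformly at random (with
#' replacement) on integer columns `1..L`, recomputes the relative-density
#' profile of every branch, and records its maximum over positions. The
#' per-branch threshold is the empirical `percentile`-th percentile of those
#' maxima: a profile value above it is reached anywhere in fewer than
#' `1 - percentile/100` of random substitution placements.
#'
#' `statistic = "pointwise"` additionally stores per-position thresholds
#' (the per-column percentile of the null relative density), a less
#' conservative sensitivity-analysis mode.
#'
#' @param n Named (or ordered outgroup/paralog1/paralog2) integer vector of
#'   per-branch event counts.
#' @param L Alignment length.
#' @param h Kernel standard deviation (residues).
#' @param eps Denominator floor, as in [relativeDensity()].
#' @param nSim Number of simulations (default 10000).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param percentile Threshold percentile (default 99).
#' @param statistic `"max"` (family-wise, default) or `"pointwise"`.
#' @return A [NullDistribution-class].
#' @export
simulateNull <- function(n, L, h = 15, eps = 1e-8, nSim = 10000L,
                         seed = 1L, percentile = 99,
                         statistic = c("max", "pointwise")) {
  statistic <- match.arg(statistic)
  if (is.null(names(n))) names(n) <- BRANCHES
  stopifnot(setequal(names(n), BRANCHES))
  n <- n[BRANCHES]
  nTotal <- sum(n)
  if (nTotal < 1L) stop("no null definable: n_total = 0")
  stopifnot(nSim >= 1L, L >= 1L, h > 0)
  set.seed(seed)
  pos <- lapply(n, function(nb)
    matrix(if (nb > 0L) sample.int(L, nb * nSim, replace = TRUE)
           else integer(), nrow = max(nb, 0L), ncol = nSim))
  kern <- .scanKernel(h)
  maxima <- cpp_null_maxima(pos[[1L]], pos[[2L]], pos[[3L]], as.integer(L),
                            kern, eps, 1 / nTotal)
  colnames(maxima) <- BRANCHES
  thresholds <- apply(maxima, 2L, quantile, probs = percentile / 100,
                      names = FALSE)
  pw <- matrix(numeric(), 0L, 3L)
  if (statistic == "pointwise") {
    if (nSim > 2000L)
      stop("pointwise mode stores the full null field; use nSim <= 2000")
    vals <- array(0, dim = c(L, 3L, nSim))
    for (s in seq_len(nSim)) {
      d <- vapply(seq_along(BRANCHES), function(b)
        cpp_density_profile(pos[[b]][, s], as.integer(L), kern, 1 / nTotal),
        numeric(L))
      for (b in 1:3) {
        den <- pmax(rowSums(d[, -b, drop = FALSE]), eps)
        vals[, b, s] <- d[, b] / den
      }
    }
    pw <- apply(vals, c(1L, 2L), quantile, probs = percentile / 100,
                names = FALSE)
    colnames(pw) <- BRANCHES
  }
  methods::new("NullDistribution", maxima = maxima,
               thresholds = stats::setNames(as.numeric(thresholds), BRANCHES),
               percentile = percentile, nSim = as.integer(nSim),
               seed = as.integer(seed), L = as.integer(L), bandwidth = h,
               eps = eps, pointwise = pw)
}

#' Null thresholds
#' @param null A [NullDistribution-class].
#' @return Named numeric vector of per-branch thresholds `q_b`.
#' @export
nullThresholds <- function(null) null@thresholds

#' Call hotspot regions from a relative-density profile
#'
#' Maximal runs of consecutive columns with `R_b(x)` strictly above the
#' branch threshold.
#'
#' @param profile A [RelativeDensityProfile-class].
#' @param threshold Scalar threshold `q_b` (e.g. from [nullThresholds()]), or
#'   a length-`L` vector for pointwise thresholds.
#' @return data.frame with columns `start`, `end`, `peak_x`, `peak_R`,
#'   `fold_over_threshold`; zero rows if nothing exceeds the threshold.
#' @export
callHotspots <- function(profile, threshold) {
  stopifnot(methods::is(profile, "RelativeDensityProfile"))
  v <- profile@values
  L <- length(v)
  thr <- if (length(threshold) == 1L) rep(threshold, L) else threshold
  if (length(thr) != L) stop("threshold length must be 1 or L")
  above <- v > thr
  if (!any(above))
    return(data.frame(start = integer(), end = integer(), peak_x = integer(),
                      peak_R = numeric(), fold_over_threshold = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- do.call(rbind, lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    pk <- i[which.max(v[i])]
    data.frame(start = starts[k], end = ends[k], peak_x = pk,
               peak_R = v[pk], fold_over_threshold = v[pk] / thr[pk])
  }))
  rownames(out) <- NULL
  out
}

#' Full hotspot scan of a trio event map
#'
#' Convenience wrapper chaining [substitutionDensity()], [relativeDensity()],
#' [simulateNull()] (with the observed per-branch counts) and
#' [callHotspots()] for every branch.
#'
#' @param map A [BranchEventMap-class].
#' @param h,eps,nSim,seed,percentile,statistic Passed through to the stages.
#' @param includeIndels Count indels in the densities (default `FALSE`).
#' @return List with elements `profiles` (densities), `relative`,
#'   `null` ([NullDistribution-class]) and `hotspots` (named list of
#'   data.frames per branch).
#' @export
scanTrio <- function(map, h = 15, eps = 1e-8, nSim = 10000L, seed = 1L,
                     percentile = 99, statistic = c("max", "pointwise"),
                     includeIndels = FALSE) {
  statistic <- match.arg(statistic)
  profiles <- lapply(stats::setNames(BRANCHES, BRANCHES), substitutionDensity,
                     map = map, h = h, includeIndels = includeIndels)
  rel <- relativeDensity(profiles, eps = eps)
  n <- lengths(.eventPositions(map, includeIndels))
  null <- simulateNull(n, map@L, h = h, eps = eps, nSim = nSim, seed = seed,
                       percentile = percentile, statistic = statistic)
  hot <- lapply(stats::setNames(BRANCHES, BRANCHES), function(b) {
    thr <- if (statistic == "pointwise") null@pointwise[, b] else
      null@thresholds[[b]]
    callHotspots(rel[[b]], thr)
  })
  list(profiles = profiles, relative = rel, null = null, hotspots = hot)
}

#' Per-position scan table
#'
#' @param scan Result of [scanTrio()].
#' @return data.frame: `column`, `d_outgroup`, `d_paralog1`, `d_paralog2`,
#'   `R_outgroup`, `R_paralog1`, `R_paralog2`.
#' @export
scanTable <- function(scan) {
  L <- scan$null@L
  out <- data.frame(column = seq_len(L))
  for (b in BRANCHES) out[[paste0("d_", b)]] <- scan$profiles[[b]]@values
  for (b in BRANCHES) out[[paste0("R_", b)]] <- scan$relative[[b]]@values
  out
}

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf(
    "DensityProfile [%s]: L = %d, h = %g, n = %d, w = %.3f, max = %.4g\n",
    object@branch, length(object@values), object@bandwidth, object@nEvents,
    object@weight, max(object@values)))
})

setMethod("show", "RelativeDensityProfile", function(object) {
  cat(sprintf("RelativeDensityProfile [%s]: L = %d, max R = %.3f\n",
              object@branch, length(object@values), max(object@values)))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d simulations, L = %d, h = %g, seed = %d\n",
              object@nSim, object@L, object@bandwidth, object@seed))
  cat(sprintf("  %g%% thresholds: %s\n", object@percentile,
              paste(sprintf("%s = %.3f", names(object@thresholds),
                            object@thresholds), collapse = ", ")))
})
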