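# Goldman-Yang codon substitution model with F3X4 frequencies: rate matrix,
# transition probabilities and the pruning log-likelihood.

.codonEnv <- new.env(parent = emptyenv())

# 61 sense codons (standard genetic code) and the pairwise change structure:
# which ordered pairs differ at exactly one nucleotide, whether that change
# is a transition, and whether it is nonsynonymous.
.codonStructure <- function() {
  if (!is.null(.codonEnv$codons)) return(as.list(.codonEnv))
  nts <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nts, nts, nts,
                             stringsAsFactors = FALSE)[, 3:1], 1L,
                 paste, collapse = "")
  codons <- all64[!all64 %in% STOP_CODONS]
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, ""))
  diffpos <- matrix(0L, n, n)
  for (k in 1:3) diffpos <- diffpos + outer(cm[, k], cm[, k], `!=`)
  oneNt <- diffpos == 1L
  isTs <- matrix(FALSE, n, n)
  purine <- cm %in% c("A", "G")
  dim(purine) <- dim(cm)
  for (k in 1:3) {
    diffk <- outer(cm[, k], cm[, k], `!=`)
    tsk <- outer(purine[, k], purine[, k], `==`)  # both purines or both pyr.
    isTs <- isTs | (diffk & tsk & diffpos == 1L)
  }
  isNonsyn <- outer(aa, aa, `!=`)
  list2env(list(codons = codons, aa = aa, oneNt = oneNt, isTs = isTs,
                isNonsyn = isNonsyn), .codonEnv)
  as.list(.codonEnv)
}

#' The 61 sense codons of the standard genetic code
#' @return Character vector of codons in the package's canonical order.
#' @export
senseCodons <- function() .codonStructure()$codons

#' F3X4 equilibrium codon frequencies
#'
#' Empirical nucleotide frequencies are computed separately at codon
#' positions 1, 2 and 3 across all sequences (gap and ambiguous characters
#' excluded), multiplied per codon, zeroed on stop codons and renormalized
#' over the 61 sense codons.
#'
#' @param x A [CodonAlignment-class].
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4Frequencies <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  st <- .codonStructure()
  s <- toupper(as.character(x@seqs))
  chars <- do.call(rbind, strsplit(s, ""))
  posIdx <- rep(1:3, length.out = ncol(chars))
  nts <- c("T", "C", "A", "G")
  f <- sapply(1:3, function(k) {
    cc <- chars[, posIdx == k, drop = FALSE]
    counts <- vapply(nts, function(b) sum(cc == b), numeric(1L))
    if (sum(counts) == 0)
      stop("codon position ", k, " has no unambiguous data")
    counts / sum(counts)
  })
  rownames(f) <- nts
  cm <- do.call(rbind, strsplit(st$codons, ""))
  pi <- f[cm[, 1L], 1L] * f[cm[, 2L], 2L] * f[cm[, 3L], 3L]
  pi <- pi / sum(pi)
  stats::setNames(pi, st$codons)
}

#' Goldman-Yang (GY94) instantaneous rate matrix
#'
#' Rates between codons differing at more than one nucleotide are 0; a single
#' nucleotide change to codon `d` has rate proportional to `pi_d`, multiplied
#' by `kappa` for transitions and by `omega` when the change is
#' nonsynonymous. The matrix is rescaled so that `-sum(pi * diag(Q)) = 1`,
#' i.e. branch lengths are in expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS (>= 0).
#' @param pi Codon frequencies over [senseCodons()].
#' @return 61 x 61 rate matrix with zero row sums.
#' @export
gy94RateMatrix <- function(kappa, omega, pi) {
  st <- .codonStructure()
  n <- length(st$codons)
  stopifnot(kappa > 0, omega >= 0, length(pi) == n)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6)
    stop("invalid pi: must be non-negative and sum to 1")
  mult <- st$oneNt * ifelse(st$isTs, kappa, 1) *
    ifelse(st$isNonsyn, omega, 1)
  Q <- mult * rep(pi, each = n)        # q_cd = mult_cd * pi_d
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(st$codons, st$codons)
  nu <- -sum(pi * diag(Q))
  if (nu <= 0) stop("degenerate rate matrix (no reachable states)")
  Q / nu
}

# Eigendecomposition of Q in the pi^{1/2}-symmetrized basis; GY94 is
# time-reversible so B = D^{1/2} Q D^{-1/2} is symmetric with real
# eigenvalues. P(t) = U1 diag(exp(lambda t)) U2.
.gyEigen <- function(kappa, omega, pi) {
  piSafe <- pmax(pi, 1e-10)
  piSafe <- piSafe / sum(piSafe)
  Q <- gy94RateMatrix(kappa, omega, piSafe)
  sq <- sqrt(piSafe)
  B <- (sq * Q) / rep(sq, each = length(sq))   # D^{1/2} Q D^{-1/2}
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U1 = e$vectors / sq, U2 = t(e$vectors) * rep(sq, each = length(sq)),
       lambda = e$values)
}

.gyTransition <- function(eig, t) {
  P <- eig$U1 %*% (exp(eig$lambda * t) * eig$U2)
  P[P < 0] <- 0
  P
}

#' GY94 transition probability matrix
#'
#' @param kappa,omega,pi As in [gy94RateMatrix()].
#' @param t Branch length (expected substitutions per codon).
#' @return 61 x 61 row-stochastic matrix `exp(Q t)`.
#' @export
gy94TransitionMatrix <- function(kappa, omega, pi, t) {
  stopifnot(t >= 0)
  P <- .gyTransition(.gyEigen(kappa, omega, pi), t)
  dimnames(P) <- list(senseCodons(), senseCodons())
  P
}

# --- alignment/tree preprocessing for the likelihood ---------------------

.codonCodes <- function(x) {
  st <- .codonStructure()
  m <- toupper(.codonMatrix(x))
  codes <- match(m, st$codons)          # NA for gaps/ambiguous codons
  dim(codes) <- dim(m)
  rownames(codes) <- names(x@seqs)
  codes
}

# Site-pattern compression plus postorder edge traversal data.
.codonData <- function(aln, ltree, dropGapped = FALSE) {
  tr <- ltree@tree
  codes <- .codonCodes(aln)
  miss <- setdiff(tr$tip.label, rownames(codes))
  if (length(miss))
    stop("leaf names missing from alignment: ", paste(miss, collapse = ", "))
  codes <- codes[tr$tip.label, , drop = FALSE]
  if (dropGapped) {
    keep <- colSums(is.na(codes)) == 0L
    codes <- codes[, keep, drop = FALSE]
    if (!ncol(codes)) stop("no ungapped codon columns left")
  }
  key <- apply(codes, 2L, paste, collapse = "_")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  patterns <- codes[, first, drop = FALSE]
  po <- ape::reorder.phylo(tr, "postorder")
  list(patterns = patterns, weights = weights, nPat = sum(first),
       edge = po$edge, edgeOrder = match(paste(po$edge[, 1], po$edge[, 2]),
                                         paste(tr$edge[, 1], tr$edge[, 2])),
       nTip = length(tr$tip.label), root = length(tr$tip.label) + 1L,
       nNode = tr$Nnode, foreground = ltree@foreground)
}

# Pruning log-likelihood. `eigs` is a list of eigendecompositions indexed by
# omega class; `classIdx` maps each edge (original order) to an eigs entry;
# `t` holds branch lengths in original edge order.
.pruneLogLik <- function(data, eigs, classIdx, t, pi) {
  nPat <- data$nPat
  partials <- vector("list", data$nTip + data$nNode)
  logScale <- numeric(nPat)
  rescale <- data$nTip > 8L   # deep trees only; shallow products cannot underflow
  nEdges <- nrow(data$edge)
  for (i in seq_len(nEdges)) {
    parent <- data$edge[i, 1L]
    child <- data$edge[i, 2L]
    origIdx <- data$edgeOrder[i]
    P <- .gyTransition(eigs[[classIdx[origIdx]]], t[origIdx])
    if (child <= data$nTip) {
      cc <- data$patterns[child, ]
      contrib <- matrix(1, 61L, nPat)
      ok <- !is.na(cc)
      contrib[, ok] <- P[, cc[ok]]
    } else {
      contrib <- P %*% partials[[child]]
    }
    cur <- partials[[parent]]
    cur <- if (is.null(cur)) contrib else cur * contrib
    if (rescale) {
      mx <- apply(cur, 2L, max)
      bad <- mx < 1e-200 & mx > 0
      if (any(bad)) {
        cur[, bad] <- cur[, bad, drop = FALSE] / rep(mx[bad], each = 61L)
        logScale[bad] <- logScale[bad] + log(mx[bad])
      }
    }
    partials[[parent]] <- cur
  }
  site <- colSums(pmax(pi, 1e-10) / sum(pmax(pi, 1e-10)) *
                    partials[[data$root]])
  if (any(site <= 0)) return(-Inf)
  sum(data$weights * (log(site) + logScale))
}

#' Codon-model log-likelihood by Felsenstein pruning
#'
#' Sums, over codon columns, the log probability of the observed tip codons
#' under the GY94 model with per-branch-class dN/dS, using postorder pruning
#' with transition matrices `exp(Q_b t_b)`. Gap or ambiguous codons are
#' treated as missing data (partial likelihood 1 over all states).
#'
#' @param aln A [CodonAlignment-class]; ids must cover the tree's leaves.
#' @param tree A [LabeledTree-class]. Branch lengths are taken from
#'   `branchLengths` if given, else from the tree.
#' @param kappa Transition/transversion ratio.
#' @param omega Either a single dN/dS (one-ratio) or a named vector
#'   `c(background = ..., foreground = ...)` resolved through the tree's
#'   foreground flags.
#' @param pi Codon frequencies; default [f3x4Frequencies()] of `aln`.
#' @param branchLengths Optional numeric, one per edge (tree edge order).
#' @param dropGapped Drop codon columns containing any gap instead of
#'   treating them as missing.
#' @return Log-likelihood (scalar).
#' @export
codonLogLikelihood <- function(aln, tree, kappa, omega, pi = NULL,
                               branchLengths = NULL, dropGapped = FALSE) {
  stopifnot(methods::is(aln, "CodonAlignment"),
            methods::is(tree, "LabeledTree"))
  data <- .codonData(aln, tree, dropGapped)
  if (is.null(pi)) pi <- f3x4Frequencies(aln)
  t <- if (!is.null(branchLengths)) branchLengths else
    tree@tree$edge.length
  if (is.null(t)) stop("no branch lengths available")
  if (length(t) != nrow(tree@tree$edge))
    stop("branchLengths must have one entry per edge")
  if (length(omega) == 1L && is.null(names(omega)))
    omega <- c(all = unname(omega))
  if (identical(names(omega), "all")) {
    eigs <- list(all = .gyEigen(kappa, omega[["all"]], pi))
    classIdx <- rep("all", length(t))
  } else {
    if (!setequal(names(omega), c("background", "foreground")))
      stop("omega must be scalar or named background/foreground")
    if (!any(data$foreground) || all(data$foreground))
      stop("two-ratio model needs >= 1 foreground and >= 1 background branch")
    eigs <- list(background = .gyEigen(kappa, omega[["background"]], pi),
                 foreground = .gyEigen(kappa, omega[["foreground"]], pi))
    classIdx <- ifelse(data$foreground, "foreground", "background")
  }
  lnL <- .pruneLogLik(data, eigs, classIdx, t, pi)
  if (!is.finite(lnL) && lnL != -Inf)
    stop("non-finite likelihood")
  lnL
}
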