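# Independent straight-line oracles, deliberately avoiding the package's
# computational paths (no kernel truncation, expm instead of the symmetrized
# eigendecomposition, explicit enumeration instead of pruning).

# Monte-Carlo null for the relative-density scan: plain dnorm sums.
oracleNullMaxima <- function(n, L, h, eps, nSim, seed) {
  set.seed(seed)
  nTotal <- sum(n)
  out <- matrix(0, nSim, 3)
  xs <- seq_len(L)
  for (s in seq_len(nSim)) {
    d <- sapply(1:3, function(b) {
      p <- sample.int(L, n[b], replace = TRUE)
      rowSums(vapply(p, function(pp) dnorm(xs, pp, h), numeric(L))) / nTotal
    })
    for (b in 1:3) {
      den <- pmax(rowSums(d[, -b, drop = FALSE]), eps)
      out[s, b] <- max(d[, b] / den)
    }
  }
  out
}

# Exhaustive ancestral-state enumeration of the codon-model likelihood on a
# small ape tree; transition matrices via Matrix::expm.
oracleCodonLogLik <- function(phy, codes, kappa, omega, pi, foreground) {
  edges <- phy$edge
  nTip <- length(phy$tip.label)
  nNode <- phy$Nnode
  Qb <- gy94RateMatrix(kappa,
                       if (is.null(names(omega))) omega else
                         omega[["background"]], pi)
  Qf <- if (is.null(names(omega))) Qb else
    gy94RateMatrix(kappa, omega[["foreground"]], pi)
  P <- lapply(seq_len(nrow(edges)), function(e) {
    Q <- if (foreground[e]) Qf else Qb
    as.matrix(Matrix::expm(Q * phy$edge.length[e]))
  })
  internals <- (nTip + 1L):(nTip + nNode)
  grid <- do.call(expand.grid, rep(list(1:61), nNode))
  root <- nTip + 1L
  lnL <- 0
  for (col in seq_len(ncol(codes))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- unlist(grid[g, ])
      stateOf <- function(node) {
        if (node <= nTip) codes[node, col] else assign[node - nTip]
      }
      term <- unname(pi[assign[1L]])
      for (e in seq_len(nrow(edges))) {
        cs <- stateOf(edges[e, 2L])
        if (is.na(cs)) next                 # missing tip: sums to 1
        ps <- stateOf(edges[e, 1L])
        term <- term * P[[e]][ps, cs]
      }
      tot <- tot + term
    }
    lnL <- lnL + log(tot)
  }
  lnL
}

# codon codes (1..61 in the package's canonical order) for a CodonAlignment,
# rows ordered to match the tree's tip labels
tipCodes <- function(aln, phy) {
  s <- as.character(aln@seqs)[phy$tip.label]
  ncod <- nchar(s[1L]) %/% 3L
  starts <- seq(1L, by = 3L, length.out = ncod)
  m <- t(vapply(s, function(x) substring(x, starts, starts + 2L),
                character(ncod)))
  codes <- match(toupper(m), senseCodons())
  dim(codes) <- dim(m)
  codes
}

# standard-code amino-acid degeneracies (independent hand enumeration)
AA_DEGENERACY <- c(A = 4, R = 6, N = 2, D = 2, C = 2, Q = 2, E = 2, G = 4,
                   H = 2, I = 3, L = 6, K = 2, M = 1, F = 2, P = 4, S = 6,
                   T = 4, W = 1, Y = 2, V = 4)

# random valid protein alignment (no X) for property tests
randomTrio <- function(L, seed, gapProb = 0) {
  set.seed(seed)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  m <- matrix(sample(aas, 3 * L, replace = TRUE), nrow = 3)
  if (gapProb > 0) m[runif(3 * L) < gapProb] <- "-"
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- c("og", "p1", "p2")
  ProteinAlignment(seqs, roles = c(og = "outgroup", p1 = "paralog1",
                                   p2 = "paralog2"))
}

# brute-force substitution-event counter on residue-only columns
bruteSubstCount <- function(trio) {
  m <- t(vapply(as.character(trio@seqs),
                function(z) strsplit(z, "")[[1L]],
                character(nchar(as.character(trio@seqs)[1L]))))
  n <- 0L
  for (j in seq_len(ncol(m))) {
    a <- m[, j]
    if (any(a == "X") || any(a == "-")) next
    u <- length(unique(a))
    n <- n + if (u == 1L) 0L else if (u == 2L) 1L else 3L
  }
  n
}
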