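test_that("F3X4 frequencies follow the positional product construction", {
  # balanced nucleotide usage at every codon position -> uniform over 61
  aln <- CodonAlignment(c(s = "AAACCCGGGTTT"))
  pi <- f3x4Frequencies(aln)
  expect_equal(length(pi), 61L)
  expect_equal(sum(pi), 1)
  expect_equal(unname(pi), rep(1 / 61, 61), tolerance = 1e-12)
  # single-codon alignment concentrates mass on A-rich codons
  pa <- f3x4Frequencies(CodonAlignment(c(s = "AAAAAA")))
  expect_equal(sum(pa), 1)
  expect_equal(unname(pa[["AAA"]]), 1)
  # hand-computed product for a small gapped alignment: codons present are
  # ATG, AAA, ATG, --- so position-1 counts are A:3, position-2 T:2 A:1,
  # position-3 G:2 A:1; only A{T,A}{G,A} codons get nonzero mass (none are
  # stops) and those products already sum to 1
  small <- CodonAlignment(c(a = "ATGAAA", b = "ATG---"))
  ph <- f3x4Frequencies(small)
  expect_equal(unname(ph[["ATG"]]), (2/3) * (2/3), tolerance = 1e-12)
  expect_equal(unname(ph[["AAA"]]), (1/3) * (1/3), tolerance = 1e-12)
  expect_equal(unname(ph[["ATA"]]), (2/3) * (1/3), tolerance = 1e-12)
})

test_that("F3X4 errors when a codon position has no data", {
  aln <- methods::new("CodonAlignment",
                      seqs = Biostrings::DNAStringSet(c(a = "A-N")))
  expect_error(f3x4Frequencies(aln), "position 2")
})

test_that("the GY94 generator has zero row sums, reversibility and unit scale", {
  pi <- f3x4Frequencies(CodonAlignment(c(s = "AAACCCGGGTTT")))
  Q <- gy94RateMatrix(kappa = 3, omega = 0.4, pi = pi)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance pi_c q_cd = pi_d q_dc
  F <- pi * Q
  expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-14)
  # omega = 0 silences exactly the nonsynonymous moves
  Q0 <- gy94RateMatrix(kappa = 3, omega = 0, pi = pi)
  aa <- Biostrings::GENETIC_CODE[senseCodons()]
  nonsyn <- outer(aa, aa, `!=`)
  expect_true(all(Q0[nonsyn] == 0))
  expect_true(any(Q0[!nonsyn & upper.tri(Q0)] > 0))
  # multi-nucleotide changes are forbidden
  expect_equal(Q["AAA", "ACC"], 0)
  # kappa and omega act multiplicatively on single-nucleotide changes:
  # TTT->TTC is a synonymous transition, TTT->TTA a nonsynonymous transversion
  k <- 3; w <- 0.4
  Qk <- gy94RateMatrix(k, w, pi)
  expect_equal(Qk["TTT", "TTC"] / Qk["TTT", "TTA"],
               (k * pi[["TTC"]]) / (w * pi[["TTA"]]), tolerance = 1e-12)
})

test_that("transition matrices are stochastic and stationary", {
  pi <- f3x4Frequencies(CodonAlignment(c(s = "ATGAAACCCGGGTTTCAG")))
  for (t in c(0, 0.05, 0.7)) {
    P <- gy94TransitionMatrix(2, 0.3, pi, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(as.numeric(pi %*% P), unname(pi), tolerance = 1e-9)
  }
  expect_equal(gy94TransitionMatrix(2, 0.3, pi, 0), diag(61),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("degenerate tree: zero branch lengths give the stationary likelihood", {
  seqs <- c(a = "ATGAAATTT", b = "ATGAAATTT", c = "ATGAAATTT")
  aln <- CodonAlignment(seqs)
  tree <- readNewickTree("(a:0,b:0,c:0);")
  pi <- f3x4Frequencies(aln)
  lnL <- codonLogLikelihood(aln, tree, kappa = 2, omega = 0.5, pi = pi)
  expect_equal(lnL, sum(log(pi[c("ATG", "AAA", "TTT")])), tolerance = 1e-8)
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  pi <- f3x4Frequencies(CodonAlignment(c(s = "ATGAAACCCGGGTTTCAGCTA")))
  # 3 taxa, one internal node
  aln3 <- CodonAlignment(c(a = "ATGAAA", b = "ATGCAA", c = "TTGAAA"))
  tr3 <- readNewickTree("(a:0.2,b:0.15,c:0.4);")
  lnL <- codonLogLikelihood(aln3, tr3, 2.5, 0.3, pi = pi)
  oracle <- oracleCodonLogLik(tr3@tree, tipCodes(aln3, tr3@tree),
                              2.5, 0.3, pi, tr3@foreground)
  expect_equal(lnL, oracle, tolerance = 1e-8)
  # 4 taxa, two internal nodes, two-ratio model, 3 columns with a gap codon
  aln4 <- CodonAlignment(c(a = "ATGAAACCC", b = "ATGCAACCC",
                           c = "TTGAAA---", d = "TTGTCACCG"))
  tr4 <- readNewickTree("(a:0.2,b:0.3,(c:0.15,d:0.25)#1:0.1);")
  om <- c(background = 0.2, foreground = 1.7)
  lnL4 <- codonLogLikelihood(aln4, tr4, 2, om, pi = pi)
  oracle4 <- oracleCodonLogLik(tr4@tree, tipCodes(aln4, tr4@tree),
                               2, om, pi, tr4@foreground)
  expect_equal(lnL4, oracle4, tolerance = 1e-8)
})

test_that("likelihood is invariant to consistent taxon relabeling", {
  pi <- f3x4Frequencies(CodonAlignment(c(s = "ATGAAACCCGGGTTTCAG")))
  aln <- CodonAlignment(c(a = "ATGAAA", b = "ATGCAA", c = "TTGAAA"))
  tr <- readNewickTree("(a:0.2,b:0.15,c:0.4);")
  ren <- CodonAlignment(c(x = "ATGAAA", y = "ATGCAA", z = "TTGAAA"))
  trRen <- readNewickTree("(x:0.2,y:0.15,z:0.4);")
  expect_equal(codonLogLikelihood(aln, tr, 2, 0.3, pi = pi),
               codonLogLikelihood(ren, trRen, 2, 0.3, pi = pi))
})

test_that("gap codons act as missing data", {
  pi <- f3x4Frequencies(CodonAlignment(c(s = "ATGAAACCCGGGTTTCAG")))
  tr <- readNewickTree("(a:0.2,b:0.15,c:0.4);")
  withGap <- CodonAlignment(c(a = "ATGAAA", b = "ATGCAA", c = "TTG---"))
  noCol <- CodonAlignment(c(a = "ATG", b = "ATG", c = "TTG"))
  one <- CodonAlignment(c(a = "AAA", b = "CAA", c = "AAA"))
  # all-missing column contributes sum(pi) = 1, i.e. zero log-likelihood
  allGap <- CodonAlignment(c(a = "ATG---", b = "ATG---", c = "TTG---"))
  expect_equal(codonLogLikelihood(withGap, tr, 2, 0.3, pi = pi),
               codonLogLikelihood(noCol, tr, 2, 0.3, pi = pi) +
                 oracleCodonLogLik(tr@tree,
                                   matrix(c(match("AAA", senseCodons()),
                                            match("CAA", senseCodons()), NA),
                                          ncol = 1),
                                   2, 0.3, pi, tr@foreground),
               tolerance = 1e-8)
  expect_equal(codonLogLikelihood(allGap, tr, 2, 0.3, pi = pi),
               codonLogLikelihood(noCol, tr, 2, 0.3, pi = pi),
               tolerance = 1e-10)
  # dropGapped removes the gapped column entirely
  expect_equal(codonLogLikelihood(withGap, tr, 2, 0.3, pi = pi,
                                  dropGapped = TRUE),
               codonLogLikelihood(noCol, tr, 2, 0.3, pi = pi),
               tolerance = 1e-10)
})
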