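test_that("all simulators are reproducible from their seed", {
  a <- simulateCodonTrio(80, c(outgroup = 0.3, paralog1 = 0.05,
                               paralog2 = 0.05), seed = 5)
  b <- simulateCodonTrio(80, c(outgroup = 0.3, paralog1 = 0.05,
                               paralog2 = 0.05), seed = 5)
  expect_identical(as.character(a$alignment@seqs),
                   as.character(b$alignment@seqs))
  expect_identical(a$ledger, b$ledger)
  tr <- readNewickTree("(x:0.2,y:0.1,z:0.1);")
  expect_identical(
    as.character(simulateMultitaxonCodon(tr, 2, 0.3, 50, seed = 2)@seqs),
    as.character(simulateMultitaxonCodon(tr, 2, 0.3, 50, seed = 2)@seqs))
  expect_identical(simulateTraces("step", seed = 3)@current,
                   simulateTraces("step", seed = 3)@current)
  expect_identical(simulateExpressionTable(c(gA = 10), seed = 4),
                   simulateExpressionTable(c(gA = 10), seed = 4))
  m1 <- simulateEventMap(c(10L, 5L, 5L), 100, seed = 6)
  m2 <- simulateEventMap(c(10L, 5L, 5L), 100, seed = 6)
  expect_identical(eventTable(m1), eventTable(m2))
})

test_that("the trio ledger matches its alignment and honours omega limits", {
  sim <- simulateCodonTrio(120, c(outgroup = 0.4, paralog1 = 0.1,
                                  paralog2 = 0), omega = c(outgroup = 0,
                                  paralog1 = 0.5, paralog2 = 0.5), seed = 9)
  led <- sim$ledger
  # omega = 0 branch: no nonsynonymous events
  expect_equal(sum(led$type == "nonsynonymous" & led$branch == "outgroup"),
               0L)
  # zero-length branch: no events at all, child equals root
  expect_equal(sum(led$branch == "paralog2"), 0L)
  # every ledger event stays inside the alignment
  expect_true(all(led$column >= 1 & led$column <= 120))
  # nonsynonymous events change the amino acid; synonymous do not
  expect_true(all((led$aaFrom != led$aaTo) ==
                    (led$type == "nonsynonymous")))
})

test_that("parsimony mapping agrees with the ledger for well-separated trios", {
  sim <- simulateCodonTrio(400, c(outgroup = 0.25, paralog1 = 0.04,
                                  paralog2 = 0.04),
                           omega = c(outgroup = 0.15, paralog1 = 1,
                                     paralog2 = 0.15), seed = 17)
  m <- assignEvents(sim$protein)
  # columns whose final amino acid differs on exactly one branch are the
  # parsimony-visible events; mapped totals cannot exceed ledger activity
  aaChanged <- with(sim$ledger, tapply(type == "nonsynonymous", branch, sum))
  for (b in intersect(names(aaChanged), names(eventTotals(m))))
    expect_lte(eventTotals(m)[[b]], aaChanged[[b]] + 5L)
  expect_gt(sum(eventTotals(m)), 0L)
})

test_that("hotspot windows concentrate nonsynonymous events", {
  win <- data.frame(start = 41, end = 60, mult = 15, branch = "paralog1")
  sim <- simulateCodonTrio(200, c(outgroup = 0.1, paralog1 = 0.08,
                                  paralog2 = 0.08),
                           omega = 0.4, hotspotWindows = win, seed = 23)
  led <- sim$ledger
  ns <- led[led$type == "nonsynonymous" & led$branch == "paralog1", ]
  inWin <- mean(ns$column >= 41 & ns$column <= 60)
  expect_gt(inWin, 0.4)      # 10% of columns carry >40% of events
  expect_error(simulateCodonTrio(100, c(outgroup = 0.1, paralog1 = 0.1,
                                        paralog2 = 0.1),
                                 hotspotWindows = data.frame(
                                   start = 90, end = 120, mult = 2,
                                   branch = "paralog1"), seed = 1),
               "invalid hotspot windows")
})

test_that("without a hotspot, nonsynonymous events are uniform over columns", {
  counts <- numeric(10)
  for (s in 1:25) {
    sim <- simulateCodonTrio(300, c(outgroup = 0.15, paralog1 = 0.1,
                                    paralog2 = 0.1), omega = 0.8,
                             seed = 100 + s)
    ns <- sim$ledger$column[sim$ledger$type == "nonsynonymous"]
    counts <- counts + tabulate(ceiling(ns / 30), nbins = 10)
  }
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("endpoint simulation respects zero-length branches", {
  tr <- readNewickTree("(a:0,b:0.3);")
  aln <- simulateMultitaxonCodon(tr, 2, 0.5, 60, seed = 8)
  tr0 <- readNewickTree("(a:0,b:0);")
  aln0 <- simulateMultitaxonCodon(tr0, 2, 0.5, 60, seed = 8)
  s0 <- as.character(aln0@seqs)
  expect_identical(s0[["a"]], s0[["b"]])   # both copies of the root
  expect_false(identical(as.character(aln@seqs)[["a"]],
                         as.character(aln@seqs)[["b"]]))
})

test_that("noiseless traces decay to the persistent floor by pulse end", {
  x <- simulateTraces("step", persistentFrac = 0, gLeak = 0, noiseSd = 0,
                      tauH = 3, seed = 1)
  j <- which(x@sweeps$voltage == -20)
  i <- x@current[, j]
  pk <- max(abs(i))
  expect_lt(abs(i[length(i)]), 0.01 * pk)
  # g_max = 0 gives pure leak, which leak subtraction zeroes (elsewhere)
  x6 <- simulateTraces("step", persistentFrac = 0.06, gLeak = 0,
                       noiseSd = 0, seed = 1)
  i6 <- x6@current[, which(x6@sweeps$voltage == -20)]
  expect_gt(abs(i6[length(i6)]), 0.04 * max(abs(i6)))
})

test_that("expression tables honour zero dispersion exactly", {
  mm <- matrix(c(50, 150), 2, 1, dimnames = list(c("gA", "gB"), "m"))
  df <- simulateExpressionTable(mm, replicates = 2, dispersion = 0,
                                nTransfrags = 2, nIsoforms = 3, seed = 1)
  ag <- aggregateGeneExpression(df, "sum_isoforms_then_mean")
  expect_true(all(ag$abundance[ag$gene == "gA"] == 50))
  expect_true(all(ag$abundance[ag$gene == "gB"] == 150))
  sh <- scaleByTotalChannelExpression(ag, c("gA", "gB"))
  expect_equal(sort(unique(round(sh$share, 12))), c(0.25, 0.75))
})

test_that("event-map hotspots multiply local density as specified", {
  m <- simulateEventMap(c(outgroup = 0L, paralog1 = 4000L, paralog2 = 0L),
                        L = 1000, hotspotWindow = c(101, 200),
                        hotspotMult = 10, seed = 3)
  pos <- eventTable(m)$column
  inWin <- mean(pos >= 101 & pos <= 200)
  # expected share: 10*100 / (10*100 + 900) ~ 0.526
  expect_equal(inWin, 1000 / 1900, tolerance = 0.05)
})
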