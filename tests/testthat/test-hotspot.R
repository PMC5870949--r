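mapFrom <- function(og = integer(), p1 = integer(), p2 = integer(), L)
  branchEventMap(list(outgroup = og, paralog1 = p1, paralog2 = p2), L)

test_that("kernel density matches Gaussian closed forms", {
  # single event, full weight: peak value is the Gaussian mode 1/(h sqrt(2 pi))
  m <- mapFrom(p1 = 50L, L = 200L)
  d <- substitutionDensity(m, "paralog1", h = 15)
  expect_equal(d@values[50], 1 / (15 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(d@weight, 1)
  # two events at 40 and 70: midpoint value is twice the kernel at z = 1
  m2 <- mapFrom(p1 = c(40L, 70L), L = 200L)
  d2 <- substitutionDensity(m2, "paralog1", h = 15)
  expect_equal(d2@values[55],
               2 * (1 / (15 * sqrt(2 * pi))) * exp(-0.5) * (1 / 2),
               tolerance = 1e-6)
})

test_that("profile mass approximates the branch weight for interior events", {
  set.seed(2)
  pos <- sample(200:1600, 10)
  m <- mapFrom(og = sample(200:1600, 30), p1 = pos, L = 1800L)
  d <- substitutionDensity(m, "paralog1", h = 15)
  expect_equal(d@weight, 0.25)
  expect_equal(sum(d@values), 0.25, tolerance = 0.005)
  # empty branch gives a zero profile
  expect_true(all(substitutionDensity(m, "paralog2")@values == 0))
})

test_that("relative density follows the ratio definition with a floor", {
  mk <- function(vals, branch) methods::new("DensityProfile",
    branch = branch, values = vals, bandwidth = 15, weight = 0.3,
    nEvents = 1L)
  pr <- list(mk(rep(0.02, 5), "outgroup"), mk(rep(0.005, 5), "paralog1"),
             mk(rep(0.005, 5), "paralog2"))
  r <- relativeDensity(pr, eps = 1e-8)
  expect_equal(r$outgroup@values, rep(2, 5))      # twice the other two
  eq <- list(mk(rep(0.01, 5), "outgroup"), mk(rep(0.01, 5), "paralog1"),
             mk(rep(0.01, 5), "paralog2"))
  re <- relativeDensity(eq)
  expect_equal(re$paralog1@values, rep(0.5, 5))
  z <- list(mk(rep(0.02, 5), "outgroup"), mk(rep(0, 5), "paralog1"),
            mk(rep(0, 5), "paralog2"))
  rz <- relativeDensity(z, eps = 1e-8)
  expect_equal(rz$outgroup@values, rep(0.02 / 1e-8, 5))
  expect_true(all(rz$outgroup@floored))
  bad <- list(mk(rep(0.01, 5), "outgroup"), mk(rep(0.01, 6), "paralog1"),
              mk(rep(0.01, 5), "paralog2"))
  expect_error(relativeDensity(bad), "disagree in L")
})

test_that("the null simulation is reproducible and rejects degenerate input", {
  n <- c(outgroup = 20L, paralog1 = 10L, paralog2 = 10L)
  a <- simulateNull(n, 300, nSim = 200, seed = 42)
  b <- simulateNull(n, 300, nSim = 200, seed = 42)
  expect_identical(a@maxima, b@maxima)
  expect_identical(a@thresholds, b@thresholds)
  expect_error(simulateNull(c(outgroup = 0L, paralog1 = 0L, paralog2 = 0L),
                            300, nSim = 10), "n_total = 0")
})

test_that("null thresholds agree with an independent Monte-Carlo oracle", {
  n <- c(20L, 15L, 15L); L <- 200L; h <- 15; eps <- 1e-8
  pkg <- simulateNull(setNames(n, c("outgroup", "paralog1", "paralog2")),
                      L, h = h, eps = eps, nSim = 1500, seed = 7)
  orc <- oracleNullMaxima(n, L, h, eps, nSim = 1500, seed = 99)
  for (b in 1:3) {
    qPkg <- unname(pkg@thresholds[b])
    qOrc <- quantile(orc[, b], 0.99, names = FALSE)
    # bootstrap spread of the oracle's 99th percentile
    bootSd <- sd(replicate(200, quantile(sample(orc[, b], replace = TRUE),
                                         0.99, names = FALSE)))
    expect_lt(abs(qPkg - qOrc), 5 * bootSd)
  }
})

test_that("hotspot calling returns maximal runs above threshold", {
  prof <- methods::new("RelativeDensityProfile", branch = "paralog1",
                       values = c(0.1, 0.2, 1.5, 2.0, 1.2, 0.3, 0.9, 1.1),
                       eps = 1e-8, bandwidth = 15, floored = rep(FALSE, 8))
  h <- callHotspots(prof, 1.0)
  expect_equal(h$start, c(3L, 8L))
  expect_equal(h$end, c(5L, 8L))
  expect_equal(h$peak_x, c(4L, 8L))
  expect_equal(h$fold_over_threshold, c(2.0, 1.1))
  expect_equal(nrow(callHotspots(prof, 5)), 0L)
})

test_that("a constructed dense cluster is called and overlaps its window", {
  # dense outgroup/paralog2 branches keep the denominator of the relative
  # density well above the floor everywhere, as in real trios; 12 of the 32
  # paralog1 events are packed into columns 300-320
  set.seed(31)
  m <- mapFrom(og = sample.int(1800, 300, replace = TRUE),
               p1 = c(sample(300:320, 12, replace = TRUE),
                      sample.int(1800, 20, replace = TRUE)),
               p2 = sample.int(1800, 180, replace = TRUE), L = 1800L)
  scan <- scanTrio(m, nSim = 500, seed = 8)
  called <- scan$hotspots$paralog1
  expect_gte(nrow(called), 1L)
  expect_true(any(called$start <= 320 & called$end >= 300))
})

test_that("adding an event never decreases that branch's relative density", {
  base <- mapFrom(og = c(100L, 500L), p1 = c(250L, 700L), p2 = 400L,
                  L = 800L)
  more <- mapFrom(og = c(100L, 500L), p1 = c(250L, 700L, 420L), p2 = 400L,
                  L = 800L)
  relAt <- function(m, x) {
    pr <- lapply(setNames(c("outgroup", "paralog1", "paralog2"),
                          c("outgroup", "paralog1", "paralog2")),
                 substitutionDensity, map = m)
    relativeDensity(pr)$paralog1@values[x]
  }
  expect_gte(relAt(more, 420), relAt(base, 420))
})

test_that("pointwise thresholds are less conservative than the max statistic", {
  n <- c(outgroup = 30L, paralog1 = 20L, paralog2 = 20L)
  nd <- simulateNull(n, 400, nSim = 300, seed = 5, statistic = "pointwise")
  expect_equal(dim(nd@pointwise), c(400L, 3L))
  expect_true(all(nd@pointwise[, "paralog1"] <=
                    nd@thresholds[["paralog1"]] + 1e-12))
})

test_that("pointwise thresholds give high power against a 10-fold window", {
  # the sensitivity-analysis mode trades family-wise control for per-column
  # calibration; a 10-fold 20-column enrichment is then readily detected
  det <- 0L
  for (i in 1:20) {
    m <- simulateEventMap(c(outgroup = 300L, paralog1 = 180L,
                            paralog2 = 180L), 1800L,
                          hotspotWindow = c(300L, 319L), hotspotMult = 10,
                          seed = 1000L + i)
    sc <- scanTrio(m, nSim = 1000L, seed = 70000L + i,
                   statistic = "pointwise")
    h <- sc$hotspots$paralog1
    det <- det + as.integer(nrow(h) > 0 &&
                              any(h$start <= 319L & h$end >= 300L))
  }
  expect_gte(det, 15L)
})

test_that("the scan table exposes densities and ratios per column", {
  m <- mapFrom(og = 10L, p1 = 20L, p2 = 30L, L = 50L)
  sc <- scanTrio(m, nSim = 50, seed = 2)
  tab <- scanTable(sc)
  expect_equal(nrow(tab), 50L)
  expect_named(tab, c("column", "d_outgroup", "d_paralog1", "d_paralog2",
                      "R_outgroup", "R_paralog1", "R_paralog2"))
  expect_equal(tab$d_outgroup[10], sc$profiles$outgroup@values[10])
})
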