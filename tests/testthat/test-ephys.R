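test_that("leak subtraction cancels pure leak exactly and is identity on empty traces", {
  pure <- simulateTraces("step", gMax = 0, gLeak = 0.003, noiseSd = 0,
                         seed = 1)
  corr <- leakSubtract(pure)
  expect_lt(max(abs(corr@current)), 1e-10)
  empty <- simulateTraces("step", gMax = 0, gLeak = 0, noiseSd = 0,
                          seed = 1)
  expect_lt(max(abs(leakSubtract(empty)@current)), 1e-10)
  # with channel current present, a zero-leak family is perturbed only by
  # the activation-curve foot leaking into the fit window (<0.5% of peak)
  none <- simulateTraces("step", gMax = 0.2, gLeak = 0, noiseSd = 0,
                         seed = 1)
  same <- leakSubtract(none)
  expect_lt(max(abs(same@current - none@current)),
            0.005 * max(abs(none@current)))
})

test_that("leak subtraction leaves channel current intact above threshold", {
  leaky <- simulateTraces("step", gLeak = 0.002, noiseSd = 0, seed = 3)
  clean <- simulateTraces("step", gLeak = 0, noiseSd = 0, seed = 3)
  corr <- leakSubtract(leaky)
  peak <- max(abs(clean@current))
  sub <- which(corr@sweeps$voltage <= -100)
  expect_lt(max(abs(corr@current[, sub])), 5e-3)
  supra <- which(corr@sweeps$voltage >= -40)
  expect_lt(max(abs(corr@current[, supra] - clean@current[, supra])),
            0.005 * peak)
})

test_that("explicit leak coefficients subtract without subthreshold sweeps", {
  leaky <- simulateTraces("recovery", gLeak = 0.002, noiseSd = 0, seed = 3)
  clean <- simulateTraces("recovery", gLeak = 0, noiseSd = 0, seed = 3)
  corr <- leakSubtract(leaky, coefficients = c(0.002, 0))
  expect_lt(max(abs(corr@current - clean@current)), 1e-9)
  expect_error(leakSubtract(leaky), "subthreshold")
})

test_that("persistent percentage is ~0 without a floor and 100% for flat current", {
  clean <- simulateTraces("step", persistentFrac = 0, gLeak = 0,
                          noiseSd = 0, seed = 1)
  pp <- suppressWarnings(persistentPercent(clean))
  tab <- persistentTable(pp)
  # evaluate where inactivation is complete at steady state (V >= -20);
  # nearer threshold the equilibrium open fraction is itself nonzero
  strong <- tab$included & tab$voltage >= -20
  expect_lt(max(abs(tab$pctPersistent[strong])), 0.3)
  # non-inactivating rectangular current
  tm <- seq(0, 31.98, by = 0.02)
  cur <- matrix(ifelse(tm >= 2, -5, 0), ncol = 1)
  rect <- voltageClampTraceSet(tm, cur,
                               data.frame(sweep = 1, voltage = -20,
                                          tag = "step"),
                               protocol = list(baseline_ms = 2,
                                               pulse_ms = 30))
  rpp <- persistentTable(persistentPercent(rect))
  expect_equal(rpp$pctPersistent, 100, tolerance = 0.5)
})

test_that("a 6% persistent floor is recovered through the noisy leaky pipeline", {
  noisy <- leakSubtract(simulateTraces("step", persistentFrac = 0.06,
                                       seed = 8))
  est <- persistentTable(suppressWarnings(persistentPercent(noisy)))
  clean <- simulateTraces("step", persistentFrac = 0.06, gLeak = 0,
                          noiseSd = 0, seed = 8)
  truth <- persistentTable(suppressWarnings(persistentPercent(clean)))
  for (v in c(-35, -20, 0)) {
    expect_lt(abs(est$pctPersistent[est$voltage == v] -
                    truth$pctPersistent[truth$voltage == v]), 0.5)
  }
})

test_that("sweeps below the noise floor are excluded with a warning", {
  x <- simulateTraces("step", gMax = 0.2, gLeak = 0, noiseSd = 0.02,
                      seed = 2)
  expect_warning(pp <- persistentPercent(x), "noise floor")
  tab <- persistentTable(pp)
  expect_true(all(is.na(tab$pctPersistent[!tab$included])))
  expect_true(all(tab$voltage[!tab$included] < -60))
})

test_that("G-V fits recover the generator's conductance curve", {
  x <- leakSubtract(simulateTraces("step", seed = 4))
  gv <- gvCurve(x, eRev = 50)
  expect_true(gv@converged)
  expect_lt(abs(gv@v50 - (-40)), 1)
  expect_lt(abs(gv@slope - 7), 0.5)
  expect_equal(gv@pedestal, 0)
  # the fitted curve passes through one half at V50 by definition
  expect_equal(1 / (1 + exp((gv@v50 - gv@v50) / gv@slope)), 0.5)
  # sweep order does not matter
  rev <- x
  ord <- rev(seq_len(ncol(x@current)))
  rev@current <- x@current[, ord]
  rev@sweeps <- x@sweeps[ord, ]
  gv2 <- gvCurve(rev, eRev = 50)
  expect_equal(gv2@v50, gv@v50, tolerance = 1e-6)
})

test_that("SSI fits recover midpoint, slope and pedestal", {
  x0 <- simulateTraces("ssi", persistentFrac = 0, gLeak = 0, seed = 5)
  s0 <- ssiCurve(x0)
  expect_true(s0@converged)
  expect_lt(abs(s0@v50 - (-70)), 1.5)
  expect_lt(s0@pedestal, 0.02)
  # availability at very negative conditioning is ~1
  av <- s0@data$value[which.min(s0@data$voltage)]
  expect_lt(abs(av - 1), 0.05)
  x5 <- simulateTraces("ssi", persistentFrac = 0.05, gLeak = 0, seed = 5)
  s5 <- ssiCurve(x5)
  expect_lt(abs(s5@pedestal - 0.05), 0.02)
})

test_that("recovery fractions follow the generator's closed form", {
  x <- simulateTraces("recovery", gLeak = 0, noiseSd = 0, tauRec = 2,
                      seed = 6)
  tab <- recoveryTable(recoveryFractions(x))
  f05 <- tab$fraction[tab$interval == 0.5]
  expect_lt(abs(f05 - (1 - exp(-0.25))), 0.01)
  expect_lt(abs(tab$fraction[tab$interval == 1.0] - (1 - exp(-0.5))), 0.01)
  # monotone non-decreasing on noiseless input, and -> 1 at long intervals
  expect_true(all(diff(tab$fraction) >= -1e-9))
  expect_lt(abs(tab$fraction[which.max(tab$interval)] - 1), 0.01)
})

test_that("recovery analysis requires paired conditioning sweeps", {
  x <- simulateTraces("recovery", gLeak = 0, seed = 6)
  drop <- x@sweeps$role != "cond" | x@sweeps$interval != 0.5
  x@current <- x@current[, drop]
  x@sweeps <- x@sweeps[drop, ]
  expect_error(recoveryFractions(x), "missing conditioning")
})

test_that("trace sets survive the CSV + JSON round trip", {
  x <- simulateTraces("step", voltages = seq(-120, -60, by = 20), seed = 9)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeTraceSet(x, csv, js)
  back <- readTraceSet(csv, js)
  expect_equal(back@current, x@current, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back@sweeps$voltage, x@sweeps$voltage)
  expect_equal(back@samplingRate, x@samplingRate)
  expect_equal(back@protocol$pulse_ms, x@protocol$pulse_ms)
  unlink(c(csv, js))
})
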