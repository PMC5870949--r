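# Quantification of persistent sodium current, activation and steady-state
# inactivation curves, and recovery from inactivation from voltage-clamp
# trace sets.

#' Construct a VoltageClampTraceSet
#'
#' @param time Sample times in ms (shared across sweeps, starting at 0 =
#'   start of the pre-pulse baseline).
#' @param current Matrix of currents, samples x sweeps.
#' @param sweeps data.frame of per-sweep metadata (`sweep`, `voltage`, `tag`,
#'   optionally `role` and `interval` for recovery sweeps).
#' @param samplingRate Hz (default 50000).
#' @param holdingPotential mV (default -120).
#' @param protocol List; must include `baseline_ms` and `pulse_ms`.
#' @return A [VoltageClampTraceSet-class].
#' @export
voltageClampTraceSet <- function(time, current, sweeps,
                                 samplingRate = 50000,
                                 holdingPotential = -120,
                                 protocol = list()) {
  if (is.null(protocol$baseline_ms)) protocol$baseline_ms <- 0
  if (is.null(protocol$pulse_ms))
    protocol$pulse_ms <- max(time) - protocol$baseline_ms
  methods::new("VoltageClampTraceSet", time = time,
               current = as.matrix(current), sweeps = sweeps,
               samplingRate = samplingRate,
               holdingPotential = holdingPotential, protocol = protocol)
}

#' Per-sweep metadata
#' @param x A [VoltageClampTraceSet-class].
#' @return data.frame of sweep metadata.
#' @export
sweepInfo <- function(x) x@sweeps

.pulseWindow <- function(x) {
  b <- x@protocol$baseline_ms
  c(b, b + x@protocol$pulse_ms)
}

# command voltage at each sample for sweep j (baseline/holding outside pulse)
.commandVoltage <- function(x, j) {
  w <- .pulseWindow(x)
  ifelse(x@time >= w[1L] & x@time < w[2L], x@sweeps$voltage[j],
         x@holdingPotential)
}

# zero-phase low-pass (Butterworth, 4-pole) mirroring acquisition filtering
.lowpass <- function(i, fs, cutHz = 10000) {
  Wn <- cutHz / (fs / 2)
  if (Wn >= 1 || length(i) < 24L) return(i)
  bf <- signal::butter(4, Wn, type = "low")
  as.numeric(signal::filtfilt(bf, i))
}

# signed extremum of the (filtered) current within the pulse
.sweepPeak <- function(x, j, filterKHz = 10) {
  w <- .pulseWindow(x)
  idx <- which(x@time >= w[1L] & x@time < w[2L])
  f <- .lowpass(x@current[, j], x@samplingRate, filterKHz * 1000)
  f[idx][which.max(abs(f[idx]))]
}

#' Linear leak subtraction
#'
#' Fits a linear conductance and offset, `I = g_leak V + b`, to the
#' steady-state current of subthreshold step sweeps (default: steps at or
#' below -100 mV, where channel conductance is negligible even on the
#' Boltzmann foot of the activation curve), and subtracts the predicted leak
#' from every sample of every sweep using each sweep's command voltage (step
#' voltage during the pulse, holding elsewhere).
#'
#' @param x A [VoltageClampTraceSet-class] containing step sweeps (not
#'   needed when `coefficients` is supplied).
#' @param leakMax Most depolarized step voltage considered pure leak
#'   (default -100 mV).
#' @param coefficients Optional `c(g_leak, offset)` fitted elsewhere (e.g.
#'   on the step family of the same cell), subtracted directly; used to
#'   leak-correct SSI or recovery families that contain no subthreshold
#'   steps of their own.
#' @return The trace set with leak removed; the fitted `g_leak` (conductance
#'   per mV) and offset are recorded in `protocol$leak_fit`.
#' @export
leakSubtract <- function(x, leakMax = -100, coefficients = NULL) {
  stopifnot(methods::is(x, "VoltageClampTraceSet"))
  if (is.null(coefficients)) {
    sub <- which(x@sweeps$tag == "step" & x@sweeps$voltage <= leakMax)
    if (length(sub) < 2L)
      stop("need >= 2 subthreshold sweeps (steps <= ", leakMax,
           " mV) to fit leak")
    w <- .pulseWindow(x)
    late <- x@time >= w[1L] + 0.5 * diff(w) & x@time < w[2L]
    iss <- vapply(sub, function(j) mean(x@current[late, j]), numeric(1L))
    vv <- x@sweeps$voltage[sub]
    fit <- lm(iss ~ vv)
    b <- coef(fit)[[1L]]; g <- coef(fit)[[2L]]
  } else {
    g <- coefficients[[1L]]; b <- coefficients[[2L]]; sub <- integer()
  }
  for (j in seq_len(ncol(x@current)))
    x@current[, j] <- x@current[, j] - (g * .commandVoltage(x, j) + b)
  x@protocol$leak_fit <- list(g_leak = g, offset = b, sweeps_used = sub)
  x
}

#' Persistent-current percentage per sweep
#'
#' For each step sweep, `%I_NAP = 100 * I_late / I_peak`, where `I_late` is
#' the mean current over the terminal `windowMs` of the `pulseMs` pulse and
#' `I_peak` the extremum of the low-pass-filtered current within the pulse.
#' Both carry the inward-negative sign, so the ratio is positive for a
#' persistent inward current. Sweeps whose peak does not exceed
#' `noiseFloorK` times the pre-pulse baseline SD are excluded with a
#' warning. Run [leakSubtract()] first.
#'
#' @param x A leak-subtracted [VoltageClampTraceSet-class].
#' @param pulseMs Pulse duration (default: protocol value, nominally 30 ms).
#' @param windowMs Terminal averaging window (default 0.5 ms).
#' @param noiseFloorK Peak inclusion threshold in baseline SDs (default 3).
#' @param filterKHz Low-pass cutoff for peak detection (default 10).
#' @return A [PersistentCurrentResult-class].
#' @export
persistentPercent <- function(x, pulseMs = NULL, windowMs = 0.5,
                              noiseFloorK = 3, filterKHz = 10) {
  stopifnot(methods::is(x, "VoltageClampTraceSet"))
  if (is.null(pulseMs)) pulseMs <- x@protocol$pulse_ms
  stopifnot(pulseMs >= windowMs)
  b0 <- x@protocol$baseline_ms
  js <- which(x@sweeps$tag == "step")
  base <- x@time < b0
  lateWin <- x@time >= b0 + pulseMs - windowMs & x@time < b0 + pulseMs
  rows <- lapply(js, function(j) {
    noise <- if (any(base)) sd(x@current[base, j]) else 0
    pk <- .sweepPeak(x, j, filterKHz)
    late <- mean(x@current[lateWin, j])
    ok <- abs(pk) > noiseFloorK * noise
    data.frame(sweep = x@sweeps$sweep[j], voltage = x@sweeps$voltage[j],
               iPeak = pk, iLate = late,
               pctPersistent = if (ok) 100 * late / pk else NA_real_,
               included = ok)
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$included))
    warning(sum(!tab$included),
            " sweep(s) below the noise floor excluded from %I_NAP")
  methods::new("PersistentCurrentResult", table = tab, pulseMs = pulseMs,
               windowMs = windowMs)
}

#' Persistent-current table
#' @param x A [PersistentCurrentResult-class].
#' @return data.frame with per-sweep peak, late current and `%I_NAP`.
#' @export
persistentTable <- function(x) x@table

.boltzmannFit <- function(df, pedestalFree) {
  # df: voltage, value (normalized 0..1)
  v50_0 <- df$voltage[which.min(abs(df$value - 0.5))]
  st <- list(v50 = v50_0, k = 7)
  fit <- NULL
  if (pedestalFree) {
    fit <- tryCatch(minpack.lm::nlsLM(
      value ~ a + (1 - a) / (1 + exp((voltage - v50) / k)),
      data = df, start = c(st, list(a = max(0.01, min(df$value)))),
      lower = c(v50 = -150, k = 0.1, a = 0),
      upper = c(v50 = 50, k = 40, a = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(minpack.lm::nlsLM(
      value ~ 1 / (1 + exp((v50 - voltage) / k)),
      data = df, start = st,
      lower = c(v50 = -150, k = 0.1), upper = c(v50 = 50, k = 40),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit))
    return(methods::new("BoltzmannFit", v50 = NA_real_, slope = NA_real_,
                        amplitude = NA_real_, pedestal = NA_real_,
                        residualNorm = NA_real_, converged = FALSE,
                        data = df))
  cf <- coef(fit)
  methods::new("BoltzmannFit", v50 = unname(cf["v50"]),
               slope = unname(cf["k"]), amplitude = 1,
               pedestal = if (pedestalFree) unname(cf["a"]) else 0,
               residualNorm = sum(stats::residuals(fit)^2),
               converged = TRUE, data = df)
}

#' Conductance-voltage (activation) curve with Boltzmann fit
#'
#' Peak currents of the step family are converted to conductances,
#' `G(V) = I_peak / (V - E_rev)`, normalized to their maximum and fitted
#' with `G/G_max = 1 / (1 + exp((V50 - V) / k))` (no pedestal).
#'
#' @param x A leak-subtracted [VoltageClampTraceSet-class] (step sweeps).
#' @param eRev Reversal potential in mV.
#' @param vMin Most negative step included (default: all); steps within 1 mV
#'   of `eRev` are always excluded.
#' @param filterKHz Peak-detection filter cutoff.
#' @return A [BoltzmannFit-class] (pedestal fixed at 0).
#' @export
gvCurve <- function(x, eRev, vMin = -Inf, filterKHz = 10) {
  js <- which(x@sweeps$tag == "step" & x@sweeps$voltage >= vMin &
                abs(x@sweeps$voltage - eRev) > 1)
  if (length(js) < 4L) stop("need >= 4 usable step sweeps")
  v <- x@sweeps$voltage[js]
  pk <- vapply(js, function(j) .sweepPeak(x, j, filterKHz), numeric(1L))
  g <- pk / (v - eRev)
  g <- pmax(g, 0)
  df <- data.frame(voltage = v, value = g / max(g))
  df <- df[order(df$voltage), ]
  .boltzmannFit(df, pedestalFree = FALSE)
}

#' Steady-state inactivation curve with pedestal
#'
#' Test-pulse peak currents indexed by conditioning voltage are normalized to
#' the maximum available current and fitted with
#' `a + (1 - a) / (1 + exp((V_cond - V50) / k))`, the pedestal `a` free in
#' `[0, 1]` (a non-inactivating channel fraction shows up as `a > 0`).
#'
#' @param x A leak-subtracted (or leak-free) [VoltageClampTraceSet-class]
#'   whose `ssi` sweeps hold the test pulse recorded after each conditioning
#'   voltage (the `voltage` column is the conditioning voltage). SSI families
#'   carry no subthreshold steps, so pass the step family's leak fit to
#'   [leakSubtract()] via `coefficients` first.
#' @param filterKHz Peak-detection filter cutoff.
#' @return A [BoltzmannFit-class] with a free pedestal.
#' @export
ssiCurve <- function(x, filterKHz = 10) {
  js <- which(x@sweeps$tag == "ssi")
  if (length(js) < 5L) stop("need >= 5 conditioning voltages")
  v <- x@sweeps$voltage[js]
  pk <- vapply(js, function(j) .sweepPeak(x, j, filterKHz), numeric(1L))
  avail <- abs(pk) / max(abs(pk))
  df <- data.frame(voltage = v, value = avail)
  df <- df[order(df$voltage), ]
  .boltzmannFit(df, pedestalFree = TRUE)
}

#' Fractional recovery from inactivation
#'
#' For each recovery interval, the ratio of the test-pulse peak to its
#' paired conditioning-pulse peak, `f(dt) = I_peak,test / I_peak,cond`.
#'
#' @param x A leak-subtracted (or leak-free) [VoltageClampTraceSet-class]
#'   whose `recovery` sweeps carry `role` (`"cond"`/`"test"`) and `interval`
#'   (ms) columns; an uncorrected leak offset biases the small test-pulse
#'   peaks (see [leakSubtract()]'s `coefficients`).
#' @param intervals Optional subset of intervals to report (default all).
#' @param filterKHz Peak-detection filter cutoff.
#' @return A [RecoveryResult-class], intervals in increasing order.
#' @export
recoveryFractions <- function(x, intervals = NULL, filterKHz = 10) {
  sw <- x@sweeps
  js <- which(sw$tag == "recovery")
  if (!length(js)) stop("no recovery sweeps")
  if (!all(c("role", "interval") %in% names(sw)))
    stop("recovery sweeps need 'role' and 'interval' metadata")
  ivs <- sort(unique(sw$interval[js]))
  if (!is.null(intervals)) ivs <- ivs[ivs %in% intervals]
  rows <- lapply(ivs, function(dt) {
    jc <- js[sw$interval[js] == dt & sw$role[js] == "cond"]
    jt <- js[sw$interval[js] == dt & sw$role[js] == "test"]
    if (!length(jc)) stop("missing conditioning sweep for interval ", dt)
    if (!length(jt)) stop("missing test sweep for interval ", dt)
    f <- abs(.sweepPeak(x, jt[1L], filterKHz)) /
      abs(.sweepPeak(x, jc[1L], filterKHz))
    data.frame(interval = dt, fraction = f)
  })
  methods::new("RecoveryResult", table = do.call(rbind, rows))
}

#' Recovery table
#' @param x A [RecoveryResult-class].
#' @return data.frame `interval`, `fraction`.
#' @export
recoveryTable <- function(x) x@table

#' Write a trace set as long CSV + JSON protocol descriptor
#'
#' @param x A [VoltageClampTraceSet-class].
#' @param csvPath Long-format CSV (`time_ms`, `sweep_id`, `current`).
#' @param jsonPath Sidecar JSON with sweep metadata and protocol.
#' @return `csvPath`, invisibly.
#' @export
writeTraceSet <- function(x, csvPath, jsonPath) {
  long <- data.frame(time_ms = rep(x@time, ncol(x@current)),
                     sweep_id = rep(x@sweeps$sweep, each = length(x@time)),
                     current = as.vector(x@current))
  utils::write.csv(long, csvPath, row.names = FALSE)
  meta <- list(sweeps = x@sweeps, sampling_rate_hz = x@samplingRate,
               holding_potential_mv = x@holdingPotential,
               protocol = x@protocol)
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read a trace set written by [writeTraceSet()]
#'
#' @param csvPath,jsonPath Paths as in [writeTraceSet()].
#' @return A [VoltageClampTraceSet-class].
#' @export
readTraceSet <- function(csvPath, jsonPath) {
  long <- utils::read.csv(csvPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  sweeps <- as.data.frame(meta$sweeps)
  ids <- unique(long$sweep_id)
  tm <- long$time_ms[long$sweep_id == ids[1L]]
  cur <- vapply(sweeps$sweep, function(s) long$current[long$sweep_id == s],
                numeric(length(tm)))
  voltageClampTraceSet(tm, cur, sweeps,
                       samplingRate = meta$sampling_rate_hz,
                       holdingPotential = meta$holding_potential_mv,
                       protocol = meta$protocol)
}

setMethod("show", "VoltageClampTraceSet", function(object) {
  cat(sprintf(paste0("VoltageClampTraceSet: %d sweeps x %d samples ",
                     "@ %g kHz, holding %g mV\n"),
              ncol(object@current), nrow(object@current),
              object@samplingRate / 1000, object@holdingPotential))
  cat(sprintf("  tags: %s\n",
              paste(names(table(object@sweeps$tag)),
                    table(object@sweeps$tag), collapse = ", ")))
})

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf(paste0("BoltzmannFit: V50 = %.2f mV, k = %.2f mV, ",
                     "pedestal = %.3f%s\n"),
              object@v50, object@slope, object@pedestal,
              if (object@converged) "" else "  (NOT converged)"))
})
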