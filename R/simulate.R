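# Synthetic-data generators: every analysis stage has a generator producing
# inputs with the statistical structure that stage assumes, plus a ledger of
# the true parameters, so recovery can be tested without external downloads.

#' Simulate a trio event map by direct placement
#'
#' Places `n_b` events per branch on integer columns `1..L` uniformly at
#' random (with replacement), optionally with a hotspot window on one branch
#' inside which the local event density is `hotspotMult`-fold the uniform
#' background (event positions are drawn with weight `hotspotMult` inside
#' the window and 1 outside).
#'
#' @param n Named (outgroup/paralog1/paralog2) or ordered integer vector of
#'   per-branch event counts.
#' @param L Alignment length.
#' @param hotspotWindow Optional `c(start, end)` columns of the hotspot.
#' @param hotspotMult Local density multiplier (>= 1).
#' @param hotspotBranch Branch carrying the hotspot (default `"paralog1"`).
#' @param seed Integer seed.
#' @return A [BranchEventMap-class] of substitution events.
#' @export
simulateEventMap <- function(n, L, hotspotWindow = NULL, hotspotMult = 1,
                             hotspotBranch = "paralog1", seed = 1L) {
  if (is.null(names(n))) names(n) <- BRANCHES
  stopifnot(setequal(names(n), BRANCHES), hotspotMult >= 1)
  set.seed(seed)
  w <- rep(1, L)
  if (!is.null(hotspotWindow)) {
    stopifnot(length(hotspotWindow) == 2L, hotspotWindow[1L] >= 1,
              hotspotWindow[2L] <= L)
    w[hotspotWindow[1L]:hotspotWindow[2L]] <- hotspotMult
  }
  pos <- lapply(stats::setNames(BRANCHES, BRANCHES), function(b) {
    if (n[[b]] == 0L) return(integer())
    if (!is.null(hotspotWindow) && b == hotspotBranch)
      sample.int(L, n[[b]], replace = TRUE, prob = w)
    else sample.int(L, n[[b]], replace = TRUE)
  })
  branchEventMap(pos, L)
}

.uniformPi <- function() {
  cods <- senseCodons()
  stats::setNames(rep(1 / length(cods), length(cods)), cods)
}

# per-branch syn/nonsyn rate components for the jump-process simulator
.gyParts <- function(kappa, omega, pi) {
  st <- .codonStructure()
  base <- st$oneNt * ifelse(st$isTs, kappa, 1) *
    rep(pi, each = length(pi))
  Msyn <- base * !st$isNonsyn
  Mns <- base * st$isNonsyn * omega
  nu <- sum(pi * (rowSums(Msyn) + rowSums(Mns)))
  list(Msyn = Msyn / nu, Mns = Mns / nu,
       rSyn = rowSums(Msyn) / nu, rNs = rowSums(Mns) / nu)
}

#' Simulate a codon trio with an explicit substitution ledger
#'
#' A root codon sequence is drawn from `pi`; each of the three branches then
#' evolves every site by a GY94 jump process with the branch's dN/dS, with
#' the nonsynonymous rate multiplied by `mult` inside any hotspot window on
#' that branch. Every realized substitution is recorded in a ledger (branch,
#' codon column, from/to codon, synonymous or not), so downstream
#' parsimony-mapping accuracy can be audited against truth.
#'
#' @param L Number of codon columns.
#' @param branchLengths Named numeric (outgroup/paralog1/paralog2), expected
#'   substitutions per codon at hotspot multiplier 1.
#' @param kappa Transition/transversion ratio (default 2).
#' @param omega Named per-branch dN/dS (scalar recycled).
#' @param hotspotWindows Optional data.frame with columns `start`, `end`,
#'   `mult` (>= 1), `branch` (codon-column windows of elevated
#'   nonsynonymous rate).
#' @param pi Root/equilibrium codon frequencies (default uniform over the
#'   61 sense codons).
#' @param seed Integer seed; alignments and ledger are reproducible from it.
#' @return List: `alignment` (3-taxon [CodonAlignment-class], records named
#'   outgroup/paralog1/paralog2), `ledger` (data.frame of true events) and
#'   `protein` (the translated [ProteinAlignment-class] with trio roles).
#' @export
simulateCodonTrio <- function(L, branchLengths, kappa = 2, omega = 0.2,
                              hotspotWindows = NULL, pi = NULL, seed = 1L) {
  if (is.null(names(branchLengths))) names(branchLengths) <- BRANCHES
  stopifnot(setequal(names(branchLengths), BRANCHES))
  if (length(omega) == 1L)
    omega <- stats::setNames(rep(omega, 3L), BRANCHES)
  if (is.null(pi)) pi <- .uniformPi()
  if (!is.null(hotspotWindows)) {
    stopifnot(all(c("start", "end", "mult", "branch") %in%
                    names(hotspotWindows)))
    if (any(hotspotWindows$start < 1L) || any(hotspotWindows$end > L) ||
        any(hotspotWindows$start > hotspotWindows$end))
      stop("invalid hotspot windows")
    if (any(hotspotWindows$mult < 1)) stop("multipliers must be >= 1")
  }
  st <- .codonStructure()
  set.seed(seed)
  root <- sample.int(61L, L, replace = TRUE, prob = pi)
  seqs <- list()
  ledger <- list()
  for (b in BRANCHES) {
    parts <- .gyParts(kappa, omega[[b]], pi)
    mult <- rep(1, L)
    if (!is.null(hotspotWindows)) {
      hw <- hotspotWindows[hotspotWindows$branch == b, , drop = FALSE]
      for (r in seq_len(nrow(hw)))
        mult[hw$start[r]:hw$end[r]] <- hw$mult[r]
    }
    tb <- branchLengths[[b]]
    cur <- root
    for (s in seq_len(L)) {
      tm <- 0
      repeat {
        rate <- parts$rSyn[cur[s]] + mult[s] * parts$rNs[cur[s]]
        if (rate <= 0) break
        tm <- tm + rexp(1L, rate)
        if (tm > tb) break
        pNs <- mult[s] * parts$rNs[cur[s]] / rate
        nonsyn <- runif(1L) < pNs
        row <- if (nonsyn) parts$Mns[cur[s], ] else parts$Msyn[cur[s], ]
        dest <- sample.int(61L, 1L, prob = row)
        ledger[[length(ledger) + 1L]] <- data.frame(
          branch = b, column = s,
          from = st$codons[cur[s]], to = st$codons[dest],
          type = if (nonsyn) "nonsynonymous" else "synonymous",
          aaFrom = st$aa[cur[s]], aaTo = st$aa[dest])
        cur[s] <- dest
      }
    }
    seqs[[b]] <- paste(st$codons[cur], collapse = "")
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(branch = character(), column = integer(), from = character(),
               to = character(), type = character(), aaFrom = character(),
               aaTo = character())
  aln <- CodonAlignment(unlist(seqs))
  prot <- translateCodons(aln, roles = stats::setNames(BRANCHES, BRANCHES))
  list(alignment = aln, ledger = ledger, protein = prot)
}

#' Simulate a multi-taxon codon alignment under a branch model
#'
#' Endpoint sampling down the tree: the root codon is drawn from `pi` and
#' each branch applies its GY94 transition matrix `exp(Q_b t_b)`, with the
#' foreground branches of the tree using the foreground dN/dS.
#'
#' @param tree A [LabeledTree-class] with branch lengths.
#' @param kappa Transition/transversion ratio.
#' @param omega Scalar dN/dS or named `c(background = , foreground = )`.
#' @param L Number of codon columns.
#' @param pi Codon frequencies (default uniform).
#' @param seed Integer seed.
#' @return A [CodonAlignment-class] over the tree's tips.
#' @export
simulateMultitaxonCodon <- function(tree, kappa, omega, L, pi = NULL,
                                    seed = 1L) {
  stopifnot(methods::is(tree, "LabeledTree"))
  if (is.null(pi)) pi <- .uniformPi()
  tr <- tree@tree
  if (is.null(tr$edge.length)) stop("tree needs branch lengths")
  if (length(omega) == 1L && is.null(names(omega)))
    omega <- c(background = unname(omega), foreground = unname(omega))
  set.seed(seed)
  eigBg <- .gyEigen(kappa, omega[["background"]], pi)
  eigFg <- if (omega[["foreground"]] == omega[["background"]]) eigBg else
    .gyEigen(kappa, omega[["foreground"]], pi)
  nTip <- length(tr$tip.label)
  nNode <- tr$Nnode
  states <- matrix(NA_integer_, nTip + nNode, L)
  root <- nTip + 1L
  states[root, ] <- sample.int(61L, L, replace = TRUE, prob = pi)
  ord <- rev(ape::postorder(tr))       # parent-before-child traversal
  for (e in ord) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    P <- .gyTransition(if (tree@foreground[e]) eigFg else eigBg,
                       tr$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(L)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(61L, length(idx), replace = TRUE,
                            prob = pmax(P[s, ], 0))
    }
    states[child, ] <- cs
  }
  cods <- senseCodons()
  seqs <- vapply(seq_len(nTip),
                 function(i) paste(cods[states[i, ]], collapse = ""),
                 character(1L))
  names(seqs) <- tr$tip.label
  CodonAlignment(seqs)
}

.boltz <- function(v, v50, k) 1 / (1 + exp((v50 - v) / k))

#' Simulate voltage-clamp trace families
#'
#' Hodgkin-Huxley-style m^3 h channel with a persistent floor:
#' `i(t) = gMax m(t)^3 ((1 - p) h(t) + p) (V - eRev) + gLeak V + noise`,
#' with `m` and `h` first-order relaxations toward their voltage-dependent
#' steady states. Three protocols are generated: a step family (pre-pulse
#' baseline at holding, then `pulseMs` at each step voltage); steady-state
#' inactivation (`ssi`: a test pulse whose initial availability reflects a
#' long conditioning pulse at each conditioning voltage); and paired-pulse
#' recovery (`recovery`: conditioning and test pulses separated by a
#' recovery interval at holding, availability re-priming with `tauRec`).
#'
#' @param protocol `"step"`, `"ssi"` or `"recovery"`.
#' @param voltages Step voltages (mV) for the step family.
#' @param condVoltages Conditioning voltages for `ssi`.
#' @param intervals Recovery intervals (ms) for `recovery`.
#' @param gMax Maximal conductance (uA/mV).
#' @param eRev Reversal potential (mV).
#' @param vHalfAct,kAct Activation midpoint/slope (mV).
#' @param vHalfInact,kInact Inactivation midpoint/slope (mV).
#' @param tauM,tauH Activation/inactivation time constants (ms).
#' @param persistentFrac Persistent (non-inactivating) fraction `p` in [0,1].
#' @param tauRec Recovery-from-inactivation time constant (ms).
#' @param gLeak Linear leak conductance (uA/mV).
#' @param noiseSd Additive Gaussian noise SD (uA).
#' @param samplingRate Hz (default 50000).
#' @param holding Holding potential (mV, default -120).
#' @param baselineMs Pre-pulse baseline duration (ms).
#' @param pulseMs Step-pulse duration (ms, default 30).
#' @param testV Test-pulse voltage for `ssi`/`recovery` (mV).
#' @param testMs Test-pulse duration for `ssi`/`recovery` (ms, default 20).
#' @param seed Integer seed.
#' @return A [VoltageClampTraceSet-class].
#' @export
simulateTraces <- function(protocol = c("step", "ssi", "recovery"),
                           voltages = seq(-120, 20, by = 5),
                           condVoltages = seq(-120, -10, by = 10),
                           intervals = c(0.5, 1, 2, 5, 10, 20, 50),
                           gMax = 0.2, eRev = 50,
                           vHalfAct = -40, kAct = 7,
                           vHalfInact = -70, kInact = 7,
                           tauM = 0.1, tauH = 3, persistentFrac = 0,
                           tauRec = 2, gLeak = 0.002, noiseSd = 0.02,
                           samplingRate = 50000, holding = -120,
                           baselineMs = 2, pulseMs = 30,
                           testV = -20, testMs = 20, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(tauM > 0, tauH > 0, tauRec > 0,
            persistentFrac >= 0, persistentFrac <= 1)
  p <- persistentFrac
  set.seed(seed)
  dt <- 1000 / samplingRate
  # vHalfAct/kAct describe the steady-state conductance (G-V) curve, the
  # quantity an activation analysis reports; the m gate is its cube root so
  # that mInf(V)^3 is exactly Boltzmann(vHalfAct, kAct)
  mInf <- function(v) .boltz(v, vHalfAct, kAct)^(1 / 3)
  hInf <- function(v) 1 - .boltz(v, vHalfInact, kInact)

  sweepTrace <- function(v, dur, m0, h0) {
    tt <- seq(0, baselineMs + dur - dt, by = dt)
    inPulse <- tt >= baselineMs
    tp <- tt - baselineMs
    m <- ifelse(inPulse,
                mInf(v) + (m0 - mInf(v)) * exp(-tp / tauM), m0)
    h <- ifelse(inPulse,
                hInf(v) + (h0 - hInf(v)) * exp(-tp / tauH), h0)
    vv <- ifelse(inPulse, v, holding)
    ich <- gMax * m^3 * ((1 - p) * h + p) * (vv - eRev)
    # channel closed at holding: gates sit at their holding steady state
    ich[!inPulse] <- gMax * m0^3 * ((1 - p) * h0 + p) * (holding - eRev)
    i <- ich + gLeak * vv + rnorm(length(tt), 0, noiseSd)
    list(time = tt, current = i)
  }

  m0 <- mInf(holding); h0hold <- hInf(holding)
  if (protocol == "step") {
    voltages <- sort(voltages)
    tr <- lapply(voltages, function(v) sweepTrace(v, pulseMs, m0, h0hold))
    cur <- vapply(tr, `[[`, numeric(length(tr[[1L]]$time)), "current")
    sweeps <- data.frame(sweep = seq_along(voltages), voltage = voltages,
                         tag = "step")
    prot <- list(baseline_ms = baselineMs, pulse_ms = pulseMs)
  } else if (protocol == "ssi") {
    condVoltages <- sort(condVoltages)
    # long conditioning equilibrates availability at hInf(Vcond); the test
    # pulse starts from that availability (the brief pre-test gap is not
    # modelled -- see the methods vignette)
    tr <- lapply(condVoltages, function(vc)
      sweepTrace(testV, testMs, m0, hInf(vc)))
    cur <- vapply(tr, `[[`, numeric(length(tr[[1L]]$time)), "current")
    sweeps <- data.frame(sweep = seq_along(condVoltages),
                         voltage = condVoltages, tag = "ssi")
    prot <- list(baseline_ms = baselineMs, pulse_ms = testMs,
                 conditioning_ms = 500, test_voltage = testV)
  } else {
    intervals <- sort(intervals)
    hEnd <- hInf(testV) + (h0hold - hInf(testV)) * exp(-testMs / tauH)
    rows <- list(); trs <- list(); k <- 0L
    for (iv in intervals) {
      k <- k + 1L
      trs[[k]] <- sweepTrace(testV, testMs, m0, h0hold)
      rows[[k]] <- data.frame(sweep = k, voltage = testV, tag = "recovery",
                              role = "cond", interval = iv)
      hRec <- h0hold - (h0hold - hEnd) * exp(-iv / tauRec)
      k <- k + 1L
      trs[[k]] <- sweepTrace(testV, testMs, m0, hRec)
      rows[[k]] <- data.frame(sweep = k, voltage = testV, tag = "recovery",
                              role = "test", interval = iv)
    }
    cur <- vapply(trs, `[[`, numeric(length(trs[[1L]]$time)), "current")
    sweeps <- do.call(rbind, rows)
    tr <- trs
    prot <- list(baseline_ms = baselineMs, pulse_ms = testMs,
                 recovery_intervals = intervals, test_voltage = testV)
  }
  voltageClampTraceSet(tr[[1L]]$time, cur, sweeps,
                       samplingRate = samplingRate,
                       holdingPotential = holding, protocol = prot)
}

#' Simulate an isoform-level expression table
#'
#' Log-normal abundances around per-gene, per-tissue means: each transfrag
#' independently estimates its gene's expression with multiplicative noise
#' `exp(sigma Z - sigma^2/2)` (so the expectation equals the mean and zero
#' dispersion returns the means exactly), and isoforms split each transfrag
#' evenly.
#'
#' @param geneMeans Matrix or data.frame of mean abundances, genes x tissues
#'   (dimnames used as ids); or a named vector for one tissue.
#' @param replicates Number of replicates per tissue (default 3).
#' @param dispersion Log-scale SD sigma (default 0.3).
#' @param nTransfrags Transfrags per gene (default 1).
#' @param nIsoforms Isoforms per transfrag (default 2).
#' @param seed Integer seed.
#' @return data.frame in the layout [aggregateGeneExpression()] expects.
#' @export
simulateExpressionTable <- function(geneMeans, replicates = 3L,
                                    dispersion = 0.3, nTransfrags = 1L,
                                    nIsoforms = 2L, seed = 1L) {
  if (is.null(dim(geneMeans)))
    geneMeans <- matrix(geneMeans, ncol = 1L,
                        dimnames = list(names(geneMeans), "tissue1"))
  geneMeans <- as.matrix(geneMeans)
  set.seed(seed)
  rows <- list()
  for (g in rownames(geneMeans)) for (ti in colnames(geneMeans))
    for (r in seq_len(replicates)) for (tf in seq_len(nTransfrags)) {
      tot <- geneMeans[g, ti] *
        exp(rnorm(1L, 0, dispersion) - dispersion^2 / 2)
      for (iso in seq_len(nIsoforms))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, transfrag = paste0(g, "_g", tf),
          isoform = paste0(g, "_g", tf, "_i", iso),
          tissue = ti, replicate = r, abundance = tot / nIsoforms)
    }
  do.call(rbind, rows)
}
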