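#' @import methods
#' @importFrom stats dnorm quantile pchisq qchisq optim rnorm rexp runif
#'   setNames sd lm coef nls residuals aggregate median
#' @importFrom utils head tail read.delim write.table read.csv write.csv
#'   packageVersion modifyList
#' @useDynLib navdup, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

AA_ALPHABET_STRICT <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                        "F","P","S","T","W","Y","V","X","-")

ROLE_LEVELS <- c("outgroup", "paralog1", "paralog2", "other")

#' ProteinAlignment: aligned amino-acid sequences with branch roles
#'
#' Wraps a [Biostrings::AAStringSet] of equal-width aligned sequences and a
#' parallel vector of roles assigning each record to a branch of the
#' paralog1/paralog2/outgroup trio (or `"other"`).
#'
#' @slot seqs An `AAStringSet`; all elements the same width.
#' @slot roles Character vector, one of `"outgroup"`, `"paralog1"`,
#'   `"paralog2"`, `"other"`, parallel to `seqs`.
#' @exportClass ProteinAlignment
setClass("ProteinAlignment",
  representation(seqs = "ANY", roles = "character"),
  validity = function(object) {
    msg <- character()
    if (!methods::is(object@seqs, "AAStringSet"))
      msg <- c(msg, "'seqs' must be an AAStringSet")
    else {
      w <- Biostrings::width(object@seqs)
      if (length(w) < 1L) msg <- c(msg, "alignment must contain >= 1 record")
      if (length(unique(w)) > 1L)
        msg <- c(msg, "ragged alignment: records differ in length")
      if (length(w) >= 1L && w[1L] < 1L)
        msg <- c(msg, "alignment length must be >= 1")
      bad <- .badAAChars(as.character(object@seqs))
      if (length(bad))
        msg <- c(msg, paste0("illegal amino-acid characters: ",
                             paste(unique(bad), collapse = " ")))
    }
    if (length(object@roles) != length(object@seqs))
      msg <- c(msg, "'roles' must be parallel to 'seqs'")
    if (!all(object@roles %in% ROLE_LEVELS))
      msg <- c(msg, "roles must be outgroup/paralog1/paralog2/other")
    if (length(msg)) msg else TRUE
  })

#' CodonAlignment: in-frame nucleotide alignment
#'
#' Equal-width, in-frame (length divisible by 3) aligned coding sequences with
#' no internal stop codons. Gap characters must appear as whole `---` triplets
#' for translation.
#'
#' @slot seqs A `DNAStringSet`.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(seqs = "ANY"),
  validity = function(object) {
    msg <- character()
    if (!methods::is(object@seqs, "DNAStringSet"))
      msg <- c(msg, "'seqs' must be a DNAStringSet")
    else {
      w <- Biostrings::width(object@seqs)
      if (length(w) < 1L) msg <- c(msg, "alignment must contain >= 1 record")
      if (length(unique(w)) > 1L)
        msg <- c(msg, "ragged alignment: records differ in length")
      if (length(w) >= 1L && w[1L] %% 3L != 0L)
        msg <- c(msg, "nucleotide length must be divisible by 3")
      stops <- .internalStops(object)
      if (nrow(stops))
        msg <- c(msg, sprintf("internal stop codon in record '%s' at codon %d",
                              stops$id[1L], stops$codon[1L]))
    }
    if (length(msg)) msg else TRUE
  })

#' LabeledTree: phylogeny with per-branch foreground flags
#'
#' Wraps an [ape::phylo] tree together with a logical flag per edge marking
#' the foreground branch(es) of a two-ratio codon model (the `"#1"` Newick
#' label dialect).
#'
#' @slot tree An `ape::phylo` object.
#' @slot foreground Logical vector, one element per row of `tree$edge`.
#' @exportClass LabeledTree
setClass("LabeledTree",
  representation(tree = "ANY", foreground = "logical"),
  validity = function(object) {
    msg <- character()
    if (!inherits(object@tree, "phylo"))
      msg <- c(msg, "'tree' must be an ape phylo object")
    else {
      if (length(object@foreground) != nrow(object@tree$edge))
        msg <- c(msg, "'foreground' must have one flag per edge")
      if (anyDuplicated(object@tree$tip.label))
        msg <- c(msg, "duplicate leaf names")
      if (!is.null(object@tree$edge.length) &&
          any(object@tree$edge.length < 0))
        msg <- c(msg, "negative branch lengths")
    }
    if (length(msg)) msg else TRUE
  })

#' BranchEventMap: parsimony-mapped substitution and indel events
#'
#' Events assigned to the three branches of an outgroup/paralog1/paralog2 trio
#' by the minimum-mutation parsimony criterion.
#'
#' @slot events data.frame with columns `branch`, `column`, `type`
#'   (`"substitution"`/`"indel"`), `states`.
#' @slot totals Named integer vector of per-branch event counts `n_b`.
#' @slot L Integer, number of alignment columns.
#' @slot skipped Integer vector of columns excluded from event calling
#'   (any sequence ambiguous 'X').
#' @exportClass BranchEventMap
setClass("BranchEventMap",
  representation(events = "data.frame", totals = "integer", L = "integer",
                 skipped = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("branch", "column", "type", "states")
    if (!all(need %in% names(object@events)))
      msg <- c(msg, "events needs columns branch/column/type/states")
    if (length(object@L) != 1L || object@L < 1L)
      msg <- c(msg, "L must be a single positive integer")
    else if (nrow(object@events) &&
             (any(object@events$column < 1L) ||
              any(object@events$column > object@L)))
      msg <- c(msg, "event columns outside 1..L")
    if (!all(sort(names(object@totals)) ==
             sort(c("outgroup", "paralog1", "paralog2"))))
      msg <- c(msg, "totals must be named outgroup/paralog1/paralog2")
    else if (nrow(object@events) || sum(object@totals) > 0L) {
      tab <- table(factor(object@events$branch,
                          levels = names(object@totals)))
      if (!all(as.integer(tab[names(object@totals)]) == object@totals))
        msg <- c(msg, "totals disagree with event list")
    }
    if (length(msg)) msg else TRUE
  })

#' DensityProfile: weighted kernel substitution density along an alignment
#'
#' @slot branch Branch identifier.
#' @slot values Numeric vector `d_b(x)` at integer columns `1..L`
#'   (events per residue).
#' @slot bandwidth Gaussian kernel standard deviation (residues).
#' @slot weight Branch share `w_b = n_b / n_total`.
#' @slot nEvents Number of events on the branch.
#' @exportClass DensityProfile
setClass("DensityProfile",
  representation(branch = "character", values = "numeric",
                 bandwidth = "numeric", weight = "numeric",
                 nEvents = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@values < 0)) msg <- c(msg, "densities must be >= 0")
    if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be > 0")
    if (object@weight < 0 || object@weight > 1)
      msg <- c(msg, "weight must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' RelativeDensityProfile: one branch's density over the other two
#'
#' @slot branch Branch identifier.
#' @slot values `R_b(x) = d_b(x) / max(sum of other branches' densities, eps)`.
#' @slot eps Denominator floor (events per residue).
#' @slot bandwidth Kernel standard deviation used for the densities.
#' @slot floored Logical vector: positions where the floor was active.
#' @exportClass RelativeDensityProfile
setClass("RelativeDensityProfile",
  representation(branch = "character", values = "numeric", eps = "numeric",
                 bandwidth = "numeric", floored = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@values))) msg <- c(msg, "non-finite values")
    if (any(object@values < 0)) msg <- c(msg, "values must be >= 0")
    if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
    if (length(msg)) msg else TRUE
  })

#' NullDistribution: Monte-Carlo null for the relative-density scan
#'
#' Per-simulation maxima of the relative-density statistic under uniform
#' random placement of each branch's events, and the derived per-branch
#' thresholds.
#'
#' @slot maxima Matrix `nSim x 3` of per-simulation maximum relative density.
#' @slot thresholds Named numeric, per-branch percentile threshold `q_b`.
#' @slot percentile The percentile used (default 99).
#' @slot nSim Number of simulations.
#' @slot seed Master seed used.
#' @slot L,bandwidth,eps Scan geometry shared with the observed profiles.
#' @slot pointwise Optional `L x 3` matrix of per-position thresholds
#'   (statistic = "pointwise"), else a 0-row matrix.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(maxima = "matrix", thresholds = "numeric",
                 percentile = "numeric", nSim = "integer", seed = "integer",
                 L = "integer", bandwidth = "numeric", eps = "numeric",
                 pointwise = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@maxima) != object@nSim)
      msg <- c(msg, "maxima must have nSim rows")
    if (ncol(object@maxima) != 3L) msg <- c(msg, "maxima must have 3 columns")
    if (length(msg)) msg else TRUE
  })

#' CodonModelFit: maximum-likelihood Goldman-Yang branch-model fit
#'
#' @slot lnL Maximized log-likelihood.
#' @slot kappa Transition/transversion rate ratio.
#' @slot omega Named numeric of dN/dS per branch class (`"all"` for the
#'   one-ratio model; `"background"`/`"foreground"` for the two-ratio model).
#' @slot branchLengths Numeric, expected substitutions per codon per edge
#'   (order of `tree$edge`).
#' @slot pi Equilibrium codon frequencies (61 sense codons, F3X4).
#' @slot model `"one_ratio"` or `"two_ratio"`.
#' @slot convergence List: `converged`, `iterations`, `nStarts`, `messages`.
#' @slot tree The `LabeledTree` the fit used.
#' @exportClass CodonModelFit
setClass("CodonModelFit",
  representation(lnL = "numeric", kappa = "numeric", omega = "numeric",
                 branchLengths = "numeric", pi = "numeric", model = "character",
                 convergence = "list", tree = "ANY"))

#' LrtResult: likelihood-ratio test of nested codon models
#'
#' @slot statistic `2dL = 2 (lnL_alt - lnL_null)`, clipped at 0.
#' @slot df Degrees of freedom.
#' @slot pValue Chi-square upper-tail p-value.
#' @slot lnLNull,lnLAlt Component log-likelihoods.
#' @exportClass LrtResult
setClass("LrtResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 lnLNull = "numeric", lnLAlt = "numeric"),
  validity = function(object) {
    if (object@statistic < 0) "statistic must be >= 0" else TRUE
  })

#' VoltageClampTraceSet: sampled current sweeps plus protocol metadata
#'
#' @slot time Numeric vector of sample times (ms), shared by all sweeps.
#' @slot current Matrix, samples x sweeps (same units throughout, e.g. uA).
#' @slot sweeps data.frame of per-sweep metadata: `sweep`, `voltage` (mV),
#'   `tag` (`"step"`, `"ssi"`, `"recovery"`), and for recovery sweeps `role`
#'   (`"cond"`/`"test"`) and `interval` (ms).
#' @slot samplingRate Sampling rate (Hz).
#' @slot holdingPotential Holding potential (mV).
#' @slot protocol List: `baseline_ms`, `pulse_ms`, and protocol-specific
#'   fields (conditioning duration, recovery intervals, ...).
#' @exportClass VoltageClampTraceSet
setClass("VoltageClampTraceSet",
  representation(time = "numeric", current = "matrix", sweeps = "data.frame",
                 samplingRate = "numeric", holdingPotential = "numeric",
                 protocol = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@current) != length(object@time))
      msg <- c(msg, "current must have one row per time sample")
    if (ncol(object@current) != nrow(object@sweeps))
      msg <- c(msg, "current must have one column per sweep")
    if (!all(c("sweep", "voltage", "tag") %in% names(object@sweeps)))
      msg <- c(msg, "sweeps needs columns sweep/voltage/tag")
    if (length(msg)) msg else TRUE
  })

#' PersistentCurrentResult: per-sweep persistent-current quantification
#'
#' @slot table data.frame: `sweep`, `voltage`, `iPeak`, `iLate`,
#'   `pctPersistent`, `included`.
#' @slot pulseMs,windowMs Pulse duration and terminal averaging window (ms).
#' @exportClass PersistentCurrentResult
setClass("PersistentCurrentResult",
  representation(table = "data.frame", pulseMs = "numeric",
                 windowMs = "numeric"))

#' BoltzmannFit: sigmoid fit of a conductance-voltage or availability curve
#'
#' @slot v50 Half-activation/inactivation voltage (mV).
#' @slot slope Slope factor k (mV).
#' @slot amplitude Fitted maximal amplitude before normalization.
#' @slot pedestal Non-inactivating asymptote a in [0, 1] (0 for G-V fits).
#' @slot residualNorm Residual sum of squares.
#' @slot converged Logical.
#' @slot data data.frame of the fitted points (`voltage`, `value`).
#' @exportClass BoltzmannFit
setClass("BoltzmannFit",
  representation(v50 = "numeric", slope = "numeric", amplitude = "numeric",
                 pedestal = "numeric", residualNorm = "numeric",
                 converged = "logical", data = "data.frame"),
  validity = function(object) {
    if (length(object@slope) == 1L && object@slope == 0)
      "slope k must be nonzero" else TRUE
  })

#' RecoveryResult: fractional recovery from inactivation
#'
#' @slot table data.frame: `interval` (ms), `fraction`.
#' @exportClass RecoveryResult
setClass("RecoveryResult", representation(table = "data.frame"))
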