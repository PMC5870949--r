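# End-to-end orchestration with YAML config, provenance metadata and
# reproducible seeding. These functions are thin chains over the module
# functions; a command-line wrapper lives in inst/scripts/navdup-cli.R.

.defaultConfig <- function() {
  list(scan = list(h = 15, n_sim = 10000L, percentile = 99, eps = 1e-8,
                   statistic = "max", indel_mode = "per_run",
                   include_indels = FALSE),
       selection = list(drop_gapped = FALSE, n_starts = 3L,
                        fix_branch_lengths = FALSE),
       ephys = list(window_ms = 0.5, leak_max_mv = -100, noise_floor_k = 3,
                    filter_khz = 10, reversal_mv = 50),
       seed = 1L)
}

#' Read a YAML run configuration
#'
#' Unspecified fields fall back to defaults matching the published settings
#' (kernel bandwidth 15, 10,000 null simulations, 99th percentile).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(user[[k]]) && is.list(cfg[[k]]))
        utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
    }
  }
  cfg
}

.provenance <- function(config, outDir, stage) {
  tmp <- tempfile()
  saveRDS(config, tmp)
  prov <- list(package = "navdup",
               version = as.character(utils::packageVersion("navdup")),
               r_version = as.character(getRversion()),
               stage = stage, seed = config$seed,
               config = config,
               config_hash = unname(tools::md5sum(tmp)),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tmp)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov
}

#' Run the substitution-density hotspot scan end to end
#'
#' Chains [assignEvents()] on the trio, [substitutionDensity()],
#' [relativeDensity()], [simulateNull()] and [callHotspots()], writing the
#' events table, the per-position profile table, the thresholds JSON, the
#' hotspots TSV and a provenance record to `outDir`.
#'
#' @param trioFasta Path to the trio protein FASTA.
#' @param roles Named character vector mapping record ids to trio roles.
#' @param outDir Output directory (created if needed).
#' @param config Configuration from [readRunConfig()].
#' @return Invisibly, the [scanTrio()] result list.
#' @export
runScan <- function(trioFasta, roles, outDir,
                    config = readRunConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  aln <- readFastaAlignment(trioFasta, "protein", roles = roles)
  map <- assignEvents(aln, indelMode = config$scan$indel_mode)
  scan <- scanTrio(map, h = config$scan$h, eps = config$scan$eps,
                   nSim = config$scan$n_sim, seed = config$seed,
                   percentile = config$scan$percentile,
                   statistic = config$scan$statistic,
                   includeIndels = config$scan$include_indels)
  writeEventTable(map, file.path(outDir, "events.tsv"))
  write.table(scanTable(scan), file.path(outDir, "scan_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = as.list(scan$null@thresholds),
         n_sim = scan$null@nSim, seed = scan$null@seed,
         percentile = scan$null@percentile),
    file.path(outDir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  hot <- do.call(rbind, lapply(names(scan$hotspots), function(b) {
    h <- scan$hotspots[[b]]
    if (nrow(h)) cbind(branch = b, h) else NULL
  }))
  if (is.null(hot))
    hot <- data.frame(branch = character(), start = integer(),
                      end = integer(), peak_x = integer(),
                      peak_R = numeric(), fold_over_threshold = numeric())
  write.table(hot, file.path(outDir, "hotspots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .provenance(config, outDir, "scan")
  invisible(scan)
}

#' Run the branch-model selection analysis end to end
#'
#' Fits the one-ratio and two-ratio GY94 models and writes the fits (JSON)
#' and the likelihood-ratio test (TSV) plus provenance to `outDir`.
#'
#' @param codonFasta Path to the codon alignment FASTA.
#' @param newick Path to the Newick tree with `#1` foreground label(s).
#' @param outDir Output directory.
#' @param config Configuration from [readRunConfig()].
#' @return Invisibly, list `one_ratio`, `two_ratio`
#'   ([CodonModelFit-class]) and `lrt` ([LrtResult-class]).
#' @export
runSelection <- function(codonFasta, newick, outDir,
                         config = readRunConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  aln <- readFastaAlignment(codonFasta, "codon")
  tree <- readNewickTree(newick)
  if (!any(tree@foreground))
    stop("configuration error: no '#1' foreground branch in the tree")
  sel <- config$selection
  fit0 <- fitBranchModel(aln, tree, "one_ratio", nStarts = sel$n_starts,
                         seed = config$seed,
                         fixBranchLengths = sel$fix_branch_lengths,
                         dropGapped = sel$drop_gapped)
  warm <- list(kappa = fit0@kappa,
               omega = c(background = unname(fit0@omega[["all"]]),
                         foreground = unname(fit0@omega[["all"]])),
               t = fit0@branchLengths)
  fit1 <- fitBranchModel(aln, tree, "two_ratio", nStarts = sel$n_starts,
                         seed = config$seed + 1L,
                         fixBranchLengths = sel$fix_branch_lengths,
                         dropGapped = sel$drop_gapped, start = warm)
  lrt <- lrTest(fit0, fit1, df = 1)
  toList <- function(f) list(model = f@model, lnL = f@lnL, kappa = f@kappa,
                             omega = as.list(f@omega),
                             branch_lengths = f@branchLengths,
                             converged = f@convergence$converged)
  jsonlite::write_json(list(one_ratio = toList(fit0),
                            two_ratio = toList(fit1)),
                       file.path(outDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(data.frame(statistic = lrt@statistic, df = lrt@df,
                         p_value = lrt@pValue, lnL_null = lrt@lnLNull,
                         lnL_alt = lrt@lnLAlt),
              file.path(outDir, "lrt.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  .provenance(config, outDir, "selection")
  invisible(list(one_ratio = fit0, two_ratio = fit1, lrt = lrt))
}

#' Run the electrophysiology quantification end to end
#'
#' Leak-subtracts a step family, quantifies per-sweep persistent current and
#' the activation curve, and, when the trace set carries them, the
#' steady-state-inactivation and recovery protocols; writes results TSVs and
#' provenance to `outDir`.
#'
#' @param traceCsv,protocolJson Paths as written by [writeTraceSet()].
#' @param outDir Output directory.
#' @param config Configuration from [readRunConfig()].
#' @return Invisibly, list with `persistent`, `gv`, and (if present in the
#'   input) `ssi` and `recovery` results.
#' @export
runEphys <- function(traceCsv, protocolJson, outDir,
                     config = readRunConfig()) {
  if (!file.exists(protocolJson))
    stop("protocol descriptor not found: ", protocolJson)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  x <- readTraceSet(traceCsv, protocolJson)
  ep <- config$ephys
  out <- list()
  if (any(x@sweeps$tag == "step")) {
    xs <- leakSubtract(x, leakMax = ep$leak_max_mv)
    out$persistent <- persistentPercent(xs, windowMs = ep$window_ms,
                                        noiseFloorK = ep$noise_floor_k,
                                        filterKHz = ep$filter_khz)
    write.table(persistentTable(out$persistent),
                file.path(outDir, "persistent_current.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$gv <- gvCurve(xs, eRev = ep$reversal_mv, filterKHz = ep$filter_khz)
  }
  if (any(x@sweeps$tag == "ssi")) out$ssi <- ssiCurve(x, ep$filter_khz)
  if (any(x@sweeps$tag == "recovery"))
    out$recovery <- recoveryFractions(x, filterKHz = ep$filter_khz)
  fits <- do.call(rbind, lapply(names(out)[names(out) %in% c("gv", "ssi")],
    function(nm) data.frame(curve = nm, v50 = out[[nm]]@v50,
                            k = out[[nm]]@slope,
                            pedestal = out[[nm]]@pedestal,
                            converged = out[[nm]]@converged)))
  if (!is.null(fits))
    write.table(fits, file.path(outDir, "boltzmann_fits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$recovery))
    write.table(recoveryTable(out$recovery),
                file.path(outDir, "recovery.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  .provenance(config, outDir, "ephys")
  invisible(out)
}
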