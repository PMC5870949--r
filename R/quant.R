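# Expression-table aggregation/scaling and qPCR relative quantification.

.checkExpressionTable <- function(df) {
  need <- c("gene", "transfrag", "isoform", "tissue", "replicate",
            "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$abundance < 0)) stop("abundances must be non-negative")
  invisible(df)
}

#' Aggregate isoform/transfrag abundances to gene level
#'
#' Isoform abundances are first summed within each transfrag; multiple
#' transfrags annotated to the same gene (fragments of one locus) are then
#' combined per tissue and replicate by their maximum
#' (`"sum_isoforms_then_max"`) or mean (`"sum_isoforms_then_mean"`).
#'
#' @param df data.frame with columns `gene`, `transfrag`, `isoform`,
#'   `tissue`, `replicate`, `abundance` (TPM or FPKM, non-negative).
#' @param mode `"sum_isoforms_then_max"` or `"sum_isoforms_then_mean"`.
#' @return data.frame `gene`, `tissue`, `replicate`, `abundance`.
#' @export
aggregateGeneExpression <- function(df,
                                    mode = c("sum_isoforms_then_max",
                                             "sum_isoforms_then_mean")) {
  mode <- match.arg(mode)
  .checkExpressionTable(df)
  byTf <- stats::aggregate(abundance ~ gene + transfrag + tissue + replicate,
                           data = df, FUN = sum)
  comb <- if (mode == "sum_isoforms_then_max") max else mean
  out <- stats::aggregate(abundance ~ gene + tissue + replicate,
                          data = byTf, FUN = comb)
  out[order(out$gene, out$tissue, out$replicate), , drop = FALSE]
}

#' Scale gene abundances by total expression of a gene set
#'
#' Within each tissue and replicate, each gene's abundance is divided by the
#' summed abundance of `geneSet` (e.g. all sodium-channel genes), giving
#' shares that sum to 1 per group. Shares are unit-free, so TPM and FPKM
#' tables give comparable output.
#'
#' @param df Gene-level data.frame (`gene`, `tissue`, `replicate`,
#'   `abundance`), e.g. from [aggregateGeneExpression()].
#' @param geneSet Character vector of genes forming the denominator;
#'   default: all genes present.
#' @return data.frame with an added `share` column, restricted to `geneSet`.
#' @export
scaleByTotalChannelExpression <- function(df, geneSet = NULL) {
  if (is.null(geneSet)) geneSet <- unique(df$gene)
  if (!length(geneSet)) stop("gene set is empty")
  miss <- setdiff(geneSet, df$gene)
  if (length(miss))
    stop("gene set members absent from table: ", paste(miss, collapse = ", "))
  sub <- df[df$gene %in% geneSet, , drop = FALSE]
  key <- interaction(sub$tissue, sub$replicate, drop = TRUE)
  totals <- tapply(sub$abundance, key, sum)
  if (any(totals == 0))
    stop("zero total abundance in group(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  sub$share <- sub$abundance / as.numeric(totals[key])
  sub[order(sub$tissue, sub$replicate, sub$gene), , drop = FALSE]
}

#' Relative qPCR quantification by the 2^-ddCq method
#'
#' Per sample, `dCq = Cq_target - Cq_reference`; per target,
#' `ddCq = dCq_sample - dCq_calibrator` and the fold change is
#' `efficiency^(-ddCq)` with efficiency fixed at 2 (100% doubling) unless
#' overridden.
#'
#' @param cq data.frame with columns `sample`, `target`, `cq_target`,
#'   `cq_reference` (one row per sample x target).
#' @param calibrator Sample id used as calibrator.
#' @param efficiency Amplification base (default 2).
#' @return data.frame with `dCq`, `ddCq` and `fold` columns.
#' @export
ddcqFoldChange <- function(cq, calibrator, efficiency = 2) {
  need <- c("sample", "target", "cq_target", "cq_reference")
  miss <- setdiff(need, names(cq))
  if (length(miss))
    stop("Cq table missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(cq$cq_reference)))
    stop("missing reference measurement")
  if (any(cq$cq_target <= 0) || any(cq$cq_reference <= 0))
    stop("Cq values must be positive")
  if (!calibrator %in% cq$sample)
    stop("calibrator sample '", calibrator, "' not in table")
  cq$dCq <- cq$cq_target - cq$cq_reference
  calRows <- cq[cq$sample == calibrator, c("target", "dCq")]
  calMap <- stats::setNames(calRows$dCq, calRows$target)
  if (any(!cq$target %in% names(calMap)))
    stop("calibrator lacks measurements for some targets")
  cq$ddCq <- cq$dCq - calMap[cq$target]
  cq$fold <- efficiency^(-cq$ddCq)
  cq
}
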