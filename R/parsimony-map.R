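# Minimum-mutation parsimony mapping of substitutions and indels onto the
# three branches connecting two paralogs and an outgroup ortholog.

BRANCHES <- c("outgroup", "paralog1", "paralog2")

#' Extract the outgroup/paralog1/paralog2 trio from an alignment
#'
#' @param x A [ProteinAlignment-class] whose roles include exactly one
#'   `outgroup`, one `paralog1` and one `paralog2` record.
#' @return A 3-record [ProteinAlignment-class] ordered outgroup, paralog1,
#'   paralog2.
#' @export
trioAlignment <- function(x) {
  stopifnot(methods::is(x, "ProteinAlignment"))
  idx <- vapply(BRANCHES, function(r) {
    i <- which(x@roles == r)
    if (length(i) != 1L)
      stop("trio needs exactly one record with role '", r, "' (found ",
           length(i), ")")
    i
  }, integer(1L))
  methods::new("ProteinAlignment", seqs = x@seqs[idx], roles = BRANCHES)
}

.trioCharMatrix <- function(trio) {
  s <- as.character(trio@seqs)
  L <- nchar(s[1L])
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE)), nrow = length(s),
              ncol = L, byrow = TRUE)
  rownames(m) <- trio@roles
  m
}

#' Map substitution and indel events onto the trio branches
#'
#' Applies the minimum-mutation parsimony criterion column by column:
#' a column where two sequences agree and one differs places one substitution
#' on the differing branch; a column where all three residues differ places
#' one substitution on each branch; identical columns place none. Columns with
#' an ambiguous residue (`X`) in any sequence are excluded. Gap-vs-residue
#' differences yield indel events: under `indel_mode = "per_run"` (default) a
#' maximal run of contiguous gap columns in one sequence counts as a single
#' indel at its first column; under `"per_column"` every gapped column counts.
#' Columns gapped in all three sequences carry no event (and do not break a
#' run). Substitutions are only called where all three sequences bear
#' residues; in mixed gap/residue columns the gap event alone is scored, since
#' residue changes there cannot be polarized.
#'
#' @param trio A 3-record [ProteinAlignment-class] with trio roles (any
#'   alignment accepted; [trioAlignment()] is applied first).
#' @param indelMode `"per_run"` or `"per_column"`.
#' @return A [BranchEventMap-class].
#' @export
assignEvents <- function(trio, indelMode = c("per_run", "per_column")) {
  indelMode <- match.arg(indelMode)
  trio <- trioAlignment(trio)
  m <- .trioCharMatrix(trio)
  L <- ncol(m)

  skipped <- which(apply(m == "X", 2L, any))
  live <- setdiff(seq_len(L), skipped)

  ev <- list()
  addEvent <- function(branch, column, type, states)
    ev[[length(ev) + 1L]] <<- data.frame(branch = branch, column = column,
                                         type = type, states = states)

  gap <- m == "-"
  allGap <- colSums(gap) == 3L

  # substitutions: columns where all three are residues
  resCols <- live[colSums(gap[, live, drop = FALSE]) == 0L]
  for (j in resCols) {
    a <- m[, j]
    u <- unique(a)
    if (length(u) == 1L) next
    states <- paste(a, collapse = "/")
    if (length(u) == 3L) {
      for (b in BRANCHES) addEvent(b, j, "substitution", states)
    } else {
      odd <- names(a)[!(a %in% u[tabulate(match(a, u)) == 2L])]
      addEvent(odd, j, "substitution", states)
    }
  }

  # indels: per sequence, gapped columns where not all three are gapped.
  # all-gap columns are transparent: they neither carry events nor split a
  # run (a shared deletion does not interrupt one lineage's indel).
  for (b in BRANCHES) {
    own <- gap[b, ] & !allGap
    own[skipped] <- FALSE
    if (!any(own)) next
    # two-gapped columns belong to the residue-bearing branch, not here
    nGap <- colSums(gap)
    own <- own & nGap == 1L
    cols <- which(own)
    if (!length(cols)) next
    if (indelMode == "per_column") {
      for (j in cols) addEvent(b, j, "indel", paste(m[, j], collapse = "/"))
    } else {
      keep <- !allGap & !(seq_len(L) %in% skipped)
      pos <- match(cols, which(keep))          # positions on the opaque grid
      runStart <- cols[c(TRUE, diff(pos) != 1L)]
      for (j in runStart) addEvent(b, j, "indel",
                                   paste(m[, j], collapse = "/"))
    }
  }

  # columns where two sequences are gapped: event on the residue-bearing
  # branch (an insertion in that lineage); per_run folds contiguous columns.
  twoGap <- which(colSums(gap) == 2L & !allGap)
  twoGap <- setdiff(twoGap, skipped)
  if (length(twoGap)) {
    bearer <- apply(!gap[, twoGap, drop = FALSE], 2L, function(z)
      BRANCHES[which(z)])
    for (b in unique(bearer)) {
      cols <- twoGap[bearer == b]
      if (indelMode == "per_column") {
        for (j in cols) addEvent(b, j, "indel", paste(m[, j], collapse = "/"))
      } else {
        keep <- !allGap & !(seq_len(L) %in% skipped)
        pos <- match(cols, which(keep))
        runStart <- cols[c(TRUE, diff(pos) != 1L)]
        for (j in runStart) addEvent(b, j, "indel",
                                     paste(m[, j], collapse = "/"))
      }
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(), column = integer(),
               type = character(), states = character())
  events <- events[order(events$column, match(events$branch, BRANCHES)), ,
                   drop = FALSE]
  rownames(events) <- NULL
  totals <- vapply(BRANCHES, function(b) sum(events$branch == b), integer(1L))
  methods::new("BranchEventMap", events = events, totals = totals,
               L = L, skipped = as.integer(skipped))
}

#' Per-branch event totals
#' @param map A [BranchEventMap-class].
#' @return Named integer vector `n_b`.
#' @export
eventTotals <- function(map) map@totals

#' Event list as a data.frame
#'
#' One row per event, sorted by column then branch.
#'
#' @param map A [BranchEventMap-class].
#' @return data.frame with columns `branch`, `column`, `type`, `states`.
#' @export
eventTable <- function(map) map@events

#' Write an event table as TSV
#' @param map A [BranchEventMap-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(map, path) {
  df <- eventTable(map)
  df$L <- rep(map@L, nrow(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [writeEventTable()]
#' @param path TSV path.
#' @param L Alignment length; taken from the file's `L` column if present.
#' @return A [BranchEventMap-class].
#' @export
readEventTable <- function(path, L = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(L)) {
    if (!"L" %in% names(df)) stop("L not stored in file; supply it")
    L <- df$L[1L]
    if (is.na(L)) stop("L not recoverable from an empty table; supply it")
  }
  df <- df[, c("branch", "column", "type", "states"), drop = FALSE]
  totals <- vapply(BRANCHES, function(b) sum(df$branch == b), integer(1L))
  methods::new("BranchEventMap", events = df, totals = totals,
               L = as.integer(L), skipped = integer())
}

#' Build a BranchEventMap from raw event positions
#'
#' Used by the simulators and the permutation machinery, where events are
#' generated directly rather than called from sequences.
#'
#' @param positions Named list of integer vectors (per-branch event columns),
#'   names `outgroup`, `paralog1`, `paralog2`.
#' @param L Alignment length.
#' @param type Event type recorded for all events.
#' @return A [BranchEventMap-class].
#' @export
branchEventMap <- function(positions, L, type = "substitution") {
  stopifnot(all(BRANCHES %in% names(positions)))
  ev <- do.call(rbind, lapply(BRANCHES, function(b) {
    p <- as.integer(positions[[b]])
    if (length(p) && (any(p < 1L) || any(p > L)))
      stop("event columns outside 1..L on branch ", b)
    if (!length(p)) return(NULL)
    data.frame(branch = b, column = p, type = type, states = NA_character_)
  }))
  if (is.null(ev))
    ev <- data.frame(branch = character(), column = integer(),
                     type = character(), states = character())
  ev <- ev[order(ev$column, match(ev$branch, BRANCHES)), , drop = FALSE]
  rownames(ev) <- NULL
  totals <- vapply(BRANCHES, function(b) sum(ev$branch == b), integer(1L))
  methods::new("BranchEventMap", events = ev, totals = totals,
               L = as.integer(L), skipped = integer())
}

setMethod("show", "BranchEventMap", function(object) {
  cat(sprintf("BranchEventMap: L = %d, n_total = %d\n",
              object@L, sum(object@totals)))
  cat(sprintf("  %s: %d\n", names(object@totals), object@totals), sep = "")
  if (length(object@skipped))
    cat(sprintf("  %d columns skipped (ambiguous residues)\n",
                length(object@skipped)))
})
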