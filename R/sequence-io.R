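# Readers, writers and validators for FASTA alignments and Newick trees.

.badAAChars <- function(seqstrings) {
  chars <- unique(unlist(strsplit(seqstrings, "", fixed = TRUE)))
  setdiff(chars, AA_ALPHABET_STRICT)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codonMatrix <- function(codonAln) {
  s <- as.character(codonAln@seqs)
  ncod <- nchar(s[1L]) %/% 3L
  starts <- seq(1L, by = 3L, length.out = ncod)
  m <- vapply(s, function(x) substring(x, starts, starts + 2L),
              character(ncod))
  if (ncod == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(s)))
  t(m)
}

# rows (id, codon) of internal stop codons; terminal stops are disallowed too
# because inputs are expected pre-trimmed ("stop codons removed").
.internalStops <- function(codonAln) {
  m <- .codonMatrix(codonAln)
  hits <- which(matrix(toupper(m) %in% STOP_CODONS, nrow = nrow(m)),
                arr.ind = TRUE)
  data.frame(id = names(codonAln@seqs)[hits[, 1L]],
             codon = unname(hits[, 2L]))
}

#' Construct a ProteinAlignment
#'
#' @param seqs Named character vector or `AAStringSet` of aligned sequences.
#' @param roles Optional character vector of roles (`"outgroup"`,
#'   `"paralog1"`, `"paralog2"`, `"other"`); defaults to `"other"`. May be
#'   named by record id.
#' @return A [ProteinAlignment-class] object.
#' @export
ProteinAlignment <- function(seqs, roles = NULL) {
  if (!methods::is(seqs, "AAStringSet")) {
    w <- unique(nchar(seqs))
    if (length(w) > 1L)
      stop("ragged alignment: records differ in length (",
           paste(w, collapse = ", "), ")")
    bad <- .badAAChars(as.character(seqs))
    if (length(bad))
      stop("alphabet error: illegal amino-acid characters: ",
           paste(bad, collapse = " "))
    seqs <- Biostrings::AAStringSet(seqs)
  }
  roles <- .resolveRoles(roles, names(seqs), length(seqs))
  methods::new("ProteinAlignment", seqs = seqs, roles = roles)
}

.resolveRoles <- function(roles, ids, n) {
  if (is.null(roles)) return(rep("other", n))
  if (!is.null(names(roles)) && !is.null(ids)) {
    out <- rep("other", n)
    hit <- match(names(roles), ids)
    if (anyNA(hit))
      stop("role ids not in alignment: ",
           paste(names(roles)[is.na(hit)], collapse = ", "))
    out[hit] <- unname(roles)
    return(out)
  }
  if (length(roles) != n) stop("'roles' must be parallel to the records")
  unname(roles)
}

#' Construct a CodonAlignment
#'
#' @param seqs Named character vector or `DNAStringSet` of aligned, in-frame
#'   coding sequences (no internal stops; gaps as `---` triplets).
#' @return A [CodonAlignment-class] object.
#' @export
CodonAlignment <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) {
    w <- unique(nchar(seqs))
    if (length(w) > 1L)
      stop("ragged alignment: records differ in length")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  methods::new("CodonAlignment", seqs = seqs)
}

#' Read an aligned FASTA file
#'
#' Records are returned in file order; role assignment is the caller's job
#' (via `roles` here or later through [setRoles()]).
#'
#' @param path FASTA file path.
#' @param type `"protein"` or `"codon"`.
#' @param roles Optional roles passed to [ProteinAlignment()].
#' @return A [ProteinAlignment-class] or [CodonAlignment-class].
#' @export
readFastaAlignment <- function(path, type = c("protein", "codon"),
                               roles = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (type == "protein") {
    x <- Biostrings::readAAStringSet(path)
    w <- unique(Biostrings::width(x))
    if (length(w) > 1L)
      stop("ragged alignment: records differ in length (",
           paste(w, collapse = ", "), ")")
    bad <- .badAAChars(as.character(x))
    if (length(bad))
      stop("alphabet error: illegal amino-acid characters: ",
           paste(bad, collapse = " "))
    ProteinAlignment(x, roles = roles)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    CodonAlignment(x)
  }
}

#' Write an alignment to FASTA
#'
#' @param x A [ProteinAlignment-class] or [CodonAlignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(x, path) {
  Biostrings::writeXStringSet(x@seqs, path)
  invisible(path)
}

#' Assign trio roles to alignment records
#'
#' @param x A [ProteinAlignment-class].
#' @param roles Named character vector `c(id = role, ...)` or unnamed vector
#'   parallel to the records.
#' @return The alignment with roles set.
#' @export
setRoles <- function(x, roles) {
  stopifnot(methods::is(x, "ProteinAlignment"))
  x@roles <- .resolveRoles(roles, names(x@seqs), length(x@seqs))
  methods::validObject(x)
  x
}

#' Translate a codon alignment to protein
#'
#' Gap triplets (`---`) map to `-`; any other triplet containing a gap or an
#' ambiguous base maps to `X`. An internal stop raises an error naming the
#' record and codon column.
#'
#' @param x A [CodonAlignment-class].
#' @param roles Optional roles for the resulting protein alignment.
#' @return A [ProteinAlignment-class] with one residue per codon column.
#' @export
translateCodons <- function(x, roles = NULL) {
  stopifnot(methods::is(x, "CodonAlignment"))
  m <- toupper(.codonMatrix(x))
  stops <- which(matrix(m %in% STOP_CODONS, nrow = nrow(m)), arr.ind = TRUE)
  if (nrow(stops))
    stop(sprintf("internal stop codon in record '%s' at codon column %d",
                 names(x@seqs)[stops[1L, 1L]], stops[1L, 2L]))
  code <- Biostrings::GENETIC_CODE
  aa <- matrix("X", nrow = nrow(m), ncol = ncol(m))
  aa[m == "---"] <- "-"
  known <- m %in% names(code)
  aa[known] <- unname(code[m[known]])
  prot <- apply(aa, 1L, paste, collapse = "")
  names(prot) <- names(x@seqs)
  ProteinAlignment(prot, roles = roles)
}

#' Read a Newick tree with foreground branch labels
#'
#' Branches carrying a `#1` label (on the tip name or internal node label,
#' e.g. `((A:1,B:1)#1:1,C:2);`) are flagged as foreground for two-ratio
#' codon models. Missing branch lengths default to 0.1 with a warning.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return A [LabeledTree-class].
#' @export
readNewickTree <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "") else path
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) stop("unparseable Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick string")
  if (anyDuplicated(sub("#\\d+$", "", tr$tip.label)))
    stop("duplicate leaf names")
  nTip <- length(tr$tip.label)
  fgNodes <- integer()
  hasTag <- grepl("#\\d+$", tr$tip.label)
  if (any(hasTag)) {
    fgNodes <- c(fgNodes, which(hasTag))
    tr$tip.label <- sub("#\\d+$", "", tr$tip.label)
  }
  if (!is.null(tr$node.label)) {
    nodeTag <- grepl("#\\d+$", tr$node.label)
    if (any(nodeTag)) fgNodes <- c(fgNodes, nTip + which(nodeTag))
    tr$node.label <- sub("#\\d+$", "", tr$node.label)
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0.1")
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths; defaulting to 0.1")
    tr$edge.length[is.na(tr$edge.length)] <- 0.1
  }
  fg <- tr$edge[, 2L] %in% fgNodes
  root <- nTip + 1L
  if (any(fgNodes == root))
    warning("foreground label on the root node has no branch; ignored")
  methods::new("LabeledTree", tree = tr, foreground = fg)
}

#' Write a LabeledTree to Newick with `#1` foreground labels
#'
#' @param x A [LabeledTree-class].
#' @param path Output path; if `NULL`, the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
writeNewickTree <- function(x, path = NULL) {
  stopifnot(methods::is(x, "LabeledTree"))
  tr <- x@tree
  nTip <- length(tr$tip.label)
  fgNodes <- tr$edge[x@foreground, 2L]
  tipFg <- fgNodes[fgNodes <= nTip]
  tr$tip.label[tipFg] <- paste0(tr$tip.label[tipFg], "#1")
  inFg <- fgNodes[fgNodes > nTip]
  if (length(inFg)) {
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    tr$node.label[inFg - nTip] <- paste0(tr$node.label[inFg - nTip], "#1")
  }
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Number of alignment columns
#' @param x A [ProteinAlignment-class] or [CodonAlignment-class] (codon
#'   columns for the latter).
#' @return Integer column count.
#' @export
alignmentLength <- function(x) {
  if (methods::is(x, "CodonAlignment"))
    return(Biostrings::width(x@seqs)[1L] %/% 3L)
  Biostrings::width(x@seqs)[1L]
}

#' Record roles of a protein alignment
#' @param x A [ProteinAlignment-class].
#' @return Character vector named by record id.
#' @export
alignmentRoles <- function(x) stats::setNames(x@roles, names(x@seqs))

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d records x %d columns\n",
              length(object@seqs), alignmentLength(object)))
  info <- sprintf("  %s [%s]", names(object@seqs), object@roles)
  cat(paste(head(info, 6L), collapse = "\n"), "\n")
  if (length(info) > 6L) cat("  ...\n")
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d records x %d codon columns\n",
              length(object@seqs), alignmentLength(object)))
})

setMethod("show", "LabeledTree", function(object) {
  cat(sprintf("LabeledTree: %d tips, %d edges, %d foreground\n",
              length(object@tree$tip.label), nrow(object@tree$edge),
              sum(object@foreground)))
})
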