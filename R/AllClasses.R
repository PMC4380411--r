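#' SmallRNATagSet: collapsed unique sequence tags with per-library counts
#'
#' The central container for a collapsed small RNA dataset: one row per
#' distinct 15--27 nt sequence tag, one column per library, integer read
#' counts. Produced by [collapseReads()].
#'
#' @slot tags a [Biostrings::DNAStringSet] of unique tag sequences.
#' @slot counts integer matrix, `length(tags)` rows by one column per
#'   library; `sum(counts[, lib])` equals the filtered read count of that
#'   library exactly.
#'
#' @aliases SmallRNATagSet-class
#' @exportClass SmallRNATagSet
setClass("SmallRNATagSet",
  representation(tags = "DNAStringSet", counts = "matrix"))

setValidity("SmallRNATagSet", function(object) {
  msg <- character()
  if (length(object@tags) != nrow(object@counts))
    msg <- c(msg, "number of tags and count rows differ")
  if (length(object@tags)) {
    w <- Biostrings::width(object@tags)
    if (any(w < 1)) msg <- c(msg, "empty tag sequence")
    if (any(object@counts < 0)) msg <- c(msg, "negative counts")
    if (any(rowSums(object@counts) == 0))
      msg <- c(msg, "tag with zero total count")
    if (anyDuplicated(as.character(object@tags)))
      msg <- c(msg, "duplicate tag sequences (tags must be collapsed)")
  }
  if (is.null(colnames(object@counts)))
    msg <- c(msg, "count columns must be named by library")
  if (length(msg)) msg else TRUE
})

#' Construct a SmallRNATagSet
#'
#' @param tags character vector or `DNAStringSet` of unique tag sequences.
#' @param counts integer matrix of per-library counts (columns named).
#' @return a [SmallRNATagSet-class] object.
#' @export
SmallRNATagSet <- function(tags, counts) {
  if (is.character(tags)) tags <- Biostrings::DNAStringSet(tags)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  new("SmallRNATagSet", tags = tags, counts = counts)
}

#' @describeIn SmallRNATagSet number of unique tags
#' @param x,object a `SmallRNATagSet`.
#' @export
setMethod("length", "SmallRNATagSet", function(x) length(x@tags))

#' Accessors for SmallRNATagSet
#'
#' `tagSequences()` returns the unique tag sequences, `tagCounts()` the
#' per-library count matrix, and `libNames()` the library names.
#'
#' @param x a [SmallRNATagSet-class].
#' @return a `DNAStringSet`, an integer matrix, or a character vector.
#' @name tagSequences
#' @export
tagSequences <- function(x) x@tags

#' @rdname tagSequences
#' @export
tagCounts <- function(x) x@counts

#' @rdname tagSequences
#' @export
libNames <- function(x) colnames(x@counts)

setMethod("show", "SmallRNATagSet", function(object) {
  cat("SmallRNATagSet with", length(object), "unique tags over",
      ncol(object@counts), "libraries\n")
  if (length(object)) {
    w <- Biostrings::width(object@tags)
    cat("  tag lengths:", min(w), "-", max(w), "nt\n")
    cat("  libraries:", paste(colnames(object@counts), collapse = ", "), "\n")
    cat("  reads per library:",
        paste(colSums(object@counts), collapse = ", "), "\n")
  }
})

#' Subset a SmallRNATagSet by tag index
#' @param x a `SmallRNATagSet`; @param i index vector.
#' @param i,j,...,drop index (j, drop unused).
#' @export
setMethod("[", "SmallRNATagSet", function(x, i, j, ..., drop = FALSE) {
  SmallRNATagSet(x@tags[i], x@counts[i, , drop = FALSE])
})

#' FoldResult: a predicted RNA secondary structure
#'
#' Result of [foldMFE()]: the folded sequence (RNA alphabet), its
#' dot-bracket structure and the minimum free energy in kcal/mol.
#'
#' @slot sequence RNA sequence (character, ACGU).
#' @slot structure dot-bracket string, same length as `sequence`.
#' @slot mfe minimum free energy, kcal/mol (<= 0).
#'
#' @aliases FoldResult-class
#' @exportClass FoldResult
setClass("FoldResult",
  representation(sequence = "character", structure = "character",
                 mfe = "numeric"))

setValidity("FoldResult", function(object) {
  msg <- character()
  if (nchar(object@sequence) != nchar(object@structure))
    msg <- c(msg, "sequence and structure lengths differ")
  o <- lengths(regmatches(object@structure, gregexpr("[(]", object@structure)))
  c_ <- lengths(regmatches(object@structure, gregexpr("[)]", object@structure)))
  if (o != c_) msg <- c(msg, "unbalanced brackets")
  if (object@mfe > 0) msg <- c(msg, "positive MFE (empty structure has 0)")
  if (length(msg)) msg else TRUE
})

#' @describeIn foldMFE dot-bracket structure of a `FoldResult`
#' @param x a `FoldResult`.
#' @export
dotBracket <- function(x) x@structure

#' @describeIn foldMFE minimum free energy (kcal/mol) of a `FoldResult`
#' @export
mfe <- function(x) x@mfe

#' @describeIn foldMFE folded sequence (RNA alphabet) of a `FoldResult`
#' @export
foldedSequence <- function(x) x@sequence

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult:", nchar(object@sequence), "nt, MFE",
      sprintf("%.2f", object@mfe), "kcal/mol\n")
  cat(" ", object@sequence, "\n ", object@structure, "\n")
})

#' HairpinCandidate: a precursor window with structure and verdict
#'
#' One candidate pre-miRNA: the precursor sequence and genomic span, its
#' MFE fold, the mature arm placement, the located star arm (if any), the
#' mature/star complementarity and the pass/fail verdict under the three
#' structural criteria.
#'
#' @slot precursor precursor sequence (DNA alphabet, genome strand already
#'   resolved so the mature reads 5'->3').
#' @slot contig,start,end,strand genomic span of the precursor (1-based
#'   inclusive; strand "+" or "-").
#' @slot fold a [FoldResult-class] of the precursor.
#' @slot matureStart,matureEnd 1-based mature coordinates within the
#'   precursor.
#' @slot armLabel "5p" or "3p".
#' @slot starStart,starEnd star coordinates within the precursor
#'   (`NA_integer_` when no star could be located).
#' @slot complementarity percent of mature bases paired to star positions
#'   (`NA` when star absent).
#' @slot verdict `TRUE` if all criteria pass.
#' @slot failed character vector naming failed criteria
#'   (subset of "mfe", "length", "complementarity").
#'
#' @aliases HairpinCandidate-class
#' @exportClass HairpinCandidate
setClass("HairpinCandidate",
  representation(precursor = "character", contig = "character",
                 start = "integer", end = "integer", strand = "character",
                 fold = "FoldResult",
                 matureStart = "integer", matureEnd = "integer",
                 armLabel = "character",
                 starStart = "integer", starEnd = "integer",
                 complementarity = "numeric",
                 verdict = "logical", failed = "character"))

setValidity("HairpinCandidate", function(object) {
  msg <- character()
  n <- nchar(object@precursor)
  if (object@matureStart < 1 || object@matureEnd > n)
    msg <- c(msg, "mature must lie wholly within the precursor")
  if (!is.na(object@complementarity) &&
      (object@complementarity < 0 || object@complementarity > 100))
    msg <- c(msg, "complementarity outside [0,100]")
  if (length(msg)) msg else TRUE
})

#' @describeIn applyHairpinCriteria stem-loop (precursor) length in nt
#' @param x a `HairpinCandidate`.
#' @export
stemLoopLength <- function(x) nchar(x@precursor)

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf("HairpinCandidate %s:%d-%d(%s) %d nt, MFE %.2f, arm %s",
              object@contig, object@start, object@end, object@strand,
              nchar(object@precursor), object@fold@mfe, object@armLabel))
  if (!is.na(object@starStart))
    cat(sprintf(", star %d-%d, compl %.1f%%",
                object@starStart, object@starEnd, object@complementarity))
  cat(if (object@verdict) " [PASS]\n" else
      sprintf(" [FAIL: %s]\n", paste(object@failed, collapse = ",")))
})
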