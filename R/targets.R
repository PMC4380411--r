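#' Score a miRNA against one transcript by local complementarity
#'
#' Plant miRNAs target near-perfectly complementary sites in coding
#' sequence, so the reverse complement of the miRNA is locally aligned
#' against the transcript sense strand under match +2, mismatch -3 and
#' an affine gap cost of 5 + 2(L-1) for a length-L gap (open -5, extend
#' -2); G:U is not rewarded. A perfect 21-nt site scores 42. The
#' alignment engine is `Biostrings::pairwiseAlignment` (Smith-Waterman);
#' ties are resolved deterministically (leftmost).
#'
#' @param mirna mature miRNA sequence, 15--27 nt.
#' @param transcript transcript (CDS) sequence, at least as long as the
#'   miRNA.
#' @param scores named vector of scoring constants
#'   `c(match, mismatch, gapOpen, gapExtend)`; defaults
#'   `c(2, -3, -5, -2)`.
#' @return a one-row data.frame: `score`, `start`, `end` (1-based span
#'   on the transcript), `matches`, `mismatches`, `gaps` (gapped
#'   positions).
#' @examples
#' m <- "ACGGACGAGGCAUUAGCAUGA"
#' tx <- paste0("GGGG", as.character(
#'   Biostrings::reverseComplement(Biostrings::RNAString(m))), "GGGG")
#' scoreTarget(m, tx)$score  # 42
#' @export
scoreTarget <- function(mirna, transcript,
                        scores = c(match = 2, mismatch = -3,
                                   gapOpen = -5, gapExtend = -2)) {
  mirna <- chartr("U", "T", toupper(as.character(mirna)))
  transcript <- chartr("U", "T", toupper(as.character(transcript)))
  if (nchar(transcript) < 1L) stop("empty transcript")
  if (nchar(mirna) < 15L || nchar(mirna) > 27L)
    stop("miRNA length must be 15-27 nt")
  if (nchar(transcript) < nchar(mirna))
    stop("transcript shorter than the miRNA")
  query <- revComp(mirna)
  mat <- matrix(scores[["mismatch"]], 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
  diag(mat) <- scores[["match"]]
  # Biostrings charges gapOpening + L * gapExtension for a length-L gap;
  # open -5 / extend -2 (first base included) maps to opening 3, ext 2
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = transcript, type = "local",
    substitutionMatrix = mat,
    gapOpening = -(scores[["gapOpen"]] - scores[["gapExtend"]]),
    gapExtension = -scores[["gapExtend"]])
  sub <- Biostrings::subject(aln)
  data.frame(score = Biostrings::score(aln),
             start = Biostrings::start(sub),
             end = Biostrings::end(sub),
             matches = Biostrings::nmatch(aln),
             mismatches = Biostrings::nmismatch(aln),
             gaps = Biostrings::nindel(aln)@insertion[, "WidthSum"] +
                    Biostrings::nindel(aln)@deletion[, "WidthSum"])
}

#' Scan a CDS set for miRNA targets
#'
#' Runs [scoreTarget()] for every miRNA x transcript combination and
#' keeps hits with `score >= minScore` (default 25, the standard gate; a
#' relaxed gate of 20 is conventional for focused scans such as
#' lipid-pathway gene lists). Per miRNA, hits are sorted by decreasing
#' score, then transcript id. Lowering `minScore` can only grow the hit
#' set (monotone gate).
#'
#' @param mirnas named character vector (or `DNAStringSet`) of mature
#'   miRNAs.
#' @param cds named character vector, `DNAStringSet` or FASTA path of
#'   coding sequences.
#' @param minScore score gate (default 25).
#' @param restrictTo optional character vector of transcript ids to scan
#'   (e.g. a lipid-pathway gene list).
#' @param scores scoring constants, see [scoreTarget()].
#' @return data.frame: `mirnaId`, `transcriptId`, `start`, `end`,
#'   `score`, `matches`, `mismatches`, `gaps`.
#' @export
scanTargets <- function(mirnas, cds, minScore = 25,
                        restrictTo = NULL,
                        scores = c(match = 2, mismatch = -3,
                                   gapOpen = -5, gapExtend = -2)) {
  cds <- .loadRef(cds)
  if (is(mirnas, "XStringSet")) {
    mirnas <- setNames(as.character(mirnas), names(mirnas))
  }
  if (is.null(names(mirnas))) stop("miRNAs must be named")
  if (!is.null(restrictTo)) cds <- cds[names(cds) %in% restrictTo]
  rows <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(cds)) {
      if (nchar(cds[[ti]]) < nchar(mirnas[[mi]])) next
      h <- scoreTarget(mirnas[[mi]], cds[[ti]], scores = scores)
      if (h$score >= minScore) {
        h$mirnaId <- names(mirnas)[mi]
        h$transcriptId <- names(cds)[ti]
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirnaId = character(0), transcriptId = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), matches = integer(0),
                      mismatches = integer(0), gaps = integer(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[, c("mirnaId", "transcriptId", "start", "end", "score",
               "matches", "mismatches", "gaps")]
  df <- df[order(df$mirnaId, -df$score, df$transcriptId), ]
  rownames(df) <- NULL
  df
}

#' Attach functional annotation to target hits
#'
#' Left-joins an annotation table (columns: transcript id, ortholog id,
#' description, pipe-separated GO terms) onto target hits; hits without
#' annotation are retained with empty fields.
#'
#' @param hits data.frame from [scanTargets()].
#' @param annotation a TSV path or data.frame with columns
#'   `transcriptId`, `orthologId`, `description`, `go` (pipe-separated).
#' @return `hits` with `orthologId`, `description` and `go` columns
#'   added (`""` where missing).
#' @export
annotateHits <- function(hits, annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- if (file.size(annotation) > 0)
      read.delim(annotation, header = TRUE, stringsAsFactors = FALSE)
    else data.frame(transcriptId = character(0))
  }
  need <- c("orthologId", "description", "go")
  for (cn in need) if (is.null(annotation[[cn]]))
    annotation[[cn]] <- character(0)
  idx <- match(hits$transcriptId, annotation$transcriptId)
  for (cn in need) {
    v <- annotation[[cn]][idx]
    v[is.na(v)] <- ""
    hits[[cn]] <- v
  }
  hits
}

#' Tally GO terms over annotated target hits
#'
#' Counts hits per GO term (terms are pipe-separated per hit), output
#' sorted by decreasing count then alphabetically.
#'
#' @param hits annotated hits from [annotateHits()].
#' @return data.frame `term`, `count`.
#' @examples
#' tallyGO(data.frame(go = c("DNA binding|signaling", "DNA binding")))
#' @export
tallyGO <- function(hits) {
  terms <- unlist(strsplit(hits$go[!is.na(hits$go) & hits$go != ""],
                           "|", fixed = TRUE))
  terms <- trimws(terms)
  terms <- terms[terms != ""]
  if (!length(terms))
    return(data.frame(term = character(0), count = integer(0)))
  tab <- table(terms)
  df <- data.frame(term = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$term), ]
  rownames(df) <- NULL
  df
}
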