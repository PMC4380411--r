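#' Anchor sequence tags to a genome by exact matching
#'
#' Reports every exact occurrence of each tag on both strands of the
#' genome (minus-strand occurrences are positions whose reverse
#' complement equals the tag), up to a per-tag multi-mapping cap. Tags
#' are matched via width-grouped preprocessed dictionaries
#' (`Biostrings::PDict`), one pass per contig and strand. Anchors are
#' ordered deterministically by contig then coordinate; tags containing
#' N get no anchors.
#'
#' @param tags character vector, `DNAStringSet`, or
#'   [SmallRNATagSet-class].
#' @param genome a named [Biostrings::DNAStringSet] of contigs.
#' @param maxLoci multi-mapping cap: tags with more than `maxLoci`
#'   anchors keep only the first `maxLoci` in (contig, coordinate) order
#'   (default 20).
#' @return a [GenomicRanges::GRanges] with metadata column `tag` (the
#'   tag sequence, 5'->3' on the reported strand). 1-based inclusive
#'   coordinates; `end - start + 1` equals the tag length.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = strrep("ACGT", 30)))
#' anchorToGenome("ACGTACGTACGTACGT", g, maxLoci = 3)
#' @export
anchorToGenome <- function(tags, genome, maxLoci = 20L) {
  if (is(tags, "SmallRNATagSet")) tags <- tagSequences(tags)
  tags <- as.character(tags)
  tags <- unique(tags)
  if (is.null(names(genome))) stop("genome contigs must be named")
  clean <- !grepl("[^ACGT]", tags)
  hits <- list()
  for (w in unique(nchar(tags[clean]))) {
    sub <- tags[clean & nchar(tags) == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    pdRC <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sub)))
    for (ctg in names(genome)) {
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") pd else pdRC,
                                    genome[[ctg]])
        idx <- rep(seq_along(sub), lengths(m))
        if (!length(idx)) next
        st <- unlist(lapply(m, BiocGenerics::start), use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          tag = sub[idx], contig = ctg, start = st,
          end = st + w - 1L, strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(GenomicRanges::GRanges(tag = character(0)))
  }
  df <- do.call(rbind, hits)
  df <- df[order(df$tag, df$contig, df$start, df$strand), ]
  # multi-mapping cap, deterministic (contig, coordinate) order per tag
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$tag), function(i)
    head(i, maxLoci)), use.names = FALSE)
  df <- df[sort(keep), ]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, tag = df$tag)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.loadRef <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is(reference, "XStringSet")) {
    seqs <- chartr("U", "T", toupper(as.character(reference)))
    names(seqs) <- sub("\\s.*$", "", names(reference))
  } else {
    seqs <- chartr("U", "T", toupper(reference))
  }
  if (!length(seqs)) return(setNames(character(0), character(0)))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("reference sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]),
               collapse = ", "))
  seqs
}

#' Identify known miRNAs by exact reference match
#'
#' A tag is a known miRNA iff it is identical -- in size and nucleotide
#' composition, i.e. full-length, equal-length, zero mismatches -- to a
#' mature reference sequence (U in the reference is read as T). The
#' parsed family label is attached.
#'
#' @param tags character vector or [SmallRNATagSet-class].
#' @param matureRef named character vector, `DNAStringSet` or FASTA path
#'   of mature reference miRNAs.
#' @return data.frame with columns `tag`, `refId`, `mismatches` (all 0),
#'   `family`; one row per known tag.
#' @export
matchKnown <- function(tags, matureRef) {
  if (is(tags, "SmallRNATagSet")) tags <- as.character(tagSequences(tags))
  ref <- .loadRef(matureRef)
  idx <- match(tags, ref)
  hit <- !is.na(idx)
  data.frame(tag = tags[hit], refId = names(ref)[idx[hit]],
             mismatches = rep(0L, sum(hit)),
             family = mirFamily(names(ref)[idx[hit]]),
             stringsAsFactors = FALSE)
}

#' Find candidate novel miRNAs by mismatch-tolerant homology
#'
#' For tags not already classified as known, finds the best reference
#' hit with 1--`maxMismatch` mismatches: equal-length Hamming comparison
#' against mature references, and windowed Hamming (tag slid along the
#' reference) against precursor references. The best (fewest-mismatch)
#' hit per tag is reported; ties go to the lexicographically smallest
#' reference id. Matching uses `Biostrings::matchPattern` with
#' `max.mismatch`, which covers both the equal-length and the windowed
#' case.
#'
#' @param tags character vector or [SmallRNATagSet-class] (tags already
#'   known should be excluded by the caller).
#' @param matureRef named mature reference set (vector, `DNAStringSet`
#'   or FASTA path).
#' @param precursorRef optional precursor reference set.
#' @param maxMismatch mismatch ceiling (default 3).
#' @return data.frame with columns `tag`, `refId`, `mismatches`,
#'   `family`; one row per tag with a hit.
#' @export
matchHomolog <- function(tags, matureRef, precursorRef = NULL,
                         maxMismatch = 3L) {
  if (is(tags, "SmallRNATagSet")) tags <- as.character(tagSequences(tags))
  mat <- .loadRef(matureRef)
  prec <- if (!is.null(precursorRef)) .loadRef(precursorRef) else
    character(0)
  refs <- c(mat, prec)
  equalLen <- c(rep(TRUE, length(mat)), rep(FALSE, length(prec)))
  ord <- order(names(refs))
  refs <- refs[ord]; equalLen <- equalLen[ord]
  refSets <- Biostrings::DNAStringSet(refs)

  out <- lapply(tags, function(tg) {
    if (grepl("[^ACGT]", tg)) return(NULL)
    w <- nchar(tg)
    pat <- Biostrings::DNAString(tg)
    bestMM <- NA_integer_; bestId <- NA_character_
    for (r in seq_along(refs)) {
      if (equalLen[r] && nchar(refs[r]) != w) next
      if (nchar(refs[r]) < w) next
      m <- Biostrings::matchPattern(pat, refSets[[r]],
                                    max.mismatch = maxMismatch)
      if (!length(m)) next
      sts <- BiocGenerics::start(m)
      mm <- min(vapply(sts, function(s0)
        sum(utf8ToInt(substr(refs[r], s0, s0 + w - 1L)) !=
            utf8ToInt(tg)), integer(1)))
      if (is.na(bestMM) || mm < bestMM) {
        bestMM <- mm; bestId <- names(refs)[r]
      }
      if (bestMM == 0L) break
    }
    if (is.na(bestMM)) return(NULL)
    data.frame(tag = tg, refId = bestId, mismatches = bestMM,
               family = mirFamily(bestId), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tag = character(0), refId = character(0),
                      mismatches = integer(0), family = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag candidate precursors matching decoy ncRNAs
#'
#' A local stand-in for screening candidates against tRNA/rRNA/snRNA
#' catalogues: a precursor is flagged when it shares an exact block of at
#' least `minBlock` nt (either strand) with any decoy sequence. Flagged
#' precursors are removed from novel candidacy by the pipeline.
#'
#' @param precursors character vector (or `DNAStringSet`) of candidate
#'   precursor sequences.
#' @param decoys decoy ncRNA set (vector, `DNAStringSet` or FASTA path);
#'   may be empty.
#' @param minBlock exact shared block length (default 18).
#' @return logical vector, `TRUE` = flagged as decoy-derived.
#' @export
matchDecoys <- function(precursors, decoys, minBlock = 18L) {
  precursors <- toupper(as.character(precursors))
  if (is.character(decoys) && length(decoys) == 1L && file.exists(decoys))
    decoys <- Biostrings::readDNAStringSet(decoys)
  decoys <- toupper(as.character(decoys))
  if (!length(decoys)) return(rep(FALSE, length(precursors)))
  # index all decoy k-mers (both strands), then scan precursor k-mers
  kmers <- function(x, k) {
    unlist(lapply(x[nchar(x) >= k], function(s)
      substring(s, seq_len(nchar(s) - k + 1L),
                seq_len(nchar(s) - k + 1L) + k - 1L)), use.names = FALSE)
  }
  dict <- unique(kmers(c(decoys, revComp(decoys)), minBlock))
  vapply(precursors, function(p) {
    if (nchar(p) < minBlock) return(FALSE)
    any(kmers(p, minBlock) %in% dict)
  }, logical(1), USE.NAMES = FALSE)
}

#' Export genome anchors as BED
#'
#' Writes anchors as 6-column BED (0-based half-open, name = tag,
#' score = total tag count when a tag set is supplied, strand) via
#' `rtracklayer`.
#'
#' @param anchors `GRanges` from [anchorToGenome()].
#' @param path output file.
#' @param tagset optional [SmallRNATagSet-class] used to fill the score
#'   column with total tag counts (capped at 1000 per BED convention).
#' @return the path, invisibly.
#' @export
exportAnchorsBED <- function(anchors, path, tagset = NULL) {
  gr <- anchors
  names(gr) <- NULL
  gr$name <- gr$tag
  score <- rep(0L, length(gr))
  if (!is.null(tagset)) {
    tot <- rowSums(tagCounts(tagset))
    names(tot) <- as.character(tagSequences(tagset))
    score <- as.integer(pmin(tot[gr$tag], 1000L))
    score[is.na(score)] <- 0L
  }
  gr$score <- score
  gr$tag <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
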