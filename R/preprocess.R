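#' Clip the 3' adapter from raw reads
#'
#' Finds, for each read, the leftmost position at which a prefix of the
#' 3' adapter matches the read with at most one mismatch and an overlap
#' of at least `minOverlap` bases, and truncates the read there. On a
#' 50-cycle run with 15--27 nt inserts the adapter is always read into,
#' so reads in which no adapter can be located have unknown insert length
#' and are discarded (flagged, not clipped).
#'
#' @param sequences character vector of raw read sequences.
#' @param adapter3 adapter sequence (>= `minOverlap` nt).
#' @param minOverlap minimum adapter prefix length that must match
#'   (default 6).
#' @param maxMismatch mismatches tolerated in the matched prefix
#'   (default 1).
#' @return a list with `insertLength` (integer vector; `NA` when no
#'   adapter was found, `0` when the read starts with the adapter) and
#'   `insert` (clipped sequences, `NA` where discarded).
#' @examples
#' clipAdapter("ACGTACGTACGTACGTACGTA", "ACGTA", minOverlap = 5)
#' @export
clipAdapter <- function(sequences, adapter3, minOverlap = 6L,
                        maxMismatch = 1L) {
  if (nchar(adapter3) < minOverlap)
    stop("adapter3 must be at least minOverlap bases long")
  n <- length(sequences)
  if (n == 0L)
    return(list(insertLength = integer(0), insert = character(0)))
  width <- max(nchar(sequences))
  la <- nchar(adapter3)
  # character matrix of reads (ragged reads padded with blanks)
  padded <- formatC(sequences, width = -width)
  M <- matrix(unlist(strsplit(padded, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  A <- strsplit(adapter3, "")[[1]]
  rl <- nchar(sequences)
  best <- rep(NA_integer_, n)
  for (p in seq_len(width)) {
    ov <- min(la, width - p + 1L)
    if (ov < minOverlap) break
    block <- M[, p:(p + ov - 1L), drop = FALSE]
    mism <- rowSums(block != matrix(A[seq_len(ov)], n, ov, byrow = TRUE) &
                    block != " ")
    # overlap actually available in this read
    realOv <- pmin(ov, rl - p + 1L)
    hit <- is.na(best) & realOv >= minOverlap & mism <= maxMismatch
    best[hit] <- p
  }
  insertLength <- best - 1L
  insert <- ifelse(is.na(insertLength), NA_character_,
                   substr(sequences, 1L, pmax(insertLength, 0L)))
  list(insertLength = insertLength, insert = insert)
}

#' Quality filter on mean phred score
#'
#' Keeps a read iff the mean phred score over its (clipped) insert is at
#' least `minPhred` (boundary inclusive: a read with all bases at phred
#' 26 is kept under the default). The aggregate-mean rule is used because
#' a per-base cutoff at 26 would discard nearly all real data; a
#' `mode = "minbase"` switch applies the cutoff to every base instead.
#'
#' @param qualities integer matrix (reads x cycles) of phred scores, or a
#'   list of integer vectors.
#' @param insertLength integer vector of clipped insert lengths.
#' @param minPhred phred threshold (default 26).
#' @param mode `"mean"` (default) or `"minbase"`.
#' @return logical vector, `TRUE` = keep. Zero-length inserts return
#'   `FALSE`.
#' @export
qualityFilter <- function(qualities, insertLength, minPhred = 26,
                          mode = c("mean", "minbase")) {
  mode <- match.arg(mode)
  if (is.list(qualities)) {
    width <- max(lengths(qualities), 1L)
    qualities <- t(vapply(qualities, function(q)
      c(q, rep(0L, width - length(q))), integer(width)))
  }
  n <- nrow(qualities)
  len <- pmin(insertLength, ncol(qualities))
  mask <- outer(seq_len(n), seq_len(ncol(qualities)),
                function(i, j) j <= len[i])
  ok <- rep(FALSE, n)
  pos <- !is.na(len) & len > 0L
  if (mode == "mean") {
    s <- rowSums(qualities * mask)
    ok[pos] <- (s[pos] / len[pos]) >= minPhred
  } else {
    worst <- qualities
    worst[!mask] <- Inf
    ok[pos] <- apply(worst[pos, , drop = FALSE], 1, min) >= minPhred
  }
  ok
}

#' Length filter for clipped inserts
#'
#' Keeps sequences of 15--27 nt inclusive (both bounds are part of the
#' kept range; 14 and 28 nt are discarded).
#'
#' @param sequences character vector (or lengths as integers).
#' @param minLen,maxLen inclusive bounds (defaults 15 and 27).
#' @return logical keep vector.
#' @examples
#' lengthFilter(c(strrep("A", 14), strrep("A", 15), strrep("A", 27)))
#' @export
lengthFilter <- function(sequences, minLen = 15L, maxLen = 27L) {
  len <- if (is.character(sequences)) nchar(sequences) else sequences
  !is.na(len) & len >= minLen & len <= maxLen
}

#' Preprocess one raw library: clip, filter, count
#'
#' Applies [clipAdapter()], [qualityFilter()] and [lengthFilter()] to one
#' library and tallies every discard class, so that
#' `unfiltered = filtered + adapter + quality + length + N` holds
#' exactly. Reads containing N are excluded from the surviving set (they
#' cannot be anchored unambiguously) and counted separately.
#'
#' @param reads a FASTQ file path or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param adapter3 3' adapter sequence.
#' @param minPhred,minLen,maxLen,minOverlap stage thresholds.
#' @return a list with `sequences` (surviving insert sequences, one entry
#'   per read) and `stats` (named counts: unfiltered, filtered,
#'   discardedAdapter, discardedQuality, discardedLength, discardedN).
#' @export
preprocessFastq <- function(reads, adapter3, minPhred = 26,
                            minLen = 15L, maxLen = 27L, minOverlap = 6L) {
  if (is.character(reads) && length(reads) == 1L) {
    # (suppressed warning: FASTQ metadata columns are irrelevant here)
    reads <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(reads))
  }
  seqs <- as.character(reads)
  qm <- as(Biostrings::quality(reads), "matrix")
  qm[is.na(qm)] <- 0L

  clip <- clipAdapter(seqs, adapter3, minOverlap = minOverlap)
  adapterFound <- !is.na(clip$insertLength) & clip$insertLength > 0L
  # empty reads / adapter-at-position-0 / no adapter: discard
  qOK <- qualityFilter(qm, clip$insertLength, minPhred = minPhred)
  lOK <- lengthFilter(clip$insertLength, minLen, maxLen)
  hasN <- !is.na(clip$insert) & grepl("N", clip$insert, fixed = TRUE)

  dAdapter <- !adapterFound
  dQuality <- adapterFound & !qOK
  dLength <- adapterFound & qOK & !lOK
  dN <- adapterFound & qOK & lOK & hasN
  keep <- adapterFound & qOK & lOK & !hasN

  list(sequences = clip$insert[keep],
       stats = c(unfiltered = length(seqs), filtered = sum(keep),
                 discardedAdapter = sum(dAdapter),
                 discardedQuality = sum(dQuality),
                 discardedLength = sum(dLength), discardedN = sum(dN)))
}

#' Collapse filtered reads into unique sequence tags
#'
#' Deduplicates identical reads across libraries into one
#' [SmallRNATagSet-class] tag per distinct sequence, carrying one count
#' per library; the counts of a library sum exactly to its filtered read
#' count. Collapsing an already-collapsed set is the identity.
#'
#' @param readsPerLibrary named list: library -> character vector of
#'   surviving insert sequences (one entry per read).
#' @return a [SmallRNATagSet-class]. Tags are ordered by decreasing total
#'   count, ties lexicographic.
#' @examples
#' ts <- collapseReads(list(leaves = c("ACGTACGTACGTACGT",
#'                                     "ACGTACGTACGTACGT")))
#' tagCounts(ts)
#' @export
collapseReads <- function(readsPerLibrary) {
  stopifnot(is.list(readsPerLibrary), !is.null(names(readsPerLibrary)))
  libs <- names(readsPerLibrary)
  all <- unlist(readsPerLibrary, use.names = FALSE)
  if (!length(all)) {
    return(SmallRNATagSet(character(0),
                          matrix(integer(0), 0, length(libs),
                                 dimnames = list(NULL, libs))))
  }
  lib <- rep(libs, lengths(readsPerLibrary))
  tab <- table(factor(all), factor(lib, levels = libs))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(NULL, libs))
  tags <- rownames(tab)
  ord <- order(-rowSums(counts), tags)
  SmallRNATagSet(tags[ord], counts[ord, , drop = FALSE])
}

#' Per-library filtering and collapsing summary
#'
#' Builds the per-library summary table of the preprocessing stage:
#' unfiltered and filtered read counts, percent kept (half-up, one
#' decimal), unique tag counts, plus a `Total` row, and attaches the
#' 15--27 nt length histograms of redundant and unique reads as the
#' `"lengthHistogram"` attribute.
#'
#' @param statsPerLibrary named list: library -> the `stats` vector from
#'   [preprocessFastq()].
#' @param tagset the [SmallRNATagSet-class] from [collapseReads()]
#'   (optional; adds unique-tag counts and histograms).
#' @return a data.frame with columns `library`, `unfiltered_reads`,
#'   `filtered_reads`, `percent_kept`, `unique_tags`, and the discard
#'   classes.
#' @export
filterSummary <- function(statsPerLibrary, tagset = NULL) {
  libs <- names(statsPerLibrary)
  s <- do.call(rbind, lapply(statsPerLibrary, function(x)
    as.data.frame(as.list(x))))
  out <- data.frame(library = libs,
                    unfiltered_reads = s$unfiltered,
                    filtered_reads = s$filtered,
                    percent_kept = percentKept(s$filtered, s$unfiltered),
                    stringsAsFactors = FALSE)
  out$unique_tags <- NA_integer_
  hist <- NULL
  if (!is.null(tagset)) {
    cnt <- tagCounts(tagset)
    w <- Biostrings::width(tagSequences(tagset))
    out$unique_tags <- vapply(libs, function(l)
      sum(cnt[, l] > 0L), integer(1))
    lens <- 15:27
    hist <- do.call(rbind, lapply(libs, function(l) data.frame(
      library = l, length = lens,
      redundant = vapply(lens, function(k)
        sum(cnt[w == k, l]), integer(1)),
      unique = vapply(lens, function(k)
        sum(cnt[w == k, l] > 0L), integer(1)))))
  }
  out <- cbind(out, s[, c("discardedAdapter", "discardedQuality",
                          "discardedLength", "discardedN")])
  rownames(out) <- NULL
  tot <- data.frame(library = "Total",
                    unfiltered_reads = sum(out$unfiltered_reads),
                    filtered_reads = sum(out$filtered_reads),
                    percent_kept = percentKept(sum(out$filtered_reads),
                                               sum(out$unfiltered_reads)),
                    unique_tags = if (is.null(tagset)) NA_integer_ else
                      length(tagset),
                    discardedAdapter = sum(out$discardedAdapter),
                    discardedQuality = sum(out$discardedQuality),
                    discardedLength = sum(out$discardedLength),
                    discardedN = sum(out$discardedN))
  out <- rbind(out, tot)
  attr(out, "lengthHistogram") <- hist
  out
}

#' Percent of reads kept, rendered at one decimal
#'
#' `100 * filtered / unfiltered`, rounded half away from zero at one
#' decimal -- the rendering used in the per-library read-count summary
#' (e.g. 7,951,133 of 9,856,027 reads gives 80.7).
#'
#' @param filtered,unfiltered read counts.
#' @return numeric percentage at 1 decimal.
#' @examples
#' percentKept(7951133, 9856027)
#' @export
percentKept <- function(filtered, unfiltered) {
  roundHalfUp(100 * filtered / unfiltered, 1)
}
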