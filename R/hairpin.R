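#' Extract a precursor window around a genome anchor
#'
#' Returns `flank` nt of genomic context on each side of an anchored
#' mature (clamped at contig edges). For minus-strand anchors the window
#' is reverse-complemented so the mature always reads 5'->3' within the
#' window; the mature offset is recorded after clamping.
#'
#' @param anchor a single-row `GRanges` (from [anchorToGenome()]) or a
#'   list with `contig`, `start`, `end`, `strand`.
#' @param genome named `DNAStringSet` of contigs.
#' @param flank flank size in nt (default 200).
#' @return list with `window` (character), `matureStart`, `matureEnd`
#'   (1-based within the window), `contig`, `windowStart`, `windowEnd`
#'   (genomic, 1-based inclusive) and `strand`.
#' @export
extractWindow <- function(anchor, genome, flank = 200L) {
  if (is(anchor, "GRanges")) {
    stopifnot(length(anchor) == 1L)
    anchor <- list(contig = as.character(GenomicRanges::seqnames(anchor)),
                   start = GenomicRanges::start(anchor),
                   end = GenomicRanges::end(anchor),
                   strand = as.character(GenomicRanges::strand(anchor)))
  }
  flank <- as.integer(flank)
  anchor$start <- as.integer(anchor$start)
  anchor$end <- as.integer(anchor$end)
  ctg <- genome[[anchor$contig]]
  if (is.null(ctg)) stop("unknown contig: ", anchor$contig)
  clen <- length(ctg)
  if (clen < anchor$end - anchor$start + 1L)
    stop("contig shorter than the mature sequence")
  ws <- max(1L, anchor$start - flank)
  we <- min(clen, anchor$end + flank)
  win <- as.character(Biostrings::subseq(ctg, ws, we))
  if (anchor$strand == "-") {
    win <- revComp(win)
    matureStart <- we - anchor$end + 1L
  } else {
    matureStart <- anchor$start - ws + 1L
  }
  matureEnd <- matureStart + (anchor$end - anchor$start)
  list(window = win, matureStart = matureStart, matureEnd = matureEnd,
       contig = anchor$contig, windowStart = ws, windowEnd = we,
       strand = anchor$strand)
}

#' Locate the miRNA* arm in a folded precursor
#'
#' The star arm is derived from the fold: take the positions paired to
#' the mature's paired bases, span them, and extend the star's 3' end by
#' 2 nt (the duplex 3'-overhang convention), clipped to the precursor.
#' No star is reported (duplex absent) when fewer than half the mature
#' bases are paired, when the partner span is ragged (wider than the
#' mature plus 8 nt -- the arms do not form a clean duplex), or when the
#' star region would overlap the mature.
#'
#' @param fold a [FoldResult-class] of the precursor.
#' @param matureStart,matureEnd mature coordinates within the precursor
#'   (1-based).
#' @return list with `starStart`, `starEnd`, `armLabel` ("5p"/"3p" for
#'   the mature arm), or `NULL` when no star can be located.
#' @export
locateStar <- function(fold, matureStart, matureEnd) {
  p <- parseDotBracket(dotBracket(fold))
  n <- length(p)
  stopifnot(matureStart >= 1L, matureEnd <= n, matureStart <= matureEnd)
  mIdx <- matureStart:matureEnd
  partners <- p[mIdx]
  paired <- partners[!is.na(partners)]
  mlen <- length(mIdx)
  if (length(paired) < mlen / 2) return(NULL)
  lo <- min(paired); hi <- max(paired)
  if ((hi - lo + 1L) > mlen + 8L) return(NULL)
  armLabel <- if (lo > matureEnd) "5p" else if (hi < matureStart) "3p"
              else return(NULL)  # partners inside the mature: no duplex
  # extend the star's 3' end by the 2-nt overhang: for a 5p mature the
  # star lies 3' of it and its 3' end is the high coordinate; for a 3p
  # mature the star lies 5' and its 3' end is still the high coordinate
  hi <- min(hi + 2L, n)
  if (armLabel == "3p") hi <- min(hi, matureStart - 1L)
  if (hi >= matureStart && lo <= matureEnd) return(NULL)
  list(starStart = lo, starEnd = hi, armLabel = armLabel)
}

#' Percent complementarity of the mature to its star
#'
#' `100 * (mature bases paired to positions within the star span) /
#' mature length`, rounded half-up to one decimal. 15 of 20 bases paired
#' gives exactly 75.0 (the inclusive criterion boundary).
#'
#' @param fold a [FoldResult-class].
#' @param matureStart,matureEnd,starStart,starEnd coordinates within the
#'   precursor.
#' @return percentage in `[0, 100]`.
#' @export
complementarityPct <- function(fold, matureStart, matureEnd,
                               starStart, starEnd) {
  p <- parseDotBracket(dotBracket(fold))
  partners <- p[matureStart:matureEnd]
  nPaired <- sum(!is.na(partners) & partners >= starStart &
                 partners <= starEnd)
  roundHalfUp(100 * nPaired / (matureEnd - matureStart + 1L), 1)
}

#' Assemble a hairpin candidate from a folded precursor
#'
#' Folds (if needed) a precursor carrying a mature arm, locates the star
#' and computes complementarity, then applies the three structural
#' criteria via [applyHairpinCriteria()].
#'
#' @param precursor precursor sequence (DNA/RNA).
#' @param matureStart,matureEnd mature coordinates within the precursor.
#' @param contig,start,end,strand genomic span (optional bookkeeping).
#' @param maxPrecursorLen,minMfe,minComplementarity criteria thresholds.
#' @param params folding parameters.
#' @return a [HairpinCandidate-class].
#' @export
hairpinCandidate <- function(precursor, matureStart, matureEnd,
                             contig = "NA", start = 1L, end = nchar(precursor),
                             strand = "+",
                             maxPrecursorLen = 210L, minMfe = -20,
                             minComplementarity = 75,
                             params = foldEnergyParams()) {
  fold <- foldMFE(precursor, params)
  star <- locateStar(fold, matureStart, matureEnd)
  comp <- NA_real_
  ss <- se <- NA_integer_
  armLabel <- NA_character_
  if (!is.null(star)) {
    ss <- as.integer(star$starStart); se <- as.integer(star$starEnd)
    armLabel <- star$armLabel
    comp <- complementarityPct(fold, matureStart, matureEnd, ss, se)
  }
  cand <- new("HairpinCandidate", precursor = toupper(chartr("U", "T",
                as.character(precursor))),
              contig = as.character(contig), start = as.integer(start),
              end = as.integer(end), strand = strand, fold = fold,
              matureStart = as.integer(matureStart),
              matureEnd = as.integer(matureEnd),
              armLabel = armLabel,
              starStart = ss, starEnd = se,
              complementarity = comp, verdict = NA, failed = character(0))
  applyHairpinCriteria(cand, maxPrecursorLen = maxPrecursorLen,
                       minMfe = minMfe,
                       minComplementarity = minComplementarity)
}

#' Apply the three hairpin criteria
#'
#' A candidate passes iff its MFE is strictly below `minMfe` (-20
#' kcal/mol: a candidate at exactly -20.0 fails, -20.1 passes), its
#' stem-loop (precursor) length is at most `maxPrecursorLen` (210 nt)
#' and its mature/star complementarity is at least `minComplementarity`
#' (75%, boundary inclusive). A candidate without a locatable star fails
#' the complementarity criterion. The failed criteria are enumerated in
#' the returned object.
#'
#' @param candidate a [HairpinCandidate-class].
#' @param minMfe MFE gate, kcal/mol (default -20).
#' @param maxPrecursorLen stem-loop length gate, nt (default 210).
#' @param minComplementarity complementarity gate, percent (default 75).
#' @return the candidate with `verdict` and `failed` filled in.
#' @export
applyHairpinCriteria <- function(candidate, minMfe = -20,
                                 maxPrecursorLen = 210L,
                                 minComplementarity = 75) {
  failed <- character(0)
  if (!(mfe(candidate@fold) < minMfe)) failed <- c(failed, "mfe")
  if (stemLoopLength(candidate) > maxPrecursorLen)
    failed <- c(failed, "length")
  if (is.na(candidate@complementarity) ||
      candidate@complementarity < minComplementarity)
    failed <- c(failed, "complementarity")
  candidate@failed <- failed
  candidate@verdict <- length(failed) == 0L
  candidate
}

#' Refine a precursor window to the minimal passing stem-loop
#'
#' Searches sub-windows of the extracted window that contain the mature
#' (lengths 52--240 nt): both ends are trimmed on a 10-nt grid, every
#' sub-window is folded and judged by [applyHairpinCriteria()], and the
#' passing sub-window with the lowest MFE density (MFE / length) is then
#' polished by 1-nt end adjustments (up to 5 nt per end) while the
#' density improves and the criteria still pass. Returns `NULL` when no
#' sub-window passes.
#'
#' @param window the extracted window (list from [extractWindow()], or a
#'   sequence plus mature coordinates).
#' @param matureStart,matureEnd mature coordinates within `window` when
#'   `window` is a plain sequence.
#' @param minLen,maxLen sub-window length range (defaults 52 and 240).
#' @param gridStep coarse trim grid (default 10 nt).
#' @param minMfe,maxPrecursorLen,minComplementarity criteria thresholds.
#' @param params folding parameters.
#' @return the best passing [HairpinCandidate-class] (with genomic
#'   coordinates when `window` came from [extractWindow()]), or `NULL`.
#' @export
refinePrecursor <- function(window, matureStart = NULL, matureEnd = NULL,
                            minLen = 52L, maxLen = 240L, gridStep = 10L,
                            minMfe = -20, maxPrecursorLen = 210L,
                            minComplementarity = 75,
                            params = foldEnergyParams()) {
  if (is.list(window)) {
    seqc <- window$window
    m1 <- window$matureStart; m2 <- window$matureEnd
    meta <- window
  } else {
    seqc <- as.character(window)
    m1 <- matureStart; m2 <- matureEnd
    meta <- NULL
  }
  n <- nchar(seqc)
  stopifnot(m1 >= 1L, m2 <= n)
  evalSub <- function(a, b) {
    cand <- hairpinCandidate(substr(seqc, a, b),
                             matureStart = m1 - a + 1L,
                             matureEnd = m2 - a + 1L,
                             maxPrecursorLen = maxPrecursorLen,
                             minMfe = minMfe,
                             minComplementarity = minComplementarity,
                             params = params)
    attr(cand, "span") <- c(a, b)
    cand
  }
  aGrid <- unique(pmax(1L, m1 - seq(0L, n, by = gridStep)))
  aGrid <- aGrid[aGrid <= m1]
  bGrid <- unique(pmin(n, m2 + seq(0L, n, by = gridStep)))
  bGrid <- bGrid[bGrid >= m2]
  best <- NULL; bestDens <- Inf
  for (a in aGrid) {
    for (b in bGrid) {
      len <- b - a + 1L
      if (len < minLen || len > maxLen) next
      cand <- evalSub(a, b)
      if (!cand@verdict) next
      dens <- mfe(cand@fold) / len
      if (dens < bestDens) { best <- cand; bestDens <- dens }
    }
  }
  if (is.null(best)) return(NULL)
  ## 1-nt polish
  span <- attr(best, "span")
  improved <- TRUE
  polishBudget <- 5L
  while (improved && polishBudget > 0L) {
    improved <- FALSE
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      a <- span[1] + d[1]; b <- span[2] + d[2]
      len <- b - a + 1L
      if (a < 1L || b > n || a > m1 || b < m2 ||
          len < minLen || len > maxLen) next
      cand <- evalSub(a, b)
      if (!cand@verdict) next
      dens <- mfe(cand@fold) / len
      if (dens < bestDens) {
        best <- cand; bestDens <- dens; span <- c(a, b)
        improved <- TRUE
      }
    }
    polishBudget <- polishBudget - 1L
  }
  span <- attr(best, "span")
  if (!is.null(meta)) {
    if (meta$strand == "+") {
      gs <- meta$windowStart + span[1] - 1L
      ge <- meta$windowStart + span[2] - 1L
    } else {
      ge <- meta$windowEnd - span[1] + 1L
      gs <- meta$windowEnd - span[2] + 1L
    }
    best@contig <- meta$contig
    best@start <- as.integer(gs); best@end <- as.integer(ge)
    best@strand <- meta$strand
  }
  best
}

#' Write hairpin candidates in ViennaRNA-style dot-bracket text
#'
#' For each candidate: a `>id` header line, the precursor sequence (RNA
#' alphabet) and the structure line with the energy in parentheses.
#'
#' @param candidates list of [HairpinCandidate-class] objects (named).
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportDotBracket <- function(candidates, path) {
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("hairpin%03d", seq_along(candidates))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    writeLines(c(paste0(">", ids[i]), foldedSequence(cd@fold),
                 sprintf("%s (%.2f)", dotBracket(cd@fold),
                         mfe(cd@fold))), con)
  }
  invisible(path)
}

#' Export precursor/mature/star features as GFF3
#'
#' @param candidates named list of [HairpinCandidate-class] objects with
#'   genomic coordinates.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportHairpinGFF3 <- function(candidates, path) {
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("hairpin%03d", seq_along(candidates))
  rows <- list()
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    toGenomic <- function(off1, off2) {
      if (cd@strand == "+") c(cd@start + off1 - 1L, cd@start + off2 - 1L)
      else c(cd@end - off2 + 1L, cd@end - off1 + 1L)
    }
    pre <- c(cd@start, cd@end)
    mat <- toGenomic(cd@matureStart, cd@matureEnd)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cd@contig, type = "miRNA_primary_transcript",
      start = pre[1], end = pre[2], strand = cd@strand,
      id = ids[i], parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = cd@contig, type = "miRNA", start = mat[1], end = mat[2],
      strand = cd@strand, id = paste0(ids[i], "_mature"),
      parent = ids[i])
    if (!is.na(cd@starStart)) {
      st <- toGenomic(cd@starStart, cd@starEnd)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cd@contig, type = "miRNA_star", start = st[1],
        end = st[2], strand = cd@strand,
        id = paste0(ids[i], "_star"), parent = ids[i])
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand, type = df$type,
                               ID = df$id, Parent = df$parent)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
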