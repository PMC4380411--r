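#' Pipeline configuration
#'
#' Collects every input path (or in-memory object) and stage threshold,
#' with the analysis defaults: phred 26, insert length 15--27 nt, 200-nt
#' precursor flank, MFE gate -20 kcal/mol, stem-loop cap 210 nt,
#' complementarity 75%, novel abundance gate 81 reads (i.e. more than 80
#' in at least one library), family report gate 50 reads, fold-change
#' report gate 2, target score gates 25 (global) and 20 (focused lipid
#' scan). Referenced paths are checked at construction; a missing file
#' raises a named error before any work is done.
#'
#' @param fastq named list: library name -> FASTQ path or
#'   `QualityScaledDNAStringSet`.
#' @param genome,matureRef FASTA paths or `DNAStringSet`s (required).
#' @param precursorRef,decoys,cds,annotation,lipidList optional inputs
#'   (paths or objects; `lipidList` is a character vector of transcript
#'   ids).
#' @param adapter3 3' adapter sequence.
#' @param minPhred,minLen,maxLen,flank,minMfe,maxPrecursorLen,minComplementarity,minNovelCount,minReportCount,minFc,minScore,lipidMinScore,maxLoci
#'   stage thresholds (see above for defaults).
#' @param novelMode `"homology"` (novel candidates must lie within 3
#'   mismatches of a reference mature/precursor) or `"denovo"` (the
#'   reference-similarity requirement is dropped).
#' @param fcOn fold changes on `"raw"` counts (default) or
#'   `"normalized"` CPM.
#' @param seed integer seed for any randomized step.
#' @param outdir optional output directory for the result tree.
#' @return validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(fastq, genome, matureRef,
                           precursorRef = NULL, decoys = NULL,
                           cds = NULL, annotation = NULL,
                           lipidList = NULL,
                           adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                           minPhred = 26, minLen = 15L, maxLen = 27L,
                           flank = 200L, minMfe = -20,
                           maxPrecursorLen = 210L,
                           minComplementarity = 75,
                           minNovelCount = 81L, minReportCount = 50L,
                           minFc = 2, minScore = 25, lipidMinScore = 20,
                           maxLoci = 20L,
                           novelMode = c("homology", "denovo"),
                           fcOn = c("raw", "normalized"),
                           seed = 42L, outdir = NULL) {
  novelMode <- match.arg(novelMode)
  fcOn <- match.arg(fcOn)
  cfg <- as.list(environment())
  if (is.null(names(fastq)) || any(names(fastq) == ""))
    stop("fastq must be a named list (library name -> reads)")
  for (nm in c("genome", "matureRef", "precursorRef", "decoys", "cds",
               "annotation")) {
    v <- cfg[[nm]]
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      stop("input file for '", nm, "' not found: ", v)
  }
  for (nm in names(fastq)) {
    v <- fastq[[nm]]
    if (is.character(v) && !file.exists(v))
      stop("input file for library '", nm, "' not found: ", v)
  }
  chk <- function(x, lo, hi, nm) if (x < lo || x > hi)
    stop("threshold '", nm, "' outside sane bounds [", lo, ", ", hi, "]")
  chk(minPhred, 0, 41, "minPhred"); chk(minLen, 1, maxLen, "minLen")
  chk(maxLen, minLen, 50, "maxLen"); chk(flank, 0, 5000, "flank")
  chk(minMfe, -1000, 0, "minMfe")
  chk(maxPrecursorLen, 30, 5000, "maxPrecursorLen")
  chk(minComplementarity, 0, 100, "minComplementarity")
  chk(minFc, 1, 1000, "minFc")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full discovery pipeline
#'
#' Stage order: preprocess -> collapse -> genome anchoring -> known /
#' homolog matching -> abundance gate -> window extraction, folding and
#' structural criteria -> decoy exclusion -> quantification and fold
#' changes -> (optional) target prediction. Per-stage in/out counts are
#' collected in the run manifest; with `outdir` set, all tables and
#' FASTA/GFF3/BED/dot-bracket files are written and checksummed, and a
#' rerun with identical inputs and seed reproduces identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log stage progress to stderr.
#' @return a list: `tagset`, `summary`, `anchors`, `calls` (one row per
#'   called miRNA with status known/novel, structure flag, locus and
#'   counts), `hairpins` (named list of [HairpinCandidate-class]),
#'   `expression` (family x library counts), `foldChanges`
#'   (family-level report), `targets` + `goTally` (when CDS given),
#'   `manifest`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  say <- function(...) if (verbose) message("[mircam] ", ...)
  manifest <- list(parameters = config[!names(config) %in% "fastq"],
                   counts = list())

  genome <- if (is.character(config$genome))
    Biostrings::readDNAStringSet(config$genome) else config$genome
  names(genome) <- sub("\\s.*$", "", names(genome))
  matureRef <- .loadRef(config$matureRef)

  ## --- preprocess + collapse ---
  perLib <- list(); statsPerLib <- list()
  for (lib in names(config$fastq)) {
    pp <- preprocessFastq(config$fastq[[lib]], config$adapter3,
                          minPhred = config$minPhred,
                          minLen = config$minLen, maxLen = config$maxLen)
    perLib[[lib]] <- pp$sequences
    statsPerLib[[lib]] <- pp$stats
    say(lib, ": ", pp$stats[["filtered"]], "/",
        pp$stats[["unfiltered"]], " reads kept")
  }
  tagset <- collapseReads(perLib)
  summaryDF <- filterSummary(statsPerLib, tagset)
  manifest$counts$preprocess <- c(
    reads_in = sum(summaryDF$unfiltered_reads[summaryDF$library != "Total"]),
    reads_out = sum(summaryDF$filtered_reads[summaryDF$library != "Total"]),
    unique_tags = length(tagset))

  ## --- genome anchoring ---
  anchors <- anchorToGenome(tagset, genome, maxLoci = config$maxLoci)
  anchoredTags <- unique(anchors$tag)
  idx <- match(as.character(tagSequences(tagset)), anchoredTags)
  anchoredSet <- tagset[!is.na(idx)]
  say(length(anchoredSet), " of ", length(tagset), " tags anchored")
  manifest$counts$anchor <- c(tags_in = length(tagset),
                              tags_out = length(anchoredSet))

  tagChar <- as.character(tagSequences(anchoredSet))
  counts <- tagCounts(anchoredSet)

  ## --- known matching ---
  known <- matchKnown(tagChar, matureRef)
  manifest$counts$known <- c(tags_in = length(tagChar),
                             known_tags = nrow(known))

  ## --- abundance gate + novel candidacy ---
  maxCount <- apply(counts, 1, max)
  gated <- tagChar[maxCount >= config$minNovelCount &
                   !(tagChar %in% known$tag)]
  if (config$novelMode == "homology") {
    hom <- matchHomolog(gated, matureRef,
                        precursorRef = config$precursorRef)
    candidates <- hom
  } else {
    candidates <- data.frame(tag = gated, refId = NA_character_,
                             mismatches = NA_integer_,
                             family = NA_character_,
                             stringsAsFactors = FALSE)
  }
  say(nrow(candidates), " novel candidates after abundance gate")
  manifest$counts$novel_gate <- c(gated_tags = length(gated),
                                  candidates = nrow(candidates))

  ## --- hairpin analysis (known + candidates) ---
  firstAnchor <- function(tg) {
    a <- anchors[anchors$tag == tg]
    a[1]
  }
  analyze <- function(tg) {
    win <- extractWindow(firstAnchor(tg), genome, flank = config$flank)
    refinePrecursor(win,
                    maxPrecursorLen = config$maxPrecursorLen,
                    minMfe = config$minMfe,
                    minComplementarity = config$minComplementarity)
  }
  hairpins <- list()
  calls <- list()
  for (i in seq_len(nrow(known))) {
    tg <- known$tag[i]
    hp <- analyze(tg)
    pass <- !is.null(hp)
    id <- known$refId[i]
    if (pass) hairpins[[id]] <- hp
    a <- firstAnchor(tg)
    calls[[length(calls) + 1L]] <- data.frame(
      id = id, sequence = tg, family = known$family[i],
      status = "known", structuralPass = pass,
      contig = as.character(GenomicRanges::seqnames(a)),
      start = GenomicRanges::start(a), end = GenomicRanges::end(a),
      strand = as.character(GenomicRanges::strand(a)),
      stringsAsFactors = FALSE)
  }
  ## spans of already-called precursors: a candidate whose refined
  ## precursor overlaps one is the star arm (or a shifted isoform) of
  ## that locus, not a new locus -- the duplex is one precursor
  calledSpans <- do.call(rbind, lapply(hairpins, function(h)
    data.frame(contig = h@contig, start = h@start, end = h@end)))
  overlapsCalled <- function(h) {
    !is.null(calledSpans) &&
      any(calledSpans$contig == h@contig &
          calledSpans$start <= h@end & calledSpans$end >= h@start)
  }
  nNovel <- 0L
  decoySet <- config$decoys
  ## most-abundant candidates first, so matures absorb their stars
  if (nrow(candidates)) {
    candidates <- candidates[order(-maxCount[match(candidates$tag,
                                                   tagChar)]), ,
                             drop = FALSE]
  }
  for (i in seq_len(nrow(candidates))) {
    tg <- candidates$tag[i]
    hp <- analyze(tg)
    if (is.null(hp)) next
    if (!is.null(decoySet) &&
        matchDecoys(hp@precursor, decoySet)) next
    if (overlapsCalled(hp)) next
    calledSpans <- rbind(calledSpans,
                         data.frame(contig = hp@contig, start = hp@start,
                                    end = hp@end))
    nNovel <- nNovel + 1L
    id <- sprintf("csa-new%03d", nNovel)
    hairpins[[id]] <- hp
    a <- firstAnchor(tg)
    calls[[length(calls) + 1L]] <- data.frame(
      id = id, sequence = tg, family = id, status = "novel",
      structuralPass = TRUE,
      contig = as.character(GenomicRanges::seqnames(a)),
      start = GenomicRanges::start(a), end = GenomicRanges::end(a),
      strand = as.character(GenomicRanges::strand(a)),
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(id = character(0), sequence = character(0),
               family = character(0), status = character(0),
               structuralPass = logical(0), contig = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  say(sum(calls$status == "known"), " known + ",
      sum(calls$status == "novel"), " novel miRNAs called")
  manifest$counts$hairpin <- c(
    known_called = sum(calls$status == "known"),
    known_with_structure = sum(calls$status == "known" &
                               calls$structuralPass),
    novel_called = sum(calls$status == "novel"))

  ## --- quantification ---
  mirCounts <- counts[match(calls$sequence, tagChar), , drop = FALSE]
  rownames(mirCounts) <- calls$id
  for (lib in colnames(mirCounts)) calls[[paste0("count_", lib)]] <-
    mirCounts[, lib]
  expression <- aggregateFamilies(mirCounts, calls$family)
  foldChanges <- buildFoldChangeTable(expression,
                                      minCount = config$minReportCount,
                                      minFc = config$minFc,
                                      fcOn = config$fcOn)
  manifest$counts$quantify <- c(miRNAs = nrow(calls),
                                families = nrow(expression),
                                reported_families = nrow(foldChanges))

  result <- list(tagset = tagset, summary = summaryDF, anchors = anchors,
                 calls = calls, hairpins = hairpins,
                 expression = expression, foldChanges = foldChanges,
                 manifest = manifest)

  ## --- targets (optional) ---
  if (!is.null(config$cds) && nrow(calls)) {
    mir <- setNames(calls$sequence, calls$id)
    hits <- scanTargets(mir, config$cds, minScore = config$minScore)
    if (!is.null(config$annotation)) {
      hits <- annotateHits(hits, config$annotation)
      result$goTally <- tallyGO(hits)
    }
    result$targets <- hits
    if (!is.null(config$lipidList)) {
      result$lipidTargets <- scanTargets(mir, config$cds,
                                         minScore = config$lipidMinScore,
                                         restrictTo = config$lipidList)
    }
    manifest$counts$targets <- c(hits = nrow(hits))
    result$manifest <- manifest
  }

  if (!is.null(config$outdir)) {
    result <- writeRunOutputs(result, config)
  }
  result
}

# write the output tree + checksummed manifest
writeRunOutputs <- function(result, config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(df, name) {
    f <- file.path(outdir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
    f
  }
  rr <- renderReports(result, outdir)
  files <- c(files, rr)
  wtsv(result$summary, "filter_summary.tsv")
  ts <- result$tagset
  if (length(ts)) {
    fa <- tagSequences(ts)
    names(fa) <- sprintf("tag%d_counts%s", seq_along(fa),
                         apply(tagCounts(ts), 1, paste, collapse = ":"))
    f <- file.path(outdir, "tags.fasta")
    Biostrings::writeXStringSet(fa, f)
    files <- c(files, f)
    wtsv(data.frame(tag = as.character(tagSequences(ts)),
                    tagCounts(ts), check.names = FALSE),
         "tag_counts.tsv")
  }
  wtsv(result$calls, "mirna_calls.tsv")
  wtsv(as.data.frame(cbind(id = rownames(result$expression),
                           result$expression)), "family_counts.tsv")
  cpm <- normalizeCPM(result$expression)
  wtsv(data.frame(id = rownames(cpm), round(cpm, 2)), "family_cpm.tsv")
  if (!is.null(result$targets)) wtsv(result$targets, "target_hits.tsv")
  if (!is.null(result$goTally)) wtsv(result$goTally, "go_tally.tsv")
  if (length(result$hairpins)) {
    f <- file.path(outdir, "hairpins.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      vapply(result$hairpins, function(h) h@precursor, character(1))), f)
    files <- c(files, f)
    files <- c(files, exportDotBracket(result$hairpins,
                                       file.path(outdir, "hairpins.db")))
    files <- c(files, exportHairpinGFF3(result$hairpins,
                                        file.path(outdir, "hairpins.gff3")))
  }
  if (length(result$anchors)) {
    files <- c(files, exportAnchorsBED(result$anchors,
                                       file.path(outdir, "anchors.bed"),
                                       result$tagset))
  }
  sums <- tools::md5sum(files)
  result$manifest$checksums <- setNames(as.character(sums),
                                        basename(names(sums)))
  mf <- file.path(outdir, "manifest.tsv")
  write.table(data.frame(file = basename(names(sums)),
                         md5 = as.character(sums)),
              mf, sep = "\t", quote = FALSE, row.names = FALSE)
  result
}

#' Render the summary report tables
#'
#' Writes (when `outdir` is given) and returns the two report tables of
#' a run: the per-library read-count table (`Sample`, `Unfiltered
#' reads`, `Filtered reads`, `%`, with a Total row) and the family-level
#' fold-change table. Empty inputs yield headers-only tables.
#'
#' @param result a [runPipeline()] result (or a list with `summary` and
#'   `foldChanges`).
#' @param outdir optional output directory.
#' @return (invisibly) the written file paths; the tables themselves are
#'   in `result$summary` / `result$foldChanges`.
#' @export
renderReports <- function(result, outdir = NULL) {
  t1 <- data.frame(Sample = result$summary$library,
                   `Unfiltered reads` = result$summary$unfiltered_reads,
                   `Filtered reads` = result$summary$filtered_reads,
                   `%` = result$summary$percent_kept,
                   check.names = FALSE)
  t2 <- result$foldChanges
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(outdir, "table1_read_counts.tsv")
    write.table(t1, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(outdir, "table2_fold_changes.tsv")
    write.table(t2, f2, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    files <- c(f1, f2)
  }
  invisible(files)
}
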