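#' Simulation configuration for synthetic small RNA libraries
#'
#' Builds and validates the configuration of the synthetic-data
#' generator. The defaults emulate the study design the pipeline is
#' written for: four tissue libraries (leaves, flower buds and two seed
#' developmental stages), 50-cycle single-end reads carrying only a 3'
#' adapter, a bimodal 21/24-nt length structure (miRNA-derived inserts
#' plus a 24-nt siRNA-like background class), heavy-tailed (Zipf) locus
#' abundances with tissue-specific enrichment, and a tRNA/rRNA-like
#' decoy ncRNA background.
#'
#' @param seed integer; fully determines the generator output.
#' @param genomeLength total genome size in bases (two contigs).
#' @param nKnownLoci,nNovelLoci,nDecoyNcrna numbers of implanted known
#'   miRNA loci, novel miRNA loci and decoy ncRNA sequences.
#' @param libraries library names.
#' @param readsPerLibrary reads emitted per library (exact).
#' @param matureLengthRange inclusive range of mature lengths, nt.
#' @param starFraction fraction of a locus's reads drawn from the star
#'   arm rather than the mature arm.
#' @param backgroundFraction fraction of reads that are background
#'   (genome fragments, the 24-nt class, decoy fragments) rather than
#'   miRNA-derived.
#' @param adapter3 3' adapter sequence appended to every insert
#'   (>= 6 nt).
#' @param abundanceAlpha exponent of the truncated power-law (Zipf) locus
#'   abundance distribution.
#' @param lowQualityFraction fraction of reads drawn from the low-quality
#'   mixture component (mean phred 20, which fails the phred-26 filter);
#'   the remainder use mean phred 35.
#' @param seqErrorRate per-base sequencing substitution error rate.
#' @return a validated list of class `"SimulationConfig"`.
#' @examples
#' cfg <- simulationConfig(seed = 1, readsPerLibrary = 500)
#' @export
simulationConfig <- function(seed = 1L,
                             genomeLength = 100000L,
                             nKnownLoci = 24L,
                             nNovelLoci = 8L,
                             nDecoyNcrna = 6L,
                             libraries = c("leaves", "buds",
                                           "seed13", "seed19"),
                             readsPerLibrary = 10000L,
                             matureLengthRange = c(20L, 22L),
                             starFraction = 0.06,
                             backgroundFraction = 0.5,
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             abundanceAlpha = 0.7,
                             lowQualityFraction = 0.1,
                             seqErrorRate = 0.001) {
  cfg <- list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
              nKnownLoci = as.integer(nKnownLoci),
              nNovelLoci = as.integer(nNovelLoci),
              nDecoyNcrna = as.integer(nDecoyNcrna),
              libraries = as.character(libraries),
              readsPerLibrary = as.integer(readsPerLibrary),
              matureLengthRange = as.integer(matureLengthRange),
              starFraction = starFraction,
              backgroundFraction = backgroundFraction,
              adapter3 = toupper(adapter3),
              abundanceAlpha = abundanceAlpha,
              lowQualityFraction = lowQualityFraction,
              seqErrorRate = seqErrorRate)
  fr <- c(starFraction, backgroundFraction, lowQualityFraction, seqErrorRate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (nchar(cfg$adapter3) < 6L) stop("adapter3 must be at least 6 nt")
  if (grepl("[^ACGT]", cfg$adapter3)) stop("adapter3 must be ACGT only")
  if (length(cfg$libraries) < 1L) stop("at least one library required")
  if (cfg$matureLengthRange[1] < 19L || cfg$matureLengthRange[2] > 24L)
    stop("mature lengths must lie within 19-24 nt")
  # worst case implanted footprint: precursor <= 2*24 + maxloop + decoys
  footprint <- (cfg$nKnownLoci + cfg$nNovelLoci) * 260L +
    cfg$nDecoyNcrna * 130L
  if (cfg$genomeLength < footprint)
    stop("genomeLength too small for the requested implanted loci")
  class(cfg) <- "SimulationConfig"
  cfg
}

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Draw a random mature miRNA sequence
#'
#' Samples a mature sequence of the given length with a moderate G+C
#' content (50--75%), the composition range of real plant matures whose
#' precursor stems are stable enough to clear an MFE gate; uniformly
#' random A/T-rich sequences would build unrealistically weak hairpins.
#' Uses the current RNG state.
#'
#' @param length mature length in nt.
#' @return a DNA character string.
#' @export
randomMatureSequence <- function(length) {
  repeat {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c(0.22, 0.28, 0.28, 0.22))
    gc <- mean(s %in% c("G", "C"))
    if (gc >= 0.50 && gc <= 0.75) return(paste(s, collapse = ""))
  }
}

mutateSeq <- function(seq, nmut) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), nmut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Build a synthetic hairpin precursor around a mature sequence
#'
#' Constructs a stem-loop precursor `5' arm + loop + 3' arm` in which one
#' arm is the mature sequence and the other is its reverse complement
#' carrying `nBulges` point changes (creating interior loops in the
#' stem). The star is the full opposite arm, so that for a perfect stem
#' (`nBulges = 0`) the mature/star duplex is fully complementary and the
#' star is exactly the reverse complement of the mature. The loop
#' sequence is drawn A-rich so it does not pair into the stem.
#'
#' Uses the current R random number generator state.
#'
#' @param mature mature sequence, 19--24 nt (DNA alphabet).
#' @param loopLen terminal loop length, >= 3 nt.
#' @param nBulges number of point changes introduced into the non-mature
#'   arm (away from the arm ends).
#' @param arm which arm carries the mature: `"5p"` or `"3p"`.
#' @return a list with `precursor`, `star`, `matureStart`, `matureEnd`,
#'   `starStart`, `starEnd` (1-based within the precursor) and `arm`.
#' @examples
#' set.seed(1)
#' h <- buildHairpinLocus(paste(rep("ACG", 7), collapse = ""), loopLen = 12)
#' nchar(h$precursor)  # 21 + 12 + 21
#' @export
buildHairpinLocus <- function(mature, loopLen = 12L, nBulges = 0L,
                              arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  mature <- toupper(mature)
  loopLen <- as.integer(loopLen)
  lm <- nchar(mature)
  if (lm < 19L || lm > 24L) stop("mature length must be 19-24 nt")
  if (loopLen < 3L) stop("invalid geometry: loop length must be >= 3 nt")
  other <- revComp(mature)
  if (nBulges > 0L) {
    # keep changes in the central arm and well separated, so the
    # flanking helices stay long enough to pair and the duplex keeps
    # >= 75% complementarity
    ch <- strsplit(other, "")[[1]]
    lo <- 7L; hi <- lm - 6L
    repeat {
      pos <- sort(sample(lo:hi, min(nBulges, 2L)))
      if (length(pos) < 2L || diff(pos) >= 5L) break
    }
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    other <- paste(ch, collapse = "")
  }
  loop <- paste(sample(c("A", "A", "A", "C"), loopLen, replace = TRUE),
                collapse = "")
  if (arm == "5p") {
    precursor <- paste0(mature, loop, other)
    matureStart <- 1L; matureEnd <- lm
    starStart <- lm + loopLen + 1L; starEnd <- 2L * lm + loopLen
  } else {
    precursor <- paste0(other, loop, mature)
    starStart <- 1L; starEnd <- lm
    matureStart <- lm + loopLen + 1L; matureEnd <- 2L * lm + loopLen
  }
  list(precursor = precursor, star = other,
       matureStart = matureStart, matureEnd = matureEnd,
       starStart = starStart, starEnd = starEnd, arm = arm)
}

#' Simulate adapter-bearing small RNA libraries with ground truth
#'
#' Generates a synthetic genome (two contigs) with implanted known and
#' novel miRNA hairpin loci and decoy ncRNA sequences, a known-mature
#' reference set (miRBase-style `xxx-miRNNN[letter]` identifiers), and
#' one FASTQ library per configured tissue. Reads are mature/star/
#' background inserts with the 3' adapter appended and truncated to 50
#' cycles; phred strings come from a two-component quality mixture so the
#' phred-26 filter has a known expected pass rate. Per-locus, per-library
#' read counts follow a truncated power law with one tissue-enriched
#' ("primary") library per locus; realized counts are multinomial and are
#' recorded in the truth table, so truth-table counts sum exactly to the
#' number of miRNA-derived reads emitted.
#'
#' Novel-locus matures are 2--3 substitutions away from a known reference
#' mature (homologs, as the discovery path expects) but match no
#' reference exactly. Decoy reads and the exactly-24-nt background class
#' exercise decoy exclusion and length filtering; neither can form a
#' hairpin and neither must survive discovery.
#'
#' Output is byte-deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @param outdir optional directory; when given, writes per-library FASTQ
#'   files, FASTA references (genome, known matures, known precursors,
#'   decoys), the truth table as TSV and the config as a flat key=value
#'   file.
#' @return (invisibly when `outdir` is given) a list with `reads` (one
#'   [Biostrings::QualityScaledDNAStringSet] per library), `genome`,
#'   `matureRef`, `precursorRef`, `decoys` (DNAStringSets), `truth`
#'   (data.frame) and `config`; plus `files` when written.
#' @examples
#' sim <- simulateLibraries(simulationConfig(seed = 7,
#'   readsPerLibrary = 200, nKnownLoci = 6, nNovelLoci = 2,
#'   genomeLength = 20000))
#' head(sim$truth[, 1:6])
#' @export
simulateLibraries <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  nLoci <- config$nKnownLoci + config$nNovelLoci
  libs <- config$libraries

  ## --- reference matures (known) ---
  # spread known loci over families, a few with 2-3 members
  famSizes <- integer(0)
  left <- config$nKnownLoci
  while (left > 0L) {
    s <- if (left >= 3L && length(famSizes) %% 4L == 1L) 3L else
         if (left >= 2L && length(famSizes) %% 2L == 1L) 2L else 1L
    famSizes <- c(famSizes, s); left <- left - s
  }
  matures <- character(0); ids <- character(0); fams <- character(0)
  for (f in seq_along(famSizes)) {
    lm <- sample(seq(config$matureLengthRange[1],
                     config$matureLengthRange[2]), 1)
    base <- randomMatureSequence(lm)
    for (m in seq_len(famSizes[f])) {
      sq <- if (m == 1L) base else mutateSeq(base, sample(2:4, 1))
      while (sq %in% matures) sq <- mutateSeq(base, sample(2:4, 1))
      matures <- c(matures, sq)
      ids <- c(ids, sprintf("csa-miR%03d%s", f, letters[m]))
      fams <- c(fams, sprintf("miR%03d", f))
    }
  }
  ## --- novel matures: homologs of a known mature (2-3 mismatches) ---
  novSeqs <- character(0); novIds <- character(0)
  for (k in seq_len(config$nNovelLoci)) {
    repeat {
      src <- sample(seq_along(matures), 1)
      sq <- mutateSeq(matures[src], sample(2:3, 1))
      dists <- vapply(matures[nchar(matures) == nchar(sq)],
                      function(r) sum(utf8ToInt(r) != utf8ToInt(sq)),
                      integer(1))
      if (!(sq %in% c(matures, novSeqs)) && all(dists >= 1)) break
    }
    novSeqs <- c(novSeqs, sq)
    novIds <- c(novIds, sprintf("novel%03d", k))
  }
  allMat <- c(matures, novSeqs)
  allIds <- c(ids, novIds)
  allFam <- c(fams, novIds)
  status <- rep(c("known", "novel"),
                c(config$nKnownLoci, config$nNovelLoci))

  ## --- hairpin loci ---
  loci <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    loci[[i]] <- buildHairpinLocus(allMat[i],
                                   loopLen = sample(12:16, 1),
                                   nBulges = sample(0:1, 1),
                                   arm = sample(c("5p", "3p"), 1))
  }

  ## --- decoys (tRNA/rRNA-like) ---
  decoys <- vapply(seq_len(config$nDecoyNcrna),
                   function(i) randSeq(sample(70:120, 1)), character(1))
  names(decoys) <- sprintf("decoy%03d_tRNA_like", seq_along(decoys))

  ## --- genome with implants, two contigs ---
  contigLens <- c(chr1 = ceiling(config$genomeLength * 0.6),
                  chr2 = config$genomeLength -
                         ceiling(config$genomeLength * 0.6))
  genomeCh <- lapply(contigLens, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))
  inserts <- c(vapply(loci, `[[`, character(1), "precursor"), decoys)
  strands <- sample(c("+", "-"), length(inserts), replace = TRUE)
  placedContig <- character(length(inserts))
  placedStart <- integer(length(inserts))
  occupied <- list(chr1 = IRanges::IRanges(), chr2 = IRanges::IRanges())
  for (i in seq_along(inserts)) {
    w <- nchar(inserts[i])
    repeat {
      ctg <- sample(names(contigLens), 1,
                    prob = contigLens / sum(contigLens))
      pos <- sample(contigLens[[ctg]] - w - 1L, 1)
      cand <- IRanges::IRanges(pos, width = w)
      if (!length(IRanges::findOverlaps(cand, occupied[[ctg]]))) {
        occupied[[ctg]] <- c(occupied[[ctg]], cand)
        placedContig[i] <- ctg; placedStart[i] <- pos
        sq <- if (strands[i] == "+") inserts[i] else revComp(inserts[i])
        genomeCh[[ctg]][pos:(pos + w - 1L)] <- strsplit(sq, "")[[1]]
        break
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(genomeCh, paste,
                                            character(1), collapse = ""))
  names(genome) <- names(contigLens)

  ## --- abundance law: Zipf with a tissue-enriched primary library ---
  rank <- sample(nLoci)
  z <- rank^(-config$abundanceAlpha)
  primary <- libs[(seq_len(nLoci) - 1L) %% length(libs) + 1L]
  weights <- vapply(libs, function(l) z * ifelse(primary == l, 4, 1),
                    numeric(nLoci))
  props <- sweep(weights, 2, colSums(weights), "/")
  rownames(props) <- allIds

  nMir <- round(config$readsPerLibrary * (1 - config$backgroundFraction))
  nBg <- config$readsPerLibrary - nMir

  matCounts <- starCounts <- matrix(0L, nLoci, length(libs),
                                    dimnames = list(allIds, libs))
  readSets <- setNames(vector("list", length(libs)), libs)
  post <- "ATCTCGTATGCCGTCTTCTGCTTGAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"

  for (l in seq_along(libs)) {
    locReads <- as.integer(stats::rmultinom(1, nMir, props[, l]))
    starN <- stats::rbinom(nLoci, locReads, config$starFraction)
    matN <- locReads - starN
    matCounts[, l] <- matN
    starCounts[, l] <- starN
    insertsL <- c(rep(allMat, matN),
                  rep(vapply(loci, `[[`, character(1), "star"), starN))
    ## background: genome fragments 15-30 nt, 24-nt class, decoy fragments
    nFrag <- round(nBg * 0.4); n24 <- round(nBg * 0.4)
    nDec <- nBg - nFrag - n24
    fragFrom <- function(n, lenFun) {
      if (n == 0L) return(character(0))
      ctg <- sample(names(contigLens), n, replace = TRUE,
                    prob = contigLens / sum(contigLens))
      len <- lenFun(n)
      st <- vapply(seq_len(n), function(k)
        sample(contigLens[[ctg[k]]] - len[k], 1), integer(1))
      vapply(seq_len(n), function(k)
        paste(genomeCh[[ctg[k]]][st[k]:(st[k] + len[k] - 1L)],
              collapse = ""), character(1))
    }
    bg <- c(fragFrom(nFrag, function(n) sample(15:30, n, replace = TRUE)),
            fragFrom(n24, function(n) rep(24L, n)),
            if (nDec > 0) vapply(seq_len(nDec), function(k) {
              d <- decoys[[sample(length(decoys), 1)]]
              len <- sample(15:27, 1)
              st <- sample(nchar(d) - len + 1L, 1)
              substr(d, st, st + len - 1L)
            }, character(1)))
    insertsL <- c(insertsL, bg)
    insertsL <- sample(insertsL)  # shuffle read order

    ## sequencing errors
    nerr <- stats::rbinom(length(insertsL), nchar(insertsL),
                          config$seqErrorRate)
    for (k in which(nerr > 0L)) insertsL[k] <- mutateSeq(insertsL[k],
                                                         nerr[k])
    ## 50-cycle reads: insert + adapter + downstream, truncated
    reads <- substr(paste0(insertsL, config$adapter3, post), 1, 50)
    ## quality mixture
    low <- stats::runif(length(reads)) < config$lowQualityFraction
    qm <- matrix(round(stats::rnorm(length(reads) * 50,
                                    mean = ifelse(rep(low, each = 50), 20, 35),
                                    sd = 3)),
                 nrow = length(reads), byrow = TRUE)
    qm[qm < 2] <- 2L; qm[qm > 40] <- 40L
    quals <- vapply(seq_len(nrow(qm)),
                    function(r) intToUtf8(qm[r, ] + 33L), character(1))
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- sprintf("%s_read%06d", libs[l], seq_along(reads))
    readSets[[l]] <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(quals))
  }

  ## --- truth table ---
  w <- nchar(inserts[seq_len(nLoci)])
  precEnd <- placedStart[seq_len(nLoci)] + w - 1L
  mOffS <- vapply(loci, `[[`, integer(1), "matureStart")
  mOffE <- vapply(loci, `[[`, integer(1), "matureEnd")
  plus <- strands[seq_len(nLoci)] == "+"
  matGStart <- ifelse(plus, placedStart[seq_len(nLoci)] + mOffS - 1L,
                      precEnd - mOffE + 1L)
  matGEnd <- ifelse(plus, placedStart[seq_len(nLoci)] + mOffE - 1L,
                    precEnd - mOffS + 1L)
  truth <- data.frame(
    locusId = allIds, contig = placedContig[seq_len(nLoci)],
    precStart = placedStart[seq_len(nLoci)], precEnd = precEnd,
    strand = strands[seq_len(nLoci)],
    matureStart = matGStart, matureEnd = matGEnd,
    matureSeq = allMat,
    starSeq = vapply(loci, `[[`, character(1), "star"),
    arm = vapply(loci, `[[`, character(1), "arm"),
    family = allFam, status = status, primaryLib = primary,
    stringsAsFactors = FALSE)
  truth <- cbind(truth,
                 setNames(as.data.frame(matCounts),
                          paste0("count_", libs)),
                 setNames(as.data.frame(starCounts),
                          paste0("star_", libs)))
  rownames(truth) <- NULL

  matureRef <- Biostrings::DNAStringSet(matures); names(matureRef) <- ids
  precRef <- Biostrings::DNAStringSet(
    vapply(loci[seq_len(config$nKnownLoci)], `[[`, character(1),
           "precursor"))
  names(precRef) <- paste0(ids, "_precursor")
  decoySet <- Biostrings::DNAStringSet(decoys)

  decoyLoci <- if (config$nDecoyNcrna > 0L) {
    di <- nLoci + seq_len(config$nDecoyNcrna)
    data.frame(decoyId = names(decoys), contig = placedContig[di],
               start = placedStart[di],
               end = placedStart[di] + nchar(inserts[di]) - 1L,
               strand = strands[di], stringsAsFactors = FALSE)
  } else {
    data.frame(decoyId = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  }

  out <- list(reads = readSets, genome = genome, matureRef = matureRef,
              precursorRef = precRef, decoys = decoySet, truth = truth,
              decoyLoci = decoyLoci, props = props, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (l in libs) {
      f <- file.path(outdir, paste0(l, ".fastq"))
      Biostrings::writeXStringSet(readSets[[l]], f, format = "fastq",
                                  qualities = Biostrings::quality(readSets[[l]]))
      files[[paste0("fastq_", l)]] <- f
    }
    wr <- function(x, name) {
      f <- file.path(outdir, name)
      Biostrings::writeXStringSet(x, f)
      f
    }
    files$genome <- wr(genome, "genome.fasta")
    files$matures <- wr(matureRef, "matures.fasta")
    files$precursors <- wr(precRef, "precursors.fasta")
    files$decoys <- wr(decoySet, "decoys.fasta")
    files$truth <- file.path(outdir, "truth.tsv")
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files$config <- file.path(outdir, "config.txt")
    writeLines(paste0(names(unclass(config)), "=",
                      vapply(unclass(config), function(v)
                        paste(v, collapse = ","), character(1))),
               files$config)
    out$files <- files
    return(invisible(out))
  }
  out
}
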