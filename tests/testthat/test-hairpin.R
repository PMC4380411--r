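# Window extraction, star location, complementarity, criteria, refinement.

test_that("window extraction: flanks, clamping, strand symmetry", {
  set.seed(41)
  g <- Biostrings::DNAStringSet(c(chr = randomDNA(2000)))
  a <- list(contig = "chr", start = 500L, end = 520L, strand = "+")
  w <- extractWindow(a, g, flank = 200)
  expect_identical(nchar(w$window), 421L)  # 200 + 21 + 200
  expect_identical(w$matureStart, 201L)
  expect_identical(substr(w$window, 201, 221),
                   as.character(Biostrings::subseq(g[[1]], 500, 520)))
  # clamped at the contig start
  w2 <- extractWindow(list(contig = "chr", start = 1L, end = 21L,
                           strand = "+"), g, flank = 200)
  expect_identical(nchar(w2$window), 221L)
  expect_identical(w2$matureStart, 1L)
  # minus strand: reverse complement of the plus extraction
  wm <- extractWindow(list(contig = "chr", start = 500L, end = 520L,
                           strand = "-"), g, flank = 200)
  expect_identical(wm$window, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(w$window))))
  expect_identical(wm$matureStart, 201L)
  expect_error(extractWindow(list(contig = "nope", start = 1L, end = 21L,
                                  strand = "+"), g), "unknown contig")
})

test_that("star location on synthetic hairpins recovers the implanted arm", {
  set.seed(42)
  m <- randomMatureSequence(21)
  h <- buildHairpinLocus(m, loopLen = 12, nBulges = 0)
  f <- foldMFE(h$precursor)
  st <- locateStar(f, h$matureStart, h$matureEnd)
  expect_identical(st$starStart, h$starStart)
  expect_identical(st$starEnd, h$starEnd)
  expect_identical(st$armLabel, "5p")
  # mature on the 3' arm: labels swap, star on the 5' arm
  h2 <- buildHairpinLocus(m, loopLen = 12, nBulges = 0, arm = "3p")
  st2 <- locateStar(foldMFE(h2$precursor), h2$matureStart, h2$matureEnd)
  expect_identical(st2$armLabel, "3p")
  expect_lt(st2$starEnd, h2$matureStart)
})

test_that("a mature living in the terminal loop has no star", {
  # place the 'mature' across the unpaired loop of a hairpin
  sq <- paste0("GGGGGGGGGG", strrep("A", 15), "CCCCCCCCCC")
  f <- foldMFE(sq)
  expect_null(locateStar(f, 12, 24))
})

test_that("complementarity boundary arithmetic", {
  # synthetic fold: 20-nt mature, controllable pairing
  mkFold <- function(nPaired) {
    # mature 1..20 pairs the tail; unpaired mature bases moved into loop
    m <- 20
    db <- c(rep("(", nPaired), rep(".", m - nPaired), rep(".", 4),
            rep(")", nPaired))
    sq <- strrep("G", nPaired + (m - nPaired) + 4 + nPaired)
    # build a character structure directly (energies irrelevant here)
    new("FoldResult", sequence = chartr("T", "U", sq),
        structure = paste(db, collapse = ""), mfe = -30)
  }
  f15 <- mkFold(15)
  expect_identical(complementarityPct(f15, 1, 20, 25, 39), 75)   # boundary
  f14 <- mkFold(14)
  expect_identical(complementarityPct(f14, 1, 20, 24, 38), 70)
  f20 <- mkFold(20)
  expect_identical(complementarityPct(f20, 1, 20, 21, 44), 100)
})

test_that("hairpin criteria boundaries behave as specified", {
  mk <- function(mfeVal, len, comp) {
    new("HairpinCandidate", precursor = strrep("A", len), contig = "c",
        start = 1L, end = as.integer(len), strand = "+",
        fold = new("FoldResult", sequence = strrep("A", len),
                   structure = strrep(".", len), mfe = mfeVal),
        matureStart = 1L, matureEnd = 21L, armLabel = "5p",
        starStart = NA_integer_, starEnd = NA_integer_,
        complementarity = comp, verdict = NA, failed = character(0))
  }
  # all three at their passing boundaries
  expect_true(applyHairpinCriteria(mk(-20.1, 209L, 80))@verdict)
  expect_true(applyHairpinCriteria(mk(-20.1, 210L, 75))@verdict)
  # MFE is a strict inequality: exactly -20 and -19.9 both fail
  expect_identical(applyHairpinCriteria(mk(-19.9, 100L, 100))@failed, "mfe")
  expect_identical(applyHairpinCriteria(mk(-20, 100L, 100))@failed, "mfe")
  # one past each boundary
  expect_identical(applyHairpinCriteria(mk(-50, 211L, 100))@failed,
                   "length")
  expect_identical(applyHairpinCriteria(mk(-50, 100L, 74.9))@failed,
                   "complementarity")
  # a star-less candidate fails complementarity
  expect_identical(applyHairpinCriteria(mk(-50, 100L, NA_real_))@failed,
                   "complementarity")
})

test_that("refinement recovers implanted precursor spans within 10 nt", {
  sim <- smallSim()
  tr <- sim$truth
  hits <- 0L
  for (i in head(seq_len(nrow(tr)), 6)) {
    r <- tr[i, ]
    anc <- list(contig = r$contig, start = r$matureStart,
                end = r$matureEnd, strand = r$strand)
    win <- extractWindow(anc, sim$genome, flank = 200)
    cand <- refinePrecursor(win)
    expect_false(is.null(cand))
    # refined genomic span within 10 nt of the implanted precursor ends
    expect_lte(abs(cand@start - r$precStart), 10)
    expect_lte(abs(cand@end - r$precEnd), 10)
    expect_true(cand@verdict)
    expect_gte(nchar(cand@precursor), 52)
    expect_lte(nchar(cand@precursor), 240)
    hits <- hits + 1L
  }
  expect_identical(hits, 6L)
})

test_that("background windows rarely refine into passing hairpins", {
  set.seed(43)
  passes <- 0
  n <- 40
  for (i in 1:n) {
    win <- list(window = randomDNA(421), matureStart = 201L,
                matureEnd = 221L, contig = "bg", windowStart = 1L,
                windowEnd = 421L, strand = "+")
    if (!is.null(refinePrecursor(win))) passes <- passes + 1
  }
  expect_lt(passes / n, 0.05)
})

test_that("dot-bracket and GFF3 exports round-trip coherently", {
  set.seed(44)
  m <- randomMatureSequence(21)
  h <- buildHairpinLocus(m, loopLen = 12)
  cand <- hairpinCandidate(h$precursor, h$matureStart, h$matureEnd,
                           contig = "chr1", start = 1000L,
                           end = 1000L + nchar(h$precursor) - 1L)
  db <- tempfile(fileext = ".db")
  exportDotBracket(list(hp1 = cand), db)
  lines <- readLines(db)
  expect_identical(lines[1], ">hp1")
  expect_identical(lines[2], foldedSequence(cand@fold))
  expect_match(lines[3], "^[.()]+ \\(-?[0-9.]+\\)$")
  gff <- tempfile(fileext = ".gff3")
  exportHairpinGFF3(list(hp1 = cand), gff)
  gr <- rtracklayer::import(gff)
  expect_setequal(as.character(gr$type),
                  c("miRNA_primary_transcript", "miRNA", "miRNA_star"))
  pre <- gr[gr$type == "miRNA_primary_transcript"]
  expect_identical(GenomicRanges::start(pre), 1000L)
})
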