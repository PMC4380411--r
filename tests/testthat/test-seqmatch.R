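# Exact genome anchoring, known/homolog matching, decoy flagging.

test_that("anchoring finds exact occurrences on both strands", {
  set.seed(21)
  core <- randomDNA(400)
  tag <- substr(core, 101, 121)
  g <- Biostrings::DNAStringSet(c(chrA = core))
  a <- anchorToGenome(tag, g)
  expect_identical(length(a), 1L)
  expect_identical(GenomicRanges::start(a), 101L)
  expect_identical(GenomicRanges::end(a), 121L)
  expect_identical(as.character(GenomicRanges::strand(a)), "+")
  # reverse complement anchors on the minus strand at the same span
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  a2 <- anchorToGenome(rc, g)
  expect_identical(as.character(GenomicRanges::strand(a2)), "-")
  expect_identical(GenomicRanges::start(a2), 101L)
  # N-containing tags get no anchors
  expect_identical(length(anchorToGenome(paste0("N", substr(tag, 2, 21)),
                                         g)), 0L)
})

test_that("anchoring agrees with a naive full-scan search", {
  set.seed(22)
  g <- Biostrings::DNAStringSet(c(c1 = randomDNA(3000),
                                  c2 = randomDNA(2000)))
  tags <- c(vapply(1:15, function(i) {
    ctg <- sample(1:2, 1)
    w <- sample(15:25, 1)
    st <- sample(length(g[[ctg]]) - w, 1)
    sq <- as.character(Biostrings::subseq(g[[ctg]], st, st + w - 1))
    if (runif(1) < 0.5) sq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  }, character(1)), vapply(1:5, function(i) randomDNA(20), character(1)))
  tags <- unique(tags)
  a <- anchorToGenome(tags, g, maxLoci = 100)
  # oracle: regex scan of the genome strings
  naive <- list()
  for (tg in tags) {
    for (ctg in names(g)) {
      gs <- as.character(g[[ctg]])
      for (str in c("+", "-")) {
        pat <- if (str == "+") tg else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(tg)))
        hits <- gregexpr(paste0("(?=", pat, ")"), gs, perl = TRUE)[[1]]
        hits <- hits[hits > 0]
        for (h in hits)
          naive[[length(naive) + 1]] <- paste(tg, ctg, h, str)
      }
    }
  }
  got <- paste(a$tag, GenomicRanges::seqnames(a), GenomicRanges::start(a),
               GenomicRanges::strand(a))
  expect_setequal(got, unlist(naive))
})

test_that("implanted matures anchor at their truth-table spans", {
  sim <- smallSim()
  a <- anchorToGenome(sim$truth$matureSeq, sim$genome)
  key <- paste(a$tag, GenomicRanges::seqnames(a), GenomicRanges::start(a),
               GenomicRanges::strand(a))
  want <- paste(sim$truth$matureSeq, sim$truth$contig,
                sim$truth$matureStart, sim$truth$strand)
  expect_true(all(want %in% key))
})

test_that("known matching is exact in size and composition", {
  ref <- c("ath-miR166b" = "TCGGACCAGGCTTCATTCCCC")
  expect_identical(matchKnown("TCGGACCAGGCTTCATTCCCC", ref)$family,
                   "miR166")
  # one substitution: not known
  expect_identical(nrow(matchKnown("TCGGACCAGGCTTCATTCCCA", ref)), 0L)
  # truncation by one base: not known (size must match)
  expect_identical(nrow(matchKnown("TCGGACCAGGCTTCATTCCC", ref)), 0L)
  # U in the reference is handled
  refU <- c("ath-miR166b" = "UCGGACCAGGCUUCAUUCCCC")
  expect_identical(nrow(matchKnown("TCGGACCAGGCTTCATTCCCC", refU)), 1L)
  expect_error(matchKnown("ACGT", c(a = "ACGT", a = "ACGG")), "duplicate")
})

test_that("homolog matching equals an exhaustive Hamming scan", {
  set.seed(23)
  refs <- setNames(vapply(1:50, function(i) randomDNA(21), character(1)),
                   sprintf("ref%02d", 1:50))
  tags <- c(vapply(1:100, function(i) randomDNA(21), character(1)),
            # planted homologs at known distances
            vapply(sample(refs, 40, replace = TRUE), function(r) {
              ch <- strsplit(r, "")[[1]]
              pos <- sample(21, sample(1:4, 1))
              for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"),
                                                     ch[p]), 1)
              paste(ch, collapse = "")
            }, character(1), USE.NAMES = FALSE))
  tags <- unique(tags)
  got <- matchHomolog(tags, refs, maxMismatch = 3)
  # brute-force all-pairs oracle
  for (tg in tags) {
    d <- vapply(refs, hammingDist, integer(1), a = tg)
    if (min(d) <= 3) {
      row <- got[got$tag == tg, ]
      expect_identical(nrow(row), 1L)
      expect_identical(row$mismatches, min(d))
      expect_identical(row$refId,
                       sort(names(refs)[d == min(d)])[1])
    } else {
      expect_identical(nrow(got[got$tag == tg, ]), 0L)
    }
  }
})

test_that("windowed homolog matching finds tags inside precursors", {
  set.seed(24)
  prec <- c(precA = randomDNA(120))
  tag <- substr(prec[[1]], 40, 60)  # exact sub-block, 0 mismatches
  got <- matchHomolog(tag, matureRef = character(0),
                      precursorRef = prec)
  expect_identical(got$refId, "precA")
  expect_identical(got$mismatches, 0L)
})

test_that("decoy flagging: shared 18-mers on either strand", {
  set.seed(25)
  dec <- c(tRNA1 = randomDNA(80))
  blk <- substr(dec[[1]], 10, 29)  # 20-mer
  prec <- paste0(randomDNA(30), blk, randomDNA(30))
  precRC <- paste0(randomDNA(30),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(blk))), randomDNA(30))
  clean <- randomDNA(90)
  expect_identical(matchDecoys(c(prec, precRC, clean), dec),
                   c(TRUE, TRUE, FALSE))
  # empty decoy set flags nothing
  expect_identical(matchDecoys(c(prec, clean), character(0)),
                   c(FALSE, FALSE))
})

test_that("decoy-derived candidates are flagged, true loci are not", {
  sim <- smallSim()
  decoyFrags <- vapply(seq_len(3), function(i) {
    d <- as.character(sim$decoys[[i]])
    paste0(substr(d, 1, 40))
  }, character(1))
  truePrec <- vapply(seq_len(nrow(sim$truth)), function(i) {
    r <- sim$truth[i, ]
    s <- as.character(Biostrings::subseq(sim$genome[[r$contig]],
                                         r$precStart, r$precEnd))
    s
  }, character(1))
  expect_true(all(matchDecoys(decoyFrags, sim$decoys)))
  expect_false(any(matchDecoys(truePrec, sim$decoys)))
})

test_that("strand symmetry: re-anchoring the reverse complement swaps strands", {
  set.seed(26)
  g <- Biostrings::DNAStringSet(c(x = randomDNA(1000)))
  tag <- substr(as.character(g[[1]]), 200, 220)
  a <- anchorToGenome(tag, g)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  b <- anchorToGenome(rc, g)
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(GenomicRanges::end(a), GenomicRanges::end(b))
  expect_false(any(as.character(GenomicRanges::strand(a)) ==
                   as.character(GenomicRanges::strand(b))))
})
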