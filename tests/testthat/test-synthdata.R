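# The synthetic-library generator: geometry, determinism, count laws.

test_that("hairpin locus geometry: perfect stem", {
  set.seed(5)
  m <- randomDNA(21)
  h <- buildHairpinLocus(m, loopLen = 12, nBulges = 0)
  expect_identical(nchar(h$precursor), 54L)  # 21 + 12 + 21
  expect_identical(substr(h$precursor, 1, 21), m)
  expect_identical(h$star, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(m))))
  # folding the perfect stem gives full mature/star complementarity
  cand <- hairpinCandidate(h$precursor, h$matureStart, h$matureEnd)
  expect_identical(cand@complementarity, 100)
  expect_gte(cand@complementarity, 75)
  expect_error(buildHairpinLocus(m, loopLen = 2), "invalid geometry")
  expect_error(buildHairpinLocus(randomDNA(18)), "19-24")
})

test_that("generated default loci pass the three hairpin criteria", {
  # the generator's default geometry must produce callable precursors
  set.seed(1)
  for (i in 1:100) {
    m <- randomMatureSequence(sample(20:22, 1))
    h <- buildHairpinLocus(m, loopLen = sample(12:16, 1),
                           nBulges = sample(0:1, 1),
                           arm = sample(c("5p", "3p"), 1))
    cand <- hairpinCandidate(h$precursor, h$matureStart, h$matureEnd)
    expect_true(cand@verdict,
                label = paste("locus", i, "criteria:",
                              paste(cand@failed, collapse = ",")))
  }
})

test_that("same seed gives byte-identical libraries", {
  cfg <- simulationConfig(seed = 123, readsPerLibrary = 300,
                          nKnownLoci = 4, nNovelLoci = 2,
                          genomeLength = 20000)
  a <- simulateLibraries(cfg)
  b <- simulateLibraries(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  for (lib in cfg$libraries) {
    expect_identical(as.character(a$reads[[lib]]),
                     as.character(b$reads[[lib]]))
    expect_identical(as.character(Biostrings::quality(a$reads[[lib]])),
                     as.character(Biostrings::quality(b$reads[[lib]])))
  }
  expect_identical(a$truth, b$truth)
})

test_that("reads per library is exact and truth counts are conserved", {
  sim <- smallSim()
  cfg <- sim$config
  for (lib in cfg$libraries)
    expect_identical(length(sim$reads[[lib]]), cfg$readsPerLibrary)
  nMir <- round(cfg$readsPerLibrary * (1 - cfg$backgroundFraction))
  cm <- as.matrix(sim$truth[, paste0("count_", cfg$libraries)])
  sm <- as.matrix(sim$truth[, paste0("star_", cfg$libraries)])
  expect_equal(unname(colSums(cm) + colSums(sm)),
               rep(nMir, length(cfg$libraries)))
})

test_that("implanted matures sit in the genome at their recorded spans", {
  sim <- smallSim()
  for (i in seq_len(nrow(sim$truth))) {
    r <- sim$truth[i, ]
    seg <- as.character(Biostrings::subseq(sim$genome[[r$contig]],
                                           r$matureStart, r$matureEnd))
    if (r$strand == "-")
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    expect_identical(seg, r$matureSeq)
  }
})

test_that("every implanted locus clears the novel abundance gate at default depth", {
  sim <- sim42()
  cm <- as.matrix(sim$truth[, paste0("count_", sim$config$libraries)])
  expect_true(all(apply(cm, 1, max) > 80))
})

test_that("pure-miRNA config emits only implanted mature sequences", {
  cfg <- simulationConfig(seed = 9, readsPerLibrary = 200,
                          nKnownLoci = 4, nNovelLoci = 1,
                          genomeLength = 20000,
                          backgroundFraction = 0, starFraction = 0,
                          seqErrorRate = 0)
  sim <- simulateLibraries(cfg)
  for (lib in cfg$libraries) {
    cl <- clipAdapter(as.character(sim$reads[[lib]]), cfg$adapter3)
    expect_true(all(cl$insert %in% sim$truth$matureSeq))
  }
})

test_that("observed counts track configured multinomial expectations", {
  cfg <- simulationConfig(seed = 7, readsPerLibrary = 10000,
                          nKnownLoci = 10, nNovelLoci = 3,
                          genomeLength = 50000)
  sim <- simulateLibraries(cfg)
  # each locus's realized mature+star count is one multinomial cell with
  # the configured probability sim$props[i, lib]; check 3-sd agreement
  nMir <- round(cfg$readsPerLibrary * (1 - cfg$backgroundFraction))
  tot <- as.matrix(sim$truth[, paste0("count_", cfg$libraries)]) +
    as.matrix(sim$truth[, paste0("star_", cfg$libraries)])
  p <- sim$props[sim$truth$locusId, cfg$libraries]
  expect_true(all(abs(tot - nMir * p) <=
                  3 * sqrt(nMir * p * (1 - p)) + 1e-9))
})

test_that("config validation rejects bad parameters", {
  expect_error(simulationConfig(adapter3 = "ACGT"), "at least 6")
  expect_error(simulationConfig(backgroundFraction = 1.5), "fractions")
  expect_error(simulationConfig(genomeLength = 1000), "too small")
})

test_that("file output round-trips through standard formats", {
  od <- file.path(tempdir(), "simout")
  sim <- simulateLibraries(simulationConfig(seed = 11,
    readsPerLibrary = 100, nKnownLoci = 4, nNovelLoci = 1,
    genomeLength = 20000), outdir = od)
  expect_true(file.exists(file.path(od, "leaves.fastq")))
  rt <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
    file.path(od, "leaves.fastq")))
  expect_identical(as.character(rt), as.character(sim$reads$leaves))
  g <- Biostrings::readDNAStringSet(file.path(od, "genome.fasta"))
  expect_identical(as.character(g), as.character(sim$genome))
  tt <- read.delim(file.path(od, "truth.tsv"))
  expect_identical(nrow(tt), nrow(sim$truth))
  unlink(od, recursive = TRUE)
})
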