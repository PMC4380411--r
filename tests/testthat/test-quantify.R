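# Family aggregation, signed fold changes, CPM, the report table.

table2 <- read.delim(system.file("extdata", "table2_counts.tsv",
                                 package = "mircam"))

# every fold change printed in the published tissue table, as
# (family, baseline, comparison, value); NA = blank cell
printedFC <- rbind(
  data.frame(family = c("miR156", "miR165", "miR166", "miR168", "miR319",
                        "miR396", "miR408", "miR827", "miR858", "miR6300",
                        "miR6173", "miR4995"),
             base = "leaves", cmp = "buds",
             fc = c(-2.1, 4.4, 2.2, 2.1, 57.8, -2.0, 2.0, 28.0, 5.7,
                    17.9, -10.7, -2.4)),
  data.frame(family = c("miR156", "miR160", "miR165", "miR166", "miR167",
                        "miR168", "miR171", "miR173", "miR319", "miR395",
                        "miR396", "miR398", "miR403", "miR408", "miR825",
                        "miR827", "miR858", "miR4995", "miR6173"),
             base = "leaves", cmp = "seed13",
             fc = c(3.4, -8.7, 4.6, 2.7, 4.1, 3.6, -2.0, 2.1, 5.5, 4.6,
                    -4.2, 66.3, -2.9, 43.3, -4.4, 34.1, 16.2, -25.3,
                    -75.0)),
  data.frame(family = c("miR156", "miR164", "miR165", "miR166", "miR167",
                        "miR169", "miR170", "miR172", "miR173", "miR319",
                        "miR393", "miR395", "miR396", "miR398", "miR408",
                        "miR825", "miR824", "miR827", "miR858", "miR2910",
                        "miR4995", "miR6300", "miR6173"),
             base = "leaves", cmp = "seed19",
             fc = c(6.4, -2.1, 5.3, 4.7, 2.0, -2.5, 2.0, -3.7, 2.4, 36.4,
                    -2.5, -2.3, -3.2, 39.9, 5.8, -2.0, 8.5, 92.4, 38.5,
                    -3.2, -32.6, 2.6, -75.0)),
  data.frame(family = c("miR159", "miR160", "miR164", "miR167", "miR168",
                        "miR169", "miR172", "miR319", "miR393", "miR395",
                        "miR408", "miR825", "miR824", "miR827", "miR858"),
             base = "seed13", cmp = "seed19",
             fc = c(2.0, 5.6, -3.0, -2.1, -2.0, -2.0, -2.7, 6.7, -2.3,
                    -10.8, -7.5, 2.2, 4.4, 2.7, 2.4)))

test_that("signed fold change reproduces printed ratio arithmetic", {
  expect_identical(signedFoldChange(69, 3988)$signed_fc, 57.8)
  expect_identical(signedFoldChange(1627, 777)$signed_fc, -2.1)
  expect_identical(signedFoldChange(75, 1)$signed_fc, -75.0)
  expect_identical(signedFoldChange(12, 796)$signed_fc, 66.3)
  expect_identical(signedFoldChange(16976, 34027)$signed_fc, 2.0)
  # equal nonzero counts: 1.0, not reported
  r <- signedFoldChange(100, 100)
  expect_identical(r$signed_fc, 1.0)
  expect_false(r$reported)
  # zero counts: undefined (presence/absence), not a ratio
  expect_true(is.na(signedFoldChange(0, 50)$signed_fc))
  expect_true(is.na(signedFoldChange(50, 0)$signed_fc))
  # the reporting gate uses the ROUNDED value: 6405/3253 = 1.969 -> 2.0
  r2 <- signedFoldChange(3253, 6405)
  expect_identical(r2$signed_fc, 2.0)
  expect_true(r2$reported)
})

test_that("every printed fold change is reproduced from printed counts", {
  for (i in seq_len(nrow(printedFC))) {
    row <- printedFC[i, ]
    a <- table2[table2$family == row$family, row$base]
    b <- table2[table2$family == row$family, row$cmp]
    expect_identical(signedFoldChange(a, b)$signed_fc, row$fc,
                     label = paste(row$family, row$cmp, "vs", row$base))
  }
})

test_that("blank cells of the printed table stay below the report gate", {
  cols <- c("leaves", "buds", "seed13", "seed19")
  printedKey <- paste(printedFC$family, printedFC$base, printedFC$cmp)
  for (pr in list(c("leaves", "buds"), c("leaves", "seed13"),
                  c("leaves", "seed19"), c("seed13", "seed19"))) {
    for (fam in table2$family) {
      if (paste(fam, pr[1], pr[2]) %in% printedKey) next
      fc <- signedFoldChange(table2[table2$family == fam, pr[1]],
                             table2[table2$family == fam, pr[2]])
      expect_false(isTRUE(fc$reported),
                   label = paste(fam, pr[2], "vs", pr[1], "blank"))
    }
  }
})

test_that("antisymmetry of the signed convention", {
  set.seed(51)
  a <- sample(1:10000, 60); b <- sample(1:10000, 60)
  fab <- signedFoldChange(a, b)$signed_fc
  fba <- signedFoldChange(b, a)$signed_fc
  keep <- abs(fab) > 1  # at |fc| == 1.0 both directions report +1.0
  expect_equal(fab[keep], -fba[keep])
})

test_that("family aggregation is exact integer summation", {
  cnt <- matrix(c(10L, 20L, 30L, 5L, 7L, 11L), nrow = 3,
                dimnames = list(c("csa-miR166a", "csa-miR166b",
                                  "csa-miR165a"), c("leaves", "buds")))
  fam <- aggregateFamilies(cnt)
  expect_identical(fam["miR166", "leaves"], 30L)   # 10 + 20
  expect_identical(fam["miR165", "leaves"], 30L)
  expect_identical(fam["miR166", "buds"], 12L)
  # miR165 and miR166 are distinct families
  expect_identical(nrow(fam), 2L)
  # single-member family equals the member row
  one <- aggregateFamilies(cnt[3, , drop = FALSE])
  expect_identical(unname(one["miR165", ]), unname(cnt[3, ]))
})

test_that("family totals on synthetic data equal truth-table sums", {
  sim <- smallSim()
  cm <- as.matrix(sim$truth[, paste0("count_", sim$config$libraries)])
  rownames(cm) <- sim$truth$locusId
  fam <- aggregateFamilies(cm, sim$truth$family)
  for (f in unique(sim$truth$family)) {
    expect_equal(unname(fam[f, ]),
                 unname(colSums(cm[sim$truth$family == f, , drop = FALSE])))
  }
})

test_that("CPM normalization and the library-share arithmetic", {
  expect_identical(normalizeCPM(matrix(100), totals = 1e6)[1, 1], 100)
  # the dominant family share: 1,110,941 of 1,420,996 reads -> 78%
  share <- round(100 * 1110941 / 1420996)
  expect_identical(share, 78)
  # normalized columns sum to 1e6
  m <- matrix(c(10, 40, 50, 1, 1, 8), 3,
              dimnames = list(letters[1:3], c("x", "y")))
  expect_equal(unname(colSums(normalizeCPM(m))), c(1e6, 1e6))
  expect_error(normalizeCPM(matrix(0)), "total")
})

test_that("the report table applies count and fold-change gates", {
  m <- as.matrix(table2[, c("leaves", "buds", "seed13", "seed19")])
  rownames(m) <- table2$family
  rep <- buildFoldChangeTable(m)
  expect_identical(rep$fc_buds_vs_leaves[rep$family == "miR319"], 57.8)
  expect_identical(rep$fc_seed13_vs_leaves[rep$family == "miR6173"], -75.0)
  expect_identical(rep$fc_seed13_vs_leaves[rep$family == "miR398"], 66.3)
  expect_identical(rep$fc_seed19_vs_seed13[rep$family == "miR159"], 2.0)
  # below-gate cells are blank
  expect_true(is.na(rep$fc_buds_vs_leaves[rep$family == "miR159"]))
  # a family that never reaches 50 reads is dropped from the table
  m2 <- rbind(m, tiny = c(4L, 9L, 12L, 3L))
  expect_false("tiny" %in% buildFoldChangeTable(m2)$family)
  expect_true(all(abs(as.matrix(
    rep[, grep("^fc_", names(rep))])) >= 2, na.rm = TRUE))
})
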