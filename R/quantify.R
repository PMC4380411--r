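#' Signed fold change between two read counts
#'
#' The signed convention of the tissue-comparison tables: with `countA`
#' the baseline and `countB` the comparison library, the ratio
#' `countB / countA` is reported rounded at one decimal when it is at
#' least 1, and as minus the rounded reciprocal otherwise (a negative
#' number denotes a
#' decrease). Rounding is half away from zero at one decimal, and the
#' `reported` flag is `|signed_fc| >= minReport` evaluated on the
#' *rounded* value (so 6405/3253 = 1.969 rounds to 2.0 and is
#' reported). Undefined (NA) when either count is zero -- a
#' presence/absence case, not a fold change.
#'
#' @param countA,countB non-negative read counts (vectorized).
#' @param minReport reporting threshold on `|signed_fc|` (default 2).
#' @return data.frame with `signed_fc` (NA when undefined) and
#'   `reported`.
#' @examples
#' signedFoldChange(69, 3988)    #  57.8
#' signedFoldChange(1627, 777)   #  -2.1
#' signedFoldChange(75, 1)       # -75.0
#' @export
signedFoldChange <- function(countA, countB, minReport = 2) {
  stopifnot(all(countA >= 0, na.rm = TRUE),
            all(countB >= 0, na.rm = TRUE))
  n <- max(length(countA), length(countB))
  countA <- rep_len(countA, n); countB <- rep_len(countB, n)
  fc <- rep(NA_real_, n)
  ok <- countA > 0 & countB > 0
  r <- countB[ok] / countA[ok]
  fc[ok] <- ifelse(r >= 1, roundHalfUp(r, 1), -roundHalfUp(1 / r, 1))
  data.frame(signed_fc = fc, reported = !is.na(fc) & abs(fc) >= minReport)
}

#' Aggregate miRNA counts to family level
#'
#' Sums per-miRNA counts within each family for every library; a family
#' row equals the sum of its member rows exactly (integer arithmetic).
#' Families are as parsed by [mirFamily()], so miR165 and miR166 remain
#' distinct.
#'
#' @param counts integer matrix (miRNAs x libraries), rownames = miRNA
#'   ids.
#' @param families character vector of family labels per row (defaults
#'   to `mirFamily(rownames(counts))`).
#' @return integer matrix (families x libraries), rows sorted by family
#'   label.
#' @export
aggregateFamilies <- function(counts, families = NULL) {
  counts <- as.matrix(counts)
  if (is.null(families)) families <- mirFamily(rownames(counts))
  stopifnot(length(families) == nrow(counts))
  out <- rowsum(counts, group = families, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Normalize counts to counts-per-million of assigned reads
#'
#' `10^6 * count / libraryTotal`, where the library total is the total
#' number of miRNA-assigned reads in that library (so normalized columns
#' sum to 10^6 over all miRNAs when totals are the column sums).
#'
#' @param counts matrix (rows = miRNA or family, columns = libraries).
#' @param totals per-library totals; defaults to `colSums(counts)`.
#' @return numeric matrix of CPM values.
#' @examples
#' normalizeCPM(matrix(100, 1, 1, dimnames = list("x", "lib")),
#'              totals = 1e6)
#' @export
normalizeCPM <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("library total must be > 0")
  sweep(counts, 2, totals, function(x, t) 1e6 * x / t)
}

#' Build the tissue fold-change report
#'
#' The family-level differential table: one row per family reaching
#' `minCount` reads in at least one library, the four per-library read
#' counts, and the signed fold change for each requested library pair,
#' blank (NA) when the rounded `|fc|` is below `minFc` or when either
#' count is zero. By default fold changes are computed on raw counts
#' (the published table's numbers are exact raw-count ratios);
#' `fcOn = "normalized"` computes them on CPM values instead.
#'
#' @param familyCounts integer matrix (families x libraries).
#' @param pairs list of `c(baseline, comparison)` library-name pairs;
#'   default: buds vs leaves, seed13 vs leaves, seed19 vs leaves,
#'   seed19 vs seed13 (using the matrix's column names in that pattern
#'   when they match, otherwise all ordered pairs against the first
#'   column).
#' @param minCount row-inclusion threshold (default 50 reads in some
#'   library).
#' @param minFc reporting threshold on `|signed_fc|` (default 2).
#' @param fcOn `"raw"` (default) or `"normalized"`.
#' @return data.frame: `family`, one count column per library, one
#'   `fc_<comparison>_vs_<baseline>` column per pair.
#' @export
buildFoldChangeTable <- function(familyCounts, pairs = NULL,
                                 minCount = 50L, minFc = 2,
                                 fcOn = c("raw", "normalized")) {
  fcOn <- match.arg(fcOn)
  familyCounts <- as.matrix(familyCounts)
  libs <- colnames(familyCounts)
  if (is.null(pairs)) {
    pairs <- if (length(libs) == 4L) {
      list(c(libs[1], libs[2]), c(libs[1], libs[3]),
           c(libs[1], libs[4]), c(libs[3], libs[4]))
    } else {
      lapply(libs[-1], function(l) c(libs[1], l))
    }
  }
  keep <- apply(familyCounts, 1, max) >= minCount
  m <- familyCounts[keep, , drop = FALSE]
  vals <- if (fcOn == "raw") m else normalizeCPM(familyCounts)[keep, ,
                                                              drop = FALSE]
  out <- data.frame(family = rownames(m), stringsAsFactors = FALSE)
  for (l in libs) out[[l]] <- m[, l]
  for (pr in pairs) {
    fc <- signedFoldChange(vals[, pr[1]], vals[, pr[2]], minReport = minFc)
    col <- fc$signed_fc
    col[!fc$reported] <- NA_real_
    out[[paste0("fc_", pr[2], "_vs_", pr[1])]] <- col
  }
  rownames(out) <- NULL
  out
}
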