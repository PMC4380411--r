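#' Round half away from zero
#'
#' Fixed-precision rounding in which ties go away from zero (so 2.05 ->
#' 2.1 and -2.05 -> -2.1), matching how the reported tables render
#' percentages and fold changes. Base R's `round()` rounds ties to even,
#' which would print 43.25 as 43.2 rather than 43.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded at `digits` decimals.
#' @examples
#' roundHalfUp(c(57.797, 10.75, -2.05), 1)
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  # small epsilon absorbs binary representation error of values such as
  # x.x5 that are not exactly representable
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# reverse complement for plain character vectors (DNA alphabet; U treated as T)
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(chartr("U", "T", x))))
}

# deterministic child seed: derive a distinct stream seed below 2^31
childSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}

#' Parse a miRNA family label from a reference identifier
#'
#' Strips any species prefix (e.g. `ath-`), keeps `miR` plus the numeric
#' family identifier, and drops trailing member letters and arm suffixes,
#' so `ath-miR166a-5p` and `miR166b` both map to `miR166`. miR165 and
#' miR166 remain distinct families. Identifiers with no `miR<number>`
#' core are returned unchanged (novel call ids keep their own label).
#'
#' @param ids character vector of mature miRNA identifiers.
#' @return character vector of family labels.
#' @examples
#' mirFamily(c("ath-miR166a-5p", "csa-miR165a", "miR156h"))
#' @export
mirFamily <- function(ids) {
  m <- regexpr("[mM][iI][rR][-]?[0-9]+", ids)
  fam <- ifelse(m > 0, regmatches(ids, m), ids)
  fam <- sub("^[mM][iI][rR][-]?", "miR", fam)
  fam
}
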