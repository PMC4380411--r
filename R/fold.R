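#' Energy parameters of the shipped nearest-neighbor folding model
#'
#' Returns the parameter set used by [foldMFE()] and [structureEnergy()]:
#' a 6x6 stacking free-energy table (37 degrees C, kcal/mol, Turner-style
#' values; rows/columns indexed by the closing pair in the order AU, CG,
#' GC, UA, GU, UG), affine hairpin / interior / multiloop penalties, the
#' interior-loop side cap and the minimum hairpin loop size. Interior or
#' bulge loops with more than `max_intl_side` unpaired bases on either
#' side are outside the model (infinite energy). Exterior unpaired bases
#' are free; there are no dangle or coaxial terms.
#'
#' @return a named list of parameters.
#' @examples
#' p <- foldEnergyParams()
#' p$stack["GC", "CG"]
#' @export
foldEnergyParams <- function() {
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stack <- matrix(c(
    # next pair:  AU    CG    GC    UA    GU    UG      closing pair:
               -0.9, -2.2, -2.1, -1.1, -0.6, -1.4,    # AU
               -2.1, -3.3, -2.4, -2.1, -1.4, -2.1,    # CG
               -2.4, -3.4, -3.3, -2.2, -1.5, -2.5,    # GC
               -1.3, -2.4, -2.1, -0.9, -1.0, -1.3,    # UA
               -1.3, -2.5, -2.1, -1.4, -0.5, -0.5,    # GU
               -1.0, -1.5, -1.4, -0.6, -0.3, -0.5),   # UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(
    stack = stack,
    hairpin_a = 2.5,   # hairpin loop closure, kcal/mol
    hairpin_b = 0.35,  # per unpaired base beyond 3
    intl_a = 2.0,      # interior/bulge closure
    intl_b = 0.5,      # per unpaired base
    intl_asym = 0.4,   # per base of side asymmetry
    max_intl_side = 10L,
    multi_a = 3.4,     # multiloop closure
    multi_b = 0.4,     # per branch (closing helix included)
    multi_c = 0.1,     # per unpaired base in the loop
    min_hairpin = 3L
  )
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Predicts the MFE secondary structure of a single RNA (or DNA; T is
#' read as U) sequence under the shipped nearest-neighbor model (see
#' [foldEnergyParams()]) by a Zuker-style dynamic program with full
#' traceback: Watson-Crick and G:U pairs, stacking energies, affine
#' hairpin/interior/multiloop penalties, minimum hairpin loop of 3,
#' no pseudoknots. Ties are broken deterministically in favour of the
#' structure pairing the leftmost 5' base.
#'
#' @param sequence a single character string (alphabet ACGU/ACGT), or a
#'   `DNAString`/`RNAString`. Lengths up to ~450 nt are intended.
#' @param params energy parameter list, by default [foldEnergyParams()].
#' @return a [FoldResult-class] with the sequence (as RNA), the
#'   dot-bracket structure and the MFE in kcal/mol (0 for structures with
#'   no pairs).
#' @examples
#' foldMFE("GGGGGAAAACCCCC")
#' mfe(foldMFE("AAAAAAAAAA"))  # 0: nothing can pair
#' @export
foldMFE <- function(sequence, params = foldEnergyParams()) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 1L)
    stop("'sequence' must be a single non-empty string")
  rna <- chartr("T", "U", sequence)
  if (grepl("[^ACGU]", rna))
    stop("invalid character in sequence (alphabet is ACGU/ACGT)")
  res <- .fold_mfe_cpp(rna, params)
  new("FoldResult", sequence = rna, structure = res$structure,
      mfe = res$mfe)
}

#' Parse a dot-bracket string into a pairing vector
#'
#' @param structure dot-bracket string.
#' @return integer vector `p` where `p[i]` is the index paired to
#'   position i, or `NA` if i is unpaired.
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  p <- rep(NA_integer_, n)
  st <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      st <- c(st, i)
    } else if (ch[i] == ")") {
      if (!length(st)) stop("unbalanced brackets")
      j <- st[length(st)]
      st <- st[-length(st)]
      p[j] <- i; p[i] <- j
    } else if (ch[i] != ".") {
      stop("invalid character in structure: ", ch[i])
    }
  }
  if (length(st)) stop("unbalanced brackets")
  p
}

#' Free energy of a given secondary structure
#'
#' Evaluates the free energy of an explicit structure (dot-bracket) for a
#' sequence under the same nearest-neighbor model as [foldMFE()], by
#' recursive loop decomposition: each base pair closes a hairpin, a
#' stack, an interior/bulge loop or a multiloop; the exterior loop is
#' free. Structures containing a non-canonical pair, a hairpin loop
#' shorter than 3, or an interior/bulge loop exceeding the side cap are
#' outside the model and return `Inf`.
#'
#' This evaluator is independent of the dynamic program in [foldMFE()]
#' and is the basis of the exhaustive-enumeration cross-check of the
#' folding engine.
#'
#' @param sequence RNA/DNA sequence string.
#' @param structure dot-bracket string of equal length.
#' @param params energy parameters, default [foldEnergyParams()].
#' @return energy in kcal/mol (0 for the empty structure), or `Inf` if
#'   the structure is outside the model.
#' @examples
#' structureEnergy("GGGGGAAAACCCCC", "(((((....)))))")
#' @export
structureEnergy <- function(sequence, structure,
                            params = foldEnergyParams()) {
  rna <- chartr("T", "U", toupper(as.character(sequence)))
  if (nchar(rna) != nchar(structure))
    stop("sequence and structure lengths differ")
  p <- parseDotBracket(structure)
  n <- length(p)
  if (!any(!is.na(p))) return(0)
  b <- strsplit(rna, "")[[1]]
  pairName <- function(i, j) {
    key <- paste0(b[i], b[j])
    if (key %in% rownames(params$stack)) key else NA_character_
  }
  # centi-kcal integers, mirroring the DP's arithmetic exactly
  E <- 0L
  stackT <- round(params$stack * 100)
  ha <- round(params$hairpin_a * 100); hb <- round(params$hairpin_b * 100)
  ia <- round(params$intl_a * 100); ib <- round(params$intl_b * 100)
  ias <- round(params$intl_asym * 100)
  ma <- round(params$multi_a * 100); mb <- round(params$multi_b * 100)
  mc <- round(params$multi_c * 100)

  opens <- which(!is.na(p) & p > seq_len(n))
  for (i in opens) {
    j <- p[i]
    pn <- pairName(i, j)
    if (is.na(pn)) return(Inf)
    if (j - i - 1 < params$min_hairpin &&
        !any(!is.na(p[(i + 1):(j - 1)]))) return(Inf)
    # children: pairs directly enclosed by (i,j)
    ks <- integer(0)
    k <- i + 1
    while (k < j) {
      if (!is.na(p[k])) {
        if (p[k] < k || p[k] > j) return(Inf)  # pseudoknot (cannot occur)
        ks <- c(ks, k)
        k <- p[k] + 1
      } else k <- k + 1
    }
    if (length(ks) == 0L) {
      size <- j - i - 1
      if (size < params$min_hairpin) return(Inf)
      E <- E + ha + hb * (size - 3L)
    } else if (length(ks) == 1L) {
      k <- ks[1]; l <- p[k]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        pn2 <- pairName(k, l)
        if (is.na(pn2)) return(Inf)
        E <- E + stackT[pn, pn2]
      } else {
        if (n1 > params$max_intl_side || n2 > params$max_intl_side)
          return(Inf)
        E <- E + ia + ib * (n1 + n2) + ias * abs(n1 - n2)
      }
    } else {
      unp <- sum(is.na(p[(i + 1):(j - 1)])) -
        sum(vapply(ks, function(k) sum(is.na(p[k:p[k]])), integer(1)))
      E <- E + ma + mb * (length(ks) + 1L) + mc * unp
    }
  }
  as.numeric(E) / 100
}
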