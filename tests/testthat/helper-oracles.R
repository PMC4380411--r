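# Independent oracles used across the suite.

# --- exhaustive secondary-structure enumeration -------------------------
# All non-crossing pairings (canonical pairs, hairpin loops >= 3),
# evaluated with structureEnergy(); independent of the C++ dynamic
# program it cross-checks.

.pairable <- function(a, b)
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")

enumerateStructures <- function(seq) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(b)
  if (n < 5) return(list(matrix(integer(0), 0, 2)))
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- f(i + 1, j)
    if (j >= i + 4) {
      for (k in (i + 4):j) {
        if (.pairable(b[i], b[k])) {
          for (l in f(i + 1, k - 1)) for (r in f(k + 1, j))
            res[[length(res) + 1]] <- rbind(matrix(c(i, k), 1, 2), l, r)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  f(1, n)
}

pairsToDotBracket <- function(pairs, n) {
  s <- rep(".", n)
  if (nrow(pairs)) { s[pairs[, 1]] <- "("; s[pairs[, 2]] <- ")" }
  paste(s, collapse = "")
}

# minimum energy over every structure (0 = open chain included)
enumMinEnergy <- function(seq, params = foldEnergyParams()) {
  n <- nchar(seq)
  es <- vapply(enumerateStructures(seq), function(p)
    structureEnergy(seq, pairsToDotBracket(p, n), params), numeric(1))
  min(c(0, es[is.finite(es)]))
}

# --- Gotoh affine-gap local alignment (plain R) -------------------------
# match/mismatch/gapOpen (first base)/gapExtend, local (Smith-Waterman);
# independent of Biostrings::pairwiseAlignment.

gotohLocalScore <- function(a, b, match = 2, mismatch = -3,
                            gapOpen = -5, gapExtend = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (insertion)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] + gapOpen, X[i, j + 1] + gapExtend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gapOpen, Y[i + 1, j] + gapExtend)
      sc <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + sc)
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# --- misc ---------------------------------------------------------------

randomDNA <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

hammingDist <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# small simulated dataset reused by several test files (cheap)
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateLibraries(simulationConfig(
        seed = 7, readsPerLibrary = 1500, nKnownLoci = 8, nNovelLoci = 3,
        nDecoyNcrna = 3, genomeLength = 40000))
    cache
  }
})
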