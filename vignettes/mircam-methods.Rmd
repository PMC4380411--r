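---
title: "Methods: miRNA discovery from small RNA libraries with mircam"
author: "mircam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery from small RNA libraries with mircam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircam)
```

# The analysis

`mircam` re-implements, as a reusable and fully testable pipeline, a
classic small-RNA-seq workflow for discovering microRNAs in a plant
tissue panel (here: leaves, flower buds and two seed developmental
stages), quantifying their per-tissue abundance, and predicting their
transcript targets by complementarity. The stages are:

1. **Preprocessing.** 50-cycle single-end reads carry only a 3' adapter.
   The adapter is located by prefix matching (minimum overlap 6 nt, at
   most one mismatch) and clipped; reads in which no adapter is found
   have unknown insert length and are discarded. Clipped reads are
   dropped when their mean phred score is below 26 or their length is
   outside 15–27 nt, then collapsed into unique sequence *tags* carrying
   one count per library.
2. **Genome anchoring.** Tags are matched exactly against the genome on
   both strands (width-grouped `PDict` dictionaries); tags absent from
   the genome are discarded. Exact-only matching is the conservative
   reading of "present in the genome" for 15–27 nt tags, for which a
   single mismatch is a substantial fraction of the sequence.
3. **Known miRNAs.** A tag is *known* when it is identical — in size and
   nucleotide composition — to a mature reference sequence. Known
   miRNAs whose locus fails the structural criteria below are retained
   but flagged as lacking structural support, mirroring standard
   practice of keeping conserved matures with imperfect local hairpins.
4. **Novel candidates.** Tags that are not known, and that exceed the
   abundance gate (more than 80 reads, i.e. at least 81, in at least one
   library), are candidate novel miRNAs when they lie within 3
   mismatches of a reference mature (equal-length Hamming) or reference
   precursor (windowed Hamming). A `denovo` mode drops the similarity
   requirement; the default `homology` mode reflects how conserved
   families seed novel-member discovery.
5. **Hairpin analysis.** For each called mature, 200 nt of genomic flank
   is extracted on each side, the window is refined to the best
   stem-loop (below), and the three structural criteria are applied:
   MFE strictly below −20 kcal/mol, stem-loop length at most 210 nt,
   and at least 75% of mature bases paired to the located star arm.
6. **Decoy exclusion.** Candidate precursors sharing an exact 18-nt
   block (either strand) with a user-supplied tRNA/rRNA/snRNA decoy set
   are removed from novel candidacy — a local, reproducible stand-in
   for screening candidates against ncRNA catalogues.
7. **Quantification.** Counts per mature are the collapsed tag counts of
   exactly matching tags; families are the `miR<number>` label parsed
   from reference identifiers (species prefix and member/arm suffixes
   stripped; miR165 and miR166 stay distinct). Family counts are exact
   integer sums of member counts. Counts per million normalize to the
   total miRNA-assigned reads of each library.
8. **Fold changes.** The signed convention reports
   `round(B/A, 1)` for increases and `-round(A/B, 1)` for decreases,
   with half-away-from-zero rounding, blank below 2-fold, and rows
   restricted to families with at least 50 reads somewhere. Pairs with
   a zero count are flagged presence/absence rather than given a ratio.
9. **Target prediction.** The reverse complement of each miRNA is
   locally aligned (Smith–Waterman) against coding sequences under
   match +2, mismatch −3, gap open −5, gap extend −2; hits at score 25
   or more are reported, and a relaxed gate of 20 is used for focused
   scans restricted to a user-supplied gene list (e.g. lipid-pathway
   genes).

# The folding model

The structural core is a Zuker-style minimum-free-energy dynamic
program implemented in C++ (`foldMFE()`), with an explicit and
deliberately compact nearest-neighbor model:

* Watson–Crick and G:U pairs; a 6×6 stacking free-energy table
  (Turner-style 37 °C values, kcal/mol);
* affine hairpin-loop penalty `2.5 + 0.35 (n − 3)` kcal/mol, minimum
  loop 3;
* affine interior/bulge penalty `2.0 + 0.5 n + 0.4 |n1 − n2|`, with at
  most 10 unpaired bases per side — larger interior loops are *outside
  the model* (infinite energy), which bounds the interior enumeration
  and is shared by every evaluator in the package;
* affine multiloop penalty `3.4 + 0.4 per branch + 0.1 per unpaired
  base`;
* free exterior bases; no dangles, no coaxial stacking, no pseudoknots.

The pipeline uses MFE only as a −20 kcal/mol gate, so the contract is
the *gate behavior*, not thermochemical fidelity; the model is
correspondingly simpler than full mfold/ViennaRNA parameter sets. Two
independent evaluators keep the engine honest: `structureEnergy()`
scores any explicit dot-bracket by loop decomposition in R, and the
test suite enumerates *all* secondary structures of short sequences and
verifies the DP minimum equals the enumeration minimum exactly.
Energies are integer centi-kcal internally, so minima and the
deterministic tie-break (prefer pairing the leftmost 5' base) are
exact.

`locateStar()` derives the star arm from the fold: the span of
positions paired to the mature, extended by the 2-nt 3' overhang of the
duplex convention. No star is reported when under half the mature is
paired, when the partner span is more than 8 nt wider than the mature
(the arms do not form a clean duplex — this is what rejects tRNA-like
cloverleaves and random windows, whose partners scatter across
branches), or when the span would overlap the mature.

`refinePrecursor()` trims the 421-nt anchor window to the best
stem-loop: both ends move on a 10-nt grid (sub-window lengths 52–240
nt), every sub-window containing the mature is folded and judged, the
passing sub-window with the lowest MFE density (MFE/length) wins, and a
1-nt polish (up to 5 nt per end) follows. On random windows fewer than
5% of refinements produce a passing hairpin, so the structural gates —
not abundance alone — carry the discovery specificity.

# The synthetic study

`simulateLibraries()` generates the conditions the analysis assumes,
with ground truth: a two-contig genome with implanted hairpin loci
(known loci drawn from a generated miRBase-style mature reference;
novel loci 2–3 substitutions away from a known mature, matching the
homology discovery route), decoy ncRNA sequences, and four libraries of
10,000 50-cycle reads each by default.

Choices a user should know, and why:

* **Mature sequences** are drawn at 50–75% G+C
  (`randomMatureSequence()`). Uniformly random A/T-rich 21-mers build
  stems too weak for a −20 kcal/mol gate; real mature miRNAs sit in
  this moderate-GC range. With this composition, default loci
  (loop 12–16 nt, 0–1 stem bulge placed centrally) pass all three
  criteria in 400/400 generated cases, with the worst MFE at −24.2
  kcal/mol — the generator was calibrated against the hairpin module
  as its oracle before the defaults were frozen.
* **Abundances** follow a truncated power law (Zipf, α = 0.7 by
  default) over loci, with one tissue-enriched "primary" library per
  locus (weight ×4), emulating heavy-tailed family abundances and
  tissue-specific expression; realized per-locus counts are multinomial
  draws and are recorded in the truth table, so truth counts sum
  exactly to the miRNA-derived reads emitted. At default depth every
  implanted locus exceeds 80 reads in its primary library, so
  end-to-end recovery is well defined.
* **Background** (50% of reads) is genome fragments of 15–30 nt, an
  exactly-24-nt fragment class mimicking the siRNA peak of seed
  tissues, and decoy ncRNA fragments — exercising the length filter,
  the anchoring step and decoy exclusion. None of these can form a
  clean implanted hairpin and none must survive discovery.
* **Quality** is a two-component mixture (means phred 35 and 20, 10%
  low-quality reads by default), so the phred-26 mean filter has a
  known expected pass rate. The sequencing substitution error rate
  defaults to 0.1% per base; the studies this emulates do not state
  one, so it is exposed as a parameter rather than asserted.
* **Star reads** are 6% of a locus's reads, matching the usual
  mature-dominant arm asymmetry.

What the generator does *not* emulate: multimapping repeat families, an
allohexaploid genome's homeolog triplication, ligation bias, PCR
duplication structure, or real miRBase content. Passing the recovery
tests therefore demonstrates the pipeline's internal correctness on
clean heavy-tailed data, not its performance on a real crop genome.

# Numerical and design choices

* **Rounding** is half away from zero at one decimal
  (`roundHalfUp()`), matching how the reported tables render
  percentages and fold changes; base R's round-half-even would differ
  at values like 43.25. The ≥2-fold reporting gate is applied to the
  *rounded* value (a raw ratio of 1.969 prints, and reports, as 2.0).
* **Fold changes on raw counts.** The published per-family table's
  values are exact raw-count ratios, although the accompanying text
  describes per-library normalization; since all four libraries are
  single runs of comparable depth, both conventions are defensible.
  The default reproduces the table (`fcOn = "raw"`); the normalized
  convention is one switch away (`fcOn = "normalized"`). Neither is
  asserted as the original authors' intent.
* **Quality rule.** "phred < 26" leaves per-base vs aggregate
  unstated; a per-base rule at 26 would discard nearly all real reads,
  so the mean rule is the default and a `minbase` mode is provided.
* **Stem-loop cap 210 nt** is kept configurable because published
  precursor catalogues include loci a few nt above it (a 213-nt
  precursor is on record in the very study family this emulates); the
  default follows the stated criterion, the discrepancy is documented
  rather than resolved.
* **Abundance gate as raw counts.** "More than 80 reads" is read as a
  raw per-library count (≥ 81), not a per-million value, anchored by
  the stated minimum novel read count of 81.
* **Target scoring constants** (+2/−3/−5/−2) are chosen so a perfect
  ~21-nt site scores ~42 and the 25/20 gates pass biologically
  sensible mismatch loads; the original analysis used an unspecified
  BLAST server configuration, so gate *behavior*, not score
  concordance, is the contract. At gate 25 a random 21-mer hits a
  random 10-kb transcript in well under 1% of trials (measured by
  Monte Carlo in the test suite); gate 20 is meaningful only for
  restricted gene lists.
* **Multi-mapping cap** of 20 anchors per tag with deterministic
  (contig, coordinate) ordering; repeat handling is out of scope.
* **Determinism.** A single integer seed pins the generator
  byte-for-byte and the pipeline end-to-end; re-running a configuration
  reproduces identical output checksums.

# Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on synthetic or
printed-table inputs: the default synthetic study is 4 × 10,000 reads
on a 100-kb genome with 24 known, 8 novel and 6 decoy loci (about a
minute end to end); the folding oracle enumerates all structures of 200
random 8–14-nt sequences; the alignment oracle covers transcripts up
to 60 nt; auxiliary tests use a 4 × 1,500-read dataset. These sizes
were chosen so the whole suite exercises every stage at full fidelity
while remaining quick to run on a laptop.

# Known limitations

* The MFE model omits dangles, coaxial stacking, tetraloop bonuses and
  large interior loops; its energies are not comparable to ViennaRNA's
  numerically, only gate-behaviorally.
* Exact-only genome anchoring ignores SNPs/sequencing errors at the
  anchoring step (error-bearing reads are simply not anchored; with
  collapsing this costs depth, not loci).
* One genomic locus (the first anchor in deterministic order) is
  analyzed per called mature; paralogous copies beyond the cap are not
  enumerated as separate loci.
* No statistical differential-expression testing: the fold-change
  report is thresholded arithmetic, as in the emulated analysis, and
  the study design it serves has no replicates.
* Target prediction has no expectation-value statistics, conservation
  filtering or degradome support.
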