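---
title: "Methods: quantification and differential expression model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification and differential expression model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirquant)
```

This vignette is the package's own account of its methods: the read-level
processing model, the count model and its estimation, the enrichment test,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed.

## Library model and read preparation

`mirquant` targets single-end small-RNA reads with the QIAseq-style layout
*insert + 3' adapter + UMI + filler*. The preparation pipeline runs four
stages, in this fixed order:

1. **Adapter location and UMI extraction** (`locate_adapter()`,
   `extract_umi()`). The adapter is matched with substitutions only (no
   indels), at the leftmost position where the aligned part (truncation at
   the 3' end allowed, minimum overlap 6 nt) has at most
   `floor(rate * aligned_length)` mismatches; the default rate 0.1 matches
   common trimmer semantics. The insert is everything before the adapter;
   the UMI is the 12 nt immediately after it and is recorded only when
   complete — a partial UMI tail is treated as absent rather than guessed.
2. **BWA-style 3' quality trimming** (`quality_trim_3prime()`): with
   suffix sums $s_j = \sum_{k \ge j} (t - q_k)$ for threshold $t$ (default
   phred 10), the read is cut before the *smallest* index attaining the
   maximal positive $s_j$. The smallest-index tie-break makes the operation
   deterministic; all-high-quality reads are untouched and all-low-quality
   reads trim to empty.
3. **Length filter**: inserts outside [10, 40] nt (inclusive) are discarded
   — the conventional small-RNA window that keeps mature miRNAs (~20-24 nt)
   while excluding adapter dimers and longer RNAs.
4. **UMI deduplication** (`deduplicate()`): reads collapse on the exact
   (insert, UMI) string pair, first occurrence kept. No UMI-graph error
   correction is attempted; a sequencing error inside a UMI therefore splits
   a molecule in two, which at a 0.1% per-base error rate and 12 nt UMIs
   affects ~1% of molecules. Reads without an adapter are kept by default
   (flagged `no_adapter`, deduplicated on insert alone) because silently
   discarding them hides library problems; `trim_config(keep_no_adapter =
   FALSE)` drops them instead, and either way they are counted.

The kit's adapter sequence (`AACTGTAGGCACCATCAAT`) and UMI length (12) are
configuration with QIAseq-kit defaults, not constants, so other chemistries
only need a different `trim_config()`.

Stage order is a design choice: deduplication runs *after* quality trimming,
so two duplicates that differ only in a low-quality trimmed tail still
collapse. Running dedup first would preserve such pairs as distinct; the
chosen order is the more aggressive and, in our view, the more correct
reading of UMI semantics.

## Two-step quantification

**Precounting** assigns a read to a mature miRNA if and only if its insert
equals the reference sequence exactly and at full length. Identical mature
sequences (miRBase contains duplicates across arms/paralogues) are grouped
under one canonical name — the lexicographically smallest, with the others
kept as aliases — so an identical sequence can never be counted twice.
Exactness is deliberate: precounting is a fast path, not a mapper, and every
near-miss falls through to alignment.

**Fallback alignment** (`align_ungapped()`) places unmatched reads on the
genome with substitutions only, both strands, reporting the best stratum
(minimum mismatch count) up to `max_mismatches` (default 1). Candidate
positions come from exact seed hits when the read is long enough for the
pigeonhole guarantee (length ≥ (max_mismatches + 1) × seed length); shorter
reads are verified against every offset with a vectorised byte comparison,
which at toy-genome scale is exact and fast. The tests hold the aligner to
byte-for-byte agreement with an independent all-offsets scan. Reads shorter
than the seed length (default 12) are reported unaligned. Gapped alignment,
isomiR resolution and multi-mapper rescue are out of scope; users with a
production aligner can feed its SAM output through `read_sam_minimal()`
instead.

**Feature counting** (`count_features()`) assigns a read only if it has
exactly one best-stratum placement; ambiguous (multi-placement) reads are
dropped and counted, which avoids double-counting loci at the cost of
discarding repeat-derived reads. A uniquely placed read increments *every*
feature it overlaps by ≥ 1 bp on the same strand — the overlap-permitting
convention, chosen because nested/overlapping miRNA annotations are common
and a containment rule would silently zero them. Overlap arithmetic is
delegated to `GenomicRanges::findOverlaps()`. All internal coordinates are
0-based half-open (BED convention); SAM positions are shifted by exactly −1
at ingestion and nowhere else.

**Merging**: per sample, total(miRNA) = precount + feature count, with
feature names reconciled to canonical reference names by exact string match
and unknown names kept as new rows. `assemble_matrix()` unions features
across samples and keeps the per-cell precount/feature-count split as a
provenance attribute, with the invariant `precount + feature_count ==
total` enforced.

## The count model

Counts are modelled as negative binomial with per-sample size factors as
offsets:

$$K_{ij} \sim \mathrm{NB}(\mu_{ij} = s_j q_{ij},\ \alpha_i), \qquad
\log q_{ij} = x_j^\top \beta_i, \qquad \mathrm{Var}(K) = \mu + \alpha\mu^2.$$

* **Variance prefilter**: miRNAs whose raw-count variance falls strictly
  below the first percentile of the per-miRNA variance distribution are
  removed before normalisation. Percentiles use linear interpolation
  between order statistics (R's `quantile` type 7) with a strict "below"
  comparison, so a degenerate distribution (all variances equal) removes
  nothing.
* **Size factors** are median-of-ratios over miRNAs positive in all
  samples; identical columns give factors of exactly 1, and the factors are
  scale-equivariant up to the common constant absorbed by the geometric
  means. A matrix with no all-positive miRNA is an error rather than a
  silent fallback.
* **Dispersion** is estimated per miRNA by maximising the **Cox–Reid
  adjusted** profile log-likelihood over $\log\alpha \in [\log 10^{-8},
  \log 10]$ (one-dimensional bounded optimisation; mean parameters
  re-fitted by IRLS at each candidate; method-of-moments starting value
  kept as a candidate). Plain profile ML underestimates dispersion when the
  mean parameters are estimated from a handful of samples, which inflates
  Wald statistics; with two groups of six, the package's null simulations
  put the empirical type-I error at nominal 0.05 near 0.11 without the
  adjustment and near 0.08 with it. The CR term is also what the standard
  NB differential-expression packages maximise, so it is the natural
  reading of "default NB dispersion modelling". Underdispersed miRNAs
  (variance below mean, e.g. constant counts) land exactly on the
  $10^{-8}$ floor; all-zero miRNAs are skipped and reported.
* **GLM fit**: IRLS to convergence (relative log-likelihood change below
  $10^{-8}$, at most 100 iterations), linear predictors clamped to
  $|\eta| \le 50$ for numerical safety. Standard errors come from the
  inverse Fisher information at the optimum. Coefficients and SEs are
  reported in log2 units. Complete separation (an all-zero group) produces
  a capped estimate of ±30 log2 units with a `capped` flag rather than a
  runaway value.
* **Inference**: Wald statistic `log2fc / se` against the standard normal,
  two-sided; BH adjustment across all tested (post-filter) miRNAs — not
  per reported subset, a choice the tests document; classification UP/DOWN
  at |log₂FC| > 0.6 and p < 0.05 with *strict* inequalities at both
  thresholds. Classification uses the **unadjusted** p-value by default
  (`classify_on = "p_adj"` switches), matching the practice in
  underpowered pilot studies of reporting unadjusted hits while printing
  adjusted values alongside.

Deliberately **not** implemented, and recorded in the fit's `notes` field:
empirical-Bayes shrinkage of dispersions toward a mean-trend, outlier
detection via Cook's distance, independent filtering of low-count miRNAs,
and shrunken fold-change estimators. These improve power and stability on
real data; omitting them keeps every number traceable to the formulas
above.

Paired designs are expressed through the formula interface
(`~ subject + condition`), i.e. subject fixed effects; `coef` selects the
tested coefficient when the design is more complex (e.g. a group × time
interaction).

`power_two_sample_t()` computes the exact noncentral-t power of a two-sided
independent-samples t-test (df $n_1+n_2-2$, noncentrality
$d\sqrt{n_1 n_2/(n_1+n_2)}$), the conventional post-hoc power summary for a
two-group pilot.

## Over-representation analysis

DE miRNAs are mapped to target genes through a user-supplied annotation
table (no target database is bundled — predicted-target databases change
faster than package releases, and bundling one would freeze its biases into
the package). The query is the *union* of target sets; each pathway with at
least one query gene is tested with the one-sided hypergeometric tail
$P(X \ge k)$ via `stats::phyper`, BH-adjusted, flagged significant below
p < 0.01. The background defaults to all genes with pathway annotation and
is overridable; a query gene outside the background is an error, not a
silent drop. Testing through target genes (rather than miRNA-labelled
pathways directly) is a documented choice: it is the conventional ORA
construction and keeps the statistics independent of any specific web
tool's internals. `pathway_overlap()` exposes the pairwise shared-gene
counts that pathway network figures are built from; layout itself is out of
scope.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the package's reference study conditions:
72 nt reads (insert + 19 nt adapter + 12 nt UMI + random filler), log-uniform
expected expression between 10 and 1000 molecules, NB dispersion 0.2
(a typical bulk miRNA-seq magnitude), 10% of miRNAs differentially expressed
at |log₂FC| = 2, PCR duplication probability 0.5 per molecule (one extra
copy), and a 0.1% per-base substitution error rate — chosen once as
realistic desk-scale values and not tuned thereafter. Filler sequence is
rejection-sampled so it never recreates the adapter's 6 nt prefix, keeping
the leftmost adapter match the real one. Every generator draws from an RNG
stream derived from (seed, operation[, sample]), so outputs are
byte-identical given the same configuration and adding reads to one sample
never perturbs another.

The presets fix the problem sizes used throughout the tests: `tiny`
(10 miRNAs, 2 vs 2 samples, ~500 molecules/sample, zero error and
duplication — small enough that the whole FASTQ-to-matrix path runs in
seconds and its output can be compared to truth *exactly*), `de_recovery`
(200 miRNAs, 6 vs 6, 20 true effects) and `null_calibration` (500 miRNAs,
6 vs 6, no effects). The latter two are count-level fixtures: the
differential-expression properties they feed need only the count matrix, so
no FASTQ is written for them.

What is *not* emulated: cycle-dependent error profiles, quality-score
decay, ligation and sequence-composition bias, adapter dimers, isomiR
heterogeneity beyond an optional uniform 1-2 nt 3' truncation, UMI errors
interacting with duplication, and multi-locus miRNA families (loci are
placed non-overlapping with distinct sequences). Consequently, passing
tests demonstrate algorithmic correctness and statistical calibration under
the stated model — they do not certify performance on real libraries, where
the omitted artefacts dominate the error budget.

## Numerical choices and degenerate inputs

* Quality encoding is fixed to phred+33; anything outside `!`..`~` is
  rejected.
* FASTA `U` (and lower case) are transliterated to `T` at load time; reads
  are DNA-space throughout.
* Ties: canonical name of a duplicated mature sequence is the
  lexicographically smallest (C locale); the quality-trim cut takes the
  smallest index attaining the maximal suffix sum; ORA rows sort by
  (p, pathway id).
* Degenerate inputs have defined outcomes rather than surprises: an empty
  FASTQ yields an empty result with zero counters; a zero-length interval
  in BED, a negative count, duplicate feature or sample names, and
  inconsistent hypergeometric counts are errors; an all-zero miRNA is
  skipped with a report entry; `n_mirnas = 0` yields a valid empty
  reference.
* Seeds are explicit everywhere randomness exists; the package-wide default
  fixture seed is 20770305.

## Known limitations

Pure-R IRLS over thousands of features is seconds, not milliseconds; the
package is sized for desk-scale studies and simulations, not for
million-read production libraries. The Wald/plug-in-dispersion inference is
mildly anticonservative at very small n even with the Cox–Reid adjustment
(empirical type-I ~0.06-0.09 at nominal 0.05 in the shipped calibration
runs), which is the known price of not shrinking dispersions across
features. The classification rule is reproduced exactly as stated — strict
thresholds on the reported log₂FC — so values on the boundary (e.g. a
printed |log₂FC| of exactly 0.6, or 0.599 against a 0.6 threshold)
classify as "no" even when an upstream source labels them otherwise; the
acceptance tests document one published row of that kind rather than bend
the rule to fit it.
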