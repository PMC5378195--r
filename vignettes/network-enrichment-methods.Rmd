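---
title: "Methods: seed-based network expansion and permutation GSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based network expansion and permutation GSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motivenet)
```

## The problem

After a peripheral nerve injury, the balance between regenerative and
degenerative programs in spinal motoneurons differs sharply between injury
models: a distal axotomy with suture (DA) permits regeneration, while a
proximal root avulsion (RA) leads to degeneration and neuropathic pain.
Label-free LC-MS/MS of spinal cord tissue yields on the order of a thousand
quantified proteins per such experiment — too few, and too noisy at the
single-protein level, to read pathway biology directly off a
differential-abundance table.

`motivenet` implements a network-based enrichment strategy for this
setting. A *motive* is a literature-curated biological process (anoikis,
selective autophagy, ER stress, ...) represented by a small set of *seed*
genes and classified as regenerative or degenerative. Each motive is
expanded over protein–protein interaction networks into gene-set
*signatures*, and each signature is scored against the ranked log2 fold
changes of a proteomic contrast with a permutation GSEA. The result is a
motive × (contrast, network-variant) matrix of enrichment directions,
p-values and FDRs.

## Interactome assembly and confidence scoring

Interaction records come in two flavours. Direct records backed by
binary-capable detection methods (e.g. two-hybrid) form the **binary**
interactome. Protein complexes from affinity purification are converted to
pairs: when the bait is declared, the *spoke* model yields bait–prey edges
(`n − 1` edges for an `n`-member complex); otherwise the *matrix* model
yields all `n(n − 1)/2` member pairs. Direct records plus expanded
complexes form the **expanded** interactome. Edges are undirected,
canonicalized (lexicographically smaller identifier first), self-loops are
dropped, and duplicate reports are aggregated over distinct publication
identifiers.

Public interactome resources attach a confidence score to each interaction
reflecting the evidence type and the amount of independent support. The
score used here is

```
score = clamp( w_method + 0.1 * min(n_publications − 1, 4), 0, 1 )
```

with `w_method` 0.7 for binary-capable evidence, 0.5 for spoke-derived and
0.4 for matrix-derived complex evidence; mixed evidence takes the best
class. The weights encode the usual reliability ordering (binary > spoke >
matrix — matrix expansion invents edges between preys that may never touch)
and make the conventional 0.5 high-confidence threshold meaningful: a
single-publication matrix edge (0.4) is removed, a spoke edge (0.5) or
anything better survives. "Below 0.5" is read literally: a score of exactly
0.5 is retained. The weights are parameters of `build_interactome()`, not
constants.

## Signature variants

For each motive, six gene sets are built:

| variant    | definition |
|------------|------------|
| `seeds`    | the curated seed set |
| `hc_deg1`  | seeds + direct interactors, high-confidence expanded interactome |
| `hc_deg2`  | one more interactor level over `hc_deg1` |
| `bin_deg1` | seeds + direct interactors, binary interactome (unfiltered) |
| `bin_deg2` | one more level over `bin_deg1` |
| `all`      | second-degree neighborhood over the unfiltered union of both |

Two choices here were genuinely open. First, whether the binary
first/second-degree networks should also be confidence-filtered: the
variant naming ("high-confidence" vs "binary") suggests not, so the binary
variants are built on the unfiltered binary interactome. Second, the "ALL"
network is interpreted as the most inclusive object on the table — the
second-degree neighborhood over the unfiltered union of binary and
expanded interactomes — which makes it a superset of every other variant
and gives the containment chains `seeds ⊆ hc_deg1 ⊆ hc_deg2 ⊆ all` and
`seeds ⊆ bin_deg1 ⊆ bin_deg2 ⊆ all` that the tests enforce.

Seeds absent from an interactome stay in every signature: the `seeds`
variant scores them, so network expansion must never shrink a signature
below the seed list. Signatures larger than half the measured universe
trigger a warning — enrichment of a set against its own small complement is
weakly informative — but no hard cap is imposed.

## Differential abundance

Peptide peak areas are log2 transformed and median-centered per sample
(each sample's median normalized value is exactly 0), proteins with fewer
than two distinct peptides are discarded, and each protein is summarized
per sample by the median of its peptide values. The original study
quantified proteins with MSstats' linear model; `motivenet` deliberately
replaces this with the median-summarization + Welch t-test + Benjamini–
Hochberg chain. The substitution keeps the stage self-contained, exactly
testable (the noiseless planted effect is recovered to machine precision)
and assumption-light; it is an approximation, not a reimplementation of
MSstats. Missing values are not imputed: a protein quantified in fewer
than two samples of either group is skipped for that contrast. When both
groups have zero variance the Welch test is degenerate and p is reported
as 1 (equal means) or 0 (different means) — the latter occurs only in
noise-free synthetic data.

Median normalization carries the usual assumption that most proteins are
unchanged between conditions. When a condition shifts a sizeable fraction
of the measured proteome (as the synthetic generator can be asked to do),
the sample median moves with it and every fold change in that contrast is
biased by that median shift — a property of the normalization, not a bug.
At the default synthetic geometry the planted signature is ~4% of the
measured universe and the bias is a few hundredths of a log2 unit; the
noiseless-limit exactness tests therefore switch off all stochastic
spread (noise, baseline and peptide offsets), which makes the sample
median provably invariant to the planted shift and recovery exact to
machine precision.

Contrast conventions: `DA vs Ctrl` means `log2fc = mean(DA) − mean(Ctrl)`,
everywhere. The ranking metric is the log2 fold change itself (not a
signed t statistic), descending, with ties broken by gene identifier so
that rankings are fully deterministic.

## GSEA: running sum, permutation null, NES, FDR

For a ranked list of `N` genes and a signature with `N_hits` members in
the list, the running sum gains `|score|^p / N_R` at each hit (`N_R` the
sum over hits) and loses `1/(N − N_hits)` at each miss; the enrichment
score (ES) is the signed maximum deviation, always in `[−1, 1]`. The
weight exponent `p` defaults to 1 (classic weighted GSEA) and is
configurable; `p = 0` gives the unweighted Kolmogorov–Smirnov form. If all
hit scores are exactly zero (possible only with `p > 0` on degenerate
data) hits fall back to uniform weights.

The null model permutes **gene labels**: each permutation draws a uniform
random gene set of the same overlap size and re-scores it on the same
ranked list. Sample permutation is the stronger null in general, but with
4–5 animals per group there are too few distinct relabelings to support
10,000 permutations, and the procedure scores one fixed ranked list per
signature; the gene-label null matches that design. The cost is that
correlation between genes (co-membership in network neighborhoods) is not
in the null — see *Limitations*.

Normalization and significance are sign-matched: `NES = ES / mean(|null
ES| of the same sign)`, and `p = (1 + #{null : |null| ≥ |ES|, same sign})
/ (1 + #same-sign nulls)`. The add-one smoothing keeps p away from zero at
finite permutation depth; `ES = 0` or an empty same-sign null set reports
p = 1. Across all (motive, variant) tests of one contrast, FDR is
Benjamini–Hochberg over the permutation p-values; the pooled-NES FDR of
the original GSEA publication would be a possible extension. Because it is
ambiguous whether significance in this kind of report should be called on
p or on FDR, the enrichment matrix carries both flags (`sig_p`,
`sig_fdr`) and the wide rendering marks FDR-level calls with `*`.

Direction is the sign of ES for the contrast as ordered: positive ES means
the signature concentrates among proteins up in the first-named condition.

## The synthetic benchmark

The generator produces the three pipeline inputs with known ground truth;
every generator is a pure function of its spec (including the seed), so
studies are reproducible byte for byte.

* **Interactome**: preferential-attachment graph (scale-free, the
  empirical shape of protein interaction networks) of `n_genes = 16000`
  nodes at mean degree 4, plus 600 complexes of 3–8 members, alternately
  with and without bait. Publication counts are `1 + Poisson(0.5)`.
* **Catalog**: 19 motives, 3–56 seeds each, split 10 regenerative / 9
  degenerative; 5% of seeds are off-graph identifiers to exercise the
  isolated-seed path.
* **Quantification**: three conditions (Ctrl, DA, RA) × 5 samples; per
  protein a Gaussian baseline (mean 5, sd 1 log2 units), 2–5 peptides with
  per-peptide offsets (sd 0.3) constant across samples, per-measurement
  noise sd 0.5 on the log2 scale, areas `2^value` (log-normal noise). The
  planted effect adds 1.0 log2 units to every gene of the planted motive's
  `hc_deg1` signature in the DA condition.

The two scale parameters deserve justification. The interactome is
16,000 genes — the scale of a proteome-wide interaction map — while only
7.5% of proteins (~1,200) are detected in the quant table, the scale of a
label-free LC-MS/MS experiment (the motivating study identified 1,420
proteins). This separation matters: if the interactome is the same size
as the measured universe, the first-degree neighborhoods of 19 motives
with 3–56 seeds become large, strongly overlapping fractions of the
universe (every signature contains the same hubs), and any planted effect
bleeds into most non-planted signatures. With a proteome-scale graph and
an experiment-scale measured subset, signatures restricted to the
measured universe are small, weakly overlapping slices — which is what
real data look like. Detection is a uniform protein-level subset drawn
once per study; intensity-dependent peptide dropout and other real
missingness mechanisms of DDA data are deliberately not modelled, so
passing tests say nothing about robustness to informative missingness.

Effect size 1.0 log2 units at noise sd 0.5 with 5 animals per group gives
a per-protein fold-change standard error of about 0.2 — strong but not
trivial signal, comparable to a clear biological response; with 2–5
peptides per protein the median summary and the two-peptide filter are
both exercised.

## Numerical and policy choices

* Threshold semantics: `filter_high_confidence` keeps `score ≥ threshold`.
* ES tie-break: the score is the value at the first index of maximal
  absolute deviation. When the maximal positive and negative deviations
  tie exactly (possible with rational increments, e.g. weight exponent 0)
  the magnitude of ES is well defined but its sign is a convention; the
  antisymmetry identity and cross-implementation sign agreement hold only
  away from exact ties.
* Tie-break in rankings: descending fold change, then ascending gene id.
* Degenerate GSEA inputs: empty overlap → unscored (`es = NA`); signature
  = whole universe → unscored with a warning in batch mode (the miss
  decrement is undefined), an error when scored directly.
* Duplicate seeds within a motive are collapsed with a warning; duplicate
  motive names are an error.
* Seeds for stochastic steps: `run_pipeline` derives the GSEA seed of
  contrast `i` as `seed + 1000(i − 1)` and `gsea` gives signature `j` the
  seed `seed + j − 1`, so every result is reproducible and no two tests
  share a permutation stream. Artifact headers carry all parameters and
  the seed; they carry no timestamps so re-runs are byte-identical.

## Problem sizes used in the tests

The test suite runs the statistical checks at deliberately modest sizes,
chosen so the whole suite completes in a few minutes while keeping every
check meaningfully powered: ES oracle equivalence on 1,000 random
instances of up to 50 genes; null calibration with 400 random signatures
at 1,000 permutations on a 500-gene null study; planted-signal recovery
over 50 seeded studies at the full default spec (16,000-gene interactome,
1,000 permutations); determinism and smoke tests on 150–200-gene studies.
The acceptance script repeats the main computations at the same scales
(20 recovery replicates, 200 null signatures).

## Limitations

* The gene-label permutation null ignores inter-gene correlation. Genes
  that share network neighborhoods have correlated membership across
  signatures, so strong effects on one signature can elevate overlapping
  signatures ("enrichment bleed"). The synthetic benchmark bounds this
  cross-talk under its default geometry (≤ ~5% of non-planted motives
  flagged per run) but real interactomes with denser motive overlap will
  show more.
* The Welch-on-medians differential stage is a documented simplification
  of MSstats-class mixed models; peptide-level variance heterogeneity is
  absorbed, not modelled.
* Confidence scoring is a transparent surrogate for database-specific
  schemes; absolute scores are not comparable to any public resource,
  only the ordering and the 0.5 threshold semantics are meaningful.
* The catalog shipped in `inst/extdata` reproduces the published motive
  names, categories and seed *counts* with synthetic seed identifiers;
  real curated seed lists must be supplied by the user as TSV.
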