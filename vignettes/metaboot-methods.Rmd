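---
title: "Bootstrap-stabilized mRMR biomarker selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-stabilized mRMR biomarker selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabootr)
```

## The selection model

`metabootr` selects taxonomic biomarkers from a feature-by-sample
abundance table in four stages.

**Preprocessing.** Raw counts are turned into relative abundances by
per-sample normalization (`normalize_relative()`); features that are zero
in at least 80 % of samples are dropped (`filter_sparse()`, the boundary
is inclusive — a feature exactly at the threshold is removed); and each
feature is discretized against its own mean \(\mu\) and standard
deviation \(\sigma\): values strictly above \(\mu + \sigma/2\) become +1,
strictly below \(\mu - \sigma/2\) become −1, everything else 0
(`discretize()`). Three-level coding deliberately discards fine-grained
abundance information: it suppresses measurement noise, and it makes the
mutual-information machinery below well-defined without density
estimation. \(\sigma\) is the sample standard deviation (n − 1
denominator) by default; the population form is available via
`sd_denominator = "n"` since either convention is defensible and the
difference only moves values lying within \(\sigma/(2n)\) of a threshold.
Boundary values map to 0 because the coding rule is phrased with strict
inequalities; ties at a threshold are rare for continuous data but the
behavior must be fixed for reproducibility.

**First-stage mRMR screen.** Greedy forward selection under the mutual
information difference (MID) criterion. With class labels \(c\) and
selected set \(S\), step \(t > 1\) picks the unselected feature
maximizing
\[
  I(x_j; c) \;-\; \frac{1}{|S|} \sum_{x_i \in S} I(x_j; x_i),
\]
where \(I\) is plug-in mutual information (bits) on the discrete codes;
step 1 maximizes \(I(x_j; c)\) alone. No small-sample bias correction is
applied: the classical mRMR estimator on discretized data is the plain
maximum-likelihood one, and the greedy argmax is unaffected by the common
bias term of equally-sized alphabets. The screen keeps `M` candidates.

**Stratified bootstrap stage.** `B` bootstrap replicates resample the
samples with replacement *within* each stratum (subclass when the
metadata has one, class otherwise), each stratum keeping exactly its
original size, so every replicate has the same group structure as the
original design and only the multiplicity of individual samples varies.
Each replicate re-runs the mRMR selection of `M_prime` features,
restricted to the candidates.

**Occurrence ranking.** Candidates are ranked by the number of bootstrap
lists containing them; the top `M_prime` are the final biomarkers. A
feature that discriminates only thanks to a handful of particular samples
rarely survives many replicates, which is how the bootstrap stage
eliminates unstable positives and spuriously relevant negatives.

## Parameters

* `M` (default 50) — first-stage candidate count. Must exceed `M_prime`.
  Chosen by the saturation sweep (`sweep_parameters()`): increase `M`
  until the number of distinct marker groups among the top-`M` stops
  growing.
* `B` (default 40) — bootstrap count. Also chosen by sweep: beyond the
  saturation point the set of distinct features appearing in bootstrap
  lists stops growing. Because per-bootstrap seeds are derived
  deterministically from the root seed, enlarging `B` never changes
  earlier replicates and the sweep curve is non-decreasing by
  construction.
* `M_prime` (default 10) — final biomarker count and per-bootstrap
  selection size; set it to the number of markers you intend to take
  forward.
* `zero_fraction` (default 0.8) — sparsity threshold of the filter.
* For the top-100 robustness protocol the package uses `M = 200` with
  `M_prime = 100`: the screen must still exclude most of the background,
  and 2× headroom over the final size mirrors the default 50/10 ratio
  loosely while keeping the 900 negatives screened first.

## Numerical choices

* **Tie-breaking.** The MID argmax breaks ties by higher relevance, then
  lower feature index. Objectives within an absolute \(10^{-9}\) of each
  other are treated as tied, so mathematically equal scores computed in
  different summation orders (C++ kernel vs. test oracles) resolve
  identically. Occurrence ties are broken by lower mean within-bootstrap
  rank, then lower first-stage rank. All results are therefore
  bit-reproducible given (data, parameters, seed).
* **Random streams.** One root seed; bootstrap \(b\) uses the derived
  seed \((s \cdot 48271 + b \cdot 30269) \bmod (2^{31}-1)\). The
  generators and selectors save and restore the caller's RNG state.
* **Discretize once.** Discretization thresholds are estimated once on
  the full table and reused inside every bootstrap replicate (the
  alternative — re-estimating \(\mu, \sigma\) per replicate — is exposed
  as `rediscretize = TRUE`). Reusing the codes makes bootstrap replicates
  differ only in sample multiplicity, which is the resampling notion the
  occurrence ranking assumes, and is substantially faster.
* **Degenerate replicates.** A bootstrap replicate in which a class
  collapses to few distinct samples is kept as drawn: relevance may then
  vanish for every candidate and selection falls back to the
  deterministic tie-break order. Resampling such replicates away would
  bias the occurrence counts toward easy draws.
* **Degenerate inputs.** Zero-total samples are a hard error in
  normalization; constant features discretize to all zeros (zero
  relevance, never selected while an informative candidate remains);
  single-sample tables cannot be discretized.

## The synthetic benchmark designs

Three generators provide ground truth for method evaluation. All share
the skeleton: 10 positive marker groups × 10 features (mutually redundant
by construction: features of a group are i.i.d. draws from the same block
distributions) plus 900 negatives with no between-class difference, over
two classes split into subclasses.

* `generate_s1(sd, seed)` — 120 samples (2 × 3 subclasses × 20), every
  block normal with common `sd`. Block means for groups 1–5 are drawn per
  feature and per subclass from {11, 12, 13, 14} (class-1 side) and
  {17, 18, 19, 20} (class-2 side); groups 6–10 use the vectors reversed;
  negatives have mean 15. Independent per-(feature, subclass) draws are
  the default; `means_per_feature = TRUE` draws once per feature and
  class. Drawn means are recorded in the provenance so tests can check
  every block against its own target. `sd` defaults to 1 and is the
  difficulty dial of the design.
* `generate_s2(seed)` — 100 samples (2 × 2 × 25), a gamma/normal mixture:
  groups 1–5 gamma in both classes (class differences mainly in shape),
  groups 6–10 gamma in class 1 but normal in class 2 — taxa whose
  distribution family itself changes with phenotype. The class-2 normal
  blocks take mean/sd values on the scale of their class-2 gamma
  counterparts; for group 10 the sd is moment-matched to its counterpart
  gamma block (sd 0.003). Negatives are normal(0.14, 0.06). Normal blocks
  are left un-truncated: occasional small negative values are kept, since
  the block distributions are defined on the raw generated scale and
  discretization is unaffected.
* `generate_s3(seed)` — 120 samples (2 × 3 × 20), all-gamma, with three
  negative groups of 300 features each using subclass-invariant
  parameters. Gamma blocks are parameterized throughout by shape and rate
  (mean = shape/rate); implementations with scale-parameterized gamma
  must use scale = 1/rate.

Synthetic matrices are flagged `prenormalized`: they are fed to
discretization as-is, because the block distributions define the data
scale directly and per-sample renormalization would couple features
through the sampled column totals.

**What the generators do not emulate.** Real abundance tables are
compositional counts with sampling-depth noise, zero inflation, taxon
correlations beyond class structure, and long-tailed rare taxa. The
benchmarks have none of these: block draws are independent given the
design, and almost no exact zeros occur. Passing the benchmark suite
therefore demonstrates correct mechanics of selection, resampling and
scoring under known truth — not performance on real microbiome data. One
structural consequence worth knowing: within the normal design all groups
on the same side share identical mean vectors, so group identity there is
statistically invisible and any selector's unique-group count matches the
exchangeable-draw expectation; the gamma and mixture designs give each
group its own block parameters, which is what makes their non-redundancy
rates informative.

## Evaluation

`score_selection()` walks a ranked selection and counts selected
positives whose marker group already has an earlier representative —
the redundant features:
redundancy rate = #redundant / #selected × 100 %, non-redundancy rate =
100 % − redundancy rate, error rate = #negatives / #selected × 100 %.
Negatives count toward error only, never as redundant. The comparator
`wilcoxon_select()` ranks features by the two-sided rank-sum p-value
(normal approximation with tie and continuity corrections; an exact
enumeration oracle in the test suite bounds the approximation error at
0.02 for tiny groups). `svm_cv_accuracy()` estimates classification
accuracy of a feature subset by stratified k-fold cross-validation with
per-fold min–max scaling fitted on training data and an inner
cross-validated grid search over RBF-SVM cost/gamma (the customary
log2-spaced grids). `permutation_exact_test()` enumerates all
reassignments of two small groups (difference of means, two-sided) and
falls back to Monte-Carlo beyond combined size 20.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use 10 seeded replicates per
benchmark summary, selection sizes 10 and 100, and the default
M = 50 / B = 40 (M = 200 for the top-100 protocol); oracle-equivalence
properties run on 6 × 12 matrices where exhaustive recomputation is
cheap. These sizes give replicate-mean standard errors below one
percentage point for the redundancy rates while keeping a full run in the
low minutes on one CPU.

## Known limitations

* Two-phenotype discrimination only; multi-class one-vs-all selection is
  out of scope.
* Mutual information is estimated on three-level codes; signals living
  entirely in fine-grained abundance differences within the middle band
  are invisible.
* The mRMR stage is greedy: with one dominant marker group the redundancy
  penalty cannot always prevent several same-group picks, which is
  exactly what the non-redundancy benchmarks quantify.
* The Wilcoxon comparator uses the normal approximation; for very small
  studies (a handful of samples per class) use
  `permutation_exact_test()` instead.
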