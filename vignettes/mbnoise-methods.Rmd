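---
title: "Background-noise correction for multi-study microbiome data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-noise correction for multi-study microbiome data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbnoise)
```

## The problem

When microbiome feature tables (taxonomic profiles or k-mer counts) from
several studies are pooled, technical variation — extraction kits,
sequencing instruments, processing robots, the study itself — often exceeds
the biological variation of interest. Because each sample is a composition
(only relative abundances are observed), technical factors act
multiplicatively on features and become additive in log space. Pooling
without correction inflates false-positive case-control associations
whenever the phenotype is unevenly distributed across studies, and can
degrade cross-study phenotype prediction.

`mbnoise` implements the standard transforms and corrections for this
setting and, just as importantly, the two experimental procedures used to
judge them: a control-titration experiment that measures false-positive
inflation under progressively worse confounding, and leave-one-dataset-out
(LODO) phenotype prediction.

## Transforms

All corrections operate after conversion to relative abundance
(`closure()`). Zeros are replaced multiplicatively before any log
transform: every zero cell becomes `0.65 × (smallest non-zero value of the
table)`, after which rows are re-closed (`add_pseudocount()`). Two scoping
choices are deliberate:

* the minimum is **global** over the table, not per sample, so the
  replacement value is common across samples and cannot itself encode
  study membership;
* the pseudocount is recomputed for every input table a pipeline sees
  (e.g. every titration draw) and recorded in the transform log.

The centered log-ratio transform (`clr_transform()`) maps a composition
`x` to `log(x_i / G(x))` with `G(x)` the geometric mean of the row.
Natural logarithms are used throughout; the base only rescales principal
components and affects no downstream decision. The CLR cancels any
per-sample multiplicative factor, so a feature-specific multiplicative
study bias becomes an additive per-study offset — exactly what linear
corrections and PCA can see. `inverse_clr()` is the softmax; the row
maximum is subtracted before exponentiation as an overflow guard, which is
mathematically a no-op because the softmax is shift-invariant.

`log_cpm()` uses the symmetric-prior dialect
`log2((c + prior) / (L + 2·prior) × 1e6)` with `prior = 0.5`, fixed and
documented so results are bit-stable. Variance-stabilizing transforms are
out of scope; externally transformed tables enter as `space = "generic"`.

## Corrections

**BMC** (batch mean centering) subtracts each batch's per-feature mean.
**DCC** (direct covariate correction) generalizes it: per-feature OLS on an
arbitrary covariate design with intercept, residuals kept. With a single
categorical covariate the two are identical, and the test suite holds them
to that within 1e-9. **Linear batch removal** (limma-style) fits batch
plus optionally a protected phenotype and subtracts only the intercept and
batch terms, so a protected case-control contrast survives; with nothing
protected it equals DCC on batch.

**ComBat** is the parametric empirical-Bayes location-scale model:
standardize per feature with the size-weighted grand mean and pooled
variance, estimate per-batch per-feature location and scale, shrink with a
normal prior on locations and an inverse-gamma prior on scales
(method-of-moments hyperparameters), solve by the standard fixed-point
iteration (absolute change < 1e-6, at most 500 iterations), and back-scale.
One estimator choice matters: within-batch variances use the maximum
likelihood divisor `n_b`, consistent with the `/n` pooled variance, so a
table with no batch effect adjusts to itself to machine precision. With
the `n_b − 1` divisor the no-effect case is rescaled by
`sqrt(n_b / (n_b − 1))`, which is why our output differs from `sva`'s by
`O(1/n_b)`; the suite cross-checks against `sva::ComBat` at that tolerance.
Features with zero within-batch variance are location-adjusted only, and a
single feature degenerates gracefully to its own (unshrunk) estimates.
ComBat and the limma-style removal operate on the natural log of
pseudocounted relative abundance; BMC, DCC and PCA correction operate in
CLR space.

**Percentile normalization** replaces each value by its percentile within
the batch's control distribution,
`100 × (#controls below + 0.5 × #ties) / n_controls` (midrank ties — the
originating method does not fix tie handling, so we document one
convention). Only within-batch ranks matter, so the scores are invariant
to any strictly monotone per-feature-within-batch transform, and the suite
asserts that invariance.

**PCA correction** removes the projection of feature-centered CLR data on
its top `p` components (covariance PCA, no variance scaling — CLR already
puts features on a common log scale). Feature means are restored after
removal: per-sample constants cancel under the inverse CLR but per-feature
constants do not, and restoring means keeps the back-transformed
composition comparable to the input (`restore_means = FALSE` is available).
The fixed variant defaults to `p = 3`. The tuned variant scores each
candidate `p` by training a predictor on corrected training data and
evaluating on validation data corrected **with the training-fitted model**
(training means and loadings; nothing refit), then picks the best
validation metric, breaking ties toward the smallest `p` — the choice that
throws away the least phenotype signal. For k-mer features, the k-mer size
is a second hyperparameter tuned as an outer loop over user-supplied per-k
tables, since k-mer counting itself is out of scope.

## Diagnostics

`pc_covariate_correlation()` quantifies how strongly each leading PC
follows each covariate: absolute Pearson correlation (t-test) for
continuous covariates, and for categorical covariates the first canonical
correlation with the dummy matrix, computed as `sqrt(R²)` of the OLS of
scores on dummies (F-test). Both are non-negative, which makes mixed
covariate grids comparable; the suite checks the categorical path against
a brute-force normal-equations oracle to 1e-10. Distributions of
correlations before and after a transform are compared with a paired
one-sided Wilcoxon signed-rank test on matched (PC, covariate) cells,
exact for 25 or fewer non-zero differences, normal approximation with
continuity correction above, zero differences dropped; fewer than five
non-tied pairs is an error because the test has no useful power there.

## Evaluation procedures

**Titration.** Cases and controls (each of size `m`, the minimum class
size across the two studies) are drawn from study 1; a fraction `f` of the
drawn controls is replaced by study-2 controls, the full pipeline
(transform, correct, back-transform to relative abundance, prevalence
filter at 0.1, Wilcoxon rank-sum with BH correction at q < 0.05) is
re-applied, and significant features absent from that replicate's
`f = 0` baseline are counted as new — likely false-positive —
associations. Proportions default to `{0, 0.25, 0.5, 0.75, 1}` and
replacement is nested within a replicate (the first `round(f·m)` positions
of a fixed random order), which makes the count tend to rise smoothly with
`f`. Cases and controls are re-drawn each replicate, seeded. Two
degenerate points need care: at `f = 0` the mixed set has one batch, and
supervised corrections degrade to global per-feature centering, which
changes no rank test; percentile normalization is applied once to the full
two-study cohort **before** mixing (each sample scored against its own
study's controls), because the mixed subsets at high `f` no longer contain
case-study controls at all.

**Prediction.** LODO folds hold out one study; the rest splits 70/30 into
training and validation, stratified by phenotype (or phenotype quartile).
The pooled scheme is five-fold cross-validation — each fold in turn the
20% test set, the remainder split 70/30 into 56%/24% — repeated ten times,
stratified so study composition stays similar across partitions. Binary
traits use a random forest tuned over trees (100, 1000, 1500), minimum
node size to split (2, 5, 10) and minimum terminal node size (1, 5, 10),
27 grid points, scored by validation AUC; depth is unlimited and
`sqrt(n_features)` candidate features are drawn per split. The backend is
`ranger`, whose classification split criterion is the Gini impurity; no R
random-forest backend offers the entropy criterion, and the two are
near-equivalent impurity measures, so Gini is used and documented here.
Continuous traits use linear least squares with an optional ridge penalty
chosen on validation (`λ ∈ {0, 0.01, 1, 100}`); at `λ = 0` the minimum-norm
SVD solution reproduces plain least squares, which is what OLS degenerates
to when features outnumber samples.

Every fold is leak-free by construction: the pseudocount, feature means,
PCA loadings, batch coefficients and ComBat hyperparameters are fitted on
training samples only and applied frozen to validation and test data
(`fit_noise_correction()` / `apply_noise_correction()`). A batch unseen at
fit time (the LODO test study) is centered — or, for ComBat,
location-scale adjusted — using its own samples, which requires no
phenotype labels. The suite asserts bit-identical fitted parameters when
test rows are perturbed. Percentile normalization is excluded from the
prediction harness: it requires labeled controls in every batch and is not
defined for unlabeled test data.

## The synthetic generator

`simulate_dataset()` produces multi-study count tables with known ground
truth: per-feature baseline log-abundances `~ N(0, baseline_logmean_sd²)`
(default 2, giving realistically skewed compositions and multinomial
zeros); per-feature per-study log-normal multiplicative bias
`~ N(0, bias_sd²)` (default 1 — a global per-study factor would cancel
under closure, so the bias must be feature-specific to create a batch
effect); planted differential features at `effect_logfold` (default
`log 4`); per-cell log noise (default sd 0.3); closure; multinomial counts
at negative-binomially dispersed library sizes (mean 5e4). Sparsity arises
from multinomial sampling of skewed compositions; an optional
zero-inflation rate adds harsher regimes.

Three generator choices deserve explanation because they are what make the
evaluation measure the *correction* rather than artifacts of the design:

* **Balanced effect directions** (default): half the planted features go
  up in cases, half down. One-directional fold changes alter the total
  mass of case samples, so after closure every null feature genuinely
  differs between classes; a rank test then correctly flags them, but
  those calls say nothing about batch correction. `effect_direction =
  "up"` is retained precisely for studying that compositional artifact.
* **Non-dominant planting** (default): differential features are drawn
  from below-median baseline abundance. A 4-fold change in a feature that
  carries a large share of the composition rescales everything else in
  that class — again a real compositional effect, but one that no batch
  correction can or should undo, and one that makes results swing wildly
  from seed to seed depending on which feature is hit.
* **Fixed per-study class counts**: the binary phenotype is assigned as
  `round(n_s · p_case)` cases per study with randomized positions, not
  per-sample Bernoulli draws. Bernoulli assignment gives every study a
  random case fraction, which correlates the phenotype with the
  between-study principal components even at `confounding_rho = 0`;
  removing those components then imprints phenotype-correlated shifts on
  null features. Fixed counts model a designed case-control cohort and
  keep phenotype and study exactly orthogonal at `ρ = 0`.

`confounding_rho` interpolates between balanced (`ρ = 0`: half cases
everywhere) and fully confounded (`ρ = 1`: odd studies all case, even all
control). The generator does not attempt real taxon phylogenies, real
covariate structure, or k-mer sequence composition, so passing tests
demonstrate correct behavior under a log-normal multiplicative bias model
with multinomial sampling — not performance on any particular real cohort.

## Problem sizes and scenarios used by the test suite

The suite and `scripts/acceptance.R` use the smallest problem sizes at
which each property is stable:

* Titration: two studies × 70 samples, 200 features, `bias_sd = 1`, no
  planted effects; 20 replicates in the suite, 10 in the script.
* Null calibration: 100 (suite) / 50 (script) replicates of 20 vs 20
  samples × 200 null features.
* Tuned-PCA rank recovery: four studies × 40 samples (three between-study
  noise dimensions), 200 features, `bias_sd = 2`, 20 features at 2-fold,
  per-cell noise 0.5, grid `p ∈ 0..10`; the expected choice is `p ∈
  {2, 3, 4}`.
* Prediction calibration: permuted labels on two studies × 80 samples ×
  100 null features (10 repeats, single-point forest grid — hyperparameter
  tuning is irrelevant under the null); planted power on two studies × 50
  samples with 20 of 200 features at 4-fold and no bias.
* Recovery scenario: four studies × 20 samples, 200 features,
  `baseline_logmean_sd = 1` (k-mer-like evenness), `bias_sd = 1`, 10
  features at 4-fold, balanced and non-dominant; the corrected arm runs at
  `ρ = 0` and the uncorrected contrast at `ρ = 1`. At `ρ = 1` the
  between-study subspace *is* the case-control contrast, so any correction
  that removes it necessarily removes the signal too — no method can have
  both high power and low error there, which is the whole argument for
  measuring false positives (titration) and power (recovery) in separate
  designs.

## Known limitations

* Supervised corrections assume the batch variable is the dominant noise
  axis; covariates are taken as given, not discovered.
* PCA correction removes phenotype signal whenever that signal lies in the
  removed subspace (complete confounding, or `p` set too high); the tuned
  variant mitigates but does not eliminate this.
* When a removed component's loadings overlap planted signal features,
  component removal transfers a small phenotype-correlated shift onto
  null features; with dense strong signals this can inflate the
  false-positive rate of the corrected pipeline.
* The Wilcoxon/BH differential-abundance step tests relative abundances
  and inherits the usual compositional caveats; it is the benchmark
  pipeline's test, not a recommendation over dedicated compositional DA
  methods.
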