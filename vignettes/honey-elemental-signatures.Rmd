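---
title: "Methods: elemental signatures of unifloral honeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elemental signatures of unifloral honeys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeytrace)
```

This vignette documents the statistical machinery of `honeytrace`: the
models, their assumptions, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data generator does and does
not emulate.

## The measurement model

Honey is digested (≈0.7 g to a final volume of 15 cm³), and the digest is
measured by ICP-MS against an external aqueous calibration, with Rh as the
internal standard and blank correction. The package keeps two unit systems
deliberately separate: *solution* concentrations in μg dm⁻³ (calibration
range, instrument-facing operations) and *honey* concentrations in μg kg⁻¹
(sample tables, LoD/LoQ). The only bridge is
`quantify_concentration()`, which applies

$$c_{\text{honey}} = c_{\text{solution}} \cdot \frac{V_{\text{final}}
\cdot f_{\text{dil}}}{m_{\text{sample}}},$$

so with the standard digest 1 μg dm⁻³ ≈ 21.4 μg kg⁻¹. Negative solution
concentrations can arise after blank correction; they are retained signed
for blank statistics (LoD estimation needs them) and clamped to zero with a
censoring flag only when written into a sample table.

Every concentration cell carries a censoring state resolved against the
element panel: `quantified` (≥ LoQ), `below_loq` (in [LoD, LoQ), value kept
when recorded) or `below_lod` (no value). The CSV representation uses the
tokens `<LOD`/`<LOQ` (case-insensitive) and re-censors numeric cells on
input, which makes the write/read round trip lossless.

## Digestion optimization

The digestion was optimized with a 2² full factorial design plus a
duplicated center point: X₁ = sample amount (0.5–1.0 g), X₂ = HNO₃/H₂O₂
volume ratio (0.5/3 to 2/1.5 cm³). The ratio factor is coded from the
exact volume quotients (0.1667 and 1.3333), not from their rounded
two-decimal representations, to avoid double rounding. Responses are the
residual acidity (mol dm⁻³) and the efficiency of organic matter
decomposition, EOMD% = 100·(TOC − DOC)/TOC.

`fit_factorial()` fits Y = b₀ + b₁X₁ + b₂X₂ + b₁₂X₁X₂ by least squares
over all six runs. Because the design is orthogonal and the center points
carry zeros in every non-constant column, b₁, b₂ and b₁₂ equal the
contrast averages over the four corners, and b₀ equals the grand mean of
all six runs. The corner-only intercept (the mean of the four corners,
0.505 and 95.925 for the built-in study) is also reported as
`coef_corners`, since with center points included the two conventions
differ slightly and both are legitimate summaries; the least-squares b₀ is
the one used for prediction.

**Significance.** With only a duplicated center point, the honest error
estimate is the pure error s_pe = sd of the center replicates (df = 1).
Each coefficient is a contrast average of the four corner runs, so its
standard error is s_pe/√4 and t = |b|/(s_pe/2) is referred to a
t-distribution with n_center − 1 degrees of freedom, banded `*`/`**`/`***`
at p < 0.05/0.01/0.001. With df = 1 this test is deliberately
conservative: a coefficient must exceed ≈6.4 pure-error sds to reach
p < 0.05. Alternatives (the regression residual error with df = 2, which
mixes lack of fit into the error; or a normal reference) give different
bands for borderline coefficients; the pure-error t is the defensible
default and the full p-values are always reported alongside the stars.

**Adequacy.** `model_adequacy()` is a one-sample t-test of the center
replicates against the model prediction at (0,0), using s_pe/√n_center,
df = n_center − 1. Degenerate inputs are handled explicitly: zero pure
error with a nonzero bias yields an infinite t (certain lack of fit), zero
bias yields t = 0.

## Method validation

* **LoD/LoQ** (`lod_loq()`): 3 and 10 times the sd of blank-equivalent
  concentrations (defaults `k_d = 3`, `k_q = 10`, so LoQ/LoD = 10/3; both
  multipliers are arguments). The reference design uses 30 method blanks
  across sessions.
* **Precision** (`precision_cv()`, `horwitz_check()`): CV% with the n−1
  sd. Measured CVs are compared against the full Horwitz predicted RSD,
  2^(1 − 0.5·log₁₀ c) with c the mass fraction, with the Thompson
  modification (constant 22% below c = 1.2·10⁻⁷, i.e. 120 μg kg⁻¹)
  applied by default: at trace levels the unmodified curve grows without
  bound and the 22% plateau is the accepted acceptance limit. Both
  repeatability and intermediate precision are judged against the full
  PRSD (not the 2/3 within-laboratory variant), the convention under which
  a 12% repeatability at ~660 μg kg⁻¹ (PRSD ≈ 17%) is acceptable.
* **Trueness** (`recovery_test()`): per-aliquot recovery
  100·(found − base)/added, two-tailed one-sample t against 100% at
  α = 0.05 (df = n − 1). A significant deficit/excess is classified as
  under-/overestimation bias. Acceptability is additionally screened
  against an editable concentration-banded table
  (`default_recovery_bands()`: 80–110% at ≤ 100 μg kg⁻¹, 85–110% above),
  chosen by the mean spiked concentration. The t-verdict and the band
  verdict are independent outputs: a recovery of 85 ± 7% (n = 3) is
  *quantitative* (t ≈ 3.7 < 4.303) while 92 ± 1% is a significant
  underestimation (t ≈ 13.9), even though both lie inside the band.
* **Digestion efficiency** (`eomd()`): 100·(TOC − DOC)/TOC, with
  DOC > TOC rejected as physically impossible.
* **Report formatting** (`format_validation_report()`): LoD/LoQ to two
  significant figures, CV% to integers, recovery as integer ± integer —
  the rounding conventions of printed validation tables.

## Classification pipeline

The pipeline (`classify_pipeline()`) runs substitution → log₁₀ →
screening → split → PCA → LDA → cross-validation → permutation test →
validation-set prediction.

* **Censored substitution** (default LoD/2). The substitution rule for
  left-censored trace data is a convention, not an estimate; LoD/2 is the
  most common choice and the strategy is configurable (`lod_sqrt2`,
  `custom`). Recorded below-LoQ values are kept as measured; unrecorded
  ones take the interval midpoint (LoD + LoQ)/2.
* **Screening** (`screen_variables()`, threshold 0.1): elements quantified
  in fewer than 10% of samples are removed — their matrix content would be
  almost entirely substitution artifacts. On tables with the censoring
  pattern of the four Sardinian honeys this removes Ag, Be, Hg, Sb and Te,
  leaving 18 variables.
* **Split**: stratified random split, largest-remainder allocation of
  training slots per class; default training fraction 85/133 ≈ 0.64, the
  customary split of this workflow. Reproducible for a fixed seed.
* **PCA** (`pca_fit()`): eigen-decomposition of the correlation matrix
  (`autoscale`, default) or covariance matrix of the transformed training
  data. After the log transform the variables have comparable but not
  equal spreads; autoscaling keeps high-concentration elements from
  dominating the loadings. Sign convention: the largest-magnitude loading
  of every component is positive, making loadings deterministic.
* **LDA** (`lda_fit()`): class means, pooled within-class covariance
  Σ = Σₖ(nₖ−1)Sₖ/(N−K), discriminant scores
  δₖ(x) = xᵀΣ⁻¹μₖ − ½μₖᵀΣ⁻¹μₖ + log πₖ. The model assumes class-wise
  multivariate normality with a shared covariance — defensible here
  because the log transform symmetrizes the concentrations and the four
  classes have similar size and dispersion. Equal priors are the default
  (class sizes 33/30/31/39 are close); proportional priors are available.
  A ridge of 1e−8 × mean(diag Σ) keeps Σ invertible; ties in the argmax
  resolve to the lowest class index.
* **Cross-validation**: leave-one-out by default — deterministic, no
  extra seed, and appropriate at n ≈ 85; stratified k-fold is available.
* **Permutation test**: class labels permuted uniformly, CV accuracy
  recomputed per permutation, p = (1 + #{null ≥ observed})/(1 + n_perm).
  With the conventional 100 permutations the smallest attainable p is
  1/101 ≈ 0.0099.
* **Confusion statistics**: per-class % = 100·diagonal/row-sum, total % =
  100·trace/total, computed from the matrix itself (no reconciliation
  with externally printed percentages is attempted).

## The synthetic-data generator

The original sample set is not distributed, so `generate_samples()` draws
synthetic tables with the structure the analysis assumes:

* per class, log₁₀ concentrations are multivariate normal — normality is
  imposed on the log scale precisely because the pipeline log-transforms
  and LDA assumes within-class normality;
* per-element locations are geometric centers chosen inside the published
  per-class concentration ranges, and spreads are sized so ±2 sd roughly
  spans those ranges (fully censored elements sit well below their LoD);
* four correlated blocks (Fe–Mn–V, Cu–Ni–Zn, Ba–Sr–Li, Cd–Co) share a
  within-class correlation of ρ = 0.7 — the reported associations are
  "strong" but unquantified, and 0.7 encodes that without forcing
  near-collinearity;
* multiplicative measurement noise uses each element's
  intermediate-precision CV% from the default panel;
* censoring is *emergent*: values are censored at the panel LoD/LoQ after
  noise, so censoring rates follow from the profiles rather than being
  sampled directly.

Between-class separation comes from the per-class location differences
(e.g. Mn high in eucalyptus, Li high in strawberry tree, Zn/Cu high in
thistle), which reproduces the quadrant layout of the first two principal
components (asphodel −/−, eucalyptus +/+, strawberry tree −/+, thistle
+/−). The default is 30 samples per class.

**What passing tests do and do not show.** The generator's covariance is a
declared target, not an estimate of the real data: real honeys have
metadata-linked substructure (geography, urbanization), non-normal tails,
and between-element correlations beyond the four blocks. Tests that the
pipeline recovers class structure on synthetic data (cross-validated
accuracy ≥ 70%, permutation p ≤ 0.01 at 100 permutations) demonstrate the
correctness and sensitivity of the implementation in the regime of the
study, not the field performance of elemental authentication.

`generate_validation_inputs()` produces fixtures with analytically known
truth for the validation operations: blanks with a chosen sd (LoD/LoQ
known), calibration points on a chosen line, spike sets with a dialled-in
bias, and factorial responses from chosen coefficients with optional pure
error.

## Numerical conventions and degenerate inputs

* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; the command-line default seed is 20220321.
* OLS fits use `stats::lm`; t-probabilities use `stats::pt`. PCA and LDA
  are implemented in the package and cross-checked in the tests against
  brute-force oracles (explicit eigen-equations, loop-based Mahalanobis
  scores) and, where available, `stats::prcomp` and `MASS::lda`.
* Zero-variance situations are resolved explicitly rather than through
  0/0: zero replicate variance with nonzero bias → infinite t (certain
  rejection); zero bias → t = 0.
* Problem sizes in the test suite are chosen so the whole suite runs in
  well under a minute: synthetic tables of 120 samples for pipeline
  checks, 1000 per class for distributional checks, 100 permutations only
  where the permutation floor itself is under test.

## Known limitations

* The DoE engine covers only 2² designs with center replicates — the
  design actually used; higher-order and fractional designs are out of
  scope, as is any optimizer beyond contour-grid inspection.
* LoD/LoQ multipliers are fixed constants (3/10 by default), not
  distribution-based detection-decision theory with explicit α/β.
* The permutation test permutes labels uniformly and ignores any grouping
  structure among samples.
* The censored-substitution strategies are single-value conventions;
  likelihood-based censored estimators (e.g. Tobit-style) are not
  provided.
* The geographic covariates carried in sample metadata are stored but
  never used as predictors.
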