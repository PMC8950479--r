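# honeytrace

Multi-element ICP-MS workflows for honey authentication. The package
implements, as tested and reusable R functions, the computational side of a
trace-element study of unifloral honeys: optimization of the acid microwave
digestion by a two-level factorial design, validation statistics for the
analytical method, conversion of instrument signals into honey
concentrations, and classification of botanical origin from the elemental
signature. A synthetic-data generator reproduces the censored, right-skewed,
block-correlated structure of honey trace-element tables so the whole
pipeline can be exercised end to end.

## Who it is for

Analytical chemists and food-authentication researchers working with
multi-element panels (here: Ag, As, Ba, Be, Bi, Cd, Co, Cr, Cu, Fe, Hg, Li,
Mn, Mo, Ni, Pb, Sb, Sn, Sr, Te, Tl, V, Zn) measured by ICP-MS in digested
honey, who need reproducible statistics for method development, validation
and chemometric classification.

## What it computes

**Digestion optimization (DoE).** A 2² full factorial design with a
duplicated center point in the factors X₁ = sample amount (0.5–1.0 g) and
X₂ = HNO₃/H₂O₂ volume ratio, responses Y₁ = residual acidity (mol dm⁻³) and
Y₂ = EOMD% (efficiency of organic matter decomposition,
EOMD% = 100·(TOC − DOC)/TOC). The model

> Y = b₀ + b₁X₁ + b₂X₂ + b₁₂X₁X₂

is fit by least squares over all runs; on this orthogonal design the
coefficients equal the classical contrast averages. Coefficients are tested
against the pure error estimated from the center replicates, and model
adequacy is checked by a t-test of the center mean against the center
prediction.

**Method validation.** Currie-style limits LoD = 3·s(blank),
LoQ = 10·s(blank); precision as CV% checked against the Horwitz predicted
RSD (PRSD = 2^(1 − 0.5·log₁₀ c), with the Thompson 22% floor below
c = 1.2·10⁻⁷); spike-recovery trueness with a two-tailed t-test against
100% and an AOAC-style banded acceptance range; matrix-effect detection by
Welch comparison of aqueous and matrix-matched calibration slopes.

**Quantification.** Internal-standard drift correction and blank
subtraction of raw signals, OLS calibration with a center-point linearity
check, and scaling of solution concentrations (μg dm⁻³) to honey
concentrations (μg kg⁻¹) via digest mass, final volume and dilution.

**Botanical classification.** Censored-value substitution (LoD/2 by
default), log₁₀ transform, screening of rarely quantified elements,
stratified train/validation split, correlation-matrix PCA, and LDA (class
means, pooled within-class covariance, linear discriminant scores) with
leave-one-out cross-validation, a label-permutation significance test and
confusion-matrix statistics — all implemented in the package itself.

## Worked example

```r
library(honeytrace)

# --- digestion optimization ------------------------------------------------
study <- digestion_doe()               # built-in 2^2 + center design
fit <- fit_factorial(study, "eomd")
fit
#> factorial fit of eomd
#>  coefficient  value      p significance
#>           b0 95.983 0.0014           **
#>           b1 -2.775 0.0490            *
#>           b2  2.475 0.0540
#>          b12  3.475 0.0390            *
#> pure error sd = 0.424 (2 center replicates)
predict_response(fit, 0, 0)$value      # EOMD% predicted at the center
#> [1] 95.98333

# --- synthetic table + classification --------------------------------------
tab <- generate_samples(30, seed = 7)  # 4 botanical classes x 30 samples
res <- classify_pipeline(tab, seed = 7)
res
#> botanical classification: 18 elements, 77 train / 43 validation samples
#> CV total accuracy: 88.3%; prediction: 93.0%; permutation p = 0.009901
#> prediction confusion matrix:
#>                  assigned
#> true              asphodel eucalyptus strawberry_tree thistle
#>   asphodel               9          0               1       0
#>   eucalyptus             0         11               0       0
#>   strawberry_tree        1          0              10       0
#>   thistle                0          1               0      10
```

The factorial fit prints the coded-model coefficients with their pure-error
significance bands; the center prediction of ~96% EOMD confirms that the
compromise digestion (0.7 g honey, 0.5 cm³ HNO₃ / 3 cm³ H₂O₂) decomposes
essentially all organic matter. The classification run shows the elemental
signature separating the four honeys well above the 25% chance level, with
a permutation p-value at the smallest value 100 permutations can resolve.

A thin command-line wrapper around the same functions ships in
`inst/scripts/honeytrace` (subcommands `simulate`, `doe`, `classify`).

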