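---
title: "Cholesky twin models and DeFries-Fulker extremes analysis with twinpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholesky twin models and DeFries-Fulker extremes analysis with twinpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

twinpath implements the two workhorses of the classical twin design for
quantitative traits: multivariate Cholesky variance-component models fitted
by full-information maximum likelihood (FIML), and DeFries-Fulker (DF)
extremes regression. It ships a synthetic twin-cohort generator that is the
exact generative dual of the fitted model, so every stage of the pipeline is
testable against known truth without access to any cohort data.

## The biometric model

A phenotype measured on both members of same-sex twin pairs is decomposed
into additive genetic (A), shared environmental (C) or dominance (D), and
nonshared environmental (E) influences; E also absorbs measurement error.
Monozygotic (MZ) co-twins share all segregating genetic variants, dizygotic
(DZ) co-twins half of them on average (a quarter for dominance effects), and
shared environment is common to both twins by definition. For k phenotypes
the model is parameterized through lower-triangular path matrices X, Y, W, Z
with

- within-twin covariance:  A + C + D + E, where A = XX', C = YY', D = WW', E = ZZ'
- cross-twin covariance:   alpha A + C + delta D, with alpha = 1 (MZ) / 0.5 (DZ)
  and delta = 1 (MZ) / 0.25 (DZ).

The triangular-product ("Cholesky") parameterization keeps every component
matrix positive semi-definite for any real parameter value, which is why it
is the field's default. C and D cannot be estimated together from twin data
alone, and E must always be present (it is what keeps the within-twin
covariance positive definite). Means are equated across twins and zygosity
groups; under *quantitative sex limitation* all paths and means are
duplicated per sex, so the same etiological structure can operate to
different extents in males and females. These conventions give the familiar
parameter counts: for k = 5 phenotypes an ACE model has
3 x 15 + 5 = 50 free parameters with the sexes equated, 100 under
quantitative sex limitation, and the four-group saturated model
(free 10-vector mean and 10 x 10 covariance per group) has 260.

Fitting maximizes the raw-data (FIML) Gaussian likelihood: each pair
contributes the density of its *observed* sub-vector under its group's
implied moments, so partially missing phenotypes (common for test batteries)
are retained without imputation. Internally, pairs are grouped by
missingness pattern and the likelihood is evaluated from per-pattern
sufficient statistics; the analytic gradient of the objective with respect
to all path entries and means is supplied to the quasi-Newton optimizer
(`nlminb`). Starting values come from method-of-moments component estimates
(e.g. A = 2(cov_MZ - cov_DZ) for ACE) clipped to the PSD cone, plus
jittered restarts. Reported degrees of freedom follow the raw-data
convention: observed data points minus free parameters.

The fitted solution is re-expressed as the *correlated factors* solution:
standardized variance proportions per phenotype (summing to 1) plus
etiologic correlations r_g, r_c (or r_d), r_e between phenotype pairs. The
share of a phenotypic correlation r_ph attributable to A — the *bivariate
heritability* — is sqrt(A1) r_g sqrt(A2) / r_ph, and analogously for the
other components; the shares sum to 1 by the covariance decomposition.
A component correlation whose variance is zero for either phenotype is
reported as undefined (`NA`) rather than 0, with the distinction surfaced
to the caller.

Nested models are compared by the likelihood-ratio test (the -2LL
difference is chi-square with df equal to the parameter-count difference)
and by AIC computed as chi-square minus twice the df of the comparison.
p-values use the plain chi-square upper tail rather than boundary-corrected
mixtures; this is the field's common usage and is conservative for
components constrained to be non-negative.

## Confidence intervals

Intervals on standardized quantities are profile-likelihood based: the
bound is the value of the target at which the profiled -2LL rises by the
chi-square(1) quantile above its minimum. The profile is computed by an
augmented-Lagrangian equality-constrained refit (quadratic weight 3e4 with
one multiplier update, constraint honoured to ~3e-4), walking outward from
the estimate and refining the crossing by secant steps to a tolerance of
1e-3 on the target scale. Bounds that run into the edge of the parameter
space ([0, 1] for proportions, [-1, 1] for correlations — typical for
shared-environment proportions near zero) are reported at the edge and
flagged, not extrapolated. A simulation included in the test suite (100
replicate cohorts of 2000 pairs per group) checks that the nominal 95%
interval for a heritability attains empirical coverage within [0.90, 0.99].

## DeFries-Fulker extremes analysis

Probands are individuals beyond an empirical quantile of a z-scored scale
(high tail for trait scales, low tail for ability scales; ties at the
threshold are included, and either or both twins of a pair may qualify).
All scores are then rescaled so the proband mean is 1 and the population
mean 0; on that scale the mean of co-twin scores is read as a twin-group
correlation, and stronger regression of DZ than MZ co-twin means toward 0
indicates genetic influence on extreme scores. The regression

    C = b1 P + b2 R + A

of co-twin on proband scores codes zygosity as the coefficient of
relatedness (R = 1 for MZ, 0.5 for DZ), which makes b2 exactly twice the
MZ-DZ difference in transformed co-twin means on a balanced design — the
group heritability h2g. The dummy coding R in {0, 1} would break that
identity, which is why it is not offered. h2g is capped at the transformed
MZ co-twin mean; a raw value above the cap is reported and flagged as
possible non-additivity. The bivariate variant replaces the outcome with
the co-twin's transformed score on a second phenotype (transformed by that
phenotype's own proband/population means) and estimates h2.xy. Concordant
pairs are double-entered (once per ordering), the standard DF practice; a
switch disables it for sensitivity analyses. Sex and age enter all DF
regressions as covariates; their coefficients are reported, not
interpreted.

The extremes genetic correlation combines the four estimates as

    r_g = sign(bxy byx) sqrt(|bxy byx| / (bx by)),

clipped to [-1, 1] with a flag when the magnitude exceeds 1, and flagged
invalid when bx by <= 0. The published form of this ratio omits the
operator between the two parenthesized products; the square root of the
ratio is the established DF-literature convention and is what is
implemented. The phenotypic *group* correlation is the mean proband
z-score on the outcome divided by the mean proband z-score on the selection
variable; under bivariate normality with correlation rho and single-tail
selection this ratio converges to rho, which the tests exploit as an
oracle.

## The synthetic cohort generator

`simulate_twins()` draws per-twin latent factor scores with the cross-twin
correlations above (multivariate normal liabilities — the exact generative
dual of the linear-Gaussian model), forms phenotypes as path-weighted sums
plus linear age and sex effects, and only then applies monotone skew
transforms and missing-completely-at-random masking. Co-twins share their
age; sex is a pair-level variable because only same-sex pairs are analysed.
One master seed drives deterministic substreams per zygosity-sex cell, so
cells are independently reproducible.

`teds_like_config()` fixes the generator at the scale of a large community
twin register: 1113 / 1102 / 1293 / 1188 MZM / DZM / MZF / DZF pairs; a
count-like, positively skewed parent-rated autistic-trait scale (emulated
as an exponential of the Gaussian liability, log-transformed back during
preparation) plus four roughly normal receptive-language scores with 27%
missingness each; standardized ACE proportions differing quantitatively by
sex (trait scale a2 0.73 male / 0.52 female, with the shared-environment
share larger in females; language a2 0.18-0.39); a mildly negative additive
genetic correlation (-0.13) and a more strongly negative shared-environment
correlation (-0.60) between the trait scale and the language measures, with
positive correlations (0.55) among the language measures themselves. Where
a generating value was not dictated by the study design, a single realistic
choice was made once (e.g. age range 11.5-12.5 years, language
inter-correlations, small age/sex mean effects) and is not tuned
thereafter.

What the generator deliberately does not emulate: opposite-sex pairs,
rater and assortative-mating effects, non-MCAR missingness, and floor
effects of bounded scales. Passing tests therefore demonstrate correctness
of the estimators under the model's own assumptions, not robustness to
violations of them.

## Data preparation

The preparation chain is fixed and logged: optional exclusion flags, then
natural-log transformation of scales declared skewed (offset 1 by default,
since count scales include zero and no other offset is dictated), then OLS
residualization on a sex indicator and age fitted on individuals pooled
across twins and zygosity groups (the standard practice when the same
transformation must apply to every group), then z-scoring. Whether
z-scoring precedes or follows residualization is immaterial up to scale —
the two orders commute to numerical precision, which the test suite checks
— so the order above is a documented convention rather than a substantive
choice. Phenotypic correlations are computed on one randomly selected twin
per pair to respect the non-independence of twin data; cross-twin and
cross-trait cross-twin correlations use double-entry Pearson estimates
(invariant to the arbitrary labelling of twins), with Fisher-z confidence
intervals on the number of pairs rather than the doubled entries. The
double-entry estimator was preferred to the ANOVA intraclass correlation
because it matches the field's convention and extends directly to the
cross-trait case.

## Numerical choices and limitations

- Optimizer tolerance is 1e-12 (relative) on -2LL with up to 3000
  iterations; non-convergence is flagged on the fit and refused by the
  comparison functions.
- Reflection indeterminacy of the triangular factors is removed after
  fitting by flipping column signs so diagonals are non-negative.
- The likelihood rejects (returns a penalized value during optimization,
  an error at the user level) any non-positive-definite observed
  sub-matrix rather than silently regularizing it.
- Saturated fits optimize each group independently (closed-form sample
  moments when a group's data are complete).
- Problem sizes used in the test suite are chosen to make Monte-Carlo error
  small relative to the tested tolerances: 50,000 pairs for correlation
  convergence checks, 5,000 pairs per group for parameter-recovery grids
  (mean absolute error <= 0.05), 25,000 pairs for DF tail-selection
  checks (capped h2g within 0.07 of the generating a2), 100 replicates for
  interval coverage.
- Ordinal/threshold liability models, opposite-sex pairs, and qualitative
  sex limitation (different factors, not just different magnitudes, per
  sex) are out of scope.

## A worked example

```{r, eval = FALSE}
library(twinpath)

cfg <- twin_sim_config(
  n_pairs = 1500,
  paths = paths_from_components(a2 = 0.6, c2 = 0.2, e2 = 0.2),
  seed = 1
)
records <- simulate_twins(cfg)
prepared <- preprocess_twins(records, list(phenotype_spec("ph1")))

twin_correlation_table(prepared)

fit <- twin_cholesky(prepared, components = c("A", "C", "E"))
sat <- fit_saturated(prepared)
likelihood_ratio_test(fit, sat)
correlated_factors(fit)
confint(fit, "a2.male.ph1")
```
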