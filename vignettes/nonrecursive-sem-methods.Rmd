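---
title: "Methods: non-recursive SEM for co-occurring adolescent mental-health outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-recursive SEM for co-occurring adolescent mental-health outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrsem)
```

## The scientific problem

School-based surveys of adolescent mental health typically screen three
co-occurring outcomes — depression (PHQ-9A), anxiety (GAD-7) and somatic
symptom burden (SSS-8) — together with perceived stress (PSS-10), social
support (OSSS-3) and a battery of binary covariates (alcohol use, chronic
illness, sex, school type, physical trauma, and so on). Ordinary one-outcome
regressions cannot represent the *mutual* influence of depression and
anxiety on each other, nor the indirect transmission of a covariate's effect
through that feedback loop. The model of interest is therefore a
**non-recursive structural equation model**: a linear simultaneous system

$$\eta = B\,\eta + \Gamma\,\xi + \zeta$$

over latent endogenous constructs $\eta$ (depression, anxiety, somatic
symptoms) with a reciprocal depression $\leftrightarrow$ anxiety block in
$B$, exogenous variables $\xi$ (latent stress and support plus observed
covariates), and disturbances $\zeta$. Each construct is measured by Likert
items through a factor model. Solving the system requires $(I-B)$ to be
invertible, and convergence of the feedback loop requires the spectral
radius of $B$ to be below 1.

## Identification

A feedback loop is only estimable when the equations can be told apart.
The package implements the three standard devices on a declared
`structural_system()`:

* **Unique instruments** (`check_unique_instruments`): each loop variable
  must own at least one exogenous regressor that enters its equation and no
  other loop equation.
* **Order condition** (`order_condition`): each loop equation must exclude
  at least $m-1$ of the declared variables ($m$ = loop size). Necessary
  only.
* **Rank condition** (`rank_condition`): from the 0/1 *system matrix*
  (equations in rows, all variables in columns, `build_system_matrix`),
  delete each equation's row and every column it occupies; the remaining
  matrix must have rank $\ge m-1$. This is the sufficient rule and the
  pipeline's gate: nothing is fitted when it fails. The prose recipe
  "delete duplicate rows and rows that are sums of other rows" is exactly
  linear-algebra rank, which we compute by QR with tolerance 1e-8 — exact
  for 0/1 matrices.

Instrument *quality* is a separate, data-driven question. Before fitting,
the pipeline computes composite scores (item means) and runs the
Cragg–Donald minimum-eigenvalue F (strong if $F > 10$) and the Sargan
overidentification test (valid if $p > 0.05$; undefined, and reported as
such, for just-identified equations). The standard treatment for a weak or
invalid instrument is deleting the associated non-recursive path; the
pipeline applies it iteratively and logs every deletion. Note a structural
fact checked in the test suite: on data generated from the default regime,
the somatic-symptom instruments (study time, extra tutoring) are truly
irrelevant, so remediation removes the somatic feedback paths — the
intended behaviour, not a defect.

## Estimation

Estimation is covariance maximum likelihood on complete cases (listwise
deletion is guarded: `apply_listwise` refuses when more than 5% of records
would drop). The model is compiled to RAM form — one asymmetric matrix $A$
holding loadings and regressions, one symmetric matrix $S$ holding
(co)variances, implied covariance
$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top$ — and the discrepancy

$$F_{ML} = \log|\Sigma| + \mathrm{tr}(S_n\Sigma^{-1}) - \log|S_n| - p$$

is minimised by a quasi-Newton search with the analytic gradient
($W = \Sigma^{-1} - \Sigma^{-1}S_n\Sigma^{-1}$; $dF/dA = 2E^\top V M$,
$dF/dS = E^\top V E$ with $E = (I-A)^{-1}$, $M = ESE^\top$). Sample
covariances use the $n-1$ denominator and $\chi^2 = (n-1)F_{ML}$.
Numerical choices: start values are moment-based heuristics (loadings 0.7
scaled by indicator/marker SDs, regressions 0, variances at half the sample
variance); points where $\Sigma$ leaves the positive-definite cone are
handled by a smooth push-back penalty toward the start rather than a hard
failure; variances are *not* box-constrained, so Heywood cases surface as
explicit warnings instead of being silently clamped; scale-setting fixes
the first loading of each construct to 1.

Standard errors come from the numerical Hessian of $F_{ML}$
($\widehat{\mathrm{Var}} = 2H^{-1}/(n-1)$), but the package's preferred
inference — matching survey practice when Mardia's test rejects
multivariate normality — is the **bootstrap**: resample rows, refit
(warm-started at the full-data solution), and take percentile intervals.
The conventional replicate count is 3000; tests and examples scale it down
(60–300) purely for speed, a choice that affects interval smoothness, not
validity. Replicate failures are counted and more than 20% aborts with
advice to revise the model.

Fit is summarised by CMIN/DF, CFI, TLI, RMSEA (baseline = independence
model, which has a closed-form fit) and AIC in the $\chi^2 + 2q$
convention, so magnitudes are comparable with common SEM software output.
`compare_models` ranks by AIC and flags disagreement among the five
criteria.

### Measurement repair by parceling

Item-level CFA of 30+ Likert items often misfits because of shared method
variance among items. `make_parcels` implements factorial (item-to-construct
balance) parceling: items are sorted by absolute single-factor loading and
dealt to $k$ parcels in serpentine order (1..k, k..1, ...), ties broken by
item order; parcel scores are item means. Defaults: 3 parcels per
construct, 2 when a construct has fewer than 6 items, none for 3-item
scales. The serpentine deal is the standard heuristic; it balances parcel
loading sums well but is not the exhaustive optimum over all partitions,
and the tests treat it as the deterministic algorithm it is. A property
test confirms the motivating claim: under correlated item errors, parcel
CFA fit (CFI) is at least as good as item-level fit in ≥90% of replicates.

## Effect decomposition

With $B$ and $\Gamma$ extracted from a fit, total effects are the closed
form of the infinite path series:
$T_{endo} = (I-B)^{-1} - I$, $T_{exo} = (I-B)^{-1}\Gamma$, and
*indirect = total − direct* by definition, so additivity is exact (to
floating point) in every computed table, including the loop-amplified
effects of a variable on its own outcome's partner. Percentile intervals
for every component come from applying the same decomposition to each
bootstrap replicate. `standardize_effects` rescales by model-implied SD
ratios, which preserves additivity and leaves the product of the two
reciprocal paths invariant.

## The synthetic-data generator

`default_population_spec()` encodes the study regime the package targets:
$n = 1379$ respondents; reciprocal depression↔anxiety paths of 0.74 each;
somatic symptoms on depression (0.38) and anxiety (0.06); published direct
covariate effects (e.g. stress −0.06/0.54/0.53 on the three outcomes,
social support −0.13 on depression, chronic illness 0.17 on somatic
symptoms); latent stress and support with unit variance and correlation
−0.3; covariate frequencies from the study's descriptive table (alcohol
35.75%, chronic illness 10.3%, female 61.13%, private school 10.22%,
physical trauma 21.97%, physically active 16.24%).

Choices the source material leaves open, fixed here once and documented:

* **Disturbances.** $\Psi$ is diagonal (variance 0.3). The reciprocal paths
  already carry the outcome coupling; leaving residual covariances at zero
  keeps both the "complete correlation" mask (freeing `a ~~ b` lines) and
  the default constrained mask correctly specified. The default *analysis*
  model uses the constrained mask, mirroring the selection step that keeps
  only significant disturbance covariances.
* **Measurement.** Graded-response thresholding: item indicator =
  0.7 × construct + Gaussian error sized for per-item reliability ≈ 0.55;
  thresholds are standardized cutpoints placed to give symptom-skewed
  category frequencies (roughly 40/35/17/8% for 0–3 items), shifted by the
  construct's model-implied mean. Unprinted loadings default to 0.7.
* **Missingness.** MCAR at rate 2e-4 per cell, confined to predictor
  columns (covariates and stress/support items), reproducing the regime
  where a handful of records (~0.5%) are incomplete and all missingness
  sits in predictors.

What the generator does *not* emulate: differential item functioning,
non-MCAR missingness, clustering by school (ICC ≈ 0), and any non-linear
covariate effects. Passing recovery tests therefore demonstrate estimator
correctness under the declared linear-Gaussian-threshold regime, not
robustness to survey artefacts beyond it.

A consequence worth stating plainly: when items are generated ordinal and
then analysed as continuous (the field's ML-on-Likert practice), Pearson
covariances are attenuated. Ratio-type parameters (the loop coefficients)
remain nearly unbiased, but latent-exogenous slopes can shift visibly
(stress→anxiety attenuates by ≈0.2–0.3 in the default regime). The
parameter-recovery studies therefore use the generator's continuous-
indicator mode, where the parcel-level model is exactly correctly specified
and truth maps onto the fitted marker scale in closed form
(`truth_structural`); the ordinal path is exercised end-to-end by the
pipeline tests with no unbiasedness claim.

## Verification strategy and problem sizes

* **Closed-form oracles**: implied covariance against the structural-form
  formula; $F_{ML}$ scalar case $1-\ln 2$; Wilson interval against a
  brute-force score-test inversion; KMO $= 0.5$ identity at $p = 2$;
  rank condition against an SVD rank oracle on random systems.
* **Cross-implementation checks**: one-factor CFA against
  `stats::factanal`; just-identified reciprocal systems against 2SLS
  (where full-information ML coincides exactly); recursive diagonal-$\Psi$
  systems against per-equation OLS.
* **Distributional checks**: $\chi^2$ at the truth against its reference
  distribution; Bartlett and Sargan size in [0.02, 0.09]; Mardia power on
  $t_3$ data.
* **Recovery and coverage**: 200 replications at $n = 2000$ for mean bias
  of every free structural coefficient (all below 0.03 in the committed
  runs, asserted below 0.1); bootstrap percentile coverage over 100
  replications × 200 replicates for the loop and stress paths, asserted
  within [0.90, 0.99]. These sizes are the package's chosen balance of
  Monte-Carlo precision against runtime.

## Known limitations

Complete-case ML only (no missing-data FIML); no ordinal-specific
estimators (WLSMV/polychoric); no multilevel fallback when ICC ≥ 0.1 (the
report recommends one instead); no per-path mediation decomposition beyond
total − direct; percentile (not BCa) bootstrap intervals; identification
logic covers the full-correlation disturbance case, not arbitrary
correlated-error exclusion patterns.

## A worked example

```{r example, eval = FALSE}
spec <- default_population_spec(n = 1379)
dat <- generate_dataset(spec, seed = 1)
res <- run_pipeline(dat, default_config(n_boot = 300, seed = 1))
cat(res$log, sep = "\n")
subset(res$effects, outcome == "depression",
       select = c(predictor, direct, indirect, total))
```
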