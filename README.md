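# nrsem

Non-recursive structural equation modeling for school-based adolescent
mental-health surveys.

## What problem this solves, and for whom

Epidemiologists and psychometricians who screen adolescents for
co-occurring depression (PHQ-9A), anxiety (GAD-7) and somatic symptoms
(SSS-8) face two modeling obstacles that one-outcome regressions cannot
handle: depression and anxiety influence *each other*, and covariate
effects reach each outcome both directly and through that feedback loop.
`nrsem` implements the full workflow for the standard answer — a
non-recursive latent structural equation model

η = B η + Γ ξ + ζ,   with a reciprocal depression↔anxiety block in B,

measured through Likert items, estimated by maximum likelihood with
bootstrap percentile inference, and reported as direct / indirect / total
effects with T_endo = (I−B)⁻¹ − I and T_exo = (I−B)⁻¹Γ.

The package covers each stage of that workflow as composable functions:

| stage | functions |
|---|---|
| scale scoring & prevalence | `score_scale`, `classify_scale`, `prevalence`, `apply_listwise` |
| simultaneous-equation identification | `structural_system`, `build_system_matrix`, `order_condition`, `rank_condition`, `check_unique_instruments` |
| instrument diagnostics | `cragg_donald_f`, `sargan_hansen`, `instrument_report`, `tsls` |
| pre-model diagnostics | `mardia_kurtosis`, `mahalanobis_outliers`, `kmo`, `bartlett_sphericity`, `icc1`, `harman_single_factor` |
| measurement | `fit_cfa`, `make_parcels` |
| estimation | `fit_sem`, `bootstrap_fit`, `fit_indices`, `compare_models` |
| effects | `total_effects`, `effect_table`, `standardize_effects` |
| orchestration & design | `run_pipeline`, `plan_sample_size` |
| synthetic data | `population_spec`, `default_population_spec`, `generate_dataset` |

The synthetic-data generator is first-class: it encodes the target survey
regime (n ≈ 1379, published structural coefficients, graded-response
Likert measurement, predictor-only missingness) so every downstream stage
is testable without any data download, and supports parameter-recovery
studies. See the methods vignette
(`vignettes/nonrecursive-sem-methods.Rmd`) for the model, assumptions,
defaults and verification strategy.

## Worked example

```r
library(nrsem)
spec <- default_population_spec(n = 1379)     # the package's survey regime
dat  <- generate_dataset(spec, seed = 1)      # ordinal items + covariates

scored <- score_dataset(dat)
prevalence(scored$phq9a_flag)                 # 35.97% (95% CI 33.5, 38.5)

analysis <- apply_listwise(dat)               # 1372 of 1379 records retained
prepared <- prepare_analysis_data(analysis)   # factorial parcels appended
fit  <- fit_sem(analysis_model(spec, level = "parcel"), prepared)
fit
#> nrsem fit: 23 observed variables, 107 free parameters, n = 1372
#>   chi-square = 175.557 on 169 df (CMIN/DF = 1.04)
#>   CFI = 1.000  TLI = 0.999  RMSEA = 0.0053  AIC = 389.6

boot <- bootstrap_fit(fit, prepared, n_boot = 300, seed = 1)
eff  <- effect_table(fit, boot)
subset(eff, predictor == "stress" & outcome == "depression")
#> direct -0.12 [-0.24, 0.21]  indirect 0.52  total 0.40 [0.35, 0.45]
```

Reading the output: the model fits the generated data closely (CMIN/DF
near 1, RMSEA ≈ 0.005). Stress shows the signature of a feedback system —
a small direct path on depression but a large total effect, because its
strong effect on anxiety is amplified back into depression through the
reciprocal loop; the decomposition satisfies total = direct + indirect
exactly. (On ordinal items analysed as continuous, coefficients are
attenuated relative to the generating truth; the vignette quantifies
this.)

`run_pipeline(dat, default_config())` chains the whole analysis —
scoring, guarded listwise deletion, Mardia/Mahalanobis/KMO/Bartlett/Harman
diagnostics, the identification gate (nothing is fitted when the rank
condition fails), Cragg–Donald/Sargan instrument checks with weak-path
remediation, parceling, ML fit, bootstrap and effect tables — and logs
each stage's verdict.

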