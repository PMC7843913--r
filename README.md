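# comascore

Severity scoring and paired diagnostic-accuracy validation for comatose
neurocritical-care patients.

Patients admitted to a neurological ICU in coma have widely divergent
prognoses, and bedside severity scores remain the standard way to estimate
them. `comascore` implements the **INCNS score** — a 19-item scale spanning
Inflammation, Nutrition, Consciousness, Neurological function and Systemic
function, totalling 0–44 points (higher = worse) — together with the three
standard comparators it is validated against: the Glasgow Coma Scale (GCS,
3–15, lower = worse), the FOUR score (0–16, lower = worse) and APACHE II
(0–71, higher = worse). Around the scorers it provides the full validation
pipeline used in prognostic-accuracy studies:

- **Cohort construction** — coma eligibility from GCS components
  (E = 1, V ≤ 2, M ≤ 4), exclusion of short stays (< 72 h) and drug-induced
  coma, per-variable worst-value extraction over the first 24 and 72 h, and
  dichotomization of the 3-month modified Rankin Scale (mRS < 3 favorable).
- **Diagnostic accuracy** — empirical ROC analysis with the Mann–Whitney
  AUC, `AUC = Pr(score_pos > score_neg) + ½·Pr(tie)`; DeLong
  structural-component variance with logit-scale confidence intervals;
  paired DeLong z-tests for correlated AUCs at the Bonferroni-corrected
  level α = 0.05/6 = 0.0083; Youden-index cut-offs (maximizing Se + Sp);
  confusion-matrix panels including balanced accuracy (Se + Sp)/2; McNemar
  tests for paired Se/Sp/CC; and a cluster-robust generalized score test
  for paired PPV/NPV.
- **Synthetic cohorts** — a seeded latent-severity simulator producing
  timelines of repeated observations with three properly nested binary
  outcomes (unfavorable functional outcome ⊇ 3-month death ⊇ NICU death) at
  configurable prevalences (defaults 83% / 45% / 9.6%), with the
  score–outcome association calibrated through the binormal identity
  `AUC = Φ(Δ/√2)`.

## Worked example

Simulate a 271-patient cohort emulating the validation study's design, build
the analyzable table, and compare the four scales for 72-h worst scores
against unfavorable 3-month functional outcome:

```r
library(comascore)

sim    <- simulate_cohort(sim_config(), seed = 42)
cohort <- build_cohort(sim$observations, sim$outcomes)
val    <- validate_scores(cohort, outcome = "unfavorable", window = 72)
val
#> <coma_validation> outcome: unfavorable  window: 72 h  ( 225 positive / 46 negative )
#>   incns    AUC 0.805 (0.725-0.866)
#>   apache2  AUC 0.768 (0.690-0.832)
#>   four     AUC 0.789 (0.700-0.857)
#>   gcs      AUC 0.740 (0.656-0.810)
#>   ROC comparisons at alpha 0.0083 ; accuracy comparisons at alpha 0.05
```

225 of 271 simulated patients (83%) have the unfavorable outcome, matching
the configured prevalence. `glance()` gives one row per scale with its AUC,
DeLong 95% CI and the Youden cut-off panel; for instance the INCNS cut-off
lands at 21 points with Se 0.80, Sp 0.65 and balanced accuracy 0.726.
`tidy()` stacks the pairwise comparisons:

```r
dplyr::filter(tidy(val), scale_a == "incns", scale_b == "apache2")
#>   scale_a scale_b metric method             prop_a prop_b statistic  p_value  alpha
#> 1 incns   apache2 auc    delong              0.805  0.768     2.51  0.0121   0.0083
#> 2 incns   apache2 se     mcnemar_asymptotic  0.8    0.711    13.9   0.000194 0.05
#> ...
```

Here the AUC difference (z = 2.51, p = 0.012) does not pass the
multiplicity-corrected 0.0083 level, while the McNemar comparison of
sensitivities at each scale's own cut-off does — the kind of pattern these
paired analyses are designed to expose. Individual scorers are available
directly:

```r
incns_item_points("glucose", 19.35)      # 2 (rounds into the >= 19.4 band)
score_incns(worst_observation())$total   # 44
score_apache2(worst_observation())$total # 71
```

`autoplot(val)` overlays the four ROC curves; `autoplot(val$roc$incns)`
draws one with its AUC and CI.

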