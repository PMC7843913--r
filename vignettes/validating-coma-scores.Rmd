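---
title: "Scoring and validating severity scales in comatose patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating severity scales in comatose patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comascore)
```

`comascore` implements a complete prognostic-validation workflow for
comatose neurocritical-care patients: four severity scorers, the cohort
rules that turn raw observation timelines into an analyzable table, the
paired diagnostic-accuracy statistics used to compare scales, and a seeded
simulator that generates cohorts with known structure. This vignette
records the modelling choices, conventions and tunable parameters, and what
the synthetic validation does and does not demonstrate.

## The scales

The INCNS score has 19 items across five domains; each item maps a
measurement or an exam finding into 0–3 points through closed bands printed
at one-decimal resolution, and the item maxima sum to 44 (inflammation 4,
nutrition 2, consciousness 6, neurological function 15, systemic condition
17). Three conventions are worth making explicit:

- **Band assignment.** All printed interval endpoints are inclusive. Inputs
  are first rounded half-up to the one-decimal band resolution; a value
  that still falls between two printed bands (the sheet leaves gaps at
  integer-resolution items, e.g. creatinine between 43 and 44) is assigned
  to the adjacent band with *more* points. Ambiguity therefore scores as
  more severe, the conservative clinical choice.
- **Corrected cells.** The published sheet's 2-point WBC cell is corrupted
  (it repeats the temperature bands). The implementation uses the
  complement of the printed 0/1 bands — WBC ≤ 2.8 or ≥ 25.1 — which keeps
  every value scoreable and the item maximum at 2, as the 44-point total
  requires. The creatinine 0 band is likewise taken as 44–132 (the printed
  "4.4–132" contradicts the 1-point band "≤ 43"). The pupillary and corneal
  reflex items genuinely have no 1-point band (0 → 2 → 3), and are
  implemented as printed.
- **Motor item.** Either the Lovett limb-strength rubric or the
  pain-response rubric may be supplied; the INCNS scores the *worse* limb
  (bilateral strength ≤ 1 → 3, unilateral ≤ 1 → 2, worst limb 2–3 → 1,
  otherwise 0). When both rubrics are present the strength rubric wins and
  a note is recorded in the output.

GCS and FOUR are the standard instruments; for intubated patients the GCS
verbal component is unassessable and is scored 1 with a note — the dominant
clinical convention. APACHE II is implemented from its published point
tables as the comparator: 12 acute-physiology variables (GCS enters as
`15 − GCS`; creatinine points double under acute renal failure; oxygenation
uses A–aDO2 bands when FiO2 ≥ 0.5 and PaO2 bands otherwise) plus age and
chronic-health points, maximum 71. Axillary temperature feeds the APACHE II
temperature item, since it is the temperature the observation layout
carries. `max_score()` recomputes each maximum from the implemented tables
rather than quoting it.

Missing inputs are a hard error by default. An explicit
`assume_normal_missing = TRUE` imputes the 0-point (normal) band per item
and records a note per imputation; silent imputation would bias worst-value
scores downward, so the flag is never the default.

## Cohort construction

Eligibility is judged on the *earliest* recorded exam: coma means GCS eye
response 1, verbal ≤ 2 and motor ≤ 4. Patients staying under 72 h or with
drug-induced coma are excluded. Exclusion reasons are logged one per
patient, checked in the fixed order non-comatose → short stay →
drug-induced (the source criteria carry no precedence; a fixed order makes
the log deterministic).

The analyzed quantity is the *worst-in-window* score. For each scored
variable independently, the most points-adverse value among observations in
`[0, window]` hours is taken, and the composite worst-case observation is
scored; an admission-time (t = 0) observation counts as inside. Because
every scale here is item-additive, this equals taking the per-item maximum
points (minimum component, for GCS/FOUR) across in-window observations.
The alternative reading — keep the single observation with the worst total
— is available as `method = "worst_total"` for sensitivity analysis; the
per-variable composite is the default because worst-value severity scoring
(APACHE II's own convention) is defined variable-wise. A direct consequence
checked in the tests: the 72-h worst score is always at least as adverse as
the 24-h one.

## Diagnostic-accuracy statistics

**AUC.** The empirical AUC is the Mann–Whitney pair count (ties ½). GCS and
FOUR are adverse-low scales; their orientation is handled by negating
scores internally, so that AUCs of opposite-oriented scales are directly
comparable.

**Variance and CIs.** The DeLong structural components give the AUC
variance; the 95% interval is computed on the logit scale and
back-transformed, which respects the `[0, 1]` boundary at the extreme AUCs
seen in mortality panels. When the components are degenerate (perfect
separation) the interval collapses to the point estimate with a warning
rather than fabricating width. A stratified bootstrap percentile interval
(`ci_method = "bootstrap"`) is the validation alternative; the tests check
the two agree. Paired AUCs are compared with the DeLong z-test using the
paired covariance of the components; with four scales there are six
comparisons, so the ROC family is judged at `bonferroni_alpha(6)` = 0.0083.

**Cut-offs.** The Youden cut-off maximizes Se + Sp over the observed
scores, with predicted-positive defined as score ≥ threshold for
adverse-high scales and ≤ threshold for adverse-low ones. Ties are broken
toward higher sensitivity — in a prognostic setting, missing a death is the
costlier error — then toward the more inclusive threshold; both rules are
deterministic and checked against exhaustive search. The "predictive
accuracy" of a cut-off panel is balanced accuracy, (Se + Sp)/2; this
identity is an inference about how such panels are reported, and the test
suite verifies it reproduces all six published panel values it emulates.

**Paired accuracy tests.** Sensitivity, specificity and correct
classification are compared with McNemar's test on the discordant pairs —
exact binomial below 25 discordant pairs, continuity-corrected chi-square
otherwise (the conventional switch point; the tests confirm the two agree
near the boundary). PPV and NPV cannot be compared subject-wise, because
each score conditions on its *own* predicted class; the package uses a
cluster-robust generalized score statistic: records are stacked over each
subject's predicted-positive (or negative) results, and the score test for
the score-indicator effect uses an empirical variance clustered by subject.
Its operating characteristics are validated by simulation (type-I error
within [0.03, 0.07] at α = 0.05 under an exchangeable null) and against a
cluster bootstrap.

**Rounding.** All internal math is at full precision. Percentages are
rounded half-up to one decimal only at the reporting layer
(`round_half_up()`), because binary round-half-even corrupts exactly the
reporting-scale ties that occur in practice (82.55 must report as 82.6).
Reconstruction of a confusion table from a printed Se/Sp pair
(`reconstruct_confusion()`) inverts that convention with half-up rounding
of tp and tn.

## The synthetic cohort generator

No patient-level data accompany the validation design the package
implements, so the generator is a first-class module rather than a test
fixture. Its defaults encode the study conditions: 271 analyzable
patients; outcome prevalences 83% unfavorable, 45% 3-month death, 9.6%
NICU death; observations at 2, 12, 24, 48 and 72 h; and a small positive
deterioration drift (0.004 latent SD per hour), reflecting that
neurocritical patients tend to worsen beyond 24 h — which is also why 72-h
scores discriminate slightly better in simulated runs.

The design is a single latent severity factor. Each patient's outcome
stratum (favorable / unfavorable survivor / 3-month death / NICU death) is
drawn first at the nested prevalences, guaranteeing the nesting invariants
(every NICU death is a 3-month death; mRS 6 exactly for the dead). Latent
severity is then `z ~ N(m_s, 1)` given stratum `s`, with the ordered
stratum means solved numerically so that *each* of the three nested
dichotomies attains the binormal mixture AUC `Φ(Δ/√2)` on the latent scale,
where Δ is `latent_effect`. This makes `closed_form_auc()` /
`calibrate_effect_for_auc()` an exact oracle: calibrating Δ for a target
AUC and generating a cohort recovers that AUC on the latent score up to
sampling error (±0.03 at n = 1000 in the acceptance checks). Drawing class
first and z conditionally is distributionally identical to drawing z from
the mixture and thresholding with logistic noise, since equal-variance
Gaussian class conditionals imply a logistic posterior. The default
`latent_effect` is calibrated for AUC 0.80, the middle of the range such
cohorts exhibit.

Every scorer input is a monotone map of z: numeric items follow
`normal + slope · softplus(z + drift·t + noise)` with slopes placed so the
1-point band is reached around one latent SD above typical severity and the
2-point band deep in the tail; ordinal exam items cut z at fixed
thresholds; GCS/FOUR components decrease with z. First-exam GCS components
are coerced to the coma criteria for the eligible arms (and away from them
for the non-comatose arm). Per-item noise (`item_noise_sd`, default 0.5 SD)
makes items imperfect measurements of z, so the banded INCNS total sits
slightly below the latent AUC — the information loss from banding is real
and bounded (the acceptance check requires the INCNS AUC to exceed 0.75
when the latent target is 0.85). Exclusion arms (defaults 4% non-comatose,
5% short-stay, 2% drug-induced, on top of `n_patients`) exercise the
cohort rules; age is drawn around the study's demography (median ~55) and
etiology labels at the published proportions, both independent of z.

What the generator does *not* emulate: the real inter-item correlation
structure (a single factor is a stated simplification — real labs co-vary
in blocks), etiology-specific physiology, informative missingness, and
measurement error in outcome ascertainment. Passing the simulated
validation therefore demonstrates that the pipeline's mechanics and the
statistics' operating characteristics are correct — not that the INCNS
achieves any particular accuracy in real patients.

## Numerical choices and problem sizes

- Stratum means are solved by Nelder–Mead on log-increments (ordering
  enforced by construction), to squared-error tolerance 1e-8 on the three
  AUC equations; `latent_effect = 0` short-circuits to all-zero means.
- Degenerate statistics never produce NaN: zero DeLong variance with a zero
  AUC difference gives p = 1; zero discordant pairs give p = 1 with a note;
  a predictive-value test with no predicted positives is an explicit error.
- Seeds: `simulate_cohort()` runs inside `withr::with_seed()`, so identical
  seeds give identical cohorts and the caller's RNG state is untouched.
- The test suite simulates cohorts of 120–1000 patients, uses 500
  replicates for CI coverage, 1000 for type-I calibration and 10,000 for
  bootstrap oracles; the end-to-end acceptance run uses 2000 patients with
  all four scales, both windows, three outcomes and every pairwise test.
  These sizes give Monte-Carlo error comfortably inside the asserted
  tolerances while keeping the whole suite under a minute of compute.

## Limitations

The APACHE II scorer is a faithful comparator implementation, but uses the
observation layout's axillary temperature and derives its GCS item from the
same components as the GCS scorer (including the intubation convention);
sites differ on both conventions. The generalized score test is one member
of the family of paired predictive-value tests; where a different member is
wanted, the cluster bootstrap in the test suite shows how to build one. The
printed 72-h NICU-mortality specificity (82.5%) is not consistent with any
integer confusion table at the published class sizes — the reconstruction
yields 82.4% — and is treated as a print inconsistency rather than a target.
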