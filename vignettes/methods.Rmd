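---
title: "Estimating lower-limb muscle group volumes: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb muscle group volumes: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclevol)
```

## The problem

Muscle volume (MV) is the preferred in-vivo measure of muscle size for
monitoring training adaptation and injury-related atrophy, but the criterion
measurement — manual segmentation of serial MRI slices — costs hours per
limb and is unavailable to patients with metal implants. `musclevol`
implements a clinically oriented alternative: regression equations that
estimate the volume of four functionally important lower-limb muscle groups
(hip extensors, knee extensors, knee flexors, ankle plantarflexors) from
body mass, limb lengths, and single panoramic B-mode ultrasound
measurements of muscle thickness (MT) or cross-sectional area (CSA).

The package has four layers:

1. **Volumetry.** The criterion MV of a muscle is the trapezoidal sum over
   its serial axial CSA slices,
   $\mathrm{MV} = \sum_{i=1}^{n-1} \tfrac{\mathrm{CSA}_i +
   \mathrm{CSA}_{i+1}}{2}\, h$, with CSA in cm², uniform inter-slice
   distance $h$ in cm, giving cm³. Group volume is the sum over the group's
   roster muscles.
2. **Reliability.** Between-session measurement error as the typical error
   of measurement, $\mathrm{TEM} = \mathrm{SD}_\text{differences}/\sqrt 2$,
   absolute and as a percentage of the *first* session's mean.
3. **Model development.** A forced-entry OLS pipeline with outlier
   exclusion, semi-partial screening, an 80/20 split, leave-one-out
   candidate retention, a seven-criterion diagnostic battery, holdout
   cross-validation and a difference-versus-mean (Bland–Altman) agreement
   trend.
4. **Clinical prediction.** The four published equations as an embedded
   registry, evaluated on new measurements with a ±1 SEE band, plus a
   sensitivity rule (an effect is detectable when it exceeds the model's
   SEE%).

A synthetic cohort generator makes every stage runnable and testable: the
original study's data are not publicly available, so all end-to-end tests
operate on cohorts drawn from the generative structure the analysis
assumes.

## The published models

Each model is a simple regression `MV = constant + slope × predictor` where
the predictor is a product of two measurements (units are mixed by design
and encoded in the column names):

| Group | Predictor | Constant | Slope | SEE (cm³, %) |
|---|---|---|---|---|
| Hip extensors | mass (kg) × thigh length (m) | 1087.037 | 64.946 | 283.01, 8.92 |
| Knee extensors | anterior-thigh MT at 50% thigh (cm) × mass (kg) | 996.168 | 4.664 | 121.10, 5.24 |
| Knee flexors | BF short-head MT at 75% thigh (cm) × thigh length (m) | 1199.444 | 318.147 | 125.37, 7.89 |
| Ankle plantarflexors | lateral gastrocnemius CSA at 25% shank (cm²) × mass (kg) | 878.606 | 0.553 | 134.91, 10.78 |

The registry (`published_model()`) also carries standard errors, 95%
confidence intervals, p values (entries reported as "< 0.001" are stored as
the bound 0.001), R², adjusted R², Durbin–Watson statistics,
cross-validation residuals, and the development/holdout group
characteristics. The knee flexor and plantarflexor models showed a
significant positive difference-versus-mean trend in their validation;
`estimate_volume()` attaches a systematic-error caveat to those two groups
and warns when an input lies outside the development range (mean ± 3 SD of
the development group — the development min–max was not published).

Internal consistency of the registry is checkable arithmetically and is
what the acceptance suite asserts: with the shared residual-df convention,
$\text{adj}\,R^2 = 1 - \mathrm{SEE}^2/\mathrm{SD(MV)}^2$ reproduces all
four printed adjusted R² values to three decimals, and the printed SEE% and
cross-validation% values equal `100·SEE/mean(MV)` and
`100·|mean residual|/holdout mean`.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults *are* the stated world:

* Measurement marginals are normal with the published development-group
  means/SDs, truncated at ±3 SD (whole-subject redraw on violation).
  Shared anthropometrics (mass 79.8 ± 10.9 kg, height 1.81 ± 0.07 m) use
  the whole-sample characteristics because one cohort column cannot match
  four slightly different per-group tables at once; group-specific
  ultrasound measures use their own table's values. Shank length
  (0.44 ± 0.03 m) and gluteal MT (3.0 ± 0.5 cm) are not characterized in
  the published tables; the defaults are typical values for recreationally
  active adult males and were fixed once, before any testing.
* Latent group volumes follow `MV = constant + slope × predictor + ε`,
  ε ~ N(0, SEE) with the published constants, slopes and SEEs.
* Session-2 ultrasound replicates add N(0, TEM·√2) error with the
  published TEMs (the BF short-head TEM, printed as 0.00 at 0.2%, is
  carried as 0.006 cm, back-computed from the percentage).
* Each group's latent volume is partitioned across its roster muscles
  (Dirichlet-like gamma weights) and each muscle gets a CSA slice series: a
  parabolic envelope (zero at origin and insertion) with 5% multiplicative
  jitter, rescaled so the trapezoidal integral equals the latent volume
  exactly. Anatomical shape realism is explicitly a non-goal; integral
  correctness is the contract.
* One master seed; per-subject-per-group profile streams are derived from
  it deterministically, so regeneration is bit-for-bit reproducible.

**The independence assumption.** The study reports only marginal
means/SDs, never the joint distribution, so the two factors of each
composite predictor are drawn independently by default
(`predictor_correlation = 0`, a documented knob). This matters: under
independence, SD(mass × thigh length) ≈ 4.6 kg·m, whereas the printed
R²/SEE pair implies ≈ 6.5 — a variance that is unreachable even at factor
correlation 1 (and the overlapping factor pairs bound the feasible joint
correlation well below 1; an infeasible value is rejected, not adjusted).
Consequences a user of green tests should understand:

* Synthetic hip-extensor cohorts at the study's n have R² ≈ 0.5 rather
  than 0.69, and the fitted constant's 95% CI crosses zero far more often
  than in the published fit. Diagnostic criterion 1 therefore fails in a
  majority of small-n synthetic runs. This is a property of the stated
  world, not a defect of the pipeline, and the generator parameters were
  deliberately not tuned to hide it.
* Tests of the pipeline on synthetic data assert structural properties
  (determinism, retention of the generating predictor in the majority of
  seeds, exact zero-noise behaviour, planted-violation detection), not the
  published pass rates.
* Parameter recovery at n = 10 000 is asserted in the sampling-theory form
  (within 2 standard errors); the slope's standard error at that n is
  ~1% of its value for the hip model, so a fixed "within 1% always" bound
  would be a coin flip, not a test.

## Pipeline conventions and numerical choices

* **OLS** is computed by QR; SEE = √(SS_res/(n − p − 1)); CIs use the t
  distribution on n − p − 1 df. Standardised residuals are residual/SEE
  (not studentized; whether the original analysis studentized them is
  unknowable from the text). Tests cross-check coefficients and SEs
  against an explicit normal-equations oracle.
* **Normality** uses the Lilliefors-corrected Kolmogorov–Smirnov test
  (estimated mean/SD), with the published Dallal–Wilkinson/Stephens p-value
  approximations, implemented here because no Lilliefors implementation is
  guaranteed in the runtime environment; Shapiro–Wilk is available as a
  config alternative. The approximation was validated against an
  independent implementation; two frozen oracle values are asserted in the
  tests.
* **Outlier exclusion** is reconstructed as: while the criterion volumes
  fail the normality test (p < 0.05), remove the case with the largest |z|
  from the group mean, up to 2 removals, then warn and proceed. The study
  names its exclusions but not its rule; this rule reproduces
  "remove the gross outliers until the distribution tests normal".
* **Screening** ranks candidates by |correlation| with MV (the semi-partial
  with an empty partialling set), excludes non-normal candidates, and
  excludes any candidate whose *multiple* correlation with the
  already-kept, stronger candidates exceeds 0.80. The multiple-correlation
  form reduces to the pairwise rule for a single kept candidate and also
  catches a composite product's two factors, which are jointly — not
  pairwise — collinear with the product. The retained count is capped at
  one predictor per 15 cases, clamped to a minimum of one (13–14 cases
  would otherwise allow zero; every published final model has exactly one
  predictor).
* **Split**: holdout = floor(0.2·n + 0.5), unstratified (stratification is
  not described), so 17 cases give 3 and 18 give 4, matching the published
  sub-sample sizes. The seed is exposed in the provenance block.
* **Leave-one-out retention**: "present in a fold" is operationalized as
  p < 0.05 *and* 95% CI excluding zero, mirroring diagnostic criteria
  1–2; a variable must be present in every fold.
* **Diagnostics**: criterion 1's CI rule includes the constant (models
  were rejected for constants whose CIs crossed zero); criterion 2 covers
  predictor slopes only. "R² and adjusted R² similar" is a gap ≤ 0.10
  (all published models satisfy it, max gap 0.059). "Semi-partial
  correlations similar" passes vacuously with one predictor, else requires
  a spread ≤ 0.2 (an admittedly arbitrary, documented threshold).
  Homoscedasticity is made quantitative — Pearson correlation of
  |standardised residual| against standardised prediction, pass iff
  p ≥ 0.05 — because the original check was visual. Criterion 6 combines
  the Durbin–Watson verdict with residual normality. Criterion 7
  (practicality) is inherently qualitative; it is exposed as advisory
  config weights and never gates `overall_pass`.
* **Durbin–Watson** uses dataset row order and an embedded table of the
  published 5% upper bounds for n = 6–20, k = 1–2; outside the table the
  nearest bound is used conservatively with a warning. The worked
  published case quotes an upper limit of 1.40 at n = 14, k = 1, where the
  published table gives dU = 1.350 (1.400 is the n = 6 row); the verdict
  (1.67 → pass) is unaffected, and the embedded table keeps the published
  values.
* **Degenerate fits**: a zero-noise cohort yields residuals that are
  numerical noise (|SEE| < 1e−8 relative to the response scale);
  residual-based diagnostics (5, 6) and the agreement trend then report
  pass/no-trend with a degeneracy flag rather than testing noise.
* **Cross-validation residual**: signed mean (criterion − predicted) with
  the percentage over the holdout mean; the absolute-value form used by
  the published tables is reported alongside.
* **Agreement trend** is computed over all non-excluded cases (development
  plus holdout) — the published wording ("for all participants") is
  ambiguous; this choice is recorded here.

## Configuration and interfaces

All thresholds live in `run_config()` (alpha 0.05, R² gap 0.10,
collinearity 0.80, residual bound 2.00, max 2 outlier removals, holdout
0.2). Cohorts and profiles are interchanged as headered CSV with units in
the column names; configs and specs are JSON (YAML is not supported: no
YAML parser is available in the target runtime). The CLI (`run_cli()`)
exposes `simulate`, `volume`, `tem`, `develop`, `estimate`; `develop`
reports are JSON with full provenance (seed, split ids, retained
variables, config, package version) and are byte-reproducible under a
fixed seed.

## Known limitations

* The cohort generator reproduces marginals and the linear
  predictor–volume law, not the joint anthropometric distribution of real
  adults (see above); it also models only healthy adult males, as in the
  source population.
* The SEE% denominators are inferred (and verified arithmetically) to be
  development-group means; the original tables do not state this.
* The ±1 SEE band is not a prediction interval; proper intervals would
  need the development design moments, which were not published.
* The reliability sub-study behind the published TEMs used two
  participants; TEM estimates at that n are extremely imprecise, and the
  package reports whatever n it is given without pretending otherwise.
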