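---
title: "Methods: terminology-driven fall-risk modelling and outcome analysis"
author: "fallcds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terminology-driven fall-risk modelling and outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices and known limitations
behind `fallcds`. The package is an analysis pipeline for a multihospital
fall-prevention setting: a standardized-terminology catalog drives both the
comparison of local nursing vocabularies and the tailored care-plan
recommendations, a discrete Bayesian network scores the hourly fall risk of
inpatients, and interrupted time-series regression tracks monthly fall rates
around an intervention. Because the hospitals' EMR data are not public, a
synthetic cohort generator reproduces the statistical structure the analysis
assumes; every result the package computes on synthetic data is therefore a
statement about the methods, not about the original patients.

## The catalog and coverage

The content model is an ICNP-style inpatient fall-prevention catalog: 98
nursing statements grouped into 13 care-element rows (protocol provision is
merged into risk-targeted care, so the 13 rows span 14 care elements), split
into an assessment/diagnosis/outcome branch and an intervention branch.
Intervention statements carry risk-factor categories (cognition, toileting,
mobility, medications, sensory, sleep) that link predictions to
recommendations. The published table reports only element-level counts, so
the packaged statement texts are synthetic placeholders; all computations
depend only on the element/statement structure, identifiers and counts.

Coverage of a site's local vocabulary is the fraction of catalog statements
with at least one semantically equivalent local statement. Several local
phrases mapping to one catalog statement count once. Percentages are rounded
half away from zero to one decimal (`round_half_up()`), because the printed
table uses commercial rounding (47/98 prints as 48.0, which IEEE
half-to-even would render 47.9).

## The hourly risk model

The concept model is a discrete Bayesian network over feature nodes tagged
with six constructs: demographics/administrative, KPCS (nursing-needs
classification; its items are separated from the administrative construct so
sensitivity analyses can address it on its own), medication, nursing
assessment & diagnosis, nursing intervention, and the heuristic bedside tool
(Morse, Hendrich II or STRATIFY, banded low/med/high). The binary target is
`fall_next_hour`.

The packaged default structure is a three-layer tree: the target at the
root, construct-summary nodes below it, and observable features at the
leaves; single-feature constructs attach directly to the target. Design
choices worth stating explicitly:

* **Summary nodes are derived observed columns, not latent variables.** A
  summary is the banded count (`none`/`one`/`multi`) of active findings
  among its child features, computed by `derive_construct_summaries()`
  before fitting. This keeps maximum-likelihood fitting a pure counting
  problem (no EM), keeps every conditional probability table small, and
  makes the three-layer factorisation exactly consistent between training
  and inference. At prediction time the summaries can be supplied or
  marginalised out; both give exact posteriors.
* **Fitting** is additive-smoothed maximum likelihood (`alpha = 1` by
  default). Parent combinations never observed get a uniform row when
  `alpha = 0`, where the MLE is undefined.
* **Inference** is exact variable elimination for any DAG; tree-structured
  networks additionally get a vectorised message-passing path used for
  batch prediction (`predict_risk()`). The two paths agree to machine
  precision and are tested against brute-force joint enumeration.
* **Associated risk factors** are the evidence findings whose single-finding
  likelihood ratio for the target exceeds 1 — the findings that on their own
  raise the posterior. The source analysis does not define its extraction
  rule; this one is transparent and testable.
* **Continuous features** (age, tool score) are kept for distance-based
  balancing but the network itself is fully discrete; generic continuous
  columns can be discretized by `discretize_quantile()` (3 quantile bins by
  default; age uses the clinical 50/70 bands instead).

### Construct sensitivity

The contribution measure is variance reduction: with binary target prior
`p`, prior variance `p(1-p)`, and construct feature set `C`,

    VR(C) = Var(T) - sum_c P(C = c) Var(T | C = c)

summing over the joint states of the construct's observable features,
enumerated exactly (an error asks the user to raise the cap or shrink the
construct beyond 1e5 joint states). `vr_profile()` reports raw values and
shares of the total across constructs; shares sum to one. A construct
independent of the target reduces nothing; one that determines the target
removes all of `p(1-p)`.

### Model variants

Three variants mirror the study's comparison: the full model, the model
with the heuristic-tool construct ablated (`ablate_construct()`, the variant
the hospitals deployed to reduce nurses' scoring burden), and the heuristic
tool alone. The tool-alone variant is scored by the continuous tool score —
the banded node is the network's feature, but a bedside scale is used as a
score in practice. The operating threshold for sensitivity/specificity
tables is chosen by Youden's J on the validation split (the study does not
print its threshold); ties resolve to the lowest threshold, and scores at
the threshold count as positive, so outputs are bit-stable.

## The synthetic cohort generator

`generate_site_cohort()` emulates what the analysis needs and nothing more.
Per stay: a latent frailty `u ~ N(0,1)`; age, prior-fall history, KPCS items
and medication flags load on `u` with logistic prevalences; assessment
findings and the preventive-intervention flag vary hourly. The hourly fall
hazard is logistic with additive log-odds: each active finding contributes
`w * log(effect[category])` with per-category odds multipliers
(`default_risk_effects()`: cognition 3.5, mobility 3.0, toileting 2.0,
medications 2.0, sensory 1.6, sleep 1.6, and a protective 0.7 for an active
preventive intervention). Setting every multiplier to 1 removes all signal,
and held-out AUROC drops to 0.5 — the generator's built-in negative
control.

Key calibrations, chosen once:

* **Rate calibration.** The hazard intercept is solved numerically so the
  expected event rate over the realized eligible observations equals the
  site's target (events per 1000 hospital-days / 24000 per hour). Only
  Bernoulli noise remains; over 20 seeds the mean realized rate stays
  within a few percent of target, and an unreachable target raises a
  calibration error.
* **Heuristic tool scores** are the latent risk plus Gaussian noise, banded
  at the 60th/85th percentiles. The noise multipliers (2.6 Morse, 3.2
  Hendrich II, 3.5 STRATIFY) come from the binormal relation between the
  latent separation and the added noise, placing the tool-alone AUROC in
  the moderate 0.65–0.74 range reported for bedside scales (this is a
  large-sample statement; per-cohort values at ~25 events scatter well
  around it), with the Morse sites discriminating slightly better.
* **Sparsity is preserved** (1–2 falls per 1000 hospital-days, roughly 25
  falls per 2000-stay cohort), so the class-balancing stage is genuinely
  exercised rather than decorative.
* **Site profiles** encode the study setting: tools Hendrich II / STRATIFY /
  Morse / Morse at sites A–D, drug-class counts 4/11/7/8, KPCS absent at
  site D (the KPCS columns are structurally absent there, and the site's
  network drops the construct), admission volumes and mean stays matching
  the published cohort scale, and recordable intervention statements
  restricted to each site's mapped vocabulary.

What the generator does **not** emulate: clinical free text, care pathways,
competing risks, length-of-stay physiology beyond a positive-skew
distribution, temporal drift within stays beyond hourly refresh, or the
true (unpublished) effect sizes. Passing tests show the machinery recovers
what it simulates — not that the original hospitals' coefficients would be
recovered.

## Preprocessing

Eligibility: adults (>= 18 years, the boundary at exactly 24 h of stay is
inclusive) without psychiatric, obstetric, emergency or pediatric
conditions; each dropped stay is labelled with its first failing rule in
the fixed order age, duration, condition (a missing age reports
`missing_age`). A 10-stay worked table:

| stay | age | hours | condition   | outcome            |
|------|-----|-------|-------------|--------------------|
| S01  | 40  | 100   | —           | kept               |
| S02  | 17  | 100   | —           | dropped (age)      |
| S03  | 40  | 23    | —           | dropped (duration) |
| S04  | 40  | 24    | —           | kept (boundary)    |
| S05  | 85  | 48    | psychiatric | dropped (condition)|
| S06–S10 | adult | >24 | —        | kept               |

Class balancing is a mixed-type SMOTE: synthetic minority rows interpolate
continuous features uniformly along the segment to one of the `k` nearest
minority neighbours and set nominal features by majority vote among the `k`
neighbours (ties broken by the seeded stream). Distances are Euclidean on
standardized continuous features plus a per-mismatch nominal penalty equal
to the median standard deviation of the standardized features, i.e. 1.
Original rows are never modified or removed, balancing applies to training
data only, and the validation split is never resampled (asserted in the
pipeline). The default target ratio 1.0 balances classes fully; it is
configurable.

One behaviour of this SMOTE variant deserves a warning. Nominal features of
a synthetic row are a deterministic majority vote over the base row's
neighbours, so the synthetic minority can concentrate on no more distinct
nominal patterns than there are minority rows. Balancing fully
(`target_ratio = 1`) from only ~15 events therefore floods training with a
few archetypes, and the fitted conditional tables can saturate — we have
observed a site's held-out AUROC collapse towards 0.5 in such a draw while
the unbalanced fit scored 0.82. The demonstration configuration therefore
sizes cohorts so each site trains on roughly 25–35 events, at which the
effect disappears; with genuinely tiny event counts, prefer a smaller
`target_ratio`.

Splitting is 7:3, stratified by label; the pipeline splits by stay
(stratifying stays by whether they contain an event) so windows of one stay
never straddle the split. Whether the original analysis split by stay or by
window is not stated; splitting by stay is the leakage-safe choice and is a
package decision, not a claim about the study.

## Interrupted time series

Monthly fall rates (falls per 1000 hospital-days, calendar months) enter a
segmented regression

    y_t = b0 + b1 t + b2 D_t + b3 (t - t0) D_t + e_t

with `D_t = 1` from the intervention month `t0` inclusive — `b2` is the
immediate level change in the first deployment month — and Newey–West
standard errors (Bartlett weights `1 - l/(L+1)`, default lag 1, with the
`n/(n-k)` small-sample scaling used by the econometrics software the field
runs; our implementation agrees with `sandwich::NeweyWest(adjust = TRUE,
prewhite = FALSE)` to machine precision). Inference uses the t distribution
with `n - k` degrees of freedom. The two-group model adds a group indicator
with full interactions; its reference branch reproduces the single-group
fit exactly, and identical groups estimate exactly zero interactions.

**Small-sample coverage, measured honestly.** With 34 months, intervention
at month 29 (six post months, matching a six-month follow-up) and AR(1)
noise with coefficient 0.4, the nominal 95% CI for the level change covers
the truth in only about 75% of 500 simulated panels — about 81–83% even in
a balanced design. This is a property of the estimator, not a bug: the
lag-1 Bartlett kernel captures roughly 60% of the AR(1) long-run variance
(SE deflation about 0.77, asymptotic coverage about 86%), and the HAC
estimate's own sampling noise pushes small-sample coverage lower. Users who
need calibrated small-sample inference at this design should prefer
fixed-b critical values or a parametric AR model; the package deliberately
reports the estimator as specified because it is the one the field uses.

The panel generator draws AR(1) noise (`noise_sd` is the innovation SD;
the first month starts from the stationary distribution), converts rates to
integer monthly fall counts over the hospital-days denominator (20,000 per
month by default, a realistic enterprise-level volume whose 0.05 rate
granularity makes grid-valued noiseless settings exactly representable),
and recomputes the rate from the counts so `rate = 1000*falls/days` holds
in the emitted panel.

## Problem sizes and numerical conventions

* Test and demonstration cohorts use 700–3000 stays per site (roughly
  10–40 falls); the model-contrast property uses 20 seeded 3000-stay
  replications, and rate calibration is checked over 20 seeds of 8000
  stays. These sizes make the stochastic properties decisively powered
  while staying interactive.
* All randomness flows from one run seed through `child_seed()` (fixed
  multiplicative fan-out), giving per-stream reproducibility: rerunning any
  pipeline with the same config and seed is byte-identical.
* Exact-inference tolerances: posterior vs enumeration 1e-12; noiseless
  ITSA recovery 1e-10; CPT rows sum to 1 within 1e-9.
* Inconsistent evidence (probability zero under the fitted joint) raises an
  explicit error rather than returning NaN.

## Known limitations

* The default network structure is a plausible three-layer tree, not the
  study's (unpublished) supplementary edge set; any edge list can be
  supplied as YAML.
* Statement-level fixture content below the care-element level is invented
  structure; only counts and identifiers are anchored.
* The CDS rule table ships with the two documented clinical examples plus
  one illustrative rule per remaining risk category; a production inventory
  would be larger.
* The HAC small-sample undercoverage described above applies to any
  short-series segmented regression run with these conventions.
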