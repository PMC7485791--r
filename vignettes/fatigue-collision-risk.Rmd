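---
title: "Linking driver autonomic fatigue to rear-end collision risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking driver autonomic fatigue to rear-end collision risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fatiguerisk)
library(dplyr)
```

## The problem

Professional truck drivers accumulate fatigue over a working day, and
fatigue is a known contributor to rear-end collisions, the most common
truck accident type. Subjective ratings under-report fatigue, so an
objective physiological index is needed. Sympathetic nervous activity,
read out from the spectral content of resting beat-to-beat heart
intervals, rises with driving fatigue; the question this package
operationalises is whether a driver's sympathetic index measured *after*
one shift predicts their collision-risk exposure *the following day*.

The package implements the full analysis as a reusable, tested pipeline:

1. **HRV stage** — quality control of short resting RR-interval (RRI)
   recordings, spectral estimation, LF/HF band integration, and the
   age- and heart-rate-normalised *LF deviation score*.
2. **Risk stage** — conversion of automotive warning events into
   behavioural features, rule-based or CART classification into
   collision-risk situations, and a per-hour daily risk index.
3. **Association stage** — Pearson correlations and a median-split
   Welch comparison linking the fatigue indices to the risk index.
4. **Synthetic cohort generator** — a first-class module producing
   drivers, shift-days, recordings, ratings, hours and warning events
   with known ground truth, so every stage is testable without field
   data.

## The HRV model

A resting recording is a 90-s sequence of beat intervals (ms). Spectral
power in the low-frequency band LF = [0.04, 0.15) Hz indexes
predominantly sympathetic modulation; the high-frequency band
HF = [0.15, 0.40) Hz indexes parasympathetic (respiratory) modulation;
LF/HF summarises their balance. Both LF and HF depend on heart rate and
age, so the sympathetic index used throughout is the **LF deviation
score**

$$
LF_{score} \;=\; \frac{\ln(LF / RRI_{average}) - \mu_{LF}(age)}{\sigma_{LF}(age)/10} + 50,
$$

i.e. `ln(LF / mean interval)` z-scored against an age-stratified
reference distribution and rescaled to mean 50, SD 10. Dividing LF by
the mean interval absorbs the heart-rate dependence; the age-binned
moments \((\mu_{LF}, \sigma_{LF})\) absorb ageing. An HF deviation
score is deliberately *not* computed: the corresponding reference
correction cannot be validated, so HF enters only through LF/HF.

The reference table shipped with the package
(`default_norm_table()`) is **synthetic**: it is the reference
population of the cohort generator (log-scale mean declining 0.02 per
year from −0.5 at age 45, SD 0.5, 5-year bins from 20 to 70,
linearly interpolated between bin midpoints). It makes scores
internally consistent and testable; analysis of real drivers requires a
user-supplied table (`read_norm_table()`), because no public normative
distribution of this score exists.

### Quality control

Device artefacts (mis-detected R waves) corrupt short recordings. A
beat is flagged when its interval falls outside [300, 2000] ms or
differs from the previous accepted interval by more than 20%; a
recording is rejected when flagged beats *exceed* 10% of the total
(exactly 10% is still accepted — the threshold is read as "in excess
of"). The 10% rejection rule is fixed by the study design; the two
flag definitions are package policy (configurable via `qc_policy()`),
since only the rejection threshold, not the flag rule, is prescribed.
Rejected recordings contribute nothing downstream: their spectral
fields are withheld, and any driver-day missing an accepted recording
drops out of every statistic.

### Spectral estimation

Beat intervals are unevenly spaced, so the default estimator
(`spectral_config(method = "welch")`):

* cubic-spline interpolates the tachogram and resamples evenly at 4 Hz
  (comfortably above twice the 0.4-Hz band edge);
* removes a linear trend;
* averages Hann-windowed, 50%-overlap Welch segments of 180 samples
  (45 s), giving a 0.022-Hz frequency step.

The segment length balances variance reduction against keeping a
Hann-windowed peak's leakage (±2 bins ≈ ±0.044 Hz) inside its band
anywhere in the LF band. Band powers are trapezoidal integrals with
linear interpolation at band edges; bands are half-open `[lo, hi)` so
LF + HF exactly equals the integral over the combined band. On pure
sinusoidal test signals of amplitude \(A\) the estimator recovers the
analytic band power \(A^2/2\) within a few percent (the test suite
asserts 10%).

A Lomb–Scargle periodogram, which operates on the uneven beat times
directly, is selectable for sensitivity checks. Its density is rescaled
to integrate to the series variance, which is adequate for band-power
comparisons but not for absolute narrow-band amplitude claims.

Recordings shorter than 60 s are an error rather than a rejection: the
LF band needs at least a few of its ~25-s cycles to be estimable at
all.

## The risk model

A *warning event* is an episode during which the inter-vehicle-distance
alarm sounds, carrying vehicle speed at 1 Hz. Six features summarise
it: duration (s); maximum, minimum and mean speed (km/h); the standard
deviation of speed; and the largest 1-s speed drop, floored at zero.
The sample SD is used for "deviation of speed" — the dispersion measure
is not otherwise pinned down.

The reference rule set classifies an event as a collision risk when
either situation holds:

* **duration > 79.0 s** and **speed deviation in (5.8, 6.5] km/h** and
  **max speed > 39 km/h** — sustained highway warnings with
  intermittent acceleration and deceleration;
* **duration > 42.5 s** and **max speed < 39 km/h** — intermittent
  warnings in low-speed congestion.

Comparator orientation follows the CART convention (left branch takes
`<=`): "greater than" is strict, "less than or equal" inclusive. This
disambiguation matters because only example rules, not a full tree, are
available; the package therefore treats these two rules as the
reference classifier and additionally supports training its own CART
(`train_tree()`: Gini impurity, depth ∈ 1–6 × minimum leaf ∈ {1, 5, 10}
grid, seeded class-stratified 5-fold cross-validation, ties to the
shallower tree). Class imbalance is left unweighted by default, and an
event evaluation reports both the confusion-matrix accuracy and the
*all-warnings baseline* — the precision of treating every alarm as a
risk — which is the relevant comparator for the raw sensor.

Daily aggregation divides the number of risk-classified events \(R\) by
the driving duration \(WT\) in hours:
\(R_{1hr} = R / WT\). Days with under 3 h of driving are excluded
(`included = FALSE`), since a short shift makes the per-hour rate
unstable and such days were outside the study design.

## The association analysis

Analysis records join the three streams per driver-day and add
previous-day lagged copies of the post-shift measures. Lagging is by
*calendar* date: a gap in recording yields a missing value, never a
carried-forward one. Two study-level exclusions are flagged: drivers
whose VAS rating never moved from a single value (uninformative
raters), and drivers whose alarm never sounded (no risk exposure).

The battery (`run_association()`) computes pooled Pearson correlations
of \(R_{1hr}\) with the VAS ratings, LF scores and LF/HF ratios
(same-day and previous-day post-shift), and a median-split comparison:
days above the cohort median \(R_{1hr}\) form the high-risk group (ties
at the median go low), and the previous-day post-shift LF score is
compared between groups with Welch's unequal-variance t-test at the 5%
level. Shapiro–Wilk p-values per group are reported but never gate the
t-test. No multiple-testing correction is applied — the report instead
annotates how many tests were run. Repeated measures per driver are
pooled without adjustment; a per-driver mixed model is an explicit
non-goal.

## The synthetic cohort

The generator (`generate_cohort()`) emulates the study conditions: 33
drivers aged 24–65, consecutive study days, two 90-s recordings per
day, VAS ratings, lognormal driving hours, and warning events. Its
statistical skeleton:

* **Latent fatigue.** Each driver carries a latent process \(z\) over
  half-day occasions (pre₁, post₁, pre₂, …), AR(1) with coefficient
  `rho_crossday` (default 0.29, the cross-day carry-over the analysis
  is calibrated to) and standard-normal marginals. Adjacent occasions —
  in particular post-shift of day *d* and pre-shift of day *d+1* —
  correlate at exactly `rho_crossday`.
* **Recordings.** The instantaneous interval is the driver's mean RRI
  plus LF and HF sinusoids plus white noise (5 ms SD); a pure sinusoid
  of amplitude \(A\) has band power \(A^2/2\), the analytic oracle used
  throughout the tests. LF power is set to
  \(RRI \cdot \exp(\mu_{LF}(age) + \sigma_{LF}(age)\, z)\), so the LF
  deviation score equals \(50 + 10z\) up to spectral-estimation error
  (empirically the measured and latent scores correlate at ~0.99).
  HF power is lognormal around \(RRI \cdot e^{-1}\). Phases are random
  per recording.
* **Ratings and hours.** VAS = 40 + 8z + N(0, 12²), clamped to
  [0, 100] and rounded (a positive but noisy coupling); driving hours
  are lognormal with mean 8 h and log-SD 0.4, occasionally dipping
  below the 3-h exclusion threshold. Both distributions are generator
  conventions — realistic for line-haul work but not prescribed by any
  source.
* **Events.** The expected risk-event rate on day *d* is
  `base_risk_rate * exp(beta_risk * z_post(d−1))` per driving hour
  (day 1 uses one extra pre-study latent step), with
  `base_risk_rate = 3.2`/h matching the median daily index the
  analysis splits on, plus non-risk warnings at 1.5/h. Event counts are
  Poisson. `beta_risk = 0` decouples fatigue from risk — the null
  configuration used for type-I-error checks.

### Event feature regions and CART learnability

Risk events are sampled from feature regions where the reference rules
fire, non-risk events from regions where both fail, each at least a
configurable margin (default 1 unit; capped at 20% of the narrow
deviation window's width) from every rule threshold, so classifier
checks are never decided by boundary ties. Speed profiles are
sample-standardised sinusoids anchored at a drawn minimum speed, which
pins `min_speed` and `speed_deviation` exactly and bounds the other
speed features deterministically.

Beyond the margins, the regions are designed so that *every* boundary
between class-conditional supports sits in a feature gap no region
occupies: minimum speed is drawn from the same range for all
highway-speed regions (and the risk range is nested strictly inside
the non-risk range, so an extreme order statistic is never a risk
event), speeds below ~30 km/h occur only in congested-risk events, and
the deviation and duration supports leave buffers around 5.8/6.5 km/h
and 42.5/79 s. Consequently a greedy, fully-grown CART's learned
thresholds always land in unoccupied gaps, and a tree trained on 285
zero-noise events agrees with the rule classifier on essentially 100%
of fresh margin-sampled events — the property the test suite asserts
at ≥99%. The price of this design is reduced realism: real warning
logs contain boundary-straddling events, low-speed short warnings, and
non-sinusoidal speed traces that the generator deliberately avoids.

### Randomness

All draws flow from a single root seed: the generator draws five named
sub-seeds (drivers, latent process, recordings, day-level tables,
events) once at the start and reseeds each stream independently, so
e.g. switching off event generation cannot perturb the recordings.
Identical spec + seed reproduces every table byte-for-byte.

## What the tests do and do not show

The study-scale checks run on synthetic cohorts at the sizes the
analysis assumes: calibration recovery uses 100 replicate cohorts of
33 drivers × 18 days (533 lagged score pairs each, matching the
correlation-analysis sample size) and recovers the cross-day
correlation of 0.29 within ±0.03; the null check uses 500 small
cohorts (8 drivers × 4 days) and confirms the association test rejects
at 5% ± 2% when `beta_risk = 0`. These sizes were chosen so each
property is measured with adequate replication while the whole suite
stays quick to run.

Passing these tests shows the pipeline is *internally* correct and
well calibrated — the estimator recovers what the generator planted.
It does not validate the scientific claim on real drivers: the
generator's sinusoidal HRV, margin-separated event features, and
pooled-Pearson assumptions are all idealisations, and the shipped
normative table is synthetic. Cohort-level correlations from field
data cannot be reproduced here because no raw driver data are
available; the pipeline reproduces their *structure*, not their
values.

## Numerical choices and degenerate inputs

* Exactly-10%-flagged recordings are accepted; 10% + one beat rejected.
* `lf_score` errors (rather than returning NA) on non-positive LF
  power, and on ages outside the reference coverage.
* `lf_hf` errors on zero HF power — an undefined ratio, distinct from
  zero LF power, which gives 0.
* Zero variance in either series makes a correlation an error, as does
  n < 3; an all-equal split variable makes the median split an error.
* Ties at the median go to the low-risk group.
* CART hyperparameter ties go to the shallower tree, then the larger
  leaf; fold assignment is seeded and recorded in the model metadata.
* Empty event sets are legitimate (a day without alarms has R = 0); an
  empty RRI series is an error.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(outdir = "run1", seed = 1,
                       cohort = cohort_spec(n_drivers = 12, n_days = 8, seed = 1))
run_pipeline(cfg)
# artifacts: rri.csv, events.csv, hrv.csv, daily.csv,
#            analysis_records.csv, results.json, report.txt, config.json
```

```{r inmemory}
spec <- cohort_spec(n_drivers = 8, n_days = 6, seed = 1)
co <- generate_cohort(spec)
hrv <- summarize_hrv(co$recordings, co$drivers, norms = spec$norms)
daily <- daily_risk_table(co$events, co$cohort)
records <- build_records(hrv, daily, co$cohort)
res <- run_association(records)
res$correlations$lf_score_post_prev
res$group_comparison$p
```

## Known limitations

* The normative LF table is a synthetic stand-in; absolute scores on
  real data are meaningless without a genuine reference.
* The printed reference rules are treated as the full classifier; the
  original learned tree is not recoverable.
* Pooled Pearson ignores within-driver correlation; p-values for the
  cohort-level correlations are anti-conservative to an unknown degree
  on real data (the generator's AR(1) structure partially emulates
  this).
* The generator produces beat intervals, not waveforms: R-peak
  detection errors are modelled only through the QC flag rule.
* Speed profiles are sinusoidal by construction; deceleration features
  on real traces are heavier-tailed.
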