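---
title: "Methods: gaze cleaning, fixation detection, and information-theoretic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze cleaning, fixation detection, and information-theoretic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`peergaze` implements a complete analysis chain for free-viewing
eye-tracking studies of social-scene interpretation in adolescents: 300 Hz
binocular gaze and pupil recordings are cleaned, segmented into trials,
quality-controlled, and reduced to a single per-trial measure — total
fixation time on peer-face areas of interest (AOIs) during a 5 s
free-viewing window — which then enters a linear mixed model predicting
interpretation ratings on a 0–100 visual-analogue scale, analysed with an
information-theoretic (AIC) multimodel approach.

Because raw data of this kind are rarely shareable, the package ships a
synthetic-data generator that produces every input the pipeline consumes —
counterbalanced designs, gaze streams with known ground-truth events,
questionnaire responses, and ratings drawn from a known mixed-effects
model — so that each stage can be validated by recovery of known truth
rather than by eyeballing.

# Geometry

All thresholds are specified in degrees of visual angle and converted
through `geometry_config()`: a 1920 × 1080 panel at 94 ppi viewed from
57 cm, with the 1200 × 750 px scene photograph centred horizontally and
offset 2.65° above screen centre. Conversion uses the linearised
small-angle form

$$\text{deg/px} = \frac{2.54/\text{ppi}}{d_\text{cm}} \cdot \frac{180}{\pi} \approx 0.0272,$$

so the scene spans ≈ 32.6° horizontally. We use the linear rather than
arctangent convention because desktop eye-tracking thresholds are
conventionally quoted linearised; at this distance the two differ by well
under 1% across the screen. Published figures for comparable setups
(e.g. a 51.7° screen span) match the linear form. The nominal 94 ppi of a
24-inch 1080p panel is slightly generous (physically ≈ 91.8 ppi); the
geometry is fully configurable, and all internal consistency checks use
the package's own conversion.

# Signal cleaning

The cleaning stage mirrors standard practice for 300 Hz remote trackers:

* **Validity.** A sample is valid only if the tracker found both eyes,
  gaze lies on the screen, and pupil diameter is positive and inside a
  physiological range, taken as 1.5–9 mm (the instrument literature gives
  no tighter bound for adolescents).
* **Gaze smoothing.** Second-order Savitzky–Golay filter, 7 samples
  (23 ms). `signal::sgolayfilt` handles edges by evaluating the terminal
  window's polynomial fit at the edge positions, so polynomials up to
  order 2 are reproduced exactly everywhere — the property the test suite
  asserts at 1e-9.
* **Pupil smoothing.** 3-sample running median per eye
  (`stats::runmed`, edges passed through). The window is specified in
  samples: three samples at 300 Hz span 10 ms, and a short median is
  deliberate — it removes single-sample tracker spikes without smearing
  the steep diameter ramps that identify blinks.
* **Blink rejection.** Samples whose absolute first difference of smoothed
  pupil diameter exceeds 0.1 mm *per sample* in **both** eyes seed a blink
  section spanning the contiguous supra-threshold run; tracker-loss (NA)
  samples count as supra-threshold, so a full blink — collapse ramp, lost
  samples, recovery ramp — forms one section. The per-sample reading of
  the threshold ("instantaneous rate of change") is exposed in
  `cleaning_config()` should a per-second convention be preferred.
* **Repair.** Invalid gaze is replaced by the last valid value (zero-order
  hold; leading invalids take the first valid value) and invalid pupil is
  linearly interpolated between flanking valid samples. QC statistics are
  always computed on the *pre-repair* mask.
* **Pupil baseline.** The mean of the 200 ms immediately before scene
  onset is subtracted from the whole trial's trace, per eye.
* **Drift correction.** Per trial, the offset between the fixation-cross
  position and the median valid gaze of the analysis eye (left) during the
  cross window is computed; it is applied (to both eyes) only when its
  Euclidean magnitude is below 150 px (≈ 4°). The median is used as the
  cross-window summary for robustness against residual saccades.
  A participant-level vertical correction handles constant calibration
  bias: if the median vertical offset across a participant's cross windows
  exceeds 30 px it is removed session-wide before per-trial correction.
  The 30 px trigger is a package convention — such corrections are
  usually applied ad hoc — and is configurable.

# Trial and participant quality control

A trial is excluded when, on the pre-repair mask, (i) any invalid run
after fixation onset exceeds 1000 ms, (ii) any invalid run between
fixation onset and scene offset exceeds 1000 ms, or (iii) more than 40%
of samples between fixation onset and scene offset are invalid. All
bounds are strict ("more than"), so a run of exactly 1000 ms (300
samples) is retained; the comparison carries a 1 µs guard so that
floating-point timestamp arithmetic cannot flip the boundary case. Rules
(i) and (ii) differ only in their window; both windows are configurable
because the verbal forms ("after fixation onset", "prior to scene
offset") admit several readings.

Participants are retained only with at least 30 valid trials in *each*
perspective condition (self, other). "Per condition" is read as the
perspective factor: with 72 trials split 36/36 by perspective but 18 per
perspective × valence cell, a 30-trial bound is only satisfiable on the
perspective margin.

Calibration quality uses the standard 9-point layout (20/50/80% of each
screen span): a calibration passes if at least 12 samples fall within 1°
of every target.

# Fixation detection and AOI dwell time

Fixations are classified by a velocity–dispersion–duration hybrid:
samples with gaze velocity below 75°/s are candidates (central-difference
displacement over two samples, one-sided at run edges); contiguous
candidate runs are scanned left-to-right with a running centroid, closing
the current group whenever the incoming sample would lie more than 2°
from the updated centroid; groups shorter than 75 ms are discarded.
Durations are dwell times (sample count × sample period). The greedy
scan alone cannot guarantee that every member of a closed group lies
within 2° of the *final* centroid (slow drift can violate it), so each
group is re-checked and, in the rare violating case, split at its
farthest sample — emitted fixations therefore always satisfy their own
invariants, which the test suite re-verifies directly.

AOI dwell time is the sum of durations of fixations whose *centroid*
falls inside any face rectangle of the scene, clipped to the 5 s scene
window (fixations straddling a boundary contribute only their in-window
part). Centroid membership is the default because dwell is computed from
detected events; a per-sample alternative would count repaired
(held-value) samples and is deliberately not the default. No post-hoc
merging of fixations across short gaps is performed.

# Questionnaires

The SAS-A total is the sum of the 18 scored items of the 22-item form
(range 18–90), with the published clinical cut-off band 50–54 annotated.
Filler positions vary between printed versions, so they are an argument
(default 5, 10, 16, 22). The PDS category score is the mean of five
items on the 1–4 scale, menarche entering as item five coded 4 (yes) / 1
(no).

# Inference: all-subsets mixed models and Akaike-weight averaging

The global model predicts trial-level ratings from perspective, statement
valence, AOI fixation time, and one individual-difference covariate
(social anxiety, or age in the second model), with all interactions
(15 fixed terms), plus crossed random intercepts for subject and scene.
Coding: factors are effect-coded −0.5/+0.5 (perspective other/self,
valence negative/positive), continuous predictors z-scored across
retained trials; ratings stay on the 0–100 scale. The original report
does not state its coding; this choice makes the intercept the grand
mean (≈ 50) and puts coefficients on the few-units scale of the
published tables, but absolute comparability of coefficient magnitudes
with any particular reanalysis is not claimed.

Candidates are all subsets of the 15 terms that respect marginality (an
interaction only ever appears with all its lower-order terms) — taking
"all possible combinations" literally would include
interaction-without-main-effect models that have no sensible
interpretation under effect coding. For four factors this yields 167
candidates including the intercept-only model. Each candidate is fitted
by **maximum likelihood** (not REML: AIC comparisons across different
fixed-effect structures require ML) via `lme4::lmer`; the parameter
count is the fixed-effect count plus two random-intercept variances and
the residual variance. Fits that end at a variance boundary ("singular")
are legitimate ML optima and stay in the candidate set; only genuine
optimizer failures are dropped, with a warning.

Akaike weights are $w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)$
with $\Delta_i = \mathrm{AIC}_i - \min \mathrm{AIC}$. Coefficients are
**full-averaged**: a term contributes 0 from models that omit it, and
the unconditional standard error is

$$\bar{SE}_\theta = \sum_i w_i \sqrt{SE_i^2 + (\theta_i - \bar\theta)^2},$$

which folds model-selection uncertainty into the interval. Confidence
intervals are $\bar\theta \pm 1.96\,\bar{SE}$ and p-values use the normal
approximation $z = \bar\theta / \bar{SE}$ — the default reporting style
of the information-theoretic literature; conditional averaging (over
containing models only) is available behind a flag, and no
degrees-of-freedom correction is applied since none is standard for
averaged estimates.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Design.** 72 scenes per participant in 6 blocks of 12, scene order
  permuted per participant; scenes are partitioned into four groups of 18
  rotated through the perspective × valence cells across participants, so
  every scene is self-relevant for half the participants (±1 when the
  count is odd) and cells stay balanced at 18 trials.
* **Trial timing.** Fixation cross jittered 1–2 s, scene alone 5 s, scene
  with statement 3 s, self-paced rating (0.8–2.5 s), inter-trial interval
  5–6 s.
* **Gaze.** Fixational scatter is an AR(1) process with marginal SD 0.3°
  and lag-one correlation 0.95 (drift time constant ≈ 65 ms). The
  marginal distribution around each centroid is Gaussian, but the process
  is deliberately autocorrelated: at 300 Hz, *white* noise of this
  amplitude would produce median sample-to-sample velocities near 50°/s
  and spurious 75°/s threshold crossings on ~4% of samples, which no
  velocity-based detector could survive — and which real fixational drift
  does not produce. Saccades are linear interpolations between centroids;
  targets are drawn at least 2.5° apart and durations are capped by a
  main-sequence-like bound (21 ms + 2.2 ms/°), keeping every simulated
  saccade separable from fixation by the published thresholds. This is a
  validation harness, not an oculomotor model: main-sequence velocity
  profiles, microsaccades, smooth pursuit, and post-saccadic oscillations
  are out of scope, so detector performance on these synthetic streams
  bounds — but does not measure — performance on real recordings.
* **Blinks.** With per-trial probability 0.25, a 100–300 ms blink is
  injected during the scene window: both pupils ramp down at
  ≈ 0.8 mm/sample, the tracker loses both eyes (NA) in between, and the
  validity flag is false throughout — exercising both the rate-of-change
  and the validity detection pathways.
* **Calibration drift.** A constant per-trial offset with 10 px SD per
  axis, removed by the drift-correction stage.
* **Questionnaires.** SAS-A items are driven by a participant-level
  latent factor with parameters calibrated so that simulated totals
  centre at M ≈ 46.9, SD ≈ 10.6 — the published community-sample
  descriptives for adolescent females; ages are uniform on 14–19.75.
* **Ratings.** Drawn from `truth_model()`: fixed effects on the coded
  design matrix plus Gaussian subject and scene intercepts and residual,
  truncated (not resampled) to [0, 100] as befits a bounded
  visual-analogue response. The default truth model uses coefficients at
  the magnitude of published interpretation-bias tables (intercept 50,
  valence interactions ±4–5, higher-order terms zero) with
  σ_subject = 6, σ_scene = 4, σ_residual = 18 — random-effect spreads
  are not published for this paradigm, and these give mild clustering
  (ICCs ≈ 0.09 and 0.04) typical of trial-level VAS ratings. Fixation
  time feeds the rating model via its *ground-truth* AOI dwell time, so
  the full generative chain (gaze → dwell → rating) is closed.

# Validation experiments and problem sizes

The test suite validates each stage against independent oracles
(closed forms, brute-force per-sample checks, OLS in the
zero-variance limit, spreadsheet-style arithmetic for the averaging) and
runs three simulation experiments, sized to complete comfortably on one
CPU:

* **Event recovery.** 200 simulated trials at the default noise level:
  at least 95% of ground-truth fixations ≥ 150 ms must be recovered with
  onset and offset within ±10 ms (3 samples), and no emitted fixation may
  violate its own duration or dispersion invariant.
* **Coefficient recovery.** 30 replicate datasets of 50 subjects × 72
  scenes from the default truth model: every true coefficient must fall
  inside its 95% model-averaged CI in at least 90% of replicates.
  Empirically, per-term coverage runs at 93–100%: near-nominal for
  well-supported terms, conservative (≈ 100%) for null higher-order
  terms, whose estimates full averaging shrinks toward zero.
* **Null calibration.** 20 replicate datasets of 30 subjects × 72 scenes
  from an intercept-only truth model: the average rate of significant
  terms must not exceed 8%. The check is one-sided because full model
  averaging is *strongly* conservative under the null — shrinkage pulls
  unsupported estimates toward zero faster than the unconditional SE
  contracts, so the realised false-positive rate is near 0%, far below
  the nominal 5%. This is a documented property of the method, not a
  defect; conditional averaging (the `conditional` flag) trades this
  conservatism for near-nominal error rates.

`scripts/acceptance.R` re-runs the same classes of computation from a
single command-line seed and writes the resulting quantities as JSON.

# Known limitations

* The synthetic gaze is a detector-validation harness, not a generative
  model of oculomotor behaviour (see above).
* Pupil processing stops at baseline correction; no event-related pupil
  analysis is provided.
* Model-averaged p-values use the normal approximation; with few
  subjects they will be anticonservative relative to a
  degrees-of-freedom-corrected reference.
* The per-sample blink-rate threshold (0.1 mm) assumes 300 Hz; other
  sampling rates require rescaling through `cleaning_config()`.
* Right-eye analysis is supported via configuration but the defaults
  follow the left-eye convention of the motivating paradigm.
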