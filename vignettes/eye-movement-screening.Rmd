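---
title: "Screening visual field defects from eye movements: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening visual field defects from eye movements: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emcscreen)
```

This vignette documents the models implemented by `emcscreen`, the tunable
parameters and their defaults, the assumptions behind the synthetic-data
generator, and the numerical choices that were genuinely open when the
package was designed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The tracking paradigm

A Gaussian luminance blob moves on a screen and the participant follows it
with their eyes. Two stimulus regimes probe different oculomotor systems:

* **Smooth mode** — the blob performs a continuous Gaussian random walk,
  eliciting smooth pursuit. A visual field defect delays pursuit and adds
  positional scatter.
* **Displaced mode** — the same walk, but every 2 s the blob jumps to a
  random location. The participant must find it again, so saccadic
  reacquisition latency and search noise enter the signal. Peripheral field
  loss (typical of glaucoma) particularly penalizes this regime.

A session is six trials of 20 s at 60 Hz. These values are the package
defaults in `session_config()` and are used by the test suite and the
acceptance script throughout; they keep every simulation comfortably inside
a single-CPU minute-scale budget while leaving 7200 samples per
axis/mode — enough for stable correlogram and Kalman estimates.

### Stimulus parameters the paradigm does not pin down

* **Random-walk step SD** (`step_sd`, default 0.25 deg/sample): the
  paradigm specifies a Gaussian random walk but not its step size. At 60 Hz
  the default gives a per-second displacement SD of about 2 degrees —
  brisk enough to force continuous pursuit, slow enough that a healthy
  pursuit system can stay locked. The value is configuration, echoed in
  every output file.
* **Boundary rule**: the walk is reflected at the display half-extent
  (`bounds`, default 15 deg). Reflection keeps the target on screen without
  biasing the step distribution away from the edges (a clipped walk would
  pile probability mass on the boundary).
* **Jump destination law**: "jumps to a random location" is implemented as
  uniform over the bounded display area, the least-informative choice
  consistent with that description.

## The observer simulator

No deposited recordings exist for this paradigm, so the observer module is
the package's synthetic stand-in and the fixture generator for every
downstream test. Its model is deliberately phenomenological:

\[
g(t) = \gamma \, s(t - \ell) + \varepsilon(t), \qquad
\varepsilon(t) \sim N(0, \sigma^2),
\]

with pursuit gain $\gamma$, latency $\ell$, and positional noise $\sigma$.
After each displaced-mode jump the simulated observer keeps looking at the
last perceived (pre-jump) target position for `reacquisition_delay`
seconds, with `search_noise_sd` of extra scatter, before snapping onto the
lagged target again. Blinks arrive as a Poisson process and reproduce the
artifact a video eye tracker records when the lids close: the pupil is
misread as shifting sharply upward (two samples at 260 deg/s, safely above
the 190 deg/s detection threshold), after which samples are missing for the
rest of the blink.

What the generator does **not** emulate: saccadic main-sequence dynamics,
oculomotor smoothing (the simulated response is a pure delay, so simulated
correlograms are near-delta spikes rather than the broad bells of real
pursuit), pupil-size artifacts, drift, or calibration error. Passing tests
therefore demonstrate that the pipeline recovers known ground truth under
the stated noise model — not that it handles every pathology of real
recordings.

The three default phenotypes (`default_phenotypes()`) encode the
qualitative group patterns the screening method exploits — controls
(lag 0.18 s, low noise), a glaucoma-like phenotype (near-normal smooth
pursuit, slow noisy reacquisition: delay 0.20 s, search SD 2.5 deg), and a
neuro-ophthalmology-like phenotype (elevated latency 0.25 s and noise SD
1.8 deg in both modes). They are simulation configuration chosen once, not
clinical claims. Per-participant parameters receive 5% relative Gaussian
jitter so same-phenotype participants vary realistically.

## Preprocessing

The blink-repair pipeline runs in a fixed order: pixel-to-degree conversion
(per-axis angle $\arctan(\text{offset}/\text{viewing distance})$, origin at
screen centre), velocity by first differences, blink detection on the
vertical velocity, the 33% rejection rule, and autoregressive gap filling.
Open details and the choices made:

* **Velocity alignment.** First differences are assigned to the later
  sample and the series is front-padded with the first difference, so
  positions and velocities share indexing.
* **Blink detection.** A spike qualifies when the signed upward vertical
  velocity exceeds 190 deg/s *and* is followed by a flat line or missing
  data; the threshold applies to the signed component because the artifact
  is specifically an upward pupil shift. "Flat line" needs a numerical
  reading: at least two consecutive samples whose velocity changes by less
  than 1e-6 deg/s. Flagged runs are dilated by 5 samples on each side and
  merged.
* **Trial rejection** is strict: a trial is discarded only when blinks plus
  missing data exceed *more than* 33% of its duration; exactly 33% passes.
* **Gap filling.** Every sample inside a dilated blink segment is replaced
  by the average of a forward and a reverse AR extrapolation, each fitted
  on the 10 samples flanking the gap. The window length is prescribed; the
  order is not — order 2 is the smallest that reproduces linear trends
  exactly and is stable on 10 samples. The primary fit is least squares
  with an intercept; when its characteristic roots are explosive (which
  happens when a context window straddles a saccadic relocation), the fit
  falls back to Burg's method, which is guaranteed stable, and when even
  that is degenerate the last value is held. Gaps at trial edges are filled
  one-sidedly rather than discarding the trial.

## The 40 spatiotemporal properties

Ten properties per axis and mode, in a canonical property-major order
(`stp_feature_names()`): four spatial (Gaussian fit of the positional
error distribution), four temporal (Gaussian fit of the trial-averaged
velocity cross-correlogram), and two integrated (Kalman observation-noise
variance, cosine similarity). Decisions worth recording:

* **Correlogram normalization.** "Normalized cross-correlation" is read as
  the per-lag Pearson correlation over the overlapping samples: it is the
  only reading that guarantees the advertised $[-1, 1]$ range at every lag.
  Lags run from $-1$ to $+1$ s in steps of one sample (1/60 s).
* **Gaussian fits** use Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  $A = \max y$, $\mu = \arg\max y$, and a half-width-at-half-maximum
  $\sigma$ as starting values, $\mu$ bounded to the abscissa range, and
  tolerances of 1e-10. $\sigma$ is bounded below by half the abscissa
  spacing: a curve narrower than one sample is unidentifiable from sampled
  data, and the bound keeps the fitted amplitude equal to the observed peak
  for the spike-like correlograms the pure-delay observer produces.
  Adjusted $R^2$ uses $p = 3$ parameters. A failed fit is signalled as a
  typed condition and the affected features are recorded as missing with
  the reason, never silently dropped.
* **PED histogram**: bin width 0.5 deg over ±30 deg (both configurable,
  echoed in metadata); errors beyond the range are clipped into the edge
  bins so the masses stay unit-sum. The reported PED mean is the absolute
  value of the fitted $\mu$, matching its advertised $[0, \infty)$ range; the
  signed value remains available in the fit object.
* **Cosine similarity** is computed per axis — the 40-feature layout
  requires every property to exist per axis — and a negative value
  (anti-correlated tracking) is clamped to 0 with a warning to preserve the
  advertised $[0, 1]$ range.
* **Overturned Kalman filter.** With the stimulus a known random walk, the
  local-level model needs only two variances: $Q$ is estimated directly
  from the stimulus increments and the observation noise $R$ is found by a
  1-D search on $\log R$ maximizing the innovations log-likelihood
  (relative tolerance 1e-5). Because the gain recursion of this scalar
  model is data-independent, it is iterated to steady state once and the
  filtered-mean recursion is then a constant-coefficient exponential
  filter, so each likelihood evaluation is linear-time with vectorized
  internals; a plain-loop reference filter serves as the oracle in the test
  suite. Samples inside filled blink segments are included in all feature
  computations (repair precedes analysis), and displaced-mode jump
  instants are included in the correlograms.

## Normative scoring

The modified Z-score is implemented exactly as printed,
$M = (x - \tilde{x}) / (1.486 \cdot \mathrm{MAD})$ with the *raw* MAD
(no consistency constant inside the MAD itself), and the outlier bound is
$|M| > 2$. The "±2 SD" phrasing in the source material mixes SD and MAD
language; since $1.486 \cdot \mathrm{MAD}$ is the robust SD estimate for
Gaussian data, $|M| > 2$ is the coherent reading. Features whose reference
MAD is zero yield an explicit undefined score rather than ±infinity, so a
degenerate cohort is visible instead of silently absorbed.

## Classification

Trees are grown by exhaustive Gini search over midpoints of adjacent
distinct feature values. Determinism is guaranteed by explicit tie-breaks
(lower feature index in canonical order, then lower threshold). Zero-gain
splits are permitted while a node is impure and limits allow — necessary
for XOR-like structure that pays off one level deeper. Cross-validation
folds are stratified by class (small unbalanced cohorts make unstratified
folds degenerate) and seeded; the tuning grid — depth 1–6 crossed with
minimum leaf size 1–5 — is a package choice, not a claim about the original
analysis. Missing features are imputed with training-set medians that
travel with the fitted model. The published screening thresholds (root:
displaced-mode vertical cosine similarity at 0.74; then smooth-mode PED
adjusted $R^2$ at 0.99) are exposed as a fixed partial rule; branches
beyond the two documented splits return `"indeterminate"`. The axis of the
PED split is not documented, so it is an argument defaulting to
`"vertical"`, consistent with the vertical-component root split.

## Known limitations

* The observer is a pure delay plus noise; real pursuit dynamics (smoothing,
  catch-up saccades, main-sequence constraints) are out of scope, so
  simulated correlogram widths are not representative of clinical data.
* The simulated normative cohort stands in for a real normative dataset;
  normative results demonstrate the statistics, not population norms.
* Published-tree reproduction is limited to the two documented thresholds;
  the complete trees cannot be reconstructed without the original cohort.
* All angles are small-angle per-axis visual angles; no account is taken of
  screen curvature or large-eccentricity distortion.
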