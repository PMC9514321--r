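---
title: "Decoding perceptual decisions from microsaccades and pupil size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding perceptual decisions from microsaccades and pupil size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedecoder)
```

## The problem

In a no-report paradigm one wants to know, trial by trial, whether an
observer consciously perceived a weak visual target *without* relying on
their button press. Under adaptation-induced blindness (AIB), prolonged
exposure to drifting adaptor gratings makes a subsequently presented static
Gabor target invisible on a substantial fraction of trials even though the
physical stimulus is identical. Peripheral oculomotor signals — fixational
microsaccades and pupil size — carry traces of the processes that shape and
accompany the perceptual decision. This package implements a complete,
tested pipeline that turns raw binocular 500 Hz eye-tracking recordings of
such a session into per-trial feature vectors and decodes the yes/no
detection report, and the sure/maybe confidence rating, with a sparse
logistic classifier.

Because no raw recordings are publicly deposited for this paradigm, the
package ships a synthetic-session generator with known ground truth. The
generator is a first-class module: every downstream stage is validated
against planted events and planted feature–label couplings.

## Session structure

A session has 4 blocks of 43 trials. Each trial presents drifting adaptor
gratings (60 s on the first trial of a block, 6 s otherwise), a 0.5 s
inter-stimulus interval, and a 1 s target window; a response screen
(not part of any analysis period) separates trials. Per block, trial
categories are fixed by nearest-integer rounding of the design
proportions — 65% positions of interest (split equally between the top-left
and bottom-right diagonal positions), 15% among the six other positions,
20% catch trials — giving 28 + 6 + 9 = 43 trials per block and the session
totals 112 interest, 24 other, and 36 catch trials. Only the trial order is
randomized; the counts are deterministic. This rounding rule is the unique
one consistent with those session totals, which is why it is hard-coded
rather than exposed as an option.

All timing follows one convention stated once and inherited everywhere:
time in ms, 500 Hz sampling (2 ms steps), 0-based sample indices, and
half-open `[start, end)` intervals, so the 6 s adaptation period covers
exactly 3,000 samples, the ISI 250, and the target 500. Gaze is in degrees
relative to the central fixation bullseye, with x rightward and y upward
(the screen-coordinate handedness is not dictated by the task; we fix y-up
and document it here).

## Preprocessing the pupil

Blink handling comes first. *Full* blinks are maximal runs in which the
pupil is missing in both eyes; *partial* blinks are samples where the
combined pupil signal changes by more than 20 arbitrary units per sample
(the tracker reports pupil area in arbitrary units; 20 a.u. is roughly
0.5 mm²). Both kinds are padded by 200 ms on each side, and overlapping
events merge. The partial-blink derivative is evaluated on the combined
signal *before* interpolation, since interpolation would erase exactly the
fast transients the rule is meant to catch.

The binocular pupil is the mean of the two eyes where both are available
and the single available eye otherwise; spans with neither eye (and all
blink spans) are linearly interpolated between the nearest valid flanking
samples, with leading/trailing gaps taking the nearest valid value (the
procedure needs a finite trace everywhere; nearest-value fill is the least
committal choice for edges). Every filled sample is recorded in a mask, and
a session whose interpolated fraction exceeds 45% is flagged excluded
rather than silently dropped — the caller decides what to do with it.

The combined trace is low-pass filtered at 10 Hz with a zero-phase
(forward–backward) 4th-order Butterworth design — the standard
pupillometry filter; zero phase matters because a lag would misalign the
trace against period boundaries. The implementation reflect-pads the trace
before filtering so that edge transients (including on a constant trace)
are suppressed. Finally the trace is z-transformed using the mean and SD
over the union of all adaptation/ISI/target samples of the session
(response screens excluded). We pool all four blocks into one
normalization; normalizing per block would also be defensible, but
pooling keeps the feature scale comparable across blocks within a
participant.

## Detecting microsaccades

Detection is unsupervised, built to need no per-participant velocity
threshold:

1. **Velocity.** Per eye, horizontal and vertical velocities come from the
   5-point smoothed central difference standard for 500 Hz fixational
   data; speed is the per-eye magnitude averaged across eyes, and
   acceleration is the same operator applied to the speed trace. (The
   original apparatus reports instantaneous velocity directly; for CSV and
   synthetic input we estimate it, and the 5-point operator is the
   standard noise-robust choice at this rate.)
2. **Candidates.** The recording is tiled into consecutive 1 s windows
   from t = 0 and the six highest velocity peaks per window are kept —
   deliberately over-inclusive so every true microsaccade is present.
   Samples inside blink pads or invalid spans are excluded. Windows tile
   the continuous recording, not individual trials; sliding windows would
   over-count.
3. **Features and clustering.** Peak velocity and the initial/final
   acceleration (signed extremum in the 12 ms before/after the peak — the
   window length is our choice; nothing in the procedure pins it down) are
   z-transformed across the candidate set; PCA keeps components with
   eigenvalues above 5% of the largest; K-means with K = 2 (10 restarts,
   fixed seed) splits the retained scores, and the cluster with the larger
   mean raw peak velocity is the microsaccade cluster. An exact tie breaks
   toward the smaller cluster, saccades being rarer than noise peaks.
4. **Delimitation and filters.** Each saccade-labeled peak extends
   backward and forward until speed falls below `max(3 deg/s, 20% of the
   peak)`; the 3 deg/s floor matches the lower bound of the mean-velocity
   filter. Amplitude is the binocular-mean gaze displacement between onset
   and offset. Events must satisfy duration ≥ 8 ms, amplitude within
   10–120 arcmin, and mean velocity within 3–120 deg/s; overlapping
   survivors merge keeping the higher peak.

Quality control is the main sequence: the Pearson correlation between peak
velocity and amplitude must exceed 0.6 for a session to pass. The
microsaccade rate of a period is the number of detected events whose peak
falls in it, divided by the period duration.

## Features and decoding

Each trial yields six features: mean microsaccade rate and mean z-scored
pupil size over each of the adaptation, ISI, and target periods. A control
flag marks trials in which the interpolated binocular-mean gaze strays more
than 0.8 deg from fixation during any of the three periods, and each
trial's total blink time is recorded for the blink-duration control.

Decoding is per participant: an L1-regularized logistic regression on the
112 positions-of-interest trials, evaluated by 10 × 10-fold stratified
cross-validation (folds preserve class proportions; each repeat reshuffles
with a derived seed). Standardization is fit on the training folds only —
"the data were standardized" is ambiguous about the scope, and the
within-fold choice is the one that cannot leak test information; the
functions expose fold construction so a global variant can be assembled if
wanted. Accuracy (probability 0.5 threshold) and AUC are computed on each
of the 100 held-out folds; AUC is evaluated on the linear decoder scores,
which are monotone in the probabilities but free of numerical saturation.

The sparsity parameter C (inverse penalty strength; the L1 penalty weight
is `1/(C·n)` in the per-sample objective) is grid-searched over 31 values
evenly log-spaced on [1, 10³], selected to maximize mean AUC with ties
going to the smaller, sparser C. The selection uses the same folds that
are reported — this mirrors the published procedure and carries a known
optimistic bias at small n; the calibration results below quantify it
(about +0.015 AUC at 112 trials under the null), and a nested scheme can
be built from `stratified_folds()` + `grid_search_C()` if unbiased
point estimates are needed. Decoder variants: both positions pooled (the
main analysis), per-position, best-position (maximum AUC of the two), and
a balanced control that undersamples the majority class (20 resampling
repeats, averaged — the repeat count is our choice; the procedure itself
does not state one). Confidence (sure vs maybe) uses the same machinery on
all, yes-only, or no-only trials; a participant whose minority confidence
class has fewer than 2 trials is excluded, and when a class is smaller
than the fold count the fold count drops to it rather than failing. A
leave-one-participant-out group decoder trains on the pooled trials of all
but one participant (standardization and sparsity chosen on the training
pool only).

Statistics: group-level significance uses a permutation test that
reassigns yes-labels within each participant (class counts preserved
exactly), reruns the full decoding — including the grid search, unless the
faster reuse switch is chosen — and compares the observed
participant-mean metric against the null with the add-one estimator
`p = (1 + #{null ≥ obs})/(1 + n_perm)`, which never returns 0. Bayesian
paired t-tests use the JZS Bayes factor (Cauchy prior, scale 0.707,
one-dimensional numerical integration; evidence bands 1–3 anecdotal, 3–10
moderate, >10 strong). The tests cross-check it against an independent
quadrature of the mathematically distinct Cauchy-mixture-of-noncentral-t
formulation to within 1%.

## The synthetic observer

The generator emulates what the analysis needs to be sensitive to, with
one latent visibility state per trial (Bernoulli 0.5 on non-catch trials,
0 on catch trials) and an independent latent confidence state:

- **Fixational drift** is a mean-reverting (Ornstein–Uhlenbeck) 2-D walk,
  stationary SD 0.1 deg, time constant 1 s. A pure random walk would
  diffuse several degrees over a half-hour session and trip the 0.8-deg
  gaze control on nearly every trial, so mean reversion stands in for the
  visual feedback that keeps real fixation bounded.
- **Microsaccades** are an inhomogeneous point process whose per-period
  rate is a 1.2/s base plus the observer's coupling times the latent
  state; events are minimum-jerk displacements (closed-form peak velocity
  `1.875·A/T`, convenient for oracle checks) with amplitudes lognormal
  around 30 arcmin (log-SD 0.2, clipped to 18–80 arcmin) and peak
  velocities on a 60 (deg/s)/deg main sequence with 10% multiplicative
  noise by default. Directions turn corrective once gaze strays ~0.3 deg,
  and each displacement decays back over ~0.8 s. The amplitude spread and
  velocity noise defaults are deliberately on the compact side of the
  physiological range: the K-means assignment boundary sits near the
  midpoint between the noise and saccade velocity centroids, so a planted
  velocity distribution whose lower tail crosses that midpoint would be
  *unrecoverable by design* for any detector of this family; the defaults
  keep ≥95% of planted events recoverable, which is what the detection
  oracle requires. With the wider 20% velocity noise used in the
  main-sequence check, recall drops to ~0.9 while the main-sequence r
  stays well above 0.6.
- **Pupil** is a ~2000 a.u. baseline with slow AR(1) noise (SD 30 a.u.,
  coefficient 0.995 at 500 Hz), a gamma-shaped dilation transient at each
  target onset, and per-period offsets of coupling × latent state, ramped
  over ~100 ms because step offsets would trip the 20 a.u./sample
  partial-blink rule.
- **Blinks**: full blinks (~150 ms, both pupils lost, rate 2/min) and
  partial transients; planted saccades keep clear of blink pads, since
  events inside masked spans are undetectable by construction.
- **Responses**: yes with probability 0.85 given visibility, 0.12 given
  none; sure with probability 0.6 via the confidence latent.

What the generator does *not* emulate: pupil foreshortening, per-position
asymmetries in hit rate, tracker-specific noise spectra, slow fatigue
drifts in the couplings, or any dependence between decision noise and the
eye features beyond the planted coupling. Passing tests therefore show
that the pipeline recovers what it is designed to recover under a
plausible signal model — not that real recordings would yield the same
effect sizes. No quantitative effect sizes are published for this
paradigm's eye features, so the coupling magnitudes used in tests
(0.8 events/s and 30 a.u. per unit visibility) are package choices,
picked to put single-participant AUC in the 0.7–0.9 range at full session
size. One consequence of the compact amplitude distribution is that about
half of simulated trials trip the 0.8-deg gaze-deviation flag, roughly
double the published fraction; the flag is surfaced per trial and not used
to drop data by default.

## Staircase calibration

The contrast threshold comes from a fixed-step 1-up-1-down staircase on
log10 contrast (0.05 log-unit steps): a seen response lowers the level,
unseen raises it, which converges on the 50% point of the psychometric
function. It stops after 15 reversals or 65 trials, whichever is first,
and the threshold is the mean of the reversal levels excluding the first
two; with fewer than three reversals the mean of all visited levels is
returned with a warning flag. Over 500 simulated runs of a logistic
observer the mean estimate lands within 0.05 log units of the true 50%
point.

## Numerical choices and degenerate inputs

- Missing pupil samples are flags plus `NA`, never sentinel numbers.
- CSV writers print 17 significant digits so recording round trips are
  bit-faithful.
- The eigenvalue cutoff (5% of the maximum), K-means restarts (10), and
  the K-means seed are configuration entries; identical inputs and seeds
  give identical event lists and decoding results.
- Degenerate inputs fail loudly with named errors: nonuniform sampling
  (the first offending timestamp is reported), zero valid pupil samples,
  zero pupil variance, zero-variance features, a class smaller than the
  fold count, fewer than 2 pairs or zero-variance differences in the
  Bayes factor.
- Candidate sets that cannot be clustered (fewer than 2 candidates, or
  all-identical features) yield a QC failure flag and no events, not an
  error.

## Problem sizes used by the test suite

The acceptance-style tests run at sizes a laptop core handles in minutes,
chosen as the package's own trade-off between Monte-Carlo resolution and
wall time: detector oracles on 2-block × 12-trial sessions; decoding
calibration on 30 null sessions of 2 × 20 trials with 5 × 2-fold CV and
19-permutation tests (150 replicates); coupling recovery on 50 full-size
4 × 43 sessions with the full 10 × 10 CV and grid; the staircase over 500
runs; the Bayes-factor oracle over a 12-point (t, n) grid. The
reproduction script (`scripts/acceptance.R`) uses full-size sessions
throughout.
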