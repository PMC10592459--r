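---
title: "Methods: swim bout segmentation, balance kinematics, and resolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swim bout segmentation, balance kinematics, and resolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutkin)
```

## Scope

`boutkin` implements the analysis chain used in high-throughput videographic
assays of posture and vertical locomotion in small animals, with larval
zebrafish as the reference organism. A backlit camera records an animal
swimming freely in a vertical arena at 166 Hz; real-time processing reduces
each frame to a time stamp, body and head centroids, a pitch angle (the
inclination of the long body axis above the horizontal, nose-up positive),
an epoch number, and an apparent body length. The package covers:

1. reading and writing that per-frame stream (`.dlm`) and its metadata;
2. the single-animal detection/orientation algorithm itself, for users who
   start from raw grayscale frames, plus a renderer that draws synthetic
   animals with known pose to validate the detector;
3. segmentation of the stream into epochs, peak-aligned swim bouts, and
   buffered inter-bout intervals (IBIs);
4. per-bout kinematic features and the four balance models (bout timing,
   steering, fin--body coordination, righting);
5. a resampling framework that maps confidence-interval width and Cohen's
   *d* effect size against sample size;
6. a synthetic-data generator with fully known ground truth, so that every
   stage can be tested quantitatively without any recordings.

## Segmentation model

Zebrafish larvae swim in discrete episodes of translation ("swim bouts").
Instantaneous speed is the frame-to-frame displacement of the body
centroid divided by the frame interval, with the first sample back-filled
so the series stays frame-aligned. The segmentation thresholds are all
held in `analysis_config()`:

* an **epoch** (a contiguous run of valid single-animal detection) passes
  quality control when it lasts longer than 2.5 s and contains a maximum
  speed above 5 mm/s;
* a **bout** is a maximal interval of speed above 5 mm/s, aligned at its
  speed argmax (earliest frame on ties). The analysis window spans 500 ms
  before to 300 ms after the peak; windows are converted to frames by
  `round(ms * frame_rate / 1000)`, giving 83 + 1 + 50 = 134 frames at
  166 Hz. Candidates whose window does not fit inside the epoch are
  dropped; overlapping windows are all kept, since each is a complete
  observation of its own peak;
* an **IBI** is the sub-threshold duration between two consecutive
  retained bouts, with a 100 ms buffer deducted from each end to absorb
  detection error at the bout edges. Intervals that do not survive the
  deduction (or retain no frames for averaging) are discarded. Bout
  frequency is the reciprocal of the buffered duration, and IBI pitch is
  the mean pitch over the buffered interval only, so bout-edge transients
  never contaminate it.

Quantification is restricted to the zeitgeber day -- the 14 h light phase
of the 14/10 light/dark cycle -- by reconstructing wall-clock time as the
metadata start time plus the time stamp. Epochs straddling a light
boundary are truncated with their ids preserved, and the filter is
idempotent.

## Kinematic features

All per-bout features derive from pitch and position read at fixed offsets
in the aligned window:

* `pitch_initial` at -250 ms (the start of the analysed, non-reserved
  portion of the window -- used uniformly wherever "initial posture" is
  needed);
* `pitch_peak` at the peak; `pitch_post` at +100 ms;
* **trajectory**: the tangential angle of the instantaneous displacement
  at the peak, computed from the central two-frame displacement with the
  horizontal component signed by the bout's net horizontal direction.
  This makes climbing positive and the value invariant to whether the
  animal swims leftward or rightward;
* **attack angle** = trajectory - pitch at peak: the extra lift,
  attributed to the pectoral fins, that carries the animal above where
  its body points;
* **steering rotation** = pitch at peak - initial pitch, decomposed
  exactly into a **body rotation** (up to the time of peak angular
  velocity) plus a **residual rotation** (the remainder);
* **righting rotation** = pitch at +100 ms - pitch at peak: the
  corrective rotation as the animal decelerates.

Angular velocity is computed from pitch smoothed by a centred 11-frame
moving average whose window shrinks symmetrically at the edges (no data
are fabricated beyond the series); the first difference is divided by the
frame interval and back-filled at the first frame. For the time of peak
angular velocity, the sign of every bout that begins with nose-down
rotation (negative mean angular velocity over -250 to -100 ms) is
flipped so all bouts start positive; the per-time-point median across all
bouts of an experimental repeat is taken, and its argmax located within
the pre-peak steering phase (-250 to 0 ms). Per-repeat times are averaged
across repeats before features are computed, so every bout in a dataset
uses the same read point.

## The four balance models

* **Bout timing.** Bout frequency is regressed on IBI pitch with the
  parabola `y = a (x - b)^2 + c` by least squares, fitted on the raw IBI
  points (3-degree binned means are attached for display only). The fit
  is performed in the polynomial parameterisation -- an identical optimum
  with a closed form -- and converted back; `a` is the *sensitivity* (how
  strongly postural eccentricity accelerates movement initiation), `b`
  the baseline posture and `c` the baseline rate. Standard errors for the
  derived coefficients follow by the delta method.
* **Steering.** Pitch at peak speed regressed on trajectory; the slope is
  the *steering gain*. A gain of 1 means the trajectory is fully
  explained by the posture at peak speed.
* **Fin--body coordination.** Bouts at or above 7 mm/s peak speed enter;
  bouts whose steering rotation exceeds the sample's 50th percentile
  while carrying a negative attack angle are excluded (a rectification
  that removes the artifactual arm of the relation; the percentile is
  computed on the post-speed-filter sample, and both filter counts are
  reported). Attack angle is then fitted against body rotation with the
  logistic `y = a + h / (1 + exp(-k (x + b)))` by bounded nonlinear least
  squares (`h, k > 0`, enforcing the increasing sigmoid) from a small
  deterministic multi-start grid, keeping the lowest-deviance fit. The
  *fin--body ratio* is the sigmoid's maximal slope, `k h / 4`, attained
  at `x = -b`.
* **Righting.** Righting rotation regressed on initial posture. The
  behaviour is corrective, so the slope is negative; the *righting gain*
  is its absolute value, and the *set point* -- the posture at which no
  righting results -- is the x-intercept, `-intercept / slope` (flagged
  as degenerate when the slope is zero).

The variance of the fin--body ratio combines the coefficient variances as
`V = E_k^2 V_h + E_h^2 V_k + V_k V_h (1/4)^2`. A strict delta-method
expansion of `var(kh/4)` would carry the `(1/4)^2` factor on all three
terms; both conventions are implemented
(`variance_convention = "as_printed"` is the default, `"delta_method"`
the alternative) so results remain comparable with the established
convention while the textbook form stays available.

Two further conventions were genuinely open and are fixed here: "initial
posture" for the righting regression is the -250 ms pitch (an
`ibi_pitch` alternative is config-selectable), and the attack angle uses
the single-time-point trajectory at the peak rather than a window mean.

## Resolution: CI width and effect size versus sample size

`resolution_dataset()` reduces an analysed dataset to the (x, y) point
set each model is fitted on; resampling draws individual bouts or IBIs
with replacement (a grouped alternative was considered and rejected as
the literal sampling unit is the data point). For each sample size *N*,
20 bootstrap refits yield the mean and SD of the normal-theory CI width
`2 z_{0.975} SE` at the 0.95 level (`z` from the standard normal, not a
*t* quantile). For power, `impose_offset()` builds a comparison dataset
by scaling the coefficient of interest by `1 + fraction` -- curvature for
sensitivity, slope for steering and righting, sigmoid height `h` for the
fin--body ratio (any single factor of the product `k h / 4` scales the
maximal slope; `h` is used throughout) -- and replacing each `y` with the
modified model's prediction at the original `x` plus the point's original
residual, so x-values and residual structure are preserved exactly and a
full-data refit returns the parameter scaled by exactly `1 + fraction`.
`effect_size()` draws 200 bootstrap parameter values per dataset and
reports Cohen's *d*: the difference of the two means over the standard
deviation of all 400 values pooled. `effect_size_surface()` repeats the
whole computation 20 times per (offset, N) cell. For the fin--body ratio
the features entering these simulations are computed with a fixed time of
peak angular velocity (40 ms before peak speed,
`config$fixed_tmaxangvel_ms`), trading a per-repeat estimate for speed
and stability, as `analyze_dataset(for_resolution = TRUE)` does.

Every stochastic operation derives an independent sub-stream from the
master seed and the cell's own labels (parameter, offset, N, repeat), so
results are bit-reproducible and independent of execution order. Fits
that fail inside a resample are redrawn at most five times before the
repeat aborts with a logged reason.

## Detection and the frame renderer

The detector follows the real-time chain: absolute background
subtraction, noise thresholding, connected components (8-connectivity;
labelling is delegated to `EBImage::bwlabel` with a union--find merge of
diagonally adjacent labels), rejection of frames with zero or multiple
in-bounds components, a size/intensity split of the single blob into body
and head parts, and orientation extraction. The background model is a
per-pixel temporal median over a frame sample, robust to the transient
animal. Part splitting projects blob pixels onto the principal axis
(second central moments) and applies a one-dimensional intensity-weighted
two-means split; the brighter part is the head, falling back to the
smaller part when the parts are nearly iso-intense, and failing
explicitly (`parts_unresolved`) for round blobs with no defined axis.
Pitch is the angle of the principal axis, signed by the head direction
and folded to be heading invariant; `animal_length` is the blob's
major-axis length (4 sqrt of the leading moment eigenvalue). Rejection is
a result with a reason, never an error, and detection is a pure function
of frame and thresholds.

The renderer draws a trunk ellipse plus a brighter head disc centred on
the body axis with soft (antialiased) edges and optional Gaussian pixel
noise. Its defaults (head 3x the trunk's intensity gain) mimic IR
backlit larvae, where the head/swim-bladder region dominates the image;
they also keep the intensity-weighted head-part centroid within 2 px of
the drawn head centre. Ground truth (pose, centres, noiseless centroid)
travels with each frame, which is how the detector's 1-degree pitch
accuracy and sub-pixel centroid accuracy are established in the test
suite.

## The synthetic-data generator

`generator_params()` defines the study conditions; `generate_epoch()` and
`generate_dataset()` realise them frame by frame. Defaults emulate the
reference assay: 166 Hz; lognormal peak speeds with mean 12.9 and SD
4.9 mm/s, drawn truncated above the 5 mm/s detection threshold (measured
speed moments describe detected bouts -- a bump that never crosses
threshold is not a bout); a Gaussian speed bump with 60 ms SD; a
stationary pitch distribution targeting mean 8.5 degrees, SD 15 degrees;
timing parabola `a = 0.003` Hz/deg^2, `b = 10` degrees, `c = 1` Hz with
additive frequency noise (SD 0.3 Hz); steering gain 0.7; fin--body
sigmoid `k = 0.15` /deg, `h = 64/3` deg (ratio 0.8) over body rotations
of mean 1.8, SD 5 degrees; righting gain 0.18 toward a 12-degree set
point.

Within an epoch, the generator alternates scheduled sub-threshold gaps
and bouts. The gap preceding a bout is the 200 ms buffer allowance plus
the reciprocal of the timing parabola evaluated at the currently held
pitch (perturbed by the additive frequency noise), so the measured,
buffered IBI reproduces the hazard exactly in expectation. Each bout
realises: a pre-peak steering rotation whose angular-velocity bump is
centred 7.5 frames before peak speed -- placing the peak of the
frame-aligned first-difference angular velocity exactly on the 7th frame
before the peak, which is also where the fixed 40 ms convention reads --
with ground-truth body rotation defined as the rotation completed at that
read frame; an attack angle coupled to the body rotation through the
sigmoid; a displacement along the resulting trajectory (clamped inside
+/-88 degrees: translation at peak speed is forward); and a post-peak
righting rotation toward the set point, completed by +100 ms. The
inter-bout drift (a destabilising bias plus Gaussian noise, applied at
+150 ms, inside the IBI buffer) is *solved*, not chosen, so the
stationary pitch distribution has exactly the requested mean and SD;
infeasible combinations error at construction.

One coefficient deserves emphasis: with the pitch SD (15 degrees) and the
fin--body sigmoid fixed, the steering gain cannot be dialled
independently -- the joint variance structure of posture, trajectory and
attack angle determines the regression slope. The generator therefore
introduces a posture--lift coupling (attack angle gains a term
proportional to initial pitch) and *solves* its coefficient so the
population steering slope equals the requested gain: first in closed form
from normal-theory moments, then refined by root-finding against the
empirical moments of the simulated bout process (which include the pitch
clamp and the trajectory clamp). Of the two algebraic roots the one with
the smaller attack-angle variance is taken; it keeps the fin--body
relation identifiable and, together with the high sigmoid floor
(10 degrees), makes negative attack angles so rare that the rectified
exclusion filter removes essentially nothing from clean synthetic data.

### What the generator does and does not emulate

It reproduces: the marginal distributions the models estimate (speeds,
postures, the four parameter relations), posture persistence across
bouts, heading changes with wall reflections, frame quantisation, and
small observation noise on pitch (0.2 degrees/frame) and position
(0.2 um/frame; sub-pixel, representing centroid jitter after real-time
averaging). It does not reproduce: the full covariance geometry of real
data (the steering relation here is cleaner, R^2 about 0.99 versus about
0.92 in real recordings, and the timing relation far cleaner, R^2 about
0.9 versus about 0.14, because real variance sources such as
angular-velocity-dependent timing are not modelled); negative attack
angles and the artifact population the rectification filter exists for;
multi-animal occupancy; or hydrodynamics of any kind. Passing recovery
tests on this generator therefore demonstrates that the *pipeline
arithmetic and estimators* are correct under known conditions -- not that
real data will be as well behaved.

### A note on confidence-interval coverage

The timing, righting and fin--body fits satisfy their least-squares error
assumptions on generated data (independent residuals given x), and their
normal-theory CIs cover the ground truth at the nominal rate. The
steering regression is different in kind: initial posture persists across
bouts (AR coefficient = 1 - righting gain, about 0.82) and enters *both*
axes (pitch at peak = posture + rotation; trajectory = pitch at peak +
attack angle), so ordinary least-squares standard errors -- which assume
independent residuals -- understate the seed-to-seed scatter of the gain
by roughly a factor of two at any sample size. This is a property of the
estimator on persistent data, not a defect of the generator, and it will
be present in real recordings too. The test suite therefore asserts
nominal CI coverage for the three well-specified fits and holds the
steering point estimate to a tight recovery band instead; users who need
calibrated steering intervals should prefer the bootstrap machinery in
the resolution module over the analytic SE.

## Problem sizes used by the tests and the acceptance script

The shared test corpus is 4 simulated repeats of about 2,500 bouts each
(about 10,000 bouts, 2.4 million frames), generated and analysed in under
half a minute; recovery tolerances are 5 percent for steering gain,
righting gain, set point and sensitivity, and 10 percent for the
fin--body ratio, whose 4-parameter sigmoid is intrinsically the hardest
to estimate -- its CI width is correspondingly the largest, and its
recovery shows a residual upward bias of a few percent at this scale.
Coverage and convergence properties run on 8 single-repeat datasets of
1,500 bouts; the brute-force bout oracle runs exhaustively on hundreds of
randomised short epochs; the detector sweep covers pitches from -80 to
+80 degrees. The acceptance script regenerates everything from scratch at
the same sizes from a caller-supplied seed.

## Numerical choices and degenerate inputs

Peak ties break to the earliest frame. The smoother never extends past
the series (shrinking symmetric window). Trajectory is undefined (NA,
with a warning) for a bout with zero displacement at the peak; the
righting set point is NA-and-flagged when the slope is zero; the timing
fit refuses degenerate designs (fewer than three distinct pitches).
Malformed `.dlm` lines are skipped and counted rather than aborting a
long acquisition. Sigmoid fits that fail after the multi-start grid are
reported as non-converged objects, never silently; inside resampling
loops a failed fit is redrawn at most five times. The `.dlm` dialect is
fixed as tab-delimited, header-less, eight columns in schema order, six
decimal places -- the field set is documented in `?read_dlm`, and
rewriting a canonical file is byte-identical.

## Known limitations

* The epoch-level "various quality-control filters" of the original
  acquisition chain are under-specified upstream; they are implemented as
  three config-exposed optional filters (displacement cap, pitch-jump
  cap, length stability), all off by default and counted when applied.
  Analyses of real data may therefore differ slightly in epoch retention.
* The detector is single-animal by design; crowded frames are rejected,
  not resolved.
* Cohen's *d* as defined here saturates near 2 when the imposed offset
  dominates the bootstrap scatter, because the pooled SD includes the
  between-group separation; curves flatten accordingly at large N.
* The generator's realism limits are described above; in particular, do
  not read its steering or timing R^2 values as predictions for real
  recordings.
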