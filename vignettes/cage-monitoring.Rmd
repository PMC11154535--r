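---
title: "Camera-only cage monitoring: models, parameters, and design choices"
author: "cagemon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-only cage monitoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
**cagemon**: what each stage computes, which assumptions it leans on, what
the tunable parameters mean and why their defaults are what they are, what
the synthetic-scene generator does and does not emulate, and where the
design was genuinely open.

## 1. Measurement model

The input is top-view color video of a single animal in a cage at a known
frame rate (60 Hz in the targeted setup), plus a one-time calibration: the
user supplies rectangles for a body-color patch, an eye-color patch, and
the stretched body length, and optionally a crop window (region A) that
excludes cage furniture. Calibration derives exact per-channel HSV
envelopes (optionally padded) rather than robust percentile bounds: the
rectangle is assumed to be chosen over a near-uniform patch, and an exact
envelope keeps the mapping from user action to threshold transparent. Hue
wraparound is deliberately unsupported — a min/max pair cannot represent a
range straddling hue 0, so calibration rejects rectangles whose hue spread
exceeds half the circle instead of silently producing a near-full-circle
range. Subjects with red-wrapping coat colors would need a shifted hue
origin upstream.

HSV values are unit-scaled internally; profiles on disk declare their scale
(`unit`, `opencv`, `degrees`) explicitly, because published threshold
listings rarely say which convention they use. Printed listings also
sometimes swap a channel's min and max; profile loading sorts each pair, so
the range invariant cannot be violated by a transcription artifact.

## 2. Segmentation

Per frame, a backend proposes candidate masks and the largest by pixel
count becomes the animal region B. The default backend thresholds in HSV
space with the body range, labels 8-connected components, and fills
interior holes: the eyes (and any other differently-colored marking inside
the silhouette) would otherwise punch holes in region B, and the region is
by assumption a simply-connected animal. An adapter backend accepts any
external instance-segmentation detector exposing per-instance masks and
class labels; masks whose label belongs to a configurable animal-like set
count as candidates. The adapter stays inert unless a detector function is
configured, so the package and its test suite remain self-contained.

The contour is the outer boundary of the largest component by border
following, with revisited pixels deduplicated (a one-pixel-wide
protuberance is walked twice by any border follower; without deduplication
the contour could outnumber the mask pixels and bias the centroid). The
position proxy G(t) is the **contour-point mean**, not the mask mean; this
follows the upstream formulation that computes the center of gravity from
the contour point set. The two differ on shapes with strongly asymmetric
boundary curvature; a `centroid_from = "mask"` switch allows the mask-pixel
mean for comparison. The eye position F(t) is the pixel centroid of the
largest eye-colored component inside region B's bounding box inflated by
2 px (so a 1 px mask erosion cannot exclude the eye). When both eyes appear
as separate components the larger wins — a tie-break the upstream method
leaves unstated.

No-detection frames produce an explicit gap record; the pipeline never
interpolates a mask. The mask area is always reported, and area-based
gating against the calibrated minimum `alpha_th` happens downstream, so a
partially-occluded detection still contributes the features that remain
reliable.

## 3. Behavioral features

Movement `m(t)` is the Euclidean displacement of G between consecutive
frames; body extent `r(t)` is the G-to-F distance (large = stretched,
small = curled up), differenced into `r'(t)`.

The heading combines two estimators with complementary failure modes:

* `theta_m`, the axis of the contour's first principal component. The
  contour is centered (not variance-scaled — scaling each coordinate to
  unit variance would erase the axis) and the leading eigenvector of the
  2×2 covariance gives an axis defined modulo pi. When the eigenvalue
  ratio `lambda1 / lambda2` falls below a gate (default **1.2**) the
  contour is effectively isotropic — a curled-up animal has no body axis —
  and `theta_m` is reported missing rather than noise.
* `theta_c`, the angle of the vector from G toward F. The single-argument
  arctangent form of the source formulation is quadrant-blind and was
  reported there to invert under shadow noise; the default here is the
  two-argument form oriented center-toward-head, with the printed
  quadrant-blind variant available behind `strict = TRUE` for replication.

`theta_m` is an axis and `theta_c` a direction; before averaging, the axis
is flipped by pi when that reduces its angular distance to `theta_c`, and
the average is circular (both angles mapped within pi of each other first —
plain arithmetic averaging near the ±pi cut is wrong and was rejected).
With `theta_m` missing, `theta = theta_c`. Angles live in image
coordinates: x-positive is 0 rad and y points **down**, so positive angles
turn clockwise on screen. `theta'(t)` is the wrapped difference in
(−pi, pi]; a constant-rate rotation yields its angular velocity at every
step with no 2 pi jumps.

Any feature needing frame t−1 is missing at sequence starts and after any
no-detection frame. Missingness propagates to sample assembly; nothing is
imputed. This is why a recording of N frames generally yields fewer than N
samples, and the pipeline reports the exact accounting
`frames = complete + incomplete + no-detection` for every run.

## 4. Heart-rate proxy (video photoplethysmography)

Blood flow modulates skin color slightly; the green channel carries most of
the usable signal. The trace H(t) is the mean green value over a square
region C of side `gamma_px` centered on G(t). `gamma_px` defaults to
`min(ax, ay) / 2` — half the smaller calibrated body length — which keeps
region C inside the body for typical postures; it is configurable because
the right size depends on how much of the frame the animal fills. Frames
with no valid centroid or with mask area below `alpha_th` contribute gaps
("heartbeat information is not extracted" there).

Filtering is a 2nd-order Butterworth bandpass, default **4.76–7.14 Hz**
(285–428 beats/min, a small rodent's range; both cutoffs are configuration,
not code). It is applied zero-phase (forward–backward) by default because
peak *times* feed the interval estimates and a causal filter would delay
them by the group delay; a causal single-pass variant exists for live use.
Gaps are bridged by linear interpolation before filtering and re-masked to
NA afterwards, so edge transients cannot fabricate beats inside a gap, and
no peak is emitted whose comparison window touches a gap or the series
boundary.

Peak detection is a windowed local-maximum search ("mountain climbing" is
not a uniquely defined algorithm; this definition is declared and
unit-tested as the implementation). The window is **half a period of the
upper cutoff per side**, `floor(fs / (2 fh))` samples: a guard of a full
period would exceed the true peak spacing for rhythms just below `fh` and
suppress alternate beats, whereas half a period admits the fastest rhythm
the passband can contain while rejecting sub-period jitter peaks. Ties
resolve to the earliest index, so the first sample of a plateau is the
peak. Peak times are sample-grid times (`index / fs`); consequently
inter-beat intervals are quantized to whole frames, which bounds the
attainable rate accuracy near the band edge (at 60 fps a 7.0 Hz pulse has
period 8.57 samples; the nearest representable median interval is 9
samples, a ~5% bias). Sub-sample peak interpolation would remove this bias
but would break the simple sample-grid contract; it was deliberately left
out.

The rate is `h = t_H / T` with `t_H = 0.7` s — beats per 0.7-second
window — implementing the source's printed definition literally; the raw
frequency `1 / T` is always recoverable as `h / t_H`. The rate series is a
**causal zero-order hold**: the rate from peak pair `(t[i-1], t[i])` takes
effect at `t[i]` and holds until the next peak (and past the last peak);
frames before the second detected peak have no rate. A non-causal
assignment (each interval's rate painted over the interval itself) was
considered and rejected: it contradicts "no rate before the second peak"
and is unusable in live monitoring.

## 5. Anomaly model

Complete frames form samples `Z = (m, r, r', theta', h)`. Columns are
standardized by training-set mean/sd — the features mix pixels, radians,
and window-scaled rates, and a Euclidean Gaussian kernel over raw units
would be dominated by whichever feature happens to have the largest
numeric range. (The source formulation is silent on scaling; a
no-standardization path exists by passing pre-scaled features.) Constant
columns are dropped with a warning rather than producing divisions by zero.

The detector is the nu-parameterized one-class SVM with Gaussian kernel
`exp(-gamma ||z - z'||^2)`: nu upper-bounds the fraction of training
samples treated as outliers and lower-bounds the fraction of support
vectors. Two numerical choices matter at the tiny nu this application uses
(nu = 1e-4):

* the solver's termination tolerance is tightened to 1e-7 (the default
  1e-3 is comparable to the decision offset rho at small nu);
* a sample is labeled anomalous only when its decision value is below
  `-1e-3 * rho`, not merely negative. Boundary support vectors sit at a
  decision value of numerical zero, and the soft-margin formulation counts
  only strictly-outside samples as outliers; classifying by the sign of
  rounding noise would flag a sizable share of the training set. Genuine
  outliers score near `-rho`, three orders of magnitude beyond the slack.

`(nu, gamma)` are selected by k-fold cross-validation (default 5) over a
grid (default nu in {1e-4, 1e-3, 1e-2} — the source states endpoints but
no step, so the default is logarithmic — and gamma from 0.01 to 1 in steps
of 0.01). Training data are routine-only, so the objective is the mean
held-out routine-classification rate; ties break toward smaller nu, then
smaller gamma, rejecting as little of the routine data as possible. The
fold shuffle is seeded, making selection bit-reproducible.

Alerts are debounced: only `c` consecutive anomalous samples (default
**3**) raise an alert, suppressing single-frame flickers; the raw decision
series is always exported. Supervised baselines for comparison tables — a
two-class Gaussian SVM, LDA, and an MLP with two hidden layers of 20 units
(tanh, softmax, full-batch Adam, seeded; training hyperparameters are
arguments with declared defaults) — are fitted on labeled data when such
data exist.

## 6. What the synthetic scenes emulate — and what they do not

The generator renders a single anti-aliased ellipse (semi-axes `a, b`) on a
static background: piecewise-smooth heading with deterministic turn rate
plus Gaussian turn noise and wall avoidance, periodic body stretch, two
dark eye spots merged into one patch at 0.65 a along the axis, a green
sinusoid of configurable frequency and amplitude on body pixels only
(approximating blood-flow color change localized to the animal), per-pixel
Gaussian sensor noise, and an optional stimulus time after which speed,
turn rate, and pulse frequency are multiplied. Everything is deterministic
given the seed — per-frame noise is seeded per frame index — so frames are
byte-identical across runs, and the per-frame ground truth (centroid,
orientation, stretch, eye position, pulse phase, instantaneous frequency,
anomaly label) is exact.

Default conditions mirror the targeted setup: 60 Hz, 30 s scenes, 640×480
analysis region; pulse 5.5 Hz (330 beats/min, mid-passband) with 4
green-level amplitude; noise sd 2 gray levels; startle multipliers 2×
speed, 3× turn rate, 0.8× pulse. Tests and the acceptance script use
proportionally smaller frames (160×120 to 200×150 with a 16–20 px
semi-major axis) and 3–30 s durations; these sizes were chosen once as the
smallest at which the boundary-pixel effects discussed below are
representative.

Passing on these scenes shows the pipeline's operations are correct and
numerically stable under known geometry, motion, pulse, and noise. It does
**not** show robustness to what real cage video contains: fur texture and
non-uniform body color, shadows (the dominant noise source for the
direction features in the source experiments), lighting drift, occlusion by
cage furniture, grooming postures that break the elliptical shape
assumption, or a pulse signal whose amplitude competes with compression
artifacts. The segmentation-overlap invariant (IoU ≥ 0.9 against the true
ellipse) is itself scale-dependent — the color threshold loses a ~1 px
anti-aliased boundary band, so overlap degrades as perimeter/area grows —
and holds for semi-major axes above roughly 25 px at the default noise
level (sd 2 gray levels); the property is tested at 30×12 px semi-axes.

## 7. Degenerate inputs and tie-breaks (summary)

* Empty mask / no candidate: a no-detection record, never an interpolated
  mask; downstream features missing.
* Isotropic contour: `theta_m` missing (gate 1.2); heading falls back to
  `theta_c`; if G = F, `theta_c` is missing too.
* Constant feature column: dropped with a warning before the kernel.
* Zero complete samples: explicit error at assembly.
* Peak plateaus: earliest index wins; peaks never within half an
  `fh`-period of a gap or boundary.
* Fewer than two peaks: all-missing rate series; fewer than 12 finite
  trace samples: filtering skipped, all-missing cardiac outputs.
* Grid-search ties: smaller nu, then smaller gamma.
* Scene geometry that cannot stay inside the frame: an error naming the
  first offending frame.

## 8. Known limitations

Single animal only (no identity maintenance); top-view rigid-camera
geometry; color-threshold default backend assumes the animal's coat is
separable in HSV from the background; the heart-rate proxy needs the
passband to bracket the true rate (a bradycardic episode below `fl` would
be attenuated, and rates at the band edge carry the frame-quantization
bias described above); alerts are binary with no severity score; and the
supervised baselines exist for comparison, not deployment — the package's
operating mode is one-class.
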