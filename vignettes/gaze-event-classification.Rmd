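---
title: "Classifying natural-viewing gaze events from eye movements and scene video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying natural-viewing gaze events from eye movements and scene video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazevents)
```

## The problem

A head-mounted (mobile) eye tracker records two signals: the orientation of
the eye relative to the head, at a relatively high rate, and a scene-camera
video of what lies in front of the wearer, typically at 30 Hz. When the
wearer is free to move, the classical screen-based event taxonomy (fixation,
saccade, smooth pursuit) no longer suffices, because a stable gaze in the
world can be produced either by a stationary eye in a stationary head or by
an eye counter-rotating against a moving head. `gazevents` classifies every
gaze sample into one of four natural-viewing events:

* **Gaze fixation (GFi, label 1)** — stationary observer, gaze stably on a
  stationary object.
* **Gaze pursuit (GP, label 2)** — stationary observer following a moving
  object (smooth pursuit).
* **Gaze shift (GS, label 3)** — rapid gaze jump from one location to
  another, the natural-viewing generalization of a saccade.
* **Gaze following (GFo, label 4)** — gaze held on a stationary object
  while the head rotates or the body translates.

Labels 0 (unlabeled) and 5 (blink) are accepted on input and removed during
preprocessing, together with user-declared calibration windows; the first
sample retained after each removed block is flagged (`cut_before`) so that
no difference-based feature and no event ever straddles a gap.

## The feature model

Each gaze sample is described by a six-dimensional feature vector; the
classifier sees samples independently, so all temporal context must be
carried by the features themselves.

1. **Eye-movement velocity** (deg/s) and **2. direction** (deg): computed
   from each pair of consecutive samples within a contiguous segment — a
   window of two, with no multi-scale windowing. Velocity is the
   great-circle angle between the two head-centered gaze directions over
   the sample interval, computed in the numerically robust
   `atan2(|g_i x g_j|, g_i . g_j)` form. Direction is
   `atan2(delta elevation, delta azimuth)` mapped to [0, 360), with 0 =
   rightward and 90 = upward; an exactly zero-motion pair is assigned
   direction 0 rather than NaN to keep the matrix dense. Pair features are
   assigned the midpoint time of their two samples (a symmetric choice;
   only "between the two samples" is structurally required).

3. **Head-rotation velocity** (deg/s), **4. head-rotation direction**
   (deg) and **5. body-translation velocity** (px/s): derived from
   classical monocular visual odometry on consecutive scene-video frames
   (next section).

6. **Gaze-patch similarity**: a 64 x 64 pixel grayscale window is cut
   around the gaze point in each frame (the gaze sample nearest in time to
   the frame timestamp), and consecutive windows are scored with
   zero-normalized cross-correlation (ZNCC, range [-1, 1]). ZNCC is
   invariant to constant offsets and positive gain, scores 1 for identical
   structure and near 0 for unrelated content, so it drops sharply when a
   gaze shift lands on a different object. Patches whose area falls less
   than half inside the frame are invalid and bridged by interpolation.
   The scoring backend is pluggable — any function of two patches with a
   documented range can replace ZNCC.

### Visual odometry without learned components

The camera-motion unit estimates the relative pose between consecutive
frames from image correspondences alone: Harris corners (selected per cell
of an 8 x 6 grid so weakly textured regions still contribute), ZNCC patch
descriptors with mutual-nearest matching and a subpixel quadratic
refinement of each match, then robust model fitting.

Two motion models compete per frame pair:

* a **rotation-only model**, fitted by the Kabsch algorithm on bearing
  rays inside RANSAC, and
* a **full essential-matrix model** (normalized 8-point algorithm inside
  RANSAC, Sampson gating, cheirality-checked decomposition).

The rotation model is not a shortcut but a necessity: under pure rotation
the epipolar constraint is satisfied by `E = [t]x R` for *any* translation
direction, so the essential matrix is degenerate exactly in the regime
(stationary wearer) that dominates natural-viewing recordings. The
selection rule prefers rotation when it explains nearly all matches
(>= 92%), and otherwise keeps rotation only if its inlier support reaches
97% of the essential support. The margin is asymmetric on purpose: when
the scene contains genuine parallax, the rotation model loses the
near-layer correspondences and the essential model wins; when the motion
is pure rotation, the shortcut fires long before the comparison.

Monocular odometry cannot observe metric scale, so body translation is
reported as a **derotated parallax proxy**: the median inlier image
displacement remaining after the rotational flow is removed, in pixels per
second. It is zero for a stationary or head-turning wearer and grows
monotonically with walking speed, which is all the classifier needs; its
units are deliberately documented as image-relative, not metric. Head
rotation velocity is the quaternion rotation angle over the frame
interval; head-rotation direction is `atan2(pitch, yaw)` from the Z-Y-X
Euler decomposition (roll, which a direction feature cannot represent, is
ignored). Externally estimated poses can be injected from a CSV file,
bypassing the internal odometry while keeping the same downstream
contract.

### Multirate fusion

Frame-rate channels (camera motion, patch similarity) live at ~30 Hz,
pair-based eye channels at the gaze rate; all are brought to the gaze
timestamps by cubic interpolation. The spline uses
Forsythe–Malcolm–Moler end conditions (`stats::splinefun(method = "fmm")`),
which reproduce cubic polynomials exactly; with only 2–3 knots the channel
falls back to linear interpolation, and queries outside the knot span are
clamped to the boundary value rather than extrapolated (splines blow up
outside their support). Invalid entries — odometry failures, off-frame
patches — are excluded before fitting, which is how gaps are bridged.
Angular channels are unwrapped before interpolation and re-wrapped to
[0, 360); interpolating wrapped angles naively is wrong at the seam (the
midpoint of 350 and 10 degrees is 0, not 180). Eye channels are fitted
per contiguous segment so removed blocks never influence neighbors.

## Balancing and splitting without breaking events

Event-level evaluation needs event structure intact, so balancing cannot
simply delete random rows. The **within-event random sample extractor**
removes (or subsets out) a per-class quota drawn from event *interiors* —
never the first or last sample of a segment — at one class-specific ratio
applied across all recordings (largest-remainder rounding makes pooled
totals hit the quota exactly). Every segment keeps at least one sample, so
the event count is invariant; a `cut_before` flag on a removed sample
migrates to the next kept sample so same-class events never merge. When a
quota cannot be met from interiors alone, boundary samples are drawn as a
logged relaxation, still keeping one sample per segment; an infeasible
quota (more than `count - #segments`) is an error, not a silent
approximation.

Two validation regimes use this machinery:

* **Leave-one-out**: each recording is held out in turn; the remaining
  recordings are pooled and every class is down-sampled to the smallest
  class count (removal mode); the held-out recording is predicted
  unbalanced. TP/FP/FN and confusion counts are pooled across folds
  before scores are computed — per-fold F1 averaging would be undefined in
  folds where a class is absent.
* **Train–test split**: first the pooled classes are equalized by deleting
  samples from the *beginning* of each recording (cut flags mark each
  deletion boundary), then 20% of each class is extracted within events
  as the test set, preserving original sample order; the remaining 80%
  trains a single model.

## Decision making and evaluation

The classifier is a random forest over the six features. "Default
settings" are pinned in the package (100 trees, `mtry = 2`, node size 1)
rather than inherited from whatever the library currently defaults to, so
a model artifact is reproducible across versions; the seed, parameters,
feature order and class set are stored with the fitted ensemble. Class
scores are tree-vote fractions. Because the forest subsamples rows in
order, determinism is guaranteed under a fixed seed and fixed row order
(seed-equivalence, not row-permutation invariance — this is documented
behavior of the ensemble, not an accident of this package).

Scoring is one-vs-all per class: precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, and F1 in both of its equivalent printed forms
`2PR/(P+R) = TP/(TP+(FP+FN)/2)` (their identity is verified to 1e-12 in
the tests). **Sample-level** scores compare every sample;
**event-level** scores match each ground-truth event to the most frequent
predicted class within its span (majority voting; ties go to the tied
class occurring earliest in the span, a deterministic rule). Weighted
averages use the relative frequency of each class in the test set —
samples for the sample level, events for the event level. Event-level
scoring is generally more lenient than sample-level scoring, but this is a
tendency, not a theorem, and the package asserts it only on a worked
example. Zero-denominator precision/recall is defined as 0.

## The synthetic study conditions

Real natural-viewing corpora cannot ship with a package, so `gazevents`
includes a seeded simulator whose recordings exercise every pipeline
stage against known ground truth. The world is deliberately minimal but
geometrically honest:

* a textured background plane 4 m ahead (multi-scale noise with
  block-wise distinct mean and contrast, so patches from different regions
  decorrelate while corners are detectable everywhere);
* a layer of 16 high-contrast textured squares at 1.8–2.6 m, placed on a
  jittered lateral grid so several are visible in every view — they supply
  the parallax that makes body translation observable at all;
* during pursuit, a 0.66 m textured object at 2 m that the gaze tracks.

Frames (320 x 240, pinhole f = 280 px, 30 fps) are rendered by
homography-consistent bilinear sampling of the textured planes under the
scripted camera pose, lazily, so a one-minute video never resides in
memory. The gaze signal (120 Hz) follows the scripted targets with
isotropic Gaussian angular jitter (SD 0.1 deg per axis — a realistic
mobile-tracker noise floor).

Event kinematics: fixations lock gaze on a background point with a static
camera; pursuit objects move at 5–20 deg/s; gaze shifts are minimum-jerk
trajectories of 30–80 ms whose peak velocity falls in the 200–500 deg/s
band (amplitude is derived from the sampled duration and peak, matching
the saccadic main sequence in spirit); gaze following yaws the camera at
10–30 deg/s or translates it laterally at 0.6–1.0 m/s while the eye
counter-rotates to hold a world point. Gaze-following segments are kept
short (0.8–1.6 s) so these head-turn rates remain compatible with a
+-28 deg eye-in-head eccentricity budget; pursuit and shift targets are
steered to stay inside the camera field of view. Transitions are
continuous in gaze position: each shift bridges the previous event's final
gaze direction to the next event's target.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: photometric nuisances (lighting change, blur,
rolling shutter), depth-rich cluttered scenes, vergence and parallax of
the eye itself, tracker-specific noise spectra, vestibulo-ocular gain
errors, or annotation noise from human labelers. The end-to-end F1 on
synthetic data is a *pipeline-correctness* bar, not a forecast of
performance on field recordings.

With these conditions, per-sample fixation and pursuit are genuinely
confusable (at 120 Hz, a 0.1-deg jitter implies a noise-floor pairwise
velocity comparable to slow pursuit), which is the realistic hard case;
majority voting across an event is what rescues event-level scores, just
as intended.

## Numerical and design choices worth knowing

* Quaternions are canonicalized to non-negative scalar part; rotations
  between frames map frame k-1 coordinates into frame k.
* The RANSAC loops are adaptive (99% confidence) with a fixed per-call
  seed path; the keypoint budget is 500 per 320 x 240 frame with a
  1.0 px consensus threshold, 50 px match gate and 15-inlier validity
  floor.
* Interpolation never extrapolates; rows in segments too short to carry
  any pair feature (single-sample segments) are dropped with a message.
* All randomness — scripting, jitter, extraction, forest training — flows
  from explicit integer seeds; rerunning any stage with the same seeds
  reproduces its outputs bit-identically (PNG frames included).
* Problem sizes used by the package's own validation: six 60 s recordings
  for the leave-one-out bar, 30-frame clips for odometry recovery,
  200 seeded label sequences for the sampling invariants — sizes chosen to
  give stable statistics on a single CPU.

## Known limitations

* The translation proxy is image-relative; recordings with different
  optics or frame sizes are not comparable without retraining, and a
  forward (along-axis) walk produces radial parallax whose median is
  smaller than for a lateral walk of equal speed.
* The essential-matrix path needs visible parallax structure; in a scene
  that is effectively one fronto-parallel plane, translation and rotation
  are not separable from two views, and slow walking will read as near-zero
  translation.
* Pure-rotation pairs leave the translation *direction* undefined
  (`t_unit` is NA); downstream code treats only its magnitude proxy.
* Event-level scores inherit the majority-vote matching scheme's known
  leniency; comparing against methods scored with a different matcher
  requires re-scoring, not copying numbers.
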