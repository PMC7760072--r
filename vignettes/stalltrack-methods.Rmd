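---
title: "Methods: pose-track QC, validation and behaviour analytics for stabled horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-track QC, validation and behaviour analytics for stabled horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stalltrack)
```

`stalltrack` post-processes keypoint trajectories of horses filmed in box
stalls with time-lapse cameras (nominally 2 images per second at 2.7K,
2704 x 1520 px). Three anatomical markers are tracked: the nose (mouth and
nostril area), the withers (highest point where the neck merges into the
back) and the tail base. This vignette explains the statistical machinery,
the tunable parameters, and what the synthetic scenarios do and do not
establish about real recordings.

## Coordinate and indexing conventions

Pixel coordinates have their origin at the top-left corner, x rightward and
y downward, as sub-pixel floats; frames are indexed from 1. All thresholds
below are in pixels of 2.7K footage per time-lapse frame and should be
rescaled for other resolutions or frame rates; nothing is inferred from the
data — the frame rate is always explicit configuration.

## Mislabel screening

A detector that loses the horse latches onto a static lookalike, producing
a teleport: a displacement far larger than a horse can move in half a
second. The screening statistic for two predicted frames is

$$ S = \big((x_2 - x_1)(f_2 - f_1)\big)^2 + \big((y_2 - y_1)(f_2 - f_1)\big)^2 , $$

and a pair of consecutive predicted frames is flagged when the Euclidean
displacement strictly exceeds 200 px. Two reading choices deserve note.
First, "difference between the x and y pixels" is implemented as the
Euclidean distance, consistent with the sum-of-squares form of $S$, not as
per-axis differences. Second, $S$ as written multiplies displacement by the
frame gap, which inflates the statistic across prediction gaps; the 200-px
rule is defined for consecutive frames, where $S$ reduces to squared
Euclidean distance. `detect_jumps()` therefore thresholds displacement,
scaling the threshold to $g \times 200$ px across a gap of $g$ frames so
that plausible continuous motion over a dropout is not flagged; the literal
$S$ value is always reported alongside for transparency, and
`gap_rule = "adjacent_only"` restricts screening to gap-1 pairs for the
conservative reading.

Missing-prediction screening flags maximal runs of strictly more than 30
consecutive frames where a marker expected visible has no prediction. With
ground truth, frames annotated `not_visible` are excluded from the
expectation (a hidden marker correctly unpredicted is not a failure);
without ground truth every frame counts, a deliberately conservative
screening mode. Both rules use strict inequalities ("more than").

The wrongly-predicted count WP per marker is the number of distinct
predicted frames participating in at least one jump segment; a frame shared
by the in-jump and out-jump of one teleport counts once.
`remove_flagged_jumps()` strikes frames participating in two jump segments
— the signature of a teleport landing — before analytics; a clean frame
sandwiched between two immediate teleports shares that signature and is
struck conservatively.

## Validation metrics

Per-frame confusion classification needs a distance criterion that manual
visual scoring did not: a prediction is a true positive when it lies within
`match_radius_px` of the annotated position. The default is 100 px, about
3.7% of the frame width — generous for coarse body-region annotations, far
tighter than distractor mislabels, which sit hundreds of pixels away.
Markers annotated 25/50/75% occluded carry positions and are treated as
expected-predicted: their non-prediction is a miss, and only `not_visible`
counts as hidden for the true-negative case. Sensitivity, error rate and
accuracy follow the standard formulas; a metric whose denominator is zero
is undefined (`NA`), excluded and counted by `aggregate_mean_sd()` rather
than silently zeroed. Windows default to the first and last 1000 images of
a video.

Version comparisons use a paired t-test by default — the same videos are
scored under both model versions, so pairing by video is the appropriate
design; an unpaired option is exposed. Marker comparisons of
sensitivity/error rate/accuracy use one-way ANOVA over per-video values.
Significance is accepted at p < 0.05 with no multiple-testing correction,
matching the workflow this package systematises. Zero-variance differences
are reported as degenerate rather than given a spurious p-value, except the
all-identical case, which is reported as t = 0, p = 1.

## Behaviour analytics

Occupancy uses half-open square bins $[ks, (k+1)s)$ with far-edge positions
assigned to the last bin, and boundary-inclusive point-in-polygon
containment for named stall regions — both conventions fixed for
determinism across platforms. Overlapping regions each accrue a frame and
the overlap is reported; an implicit `elsewhere` key makes disjoint
partitions exhaustive, so percents sum to exactly 100.

The weight-shifting signature is elevated short-window variance of the nose
marker's vertical coordinate during rest. `detect_weight_shifting()`
computes a centred rolling sample variance (default window 60 frames =
30 s) over *settled* rest frames: non-rest frames are masked, and the first
`settle_frames` of each rest bout are trimmed because the walk to the
resting spot belongs to the bout's label but not to resting posture. Each
bout's mean rolling variance is compared against a baseline; the default is
the high-frequency noise floor $\widehat{\sigma}^2 = \mathrm{mad}(\Delta
y)^2 / 2$ over adjacent settled rest frames, which tracks localisation
jitter (it scales with the detector's noise) but is blind to slow swaying.
Quiet rest therefore yields ratios near 1 (empirically up to about 2 from
sampling variability), while genuine weight-shifting oscillations sit one
to two orders of magnitude higher; the default ratio threshold of 3
separates the regimes with a wide margin. A baseline relative to the
horse's median rest variance is exposed (`baseline = "rest_median"`) for
contrasting one restless bout against otherwise quiet rest, but it cannot
flag a uniformly restless recording, which is why it is not the default.

### Rule-based ethogram classification

The four-class classifier is a fixed cascade on smoothed kinematics,
evaluated per frame and then cleaned by minimum-duration filtering:

1. **moving** when the withers' smoothed displacement exceeds
   `move_threshold` (12 px/frame);
2. else **feeding** when the nose is below the horizontal `feeding_line`
   (y > 1000 px of 1520; feeding happens at trough or floor level);
3. else **rest** when the rolling mean nose displacement stays under
   `rest_threshold` (5 px/frame) for at least `rest_min_frames` (30 frames
   = 15 s);
4. else **standing observation**.

Positions are smoothed over `smooth_window = 5` frames before
differencing, which suppresses localisation jitter without hiding walking;
displacement across prediction gaps is the gap-averaged rate. Segments
shorter than `min_segment_frames = 10` are merged into their predecessor,
which removes the one-to-few-frame "moving" blips that teleport mislabels
cause. The thresholds are synthetic-calibrated defaults: the workflow they
systematise proposes automated behaviour classification without fixing
numbers, so the defaults were chosen once to maximise agreement on the
default synthetic scenario and are plain configuration. The key physical
margins are: walking displaces the withers ~25 px/frame versus ~2-3
px/frame of carriage jitter (threshold 12 sits between), and a resting
head moves ~2-3 px/frame versus ~10 px/frame of observational scanning
(threshold 5 sits between).

## The synthetic stall scenario

The simulator exists so every stage is testable without video. It emulates
the statistical structure the analyses rely on, not horses:

* **Labels** come from a first-order Markov chain over the four states. The
  default is symmetric with self-transition 0.998 per frame (mean dwell
  ~4 min of real time), giving a uniform stationary law; any row-stochastic
  matrix can be configured.
* **Positions.** A body-carriage point leads: in each non-moving state it
  is attracted to the centroid of the state's preferred region (standing
  observation at the stall front by the door, rest at the sidewall, feeding
  at the trough area) and transits at 60 px/frame; in the moving state it
  walks between random waypoints at ~25 px/frame. The nose adds a head
  offset — persistent AR(1)-velocity sweeps bounded at a 150-px neck radius
  while observing, small AR(1) jitter otherwise — and the withers and tail
  trail the carriage along the smoothed heading at 300 and 650 px, so the
  body stays rigid-ish without a full skeleton (markers are analysed
  independently downstream). Rest adds a sinusoidal vertical nose
  oscillation (default amplitude 25 px, period 60 frames) as the
  weight-shifting signature. Positions are clamped to the image rectangle.
* **Visibility.** The tail is scheduled `not_visible` while the horse faces
  the door (nose inside the front region) — the dominant occlusion pattern
  in stall footage; a small rate of partial-occlusion classes is sprinkled
  on all markers. Nose and withers go missing only through random dropout.
* **Artifacts.** Degradation adds Gaussian jitter (default sd 2 px),
  dropout runs (marginal rate 0.05, geometric run length with mean 5
  frames), and teleport mislabels (default 1 per 1000 frames per marker,
  displacement at least 250 px, landing on a named distractor — waterer,
  manure pile, shoes — or uniformly). Every injected event is logged with
  frame, marker, type and magnitude so recovery can be scored exactly.
  Teleports are injected at isolated frames (minimum spacing 3): they model
  single-frame relabellings onto static objects.

One pseudo-random stream per scenario seed is consumed in a fixed order
(labels, then positions and visibility); degradation takes its own seed so
one truth can be degraded many ways. Identical configuration and seed give
bit-identical tracks, labels and logs.

The camera's oblique view (~60 degrees) is not modelled: simulation happens
directly in the image plane because every downstream analysis consumes
pixel coordinates only. No kinematic default is a measured horse value —
speeds, dwell times and oscillation amplitudes are stated configuration
chosen to be plausible at this resolution. Consequently, passing tests
establish that the *algorithms* are correct (exact jump recovery, oracle
equality of the confusion counts, conservation laws, monotone degradation
with noise) and that the pipeline separates the regimes it was built to
separate; they do not certify classifier accuracy or detector performance
numbers on real hospital footage.

## Numerical and design choices

* The training-frame subsampling rule selects 1-based multiples of the
  stride strictly below the limit: with stride 10 and limit 2500 that is
  frames 10, 20, ..., 2490 — 249 frames per video, the conventional count
  for this thinning. The naive closed range would give 250; the strict
  upper bound is the simplest convention reproducing the established count
  and is fixed as the package's definition.
* Whether jump screening should apply across prediction gaps is genuinely
  open; both behaviours are exposed and the gap-scaled rule is the default
  (it preserves the 200-px rule where that rule is defined and degrades
  gracefully over gaps).
* Rolling statistics use exact cumulative-sum identities with a minimum
  support of half the window; under-supported frames are `NA`, never 0.
* Region and bin boundary conventions (inclusive polygons, half-open bins)
  are fixed so identical inputs give identical budgets on any platform.
* Report CSVs carry a `#` header with the run seed and an FNV-1a hash of
  the configuration; reruns with identical configuration are byte-identical.

## Problem sizes in the shipped tests

The test-suite sizes are the package's own choices balancing statistical
power against a quick developer loop: jump recovery uses twenty 10,000-frame
scenarios with 5-20 teleports each; confusion-oracle equality uses 1000
random 200-frame windows; behaviour recovery uses the default 28,800-frame
(4 h) scenario with a three-point noise sweep (sd 2, 15, 30 px); the
weight-shift contrast uses twenty seed pairs of 6000-frame scenarios.
Stationary-law checks run at 20,000 frames with an effective-sample-size
corrected error band, since a sticky chain mixes slowly.

## Known limitations

* The behaviour classifier assumes the camera geometry of the default
  stall: `feeding_line` is a horizontal image line, so a feeder mounted
  high in the image needs a different rule.
* Orientation ("looking at the sidewall") is only approximated by the
  nose-withers vector; with three markers, position and orientation
  conflate, and the package reports region occupancy rather than gaze.
* The paired t-tests and ANOVA are the classical procedures on per-video
  summaries; they inherit normality assumptions that short video sets
  cannot verify.
* The simulator's artifact model is stationary; real detectors fail in
  bursts tied to scene events (people entering, night lighting), which the
  dropout-run model only approximates.
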