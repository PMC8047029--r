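---
title: "Tracking and feedback methods in zebtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and feedback methods in zebtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebtrack)
```

zebtrack turns 8-bit grayscale frames of larval zebrafish into tail, eye and
heading kinematics, detects swim bouts online, links identities across
frames for groups, and computes the closed- and open-loop stimulus state
that those kinematics drive. This vignette explains each model, the
parameters that matter, the numerical choices we made where the design was
open, and what the synthetic-fixture tests do and do not demonstrate.

## Conventions

A frame is a numeric matrix (`nrow = height`) holding 0–255 intensities;
pixel (x, y) — 0-based, origin top-left, y down — lives at
`frame[y + 1, x + 1]`. All *reported* angles are radians,
counterclockwise-positive with 0 along +x. Because image y points down, a
reported angle `a` corresponds to the raw image-space angle `-a`; the flip
is absorbed exactly once, in the heading term
θ_h = −atan2(y₁ − y₀, x₁ − x₀), so downstream angles never need a sign
correction. Frame indices are 0-based in every API and CSV.

## Background model

The background is the per-pixel running extremum: in `"lightest"` mode a
pixel updates only when the incoming value exceeds the stored one by more
than `noiseThreshold` (strictly; ties never update), `"darkest"` mirrors the
rule. We initialize from the first frame, which the model itself leaves
open; any other choice converges to the same image once the animal has
vacated each pixel once. The noise threshold is applied symmetrically in
both modes — the darkest-mode margin is the mirror image of the lightest
one. The practical consequence of the extremum rule is that only a small
amount of movement is needed before subtraction isolates the animal, but a
fish that never leaves a region leaves a shadow there; offline we therefore
run a full background pass before the tracking pass, and the pipeline tests
append fish-free frames so the model can converge exactly.

## Centroid and tail fitting

`calculateCentroid()` offers raw image moments (center of mass of the whole
thresholded mask) and the largest connected region within
`[minArea, maxArea]`; the latter is the robust default. Exact area ties —
possible on synthetic imagery — go to the region nearest the previous
centroid, else to the topmost-leftmost region; this tie rule is ours, the
underlying method leaves it open.

`calculateTailPoints()` walks from the centroid to the tail tip using
precomputed rasterized circles: integer points whose rounded radius equals
the target, sorted by polar angle (at radius 1 this is the 8-neighborhood
ring). The first point comes from the `distTailBase` circle — a full-circle
extremum search when the heading is unset (any negative `headingDirection`,
kept as a sentinel deliberately), otherwise the circle point opposite the
provided heading. Each later point is searched on an arc of angular length
`rangeTailPointAngles` of the `distTailPoints` circle, centered on the
continuation of the previous segment; for the second point, where only one
previous segment exists, we continue the centroid→base direction. Three
scoring rules are available: the extremum pixel (`pixel_search`), the
contrast-weighted median along the arc (`weighted_median`, weights are the
absolute difference from the arc's opposite extremum — the signed variant is
indistinguishable on our fixtures but the absolute form is the safer
reading), and the arc point nearest the contrast center of mass
(`center_of_mass`). All three return members of the precomputed point set;
no sub-pixel interpolation is performed, by design. Ties go to the first
point in arc order. Arcs that leave the frame are clamped with a warning
rather than failing the frame.

Defaults: `distTailBase = 12` px, `distTailPoints = 6` px, arc = 2π/3,
7 segments. The base radius must clear the eyes — the darkest features of a
real (and our synthetic) fish — or a full-circle first-point search will
walk rostrally; 12 px does so for the default rendering geometry and for
typical 30 px/mm larval imagery.

## Curvature, tail angle, bout detection

Tail points P are converted to segment angles by translating the centroid
to the origin, rotating by θ_h, and taking bearings between successive
rotated points, so θ₁ = 0 identically. (The alternative reading — bearings
from the origin rather than between successive points — disagrees with the
stated θ₁ = 0 contract beyond the first segment, so we implement
successive differences.) The array is unwrapped by ±2π wherever successive
entries differ by more than π; unwrapping is idempotent. The scalar tail
angle of a frame is the mean of the last three segment angles.

The online detector keeps a ring window of recent tail angles
(`frameWindow`, default `round(0.15 s × frameRate)` — a value we chose;
150 ms spans a few beat cycles at typical rates without bridging distinct
bouts). A bout starts when the angle departs from the window extremum by
more than `boutThreshold` (default 0.1 rad). Inside a bout the detector
alternates search direction: a retreat of more than `peakThreshold`
(default 0.05 rad) from the running extremum confirms a peak, whose signed
value becomes the amplitude, and re-arms the expiry counter — so continuous
swimming is one continuing bout, which is our resolution of the ambiguous
expiry-counter semantics. Frequency is `frameRate` divided by the frame gap
between successive *same-direction* peaks (one full cycle), so a 20 Hz sine
reads 20 Hz; `cycleMode = "half"` gives the alternating-peak variant for
comparison. Because peak positions are integers, the estimate is quantized:
at 332 fps a true frequency f is recovered within
max(|fps/⌊fps/f⌋ − f|, |fps/⌈fps/f⌉ − f|) — about 0.75 Hz at 20 Hz —
and the tests assert exactly that bound.

Bout edges are taken from the rising and falling edges of the bout flag,
padded by `round(0.015 × fps)` frames (15 ms) each side, with overlapping
padded intervals merged. Per-bout features are the mean of nonzero TBF
samples, the signed integral Σ angle/fps, the SD, and the signed
maximum-magnitude angle; absolute values are applied only at clustering
time.

## Eyes and heading

Eye candidates are connected regions filtered by area, centroid distance,
and bearing within ±`angleRange`/2 of the heading; the two survivors are
ordered by signed bearing, and we *define* "left" as the positive,
counterclockwise bearing (the fish's own left in y-down imagery) — the
ordering key the original description leaves implicit. Any other survivor
count is an explicit failure carrying the count. Eye angles rotate the
moment-derived major-axis orientation (defined only modulo π) into the
heading frame and offset by π when the axis initially points against the
heading, so each eye angle lies within (−π/2, π/2] of the heading.

The cumulative heading accumulates wrapped frame-to-frame differences of
the instantaneous heading (eye-midpoint variant or tail-point variant) and
is unbounded: 72 frames of 10°/frame read 720°. The cleanup rule scans
10 ms spans; a change exceeding 180° is excised and the subsequent values
are shifted so the trace rejoins its pre-artifact level; consecutive
artifacts compose, and the applied shifts are recorded so the operation is
invertible.

## Multi-animal identities

Per-frame centroids are linked by minimizing the total Euclidean distance
between consecutive frames' positions — a linear sum assignment solved by a
shortest-augmenting-path Hungarian method implemented in the package (the
test suite checks it against exhaustive permutation enumeration). When
contacts merge blobs and fewer centroids are present than identities, each
unassigned identity maps to its nearest centroid and every identity sharing
a centroid is contact-flagged; the flags form a per-frame discard mask,
optionally padded by a configurable number of frames around each event
(default 0). Percent accuracy is (total − contacts)/total × 100. The
group-level stimulus switcher takes the mean of all centroids and flips the
drift direction only when that center of mass enters the leftmost or
rightmost arena quarter (hysteresis elsewhere).

## Closed-loop feedback

The 1-D law is V_S(t) = V_B − gain · vigor(t), with vigor the mean over a
15 ms window of the tail-angle derivative, each sample discounted by
exp(−Δt/9 ms), gated by the bout instance. Two readings of the printed form
were possible; we take 9 ms as a decay *time constant* (the prose) rather
than a multiplicative rate (the typography), and we integrate the
*magnitude* of the derivative by default so that a beat in either direction
slows the grating — a signed variant is one flag away, and the worked gain
examples constrain only the magnitude. The 1/n normalization sits outside
the exponential sum as printed; moving it inside would only rescale the
calibrated vigor scale. That scale is solved numerically once per
(frameRate, window, decay): `calibrateVigorScale()` synthesizes a 2 s,
20 Hz, unit-amplitude reference bout and sets the scale so its steady-state
vigor maps to 20 mm/s at gain 1. With V_B = 10 mm/s this yields steady
states of −10, 0 and −20 mm/s at gains 1.0, 0.5 and 1.5; the acceptance
script recomputes the gain-0.5 value from scratch. Steady state is measured
as the mean over an integer number of beat cycles (the central second of
the bout, 20 cycles), which makes the cancellation at gain 0.5 exact to
machine precision.

The 2-D law multiplies the boxcar-averaged tail-beat frequency by
(1 − |θ|/90), θ ∈ [−180°, 180°): the factor is 1 aligned, 0 at ±90°, −1
anti-aligned. It is continuous inside the interval; at the wrap itself θ
jumps from just-under 180° to −180° while the factor is continuous (−1 on
both sides) — the jump is in the representation, not the velocity. The
boxcar window defaults to 15 ms to parallel the 1-D window (unstated in the
source design). Stimulus angular velocity is mean tail curvature divided by
time since bout onset, so early-bout curvature steers hardest. The gain
schedule is three identical 18-trial blocks: three trials each of gains
1.0, 0.5, 1.5, then 1.0, 1.5, 0.5 — 54 trials.

## Open-loop stimuli

The looming dot uses the standard angular-size law
θ(t) = 2·atan((l/v)/(t_c − t)), isolated in one function because only the
l/v ratio (90 ms) is prescribed by the assay. We place the virtual
collision time t_c so truncation at `maxAngle` (120°) occurs 3 s after
expansion onset — consistent with truncation ~13 s into a trial with a 10 s
static period — and hold the dot at the expansion-onset size during the
static period (the pre-expansion size being otherwise unstated). The prey
arc sweeps φ(t) = 60°·sin(ωt) with ω = (100°/s)/60°, giving the prescribed
100°/s peak dead ahead and 0°/s at ±60°; `fixed_lateral` pins φ at one
extreme, and the reported yaw uses our left-positive sign convention. All
open-loop stimuli are anchored to the live pose, so rigid transforms of the
fish transform stimulus positions identically — the defining property of
virtual open loop, and a tested invariant. Camera-to-display mapping is the
affine map between two rectangles, applied to every stimulus position.

## Bout clustering

Features are transformed to (mean TBF, |integral|, SD, |max amplitude|) —
direction deliberately discarded — z-scored (so the Hz-scaled feature
cannot dominate the Euclidean metric; standardization was left open in the
source description and is switchable), and clustered agglomeratively with
Ward linkage, the standard default for compact kinematic clusters; both
linkage and metric are exposed. The tree is cut at every k in 2–10 and the
k maximizing the mean silhouette width wins; with fewer bouts than k the
range shrinks with a warning, and identical bouts return an explicit
degenerate result. J-turn direction uses the sign of the unnormalized
integral (positive = left under our counterclockwise-positive convention;
an exactly zero integral goes right and is flagged). Naming clusters
(forward swim / routine turn / J-turn) is a reporting heuristic by
comparison of cluster-mean kinematics, not an algorithmic output.

## The synthetic fixtures, and what the tests show

`renderFishFrame()` draws a soft-edged body ellipse centered on the
centroid, two brighter eye ellipses fully inside it (as in real larvae,
where the eyes are the darkest features within the body), and an
anti-aliased Gaussian-cross-section tail stroke through the ground-truth
polyline, whose spacing matches the fitter's search radii. The contrast
ordering eyes > body > tail lets one threshold isolate the body for
centroid detection and a higher one isolate the eyes. Swim traces are
sinusoids with per-bout frequency, amplitude and bias plus optional
Gaussian noise; prey paths alternate randomized runs, pauses and
reorientations (speeds 0.5–2 mm/s, runs 2–10 mm, pauses 0.2–1 s, turns
45–180°/s — values we consider realistic for paramecia-like motion) and
reflect at walls; bout-feature mixtures are labeled Gaussian draws. Every
generator takes an explicit seed and leaves the global RNG untouched.

Against these fixtures the test suite shows: centroids within 2 px and tail
polylines within 2 px RMS over 50 random poses for all three scoring
methods (typical errors are well under 1 px); weighted-median jitter no
larger than pixel-search jitter over 100 noise realizations; detector
frequency recovery at 5/10/20/30 Hz within the integer-frame quantization
bound with zero false bouts on silent traces; exact identity permanence for
well-separated groups; permutation-optimal assignment over 1000 random
instances; and planted-k recovery with ≥95% label agreement over 20 seeds.
Problem sizes (160×160 px frames, 3 s traces at 332 Hz, groups of 3–5) are
our choice of desk-scale study conditions.

What the fixtures do *not* emulate: pigmentation and body texture,
refraction and illumination gradients, occlusion other than centroid
merging, swim-bladder asymmetry, and motion blur. Passing tests therefore
demonstrate the correctness of the algorithms and their implementations
under controlled contrast, not robustness to every artifact of real
recordings; on real data the thresholds (intensity, area, bout, peak) are
the parameters that will need tuning, and the weighted-median scorer is the
recommended default where frame-to-frame stability matters.

## Known limitations

- Video containers (AVI/MP4) are not read directly; recordings must be
  supplied as PNG image sequences (`readFrames()`).
- Tail fitting returns members of the rasterized circle point set; spatial
  resolution is bounded by the pixel grid (by design, matching the online
  method), so sub-pixel tail kinematics require higher magnification, not a
  flag.
- The bout detector is causal and threshold-based; it will merge bouts
  separated by less than the expiry window and has no offline (spectral)
  frequency mode.
- Identity assignment is purely positional; fish that swap places while
  merged cannot be disambiguated afterwards, which is exactly why contact
  frames are masked out of downstream analysis.
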