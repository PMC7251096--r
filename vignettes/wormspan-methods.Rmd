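---
title: "Automated lifespan determination from plate image sequences: methods"
author: "wormspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lifespan determination from plate image sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wormspan)
```

# The problem

A *C. elegans* lifespan assay counts the live worms on each Petri plate once
a day until the whole synchronized population has died; the output is one
survival curve per plate. Death is operationally defined by absence of
movement over 24 hours. Automating the count from backlit plate images is
hard for three reasons: the plate wall casts a ring of dark shadows
(covering about 7% of the plate area) in which worm shape is unreadable;
worms touch and form aggregates that segment as one blob; and dust
accumulates on the lid over the weeks of the assay, creating dark spots that
imitate worms.

`wormspan` implements a dual-zone image-processing pipeline over daily
30-frame sequences (1 frame per second), a skeleton-based optimiser that
splits two touching worms, a death-event detector based on inter-day image
alignment, and an adaptive two-period filter that repairs the remaining
counting errors in the survival curves. A ground-truthed plate simulator
makes every stage testable without laboratory data.

# Pixel level: temporal signatures

Backlit acquisition with active illumination holds the background near grey
level 48, so a single fixed threshold segments every frame: a pixel is dark
iff its intensity is strictly below 33 (`segmentFrame()`). Stacking the 30
binary frames gives each pixel a 30-bit *temporal signature*
(`stackSignatures()`), classified by `classifyPixels()`:

* all dark → constant dark (wall shadow, dead worm, dirt);
* all white → constant white (background);
* otherwise, count the transitions $k = \#\{t : s_t \ne s_{t+1}\}$:
  few transitions means something moved through the pixel (MOTION), many
  means sensor or condensation flicker (NOISY).

The transition cut is the one genuinely free parameter at this level. We
calibrated it on simulator output by measuring both populations: pixels
inside moving-worm footprints show at most 11 transitions per 30 frames
(99.5% are ≤ 8), while flicker pixels switch at a far higher frequency —
near-alternating flicker has a transition count around 20 of 29, and even
fully random flicker centres on 14–15. The default
`noiseTransitionThreshold = 8` sits in the gap, losing about 0.2% of true
worm-motion pixels and admitting a negligible fraction of flicker. The
classification is invariant under time reversal of the sequence, which the
test suite asserts as a property.

The plate centre is found with no tuning at all: it is the largest
8-connected constant-white component, holes filled (`detectZones()`), and
its boundary is the wall edge. Constant-dark pixels are then recoded as
wall-dark or centre-dark (`recodeDarkByZone()`).

# Pixel-level tracks and the wall zone

Inside the wall annulus only pixel-level information exists. Motion pixels
there are bridged across the dark shadow rings by a *geodesic* dilation of
radius 40 px (native scale): the dilation grows only through dark and noisy
pixels and can never cross illuminated background, so fragments of one
worm's motion join while separate worms across a bright ring stay apart
(`dilateWallMotion()`). Connected components — with motion, centre-dark and
noisy pixels treated as equivalent inside the centre, and only bridged
motion in the wall — become pixel-level tracks (`labelPixelTracks()`), each
guaranteed to contain at least one motion pixel. Tracks fully inside the
wall count one live worm each; tracks fully or partly in the centre
(denoted centre tracks) are resolved at worm level.

# Worm level: blobs, skeletons, disaggregation

Per frame, dark components in the centre are measured
(`extractCenterBlobs()`) and filtered by area — the inclusive band 20–240 px
at native scale spans the smallest single worm to the largest two-worm
aggregate — and, after disaggregation, by intensity (mean grey strictly
below 20; dust is paler).

A blob large enough to be two worms is thinned to its topological skeleton
(Zhang–Suen, implemented in the package) and converted to a graph of
endpoints, crosses and arcs (`buildSkeletonGraph()`), with arc length
measured geodesically and arc width as twice the mean distance-transform
value. Rasterised skeletons carry artefacts, so the graph is pruned
(`pruneSkeletonGraph()`): short terminal spurs, tiny loops and redundant
parallel arcs are removed, pass-through nodes are merged, and a short
cross-to-cross bridge — the shared stretch left when two bodies overlap
along a segment rather than at a point — is contracted into one cross.

A *possible worm* is a simple connected path of skeleton edges; a candidate
interpretation is a partition of all edges into at most two such paths
(aggregates of three or more worms are out of scope; at 10–15 worms per
55 mm plate their probability is practically zero). `enumeratePartitions()`
enumerates these exhaustively; each candidate worm is scored by the
Euclidean distance of its measured (length, width) from the theoretical
worm shape, a candidate set by the mean of its members' costs, and
`disaggregate()` returns the arg-min. Exact ties prefer not splitting, then
a deterministic lexicographic order of the edge blocks. The test suite
checks the whole selection against an independent brute-force enumeration
(2-colourings of the edge set, path check by chain-building over
permutations) on hundreds of random graphs, and checks that ≥ 95% of
rendered two-worm crossing scenes are split into exactly two worms.

Blobs below `aggregateMinArea` (1.45 × the single-worm area by default) are
taken as single worms without skeleton analysis; this is a pure speed
optimisation, since a partition of a single-path skeleton is trivially the
whole path.

# Tracking, fusion and the daily count

Worm detections are linked frame to frame by greedy maximal pixel-overlap
association with a one-frame gap tolerance (`trackWorms()`); at 1 fps worms
overlap their previous footprint almost entirely, so greedy matching is
adequate. A track is *in motion* if its maximum pairwise centroid
displacement reaches 5 px (native) or the symmetric difference between its
first and last footprints exceeds 20% of the blob area; otherwise it is
*quiescent* (`classifyTrackMotion()`).

`fuseTracks()` reconciles the two levels in the centre: each worm-level
track is assigned to the pixel-level track containing the majority of its
pixels, and each centre track's live count is its number of assigned moving
worm tracks. A centre track that contains motion but no worm-level track at
all is floored at one live worm — the pixel level is trusted there exactly
as it is in the wall zone. If only quiescent worm tracks are assigned the
fusion contributes zero and the worms pass to the inter-day check, so no
worm can be counted twice.

The daily total is

$$a_{is} = \sum T_w \;+\; \sum_{T_c} a_{T_c} \;+\; \sum a_p,$$

wall tracks plus fused centre counts plus quiescent worms shown to have
moved since yesterday. The per-day log records all three terms and the test
suite audits that the total always equals their sum.

# Death events across days

Plates are repositioned by hand every day, so before comparing days the
package estimates the rigid transform (rotation + translation) between the
two representative frames — the temporally middle frame of each sequence.
Translation comes from FFT cross-correlation with parabolic sub-pixel
refinement; rotation from an alternating search (a sparse
normalized-cross-correlation score over the ~15,000 strongest-gradient
pixels, interleaved with translation re-estimates, grids shrinking from
0.5° to 0.05°), bounded by the configured limits (±5°, ±60 px native). If
the translation-only match is already near-perfect the rotation search is
skipped, and if nothing beats the unaligned score the identity is returned
(`alignDays()`).

For each quiescent worm, `detectInterdayMotion()` extracts its segmented
window today and the rigidly mapped window from the previous day's last
frame (the observation closest in time), lightly blurs both masks (Gaussian
σ 1.2 px, which makes the score tolerant of the sub-pixel residuals a
compensated displacement leaves) and takes the maximum normalized
cross-correlation over a ±3 px translation slack. A score at or above 0.90
means no shape change in 24 h: the worm is dead. Anything lower — the worm
re-curled, moved, or was not there yesterday — counts it alive through the
$a_p$ term. Day 0 has no previous day and hence no $a_p$ term.

# Post-processing: the adaptive two-period filter

Survival curves are monotone non-increasing, so any rise in the raw curve
is an error. Errors are asymmetric in time: early in the assay, worms hide
in the wall shadow or aggregate (false negatives, around 20% per day at the
start and decaying), while dirt accumulates and dominates late (false
positives rising from about 3% to about 12%). `adaptiveFilter()` therefore
applies, per plate: (1) a cap at the initial population $n_0$, which the
experimenter knows exactly; (2) up to the dividing day, a backward pass
raising each count to at least the next day's value (a later, higher count
proves the earlier worms existed); (3) from the dividing day on, a forward
pass clamping each count by the previous day's value (a later rise is
contamination). The dividing day is the strain's mean lifespan, supplied as
configuration (N2: day 14; daf-2: day 42); the package does not estimate it
from the data.

This composition order is a design choice the source description leaves
open; it is the order that guarantees the output is globally monotone,
bounded in $[0, n_0]$, idempotent, and the identity on curves that were
already valid — all verified as properties over thousands of random curves.
First-period corrections deliberately never propagate from second-period
days: a late rise is read as a false positive, never as evidence that early
counts were low.

`regressiveCorrectManual()` applies the same backward-max logic over the
whole range to manual counts, since human counters also cannot see hidden
worms; the difference between corrected and visible counts estimates the
per-day hidden-worm rate. `errorReport()` computes the evaluation metrics:
per-day population error |ΣE|/Σn₀ in percent, its mean over days (the curve
error), and the per-plate-day error distribution (mean, SD, zero-error
fraction).

# The simulator

`simulateAssay()` emulates the acquisition: a 486 × 486 frame (quarter of
the native 1944 × 1944; all pixel-denominated pipeline parameters scale by
the resolution factor, areas by its square) containing a plate of radius
0.475 × frame, a wall annulus sized to 7% of the plate area carrying dark
refraction rings at grey 20, an optional flickering band (near-alternating dark/bright pixels with small phase noise, as condensation and sensor noise switch far faster than a crawling worm), a slightly darker
irregular bacterial-lawn disc, background 48 with Gaussian sensor noise
(σ 1.5), and worms as anti-aliased sine-undulating tubes at grey 12 —
preserving the photometric ordering worm < threshold 33 < background that
the fixed-threshold segmentation relies on.

Worm geometry is specified in fixture pixels (length 21, width 2.2 by
default) rather than scaled down from native values: at quarter resolution
a native 2.8 px body width is sub-pixel, and a rasterised tube cannot be
thinner than about one pixel, so scaling areas by the square of the
resolution factor would produce a worm model band that no rendered worm can
satisfy. `simWormModel()` instead renders one canonical worm, measures its
segmented area and skeleton length/width, and derives the matched model
(area band 0.4–2.6 × the single-worm area, covering singles and pairs).

The rings carry per-plate angular irregularity — radius wobble and bright
glint gaps in the outer ring — because a geometrically perfect plate is
rotationally symmetric and would make the inter-day rotation unobservable;
real refraction rings are broken and irregular. All this static texture is
photometrically invisible to the pipeline (lawn and glints never cross the
threshold; the innermost ring is continuous so the centre-detection blob is
unchanged).

Dynamics: each worm draws a death day from a discretised Gaussian (mean 14,
SD 3 days for an N2-like strain), floored so every worm has at least one
fully mobile day. Per-frame displacement decays with age as
$(1-\text{age})^2$ from 2.5 px to a 0.3 px floor. In its last two days a
worm freezes its body and oscillates only its head, and moves a few pixels
between days; at death it freezes exactly in its final pose and never
changes again. This makes the simulator's ground truth coincide with the
pipeline's operational death criterion (no in-sequence motion and no shape
change versus the previous day's last frame), which is what makes the
zero-error acceptance test on artifact-free simulations well defined.
Optional artifact processes: per worm-day hiding in the wall shadow
(default 3%), Poisson dirt accrual (0.3 blobs/plate/day, intensity 15–40 so
some dirt passes and some fails the intensity filter), per-day rigid plate
displacement (σ 4 px, 0.5°), and free-roaming worms that can collide. The
artifact-free configuration (`cleanSimConfig()`) turns all of these off and
confines worms to disjoint home ranges so aggregation cannot occur.

What the simulator does not emulate: optics (lens distortion, defocus),
condensation imagery beyond the flicker band, progeny, worm decomposition,
and bacterial-lawn depletion. Passing the artifact-free exactness test
therefore shows the pipeline's logic is internally coherent, not that the
error rates on real plates will match; the error-process tests
(`injectCountErrors()` with the day-profiled false-negative/false-positive
rates) cover the statistical behaviour of the filter separately.

# Numerical choices and edge cases

* Component labelling is 8-connected throughout (thin diagonal worms stay
  connected).
* The dark threshold is strict (`< 33`), as are the worm-intensity ceiling
  (`< 20`) and the area band bounds (inclusive 20–240): chosen so the
  printed levels 48 (background) and below-20 (worms) are unambiguous.
* Skeleton pruning thresholds are expressed in units of the theoretical
  worm length (spur cut 0.15 L, bridge contraction 0.45 L).
* Skeletons with more than 12 edges raise a "skeleton too complex" error
  and the blob is dropped as a >2-worm aggregate, as are blobs with no
  valid one-or-two-path partition.
* Empty frames, single-pixel blobs, closed skeleton loops, missing plate
  days and failing plate-days all have defined behaviour (degenerate
  graphs, censored days, per-day error records) covered by tests.
* All simulator randomness derives from one integer seed through a
  deterministic sub-seed scheme, so image stacks and ground truth are
  bit-identical across runs and independent of rendering order.

# Problem sizes used by the test suite

The packaged checks run the full pipeline end to end on a 5-plate ×
10-worm × 20-day artifact-free assay at 486 × 486 resolution, verify the
disaggregation arg-min against brute force on 500 random graphs, the filter
algebra on 1000 random curves, the filter's error reduction on 200
corrupted plates, and alignment recovery on 100 random rigid perturbations
(|t| ≤ 15 px, |θ| ≤ 3°). The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities at slightly smaller
sizes and writes them as JSON.

# Known limitations

* Worms overlapping bodily (not crossing at a point) share a skeleton path
  and cannot be separated by edge partitioning; such blobs resolve as one
  worm. The post-processing filter absorbs the resulting transient
  undercounts.
* The wall zone counts one worm per motion component; two worms moving
  within one bridged component are counted once (a false negative the
  first-period filter corrects when they reappear in the centre).
* Greedy overlap tracking can swap identities if two worms pass through
  each other, which does not affect counts (identity is not part of the
  lifespan endpoint).
* The rotation search assumes the plate has some angular texture; on a
  hypothetical perfectly symmetric plate only translation is recoverable.
* The dividing day must be supplied; a badly wrong value degrades the
  filter toward a one-period rule.
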