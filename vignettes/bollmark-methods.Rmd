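---
title: "Detecting stink bug punctures on cotton bolls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stink bug punctures on cotton bolls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bollmark)
```

## The measurement problem

A stink bug feeds by driving its proboscis (≈ 0.17 mm across) through the
carpal wall of a developing cotton boll. Around the puncture the plant's
wound response produces a compound that fluoresces green under blue LED
excitation, while intact tissue keeps the red chlorophyll emission. A
photograph of the closed boll therefore carries a damage signal — but
control bolls that were never exposed to stink bugs also show green spots
(abrasion, mites, handling), so the task is not just detecting green
fluorescence but separating puncture marks from look-alikes.

Two features do most of the work:

* **Area `A`** of the segmented fluorescent region (mm²). Feeding marks are
  small and consistent; false positives are larger and far more variable.
* **The donut ratio `I1/I2`**. The puncture removes tissue at the center of
  the mark, so its fluorescence has a dark core: the mean intensity `I1` of
  a small central circle falls below the mean `I2` of the whole mark.
  False positives tend to be brightest at the center, pushing the ratio
  above 1.

A mark is called a puncture when `(A, I1/I2)` falls inside the rectangle
`A < 0.6 mm²` and `I1/I2 < 1.2` (strict inequalities; with real-valued
features, boundary cases have measure zero but the convention is fixed and
tested).

## Pipeline and parameter choices

The stage order is fixed: center-weighted median filter → 2×2 binning →
(mask branch: channel extraction → Butterworth low-pass → fixed threshold)
∥ (ratio branch: G/R) → mask multiplication.

**Units and resolution.** Raw frames are 12-bit RGB at 36 px/mm; binning
produces the 18 px/mm working scale at which every pixel-denominated
threshold in this package is stated (28-px minimum area = 0.09 mm², 15-px
peak spacing, 4-px inner circle). When reading your own TIFFs, set
`resolution_px_per_mm` to the *raw* frame resolution.

**Median filter** (`window = 3`, `center_weight = 3`): the window and
weight are tunable; a center weight of 3 preserves fine detail (the marks
of interest are only a few pixels across after binning) while still
knocking out single-pixel outliers.

**Butterworth mask blur** (`order = 2`, `cutoff_px = 10`): the cutoff is a
spatial wavelength — 10 px, i.e. 0.1 cycles/px. We use the standard
amplitude response `1/sqrt(1 + (f/f_c)^(2n))` with gain 1 at DC and
1/√2 at the cutoff. The mask channel defaults to red (the chlorophyll
emission outlines the whole boll) and is configurable to green.

**Mask threshold**: 5% of the blurred channel's maximum, floored at 50
counts. The floor matters only for frames with no boll at all, where a
purely relative rule would mask the entire frame instead of nothing. The
black backdrop makes the result insensitive over at least a 2–20% threshold
range (asserted by test). Because the threshold is low and the blur heavy,
the raw mask overhangs the true boll edge by a few pixels of backdrop;
those pixels have near-zero red *and* green, so their ratio is garbage. The
mask is therefore eroded by `erode_px = 6` (about the overhang of the 5%
contour of the blurred edge) before it multiplies the ratio image.

**Division guard**: `eps = 1` count (one least-significant unit of the
12-bit scale).

**Detection.** The printed constants (peak spacing 15 px, prominence 10)
are camera counts, while the G/R ratio is an O(1) quantity, so detection
runs on the ratio image rescaled so its maximum maps to 4095. The local
mean in the prominence test is computed over in-mask pixels only
(normalized convolution): a plain disc mean would mix in background zeros
near the boll edge and hand every edge pixel a spurious prominence equal to
the whole baseline height.

**Snake segmentation.** Each candidate gets a 32-vertex circular contour,
centered on a refined center — the intensity-weighted centroid of
above-local-mean pixels near the peak, because on a donut-shaped mark the
raw intensity peak sits on the bright annulus, not at the mark center (the
contour's placement only needs to be near the mark). The initial radius is
1.5× the radius at which the radial profile first drops below the local
mean, capped at 40 px. Energy weights (`α = 1`, `β = 0.5`, `γ = 2` on a
[0,1]-normalized Sobel gradient) were chosen so that step-edge disks of
radius 5–20 px are recovered within 1 px; they are configurable.

Two numerical points deserve explanation because they are where naive
implementations fail:

* *Per-vertex move criterion.* Each vertex moves greedily to the position
  minimizing **its own** energy terms (stretch to both neighbors, its own
  curvature, its image term) — the classic greedy-snake scheme. Minimizing
  the *total* energy per vertex instead adds the two neighbors' curvature
  terms, which pull symmetrically outward and exactly cancel the inward
  pull: the contour freezes on a regular polygon and never contracts. The
  full three-term energy is still evaluated after every iteration and never
  allowed to increase — an iteration that would raise it is reverted and
  ends the evolution.
* *Sub-pixel candidate grid* (`±0.5 px` in steps of `0.1 px`). For a
  32-vertex polygon of radius *r* the internal-energy optimum lies only
  `r·(1 − cos(2π/32)) ≈ 0.02 r` inside each vertex; with whole-pixel
  candidate steps no move ever decreases the energy and small contours
  freeze. The fine grid restores contraction down to radii of ~3 px,
  conveniently just below the 28-px area floor, so candidates with no real
  boundary collapse and are removed by the area filter — this is how the
  pipeline sheds the noise candidates that the permissive prominence
  threshold lets through.

Moves that would make the polygon self-intersecting are rejected (the
next-best candidate is taken). Rasterization uses the even-odd rule with
pixel centers, boundary-inclusive.

**Filters.** Kept marks satisfy `area_px ≥ 28` ("below 28 px" excluded,
28 kept), integrated intensity `Σ ratio / area_mm² ≥ 0.04`, aspect ratio
`≤ 2` (exactly 2 kept), and solidity `≥ 0.9`. Three conventions here are
package decisions worth knowing:

* *Integrated intensity* is the sum of ratio values over the region divided
  by its area in mm² — the only reading of a mm⁻² unit for a dimensionless
  ratio. For any real mark this quantity is orders of magnitude above 0.04,
  so the rule only removes pathological near-zero-intensity regions.
* *Convexity* is solidity: pixel count divided by the pixel count of the
  filled convex hull of the pixel centers (the scikit-image convention).
  Under polygon-area conventions a rasterized disk scores anywhere from
  0.80 (corner hull) to 1.03 (center-hull area), either failing obviously
  convex shapes or exceeding 1; under rasterized-hull solidity a disk
  scores exactly 1 at any radius.
* *Equal-area circle.* The snake-to-circle conversion for `I2` uses the
  equal-area circle at the region centroid, since area is the downstream
  classifier feature. The inner circle radius is 4 px at 18 px/mm
  (≈ 0.155 mm²; an approximate mm² gloss sometimes quoted for it is
  inconsistent with the resolution — the pixel radius is authoritative
  here). Marks whose equivalent radius does not exceed 4 px get no valid
  ratio and are flagged.

## Classification, contingency and ROC

`classify_marks()` applies the rectangle strictly. `contingency()` reports
counts and two percentage conventions; the *pooled* one (each cell as a
percentage of all marks from both groups) is the convention under which the
published table's infested row sums to `n_infested / n_total`, and is the
default view. `roc_sweep()` grows the rectangle along the diagonal through
the origin and (0.6, 1.2) using the six published corners, reporting
sensitivity (fraction of infested marks inside) and specificity (fraction
of control marks outside, i.e. 1 − FPR — axes are stated explicitly in the
CLI output because informal descriptions of the sweep sometimes swap the
terms).

## Statistics

`kruskal_wallis()` and `wilcoxon_signed_rank()` wrap the standard R
implementations (tie-corrected H with chi-square approximation; exact
signed-rank p for n ≤ 25 without ties, normal approximation with continuity
correction otherwise; two-sided by default, zero differences dropped).
`kruskal_wallis(..., exact = TRUE)` enumerates all group assignments (n ≤
12) — at those sizes the chi-square approximation can be off by several
hundredths, which matters when validating against enumeration. Dunn's post
test is implemented directly (pooled-rank z with tie correction) since no
installed package provides it; the family-wise adjustment defaults to
Bonferroni — the classic form of the test — with Holm available. All tests
use α = 0.05.

## The synthetic-data generator

No boll photographs were deposited with the study this package's
constants derive from, so the generator is the package's test substrate,
not a fixture: it renders what the physics says a scene should look like,
and its defaults are fixed study conditions, not tuning knobs.

* **Scene**: 400×400 px at 36 px/mm; boll as an ellipse (semi-axes
  160×136 px) with red ≈ 2500 counts, green baseline 0.5× red, backdrop
  ≈ 15 counts; additive Gaussian noise with sd = 1% of the boll intensity
  on both channels. Mark geometry is part of the scene specification;
  the seed controls only noise (and is honored bitwise).
* **Punctures and needle marks**: annuli with a logistic rim at the nominal
  radius and a Gaussian central dip (default attenuation 0.6 for feeding
  marks, 0.85 for needle punctures — needle punctures are smaller and
  darker-centered).
* **False positives**: 2–4 offset Gaussians on a plateau with a logistic
  rim. The rim is deliberate: boundaryless Gaussian blobs give the snake
  nothing to lock onto and collapse, whereas real false-positive marks were
  evidently segmentable.
* **Ground truth** records each mark's nominal circular area and its
  `I1/I2` measured on the noiseless ratio profile with the same
  equal-area-circle definition the pipeline uses (with the 4-px inner
  radius converted to the scene's raw scale).
* **Feature tables**: `sample_mark_table()` draws (A, I1/I2) per class from
  log-normals whose medians are the published group medians (0.35/0.6/0.27
  mm²; 0.96/1.2/0.86). Log-normal because both features are positive and
  right-skewed; `sdlog` 0.4 for false-positive areas (their hallmark is
  high size variability) and 0.25 elsewhere. These dispersions reproduce
  the qualitative two-group overlap of the published scatter and give the
  rectangle classifier sensitivity and specificity both above 0.7.

What the generator does **not** emulate: boll surface texture and lint,
specular structure, multi-view geometry of the rotary stage, vignetting,
or spatially correlated noise. Passing tests on generated scenes therefore
demonstrate the correctness of the algorithms under the stated intensity
model, not field performance on real bolls.

Known limitation: generator features are drawn independently per mark. Real
area and intensity ratio are likely correlated, and one published-style
claim — that the joint rectangle beats *every* specificity-matched single
criterion — does not hold under independence (the area rule alone, matched
to the rectangle's specificity, captures slightly more true positives).
What does hold, and what the tests assert, is the substantive claim: the
joint rule markedly improves specificity over either single rule at the
published thresholds and beats the intensity rule at matched specificity.

## Problem sizes and determinism

The test suite regenerates every fixture from code. The heavier suites run
at: 50 step-edge disks for snake recovery (radius 5–20 px, < 1 s each),
100 synthetic marks for brute-force I1/I2 equivalence, 2000 replicates for
the type-I error of each rank test, and 50 full scenes (3 planted marks
each) for end-to-end recovery of the planted medians — sizes chosen so the
whole suite completes in a few minutes on one CPU while keeping the
acceptance margins far from their thresholds. All randomness is seeded;
`run_pipeline()` is bitwise reproducible for a fixed configuration, and the
configuration's MD5 is stamped into every report.
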