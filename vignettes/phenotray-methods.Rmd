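---
title: "Growth-trait extraction from top-view tray images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-trait extraction from top-view tray images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phenotray` measures growth phenotypes of rosette-forming plants (and,
with restrictions, wheat) from uncalibrated top-view photographs. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, the synthetic data the package validates itself against,
and the design decisions taken where more than one reasonable choice
existed.

## Calibration model

Cameras, phones and fixed rigs produce images from 2592 × 1944 up to
4288 × 2848 pixels with unknown distance to the tray. Two devices anchor
the geometry:

* **Height normalisation.** Every image is resampled so its height is
  exactly 1024 px (bilinear; width follows the aspect ratio). All
  downstream pixel measurements live in this one working frame, which
  bounds memory for batch runs and makes thresholds transferable across
  devices. The raw image object is never modified.
* **Fiducial markers.** Four red circular stickers of known physical
  radius (4 mm; 5 mm for the wheat setting) sit at the corners of the
  tray or pot. A pixel belongs to the marker mask when
  `R > 125`, `B < 225` and `R − G > 50` (0–255 scale) — a rule that is
  deliberately generous under varied illumination. A 3 × 3 morphological
  opening detaches stray red-passing soil speckles, then connected
  components are screened by shape: solidity ≥ 0.9, eccentricity ≤ 0.6,
  area within [0.25×, 4×] of the median candidate. These three bounds are
  package choices (the screening features are standard, their numeric
  cut-offs are not canonical); they accept rasterised discs down to
  ~8 px radius and reject bars, smears and merged blobs. If more than
  four candidates survive, the four nearest the image corners win; fewer
  than four is an error that names the count found, since without the
  quadrilateral no metric calibration exists.

The scale is `px_per_mm = mean equivalent-circle radius / marker radius
(mm)`, estimated on the working image so that one coordinate frame serves
everything. The marker centres, ordered by angle about their centroid
(top-left first), define a perspective transform onto an axis-aligned
rectangle whose width/height are the means of the opposing edge lengths —
the least-distorting rectangle for a near-planar tray. Bilinear inverse
mapping fills the region of interest (ROI). Lens distortion and white
balance are out of scope.

Denoising is an edge-preserving median filter of radius 2 px, applied
after ROI extraction. On a flat region it provably cannot increase
variance; on leaf edges it preserves geometry better than Gaussian
smoothing at equal strength.

## Leaf segmentation

Two independent per-pixel routes are fused:

1. **Greenness clustering.** The vegetative greenness
   `G_V = ExG − ExR`, with `ExG = 2G − R − B` and `ExR = 1.4R − B`, is
   clipped to [0, 255] (clipping preserves order and matches the trait's
   reporting range). The `G_V` values are k-means-clustered into `k`
   groups and pixels of every cluster whose mean exceeds the global Otsu
   level of the `G_V` image are kept. `k` is estimated once per series
   from the midpoint image (1-based index `floor((n+1)/2)`): its RGB
   pixels are clustered into 8 probe groups and `k` is the number of
   clusters at least as large as the median cluster size, clamped to
   [3, 10]. The census statistic (sizes, not mean greenness) is a package
   choice. All clustering subsamples at most 50 000 pixels and runs under
   a fixed seed (default 42), so two runs agree exactly and results do
   not depend on batch scheduling.
2. **Lab opponency.** The image is converted to CIE Lab (a closed-form
   sRGB/D65 transform implemented in the package and unit-tested against
   `grDevices::convertColor`; the in-package version avoids
   `convertColor`'s per-image overhead on megapixel inputs). On the green–red opponent channel `a*` an Otsu
   threshold separates the green side, and only pixels with `a* < −2`
   are accepted — the floor keeps grey/achromatic images from producing
   phantom foreground. This route recovers leaves a few pixels across
   that clustering can miss.

The fusion is a pixelwise union followed by removal of components smaller
than 1 mm² equivalent. Union maximises recall (provably never below
either route); the precision cost is paid back at pot level. Harvested
(empty) pots need no special casing: their colour groups simply never
clear the greenness threshold.

## Pot lattice and local refinement

The ROI is tiled into `rows × cols` rectangles with boundaries at
`round(i·W/cols)`, `round(j·H/rows)` — an exact partition, pots indexed
row-major. Leaves crossing a border are clipped at it (the split is the
assignment rule; nothing is counted twice). Within each pot, components
are dropped when (a) smaller than 1 mm², (b) their mean `G_V` falls below
the pot-level Otsu level, or (c) — when several survive — their centroid
lies outside the central 90 % of the pot *and* farther than 20 % of the
pot width from the largest survivor. Rules (b)–(c) are deterministic
stand-ins for local contrast/texture/position screening whose exact form
is not canonical; they are ordered so that refinement is idempotent, and
they only ever remove pixels. An entirely emptied pot is a valid result
(destructive harvest), not an error.

## Traits

With `p = px_per_mm`: projected leaf area = foreground count / `p²`;
perimeter = summed contour chain length / `p` (single-pixel components
count their 4-px boundary). The convex hull is taken over the *corners*
of the foreground pixels, so hull area is never below projected area and
compactness `100·A/A_hull` cannot exceed 100 by construction. Hull length
is the maximal point-pair distance (rotating-calipers diameter), hull
width the minimal perpendicular extent; both rotation-invariant.
Stockiness is `100·(4πA)/(2πR)²` with `R` = hull length / 2: exactly 100
for a circle, ~63.7 for a square, → 0 for a line. Greenness is the mean
clipped `G_V` over the hull region (not only over leaf pixels — soil
visible inside the hull lowers the reading; users comparing against
leaf-only definitions should note the difference).

The daily relative growth rate between consecutive images of a pot is

```
RGR = (ln A2 − ln A1) / ln A1 / (t2 − t1  in days)
```

including the normalisation by `ln A1`. This differs from the classical
`(ln A2 − ln A1)/Δt`; the normalised form is kept deliberately, with the
singularity at `A1 = 1 mm²` (and any empty pot) reported as an absent
value rather than a number. Capture times come from filename metadata;
without them consecutive images are taken to be one day apart.

## Leaf counting

Two routes, combined by `max`:

* **Skeleton end-points.** The pot mask is thinned (Zhang–Suen) to a
  1-px skeleton, spurs shorter than 2 mm are burnt off (iterative
  removal of degree-≤1 pixels, which cannot break connectivity), and
  end-points are found by four hit-or-miss kernels — a foreground pixel
  whose far side and both laterals are background, in each of the four
  orientations. The skeleton is also read as a weighted graph: mask
  centroid and end-points as vertices, one edge per end-point carrying
  (i) the geodesic length along the skeleton from the centroid-nearest
  skeleton pixel (8-connected, √2 diagonals) in mm and (ii) a leaf-area
  weight, the end-point's component area divided by its end-point count.
  Edges longer than 15 mm or heavier than 100 mm² count as long/large
  leaves; both thresholds are configurable.
* **Outline sweeping.** For each integer degree 0–359 the squared
  distance from the mask centroid (the mask centroid, not the hull's)
  to the farthest outline pixel in that angular bin; empty bins are
  interpolated circularly; the series is smoothed by a circular Gaussian
  (σ = 3°). Peaks are circular local maxima with prominence of at least
  5 % of the series range. A nearly flat series (range < 2 % of the
  mean) reads as one disc-like leaf object, so round seedlings are not
  reported as zero leaves.

Each route under-counts in known regimes — thinning misses small central
leaves, sweeping merges overlapping tips — so the combined count takes
the maximum. σ, the prominence floor and the flat guard are package
defaults chosen once for rasterised rosette geometry. Leaf counting is
not reported for wheat: tillering canopies violate both routes'
assumptions, and the pipeline emits empty count fields there.

## Synthetic data and what the tests show

`generate_synthetic_tray()` renders, deterministically per seed: a brown
soil background with speckle and grit, four red corner discs of known
radius, per-pot rosettes as rose-curve discs
`r(θ) = L(0.6 + 0.4·cos nθ)` whose `n` bumps model `n` well-separated
leaves (L defaults to 14–20 mm), optional harvested pots, optional
algae-like green speckles, and an optional red distractor bar. Defaults
emulate the study conditions: 2592 × 1944 frames, a 4 × 6 tray, 4-mm
markers. The generator returns the exact leaf mask, per-pot pixel
counts, leaf counts and marker geometry as ground truth.

The validation suite checks, among others: scale recovery within 5 %
over marker radii 10–40 px; marker-to-marker distances after full
calibration within 2 %; per-pot segmentation precision ≥ 0.95 and recall
≥ 0.90 on identity-geometry trays; projected area within 5 % and
compactness within 3 points of truth, and exact leaf counts for 2–12
petals in ≥ 90 % of 50 seeded single-pot instances (900 × 700 renders —
sizes chosen to keep the full suite comfortably re-runnable on one core).

What passing does **not** show: the renderer draws flat-green,
non-overlapping, centrally-placed rosettes without petioles, specular
highlights, shadows, wilting or leaf overlap, and its soil is
statistically stationary. Accuracy on real photographs — particularly
leaf counts for overlapping canopies — must be expected to be lower, and
the leaf-number traits should be treated as approximate counts, not
exact enumeration.

## Numerical and degenerate-input choices

* Otsu thresholds use a 256-bin histogram over the observed value range;
  a constant image returns its maximum, so "above threshold" is empty
  rather than arbitrary.
* k-means probe counts are reduced when an image has fewer distinct
  colours than probes; a constant greenness image yields an empty mask.
* Collinear or coincident marker centres raise a degenerate-geometry
  error rather than producing a folded homography.
* Empty pots propagate as zero traits and absent RGR/leaf counts; they
  never raise errors mid-series.
* Failed images are declined and logged; a series continues, and only a
  series with zero successes is marked failed.
* Batch concurrency is capped (default 3 forked workers) and every
  stochastic step is locally seeded, so outputs are byte-identical across
  worker counts and job orders.

## Known limitations

Pixel-level ground-truth comparison across the perspective warp is only
possible for identity-geometry renders; rotated-tray accuracy is asserted
via scale and distance recovery instead. The perimeter of sub-pixel-thin
structures is resolution-limited. Greenness-over-hull mixes soil into the
reading for sparse rosettes by design. The RGR definition is
non-classical (see above). Wheat support covers calibration and area/hull
traits only.
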