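---
title: "Counting every facet: the hexeye segmentation model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting every facet: the hexeye segmentation model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexeye)
```

## The problem

The *Drosophila* compound eye is a quasi-crystalline lattice of 600-1500
facets (ommatidia), each 15-22 um across. Eye size variation — driven by
genotype, sex, nutrition and temperature — is measured most directly by
counting ommatidia, but manual counts on scanning electron micrographs are
slow, and segmenting facets in 2D images is hard for three reasons: bristles
between facets occlude them unevenly, the dome-shaped corneas reflect light
differently across the curved eye, and peripheral facets are viewed at
steeply slanted angles that compress and crescent their apparent shape. Any
global detector with a fixed spacing assumption (e.g. Fourier-domain
periodicity detection) mislocates facets exactly where curvature matters
most, at the eye margin.

hexeye instead exploits the one thing that *is* invariant across the eye:
the lattice topology. Almost every ommatidium has exactly six neighbors.
Segmentation therefore proceeds in two phases:

1. **Pixel classification.** Two random forests, trained from sparse manual
   annotations, convert the image into an *eye probability map* (eye vs
   background) and a *facet probability map* (facet interior vs facet
   boundary).
2. **Hexagonal grid expansion.** Starting from three adjacent seed facets,
   new ommatidia are added one at a time: each registered triplet of
   mutually adjacent facets predicts where a fourth must lie (a point
   reflection), a three-circle template is fitted to the facet probability
   map near that prediction, and the best-fitting candidate on the whole
   frontier is registered next. Every facet so registered acquires a unique
   integer coordinate on the hexagonal lattice.

The integer coordinates are not bookkeeping: they make facets comparable
*across eyes* (the same lattice address in different individuals), define
columns whose count reads out the developmental column-founding process
(the morphogenetic furrow specifies one R8 founder column at a time along
the anterior-posterior axis), and give each facet its set of six neighbors
for 3D spacing measurements.

## Phase 1: pixel classification

**Features.** Each pixel is described by its raw intensity plus, at
smoothing scales sigma in {1, 2, 4, 8, 16} px: the Gaussian-blurred
intensity, gradient magnitude, Laplacian, both Hessian eigenvalues and the
local Gaussian-weighted variance (31 features). These cover the classic
trainable-segmentation feature families (edge, ridge, blob, texture) while
remaining fully deterministic. All filters use replicate boundary handling;
kernels are capped at the image size so small images remain processable.

**Training data.** The user (or the synthetic generator) supplies the eye
outline and a set of labeled facet masks sampled from different eye regions
— center and periphery look different, so spatial spread matters more than
volume; ~150 facets (10-20% of an eye) suffice. Facet-*boundary* pixels are
not annotated directly; they are derived as the morphological gradient
(3 px box dilation minus erosion) of the annotated facet masks. The eye
model trains on inside-vs-outside the outline. Each class is capped at
50,000 pixels by seeded subsampling, bounding training time and making
training reproducible bit-for-bit given the seed.

**Classifiers.** Two probability forests of 100 trees each (ranger,
single-threaded for determinism, seeded). Tree depth and per-split feature
sampling follow the library defaults and are stored with the model object
together with the feature recipe; prediction refuses a recipe mismatch.

**Eye mask.** The eye region is the Otsu threshold of the eye probability
map — the split of a 256-bin histogram maximizing between-class variance,
computed in a rational form `(M0*W1 - M1*W0)^2 / (W0*W1)` that avoids
integer overflow and matches exhaustive search exactly — followed by
keeping the largest connected component and filling holes. The cleanup step
prevents satellite false-positive regions outside the eye (a known failure
mode on low-contrast, white-eyed samples) from admitting spurious facets.

## Phase 2: hexagonal grid expansion

**Coordinates.** Each ommatidium carries an integer pair `(x_hex, y_hex)`
and a continuous image position `(x, y)` in pixels (0-based, x = column,
y = row, origin top-left). Two ommatidia are neighbors iff their hex
difference is one of (1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1). The seed
triplet takes coordinates (0,0), (1,0), (0,1).

**Mirroring.** For mutually adjacent registered ommatidia 1, 2, 3, the
fourth is predicted by point reflection of ommatidium 1 through the
midpoint of 2 and 3: `hex4 = hex2 + hex3 - hex1`,
`pos4 = pos2 + pos3 - pos1`. The reflection is an involution, which the
test suite checks exactly.

**The scale parameter.** `L_grid` is the mean distance between the image
positions of all currently registered hex-adjacent pairs, recomputed
(incrementally, as a running global mean) after every acceptance. It sets
the template size and every search radius. A global rather than locally
windowed mean was chosen because the average is stated once for the whole
grid; local spacing variation is instead absorbed by the affine template
fit, which stretches with the actual ear positions.

**Template.** The "Mickey" template is an `m x m` image of three filled
circles of radius `0.225 m` whose centers form an equilateral triangle of
side `0.5 m`: two "ears" anchored on the known pair (ommatidia 2 and 3) and
one "face" at the candidate position. The binary pattern is smoothed with a
Gaussian of `sigma = m/20`; pixels farther than `0.05 m` from all three
circles are NaN and never scored, so surrounding ommatidia cannot
interfere. `m = round(2 L_grid)` ties the circle radius (`~0.45 L_grid`) to
the facet radius; `m >= 20` keeps `sigma >= 1` px. The anchor x-positions
are centered on the pixel-grid mirror axis `(m-1)/2`, making the discrete
template exactly symmetric under swapping the ears — the objective then
provably does not depend on ear order.

**Fit objective.** An affine map `A` is solved exactly from the three
anchor/target pairs (ear1, ear2, candidate face). For each non-NaN template
pixel `(i, j)` with value `t`, the facet probability map is sampled
bilinearly at `A(i, j)` (out-of-image samples read 0), giving pairs
`(p, t)`. The objective is the squared error
`Delta(x4, y4) = sum (p - theta * t)^2` with the brightness parameter
`theta` free; since `Delta` is quadratic in `theta`, the optimum
`theta* = sum(p t) / sum(t^2)` is closed-form (verified against a 1-D
brute-force scan in the tests). Candidate face positions are scanned on the
integer pixel grid within a disk of radius `0.3 L_grid` around the mirror
prediction — positions farther than that are rejected outright, so a wider
scan is pointless — followed by parabolic sub-pixel refinement along each
axis (kept only if it does not worsen the objective, and clamped to the
disk).

**Rejection constraints.** A candidate is rejected (`Delta = +Inf`) when:

* `theta* < 0.1`: the scored region is nearly empty probability. Without
  this floor, a template fitted to pure background yields a deceptively
  *small* squared error (both `p` and `theta t` near 0), which would let
  the grid creep into blank regions. The floor also realizes the hard
  distance rule: when the only plausible facet lies beyond `0.3 L_grid`,
  the search disk contains only background and the fit is rejected rather
  than returning a meaningless local optimum.
* the facet's apparent tilt leaves less than 20 degrees between the viewing
  axis and the facet plane. The tilt ("top view angle") is computed from
  the singular values `s_min <= s_max` of `A`'s linear part as
  `acos(s_min / s_max)`: an untilted facet maps the equilateral template
  triangle to an equilateral image triangle (`ratio 1`, slant 0), while
  foreshortening compresses one axis.
* the tilt differs from that of the mirrored ommatidium by more than 30
  degrees (configurable): facet orientation changes gradually across the
  eye, so a sudden jump marks a bad fit.

**Expansion order and acceptance.** All proposals go into one global
priority queue keyed by `Delta`; the best fit anywhere on the perimeter is
accepted first (ties broken lexicographically by hex coordinate, making
expansion deterministic). At acceptance time a proposal must still pass:
slot unoccupied; fitted center inside the eye mask (proposals are not even
fitted when the mirror prediction falls outside it); fitted center within
`L_grid / 2` of its prediction; and at least `L_grid / 2` away from every
registered ommatidium — together with hex uniqueness this is what
guarantees zero duplicate registrations. Each acceptance spawns proposals
from the new triangles it completes. Expansion terminates when the queue
holds no admissible candidate (a configurable cap on additions exists as a
safety valve).

**Seeding.** Seeds may be given explicitly (three adjacent facets at the
eye center) or found automatically: the smoothed facet probability map is
thresholded into blobs, and the blob nearest the mask centroid is combined
with the pair of nearby blobs forming the *smallest near-equilateral*
triangle. Requiring near-equilateral rejects triplets contaminated by
second-ring neighbors (which sit `sqrt(3)` spacings apart and would skew
the lattice basis); preferring the smallest resolves the tie between the
first-ring and the — equally equilateral — second-ring triangle.

**Manual correction.** `remove_ommatidium()` and `add_manual()` provide
scriptable correction; an added position receives the hex coordinate of the
unoccupied mirror slot whose prediction lies nearest (within `L_grid`), or
failing that the open neighbor slot, among the few nearest registered
ommatidia, minimizing the residual of a local least-squares lattice fit.
`correct_grid()` batch-reconciles a grid against reference centers by
greedy closest-first one-to-one matching: unmatched registrations are
removed, unmatched references added.

## Morphometrics

* **Altitude.** With a multifocal brightfield stack, depth-from-focus
  assigns each pixel the plane maximizing the local variance of the
  Laplacian (window 9 px, the window being the one free parameter of the
  method; the depth map is median-filtered with the same window to suppress
  speckle before the all-in-focus image is assembled). Altitude is
  `(depth - min depth) * z_step` in um, i.e. relative to the lowest plane
  in use; the default step of 8 um matches typical macroscope acquisition.
* **Spacing.** Each ommatidium's size proxy is the mean 3D Euclidean
  distance (x, y scaled by the pixel size; z from altitude) to its
  hex-neighbors — adjacent lenses are juxtaposed, so center spacing tracks
  lens diameter. Isolated ommatidia are flagged and excluded, not errors.
  Rim ommatidia are *not* excluded by default although their spacing is
  less reliable (slanted view compresses them); they are identifiable by
  their neighbor count.
* **Smooth maps.** Spacing and altitude fields are summarized by a
  least-squares bivariate polynomial (degree 3 by default: low enough not
  to chase noise, high enough to place a single interior extremum off
  center, which is what an enlarged-facet "acute zone" looks like). The
  fit is computed on centered/scaled coordinates via QR; the reported peak
  is the raster argmax restricted to the convex hull of the data.
* **Columns.** The origin is moved to the ommatidium nearest the centroid
  of all positions ("center-most"), and one of the 12 lattice symmetries
  (6 rotations x optional axis swap — all adjacency-preserving) is applied
  so the most anterior ommatidium has positive hex coordinates; the column
  index `x_hex + y_hex` then increases posterior to anterior, following R8
  birth order. The anterior direction is an acquisition convention and must
  be supplied. Orientation ties are resolved by a fixed symmetry order and
  recorded on the result.
* **Cross-eye statistics.** Column profiles (ommatidia per column) are
  aligned by integer shifts minimizing the squared difference to the
  running mean, iterated to convergence — alignment is needed because the
  absolute column origin is arbitrary per eye. Spacing fields are averaged
  across eyes by hexagonal address, keeping addresses present in at least
  half the eyes (rim addresses vary between individuals and would otherwise
  dominate the projected map), and projected onto a reference eye's
  positions.

## The synthetic eye generator

Every stage above is exercised without microscopy data by a ground-truthed
generator that emulates the geometry and photometry the segmenter relies
on:

* **Geometry.** A hexagonal lattice (apex spacing 16 um — a typical
  *D. melanogaster* facet diameter) is laid out in the plane, optionally
  warped by a radial integral map that plants a Gaussian zone of enlarged
  spacing (default +20% amplitude, matching the observed range of spacing
  variation across real eyes), jittered by 0.3 um to mimic natural lattice
  irregularity, then wrapped onto a sphere through the Lambert equal-area
  azimuthal parameterization and projected orthographically (long
  working-distance optics make perspective negligible). Equal-area was
  chosen over the equidistant mapping deliberately: a hexagonal lattice
  cannot be laid isometrically on a sphere, and the equidistant map
  compresses tangential spacing by up to 17% at a 60-degree rim, a
  systematic artifact that would drown a planted 20% zone; the equal-area
  map balances radial stretch `1/cos(alpha/2)` against tangential
  compression `cos(alpha/2)`, keeping mean surface spacing uniform to ~4%.
* **Visibility.** The visible cap spans 60 degrees from the apex (a single
  lateral 2D view does not resolve facets much beyond that; facets beyond a
  75-degree slant cutoff are excluded as not visible). The eye mask ends
  where the facet surface ends: half a facet beyond the last ring *on the
  sphere*, foreshortened by the projection — getting this edge right
  matters, because the mask is what stops the grid from hallucinating a
  ring of ghost facets just outside the eye.
* **Photometry.** Facets are shaded domes (Lambert-ish slant shading)
  separated by dark boundary ridges of the Voronoi partition; a specular
  highlight is displaced from each center along the outward radial
  direction in proportion to the facet tilt (peripheral facets reflect
  asymmetrically); bristles are dark segments rooted at alternating lattice
  vertices (half density by default); the background is smooth texture;
  Gaussian noise (sd 0.02) is added. For focal stacks, each pixel is
  blurred in proportion to the distance between its facet's altitude and
  the focal plane (8 um step).
* **Ideal maps.** For testing the grid expansion in isolation, ideal
  probability maps replace the classifier: the facet map is a smoothed
  (sigma = 0.1 spacing) indicator of facet interiors (pixels within the
  facet disc and at least 0.12 spacing from the Voronoi ridge), the eye map
  a smoothed mask indicator.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: lattice dislocations (real eyes contain
point defects where a facet has 5 or 7 neighbors; the generator's topology
is perfect), structural mutants, uneven illumination, wet-surface glare,
inter-individual pigmentation differences beyond a contrast knob, and
out-of-plane eye motion between focal planes. On real micrographs the
residual error budget is dominated by exactly these effects, which is why
the scripted (or interactive) correction step remains part of the intended
workflow.

## Numerical and design choices, in one place

| Parameter | Default | Why |
|---|---|---|
| forest size | 100 trees | fixed by the classification design |
| per-class pixel cap | 50,000 | bounded, reproducible training |
| feature scales | 1-16 px | facet radii ~7 px at 1 um/px; covers edge to texture |
| Otsu bins | 256 | classic formulation, bit-exact vs exhaustive search |
| template size | `round(2 L_grid)`, min 20 | circle radius tracks facet radius; `sigma >= 1` |
| search disk | `0.3 L_grid` | hard rejection distance of the objective |
| acceptance radius | `L_grid / 2` | closest-candidate rule |
| min separation | `L_grid / 2` | duplicate suppression |
| `theta` floor | 0.1 | rejects background-only fits |
| view-angle floor | 20 deg | slanted-rim rejection |
| slant tolerance | 30 deg | facet orientation varies gradually |
| polynomial degree | 3 | single off-center extremum without overfitting |
| coverage threshold | 50% | rim addresses unstable across eyes |
| focus window | 9 px | depth-from-focus neighborhood (unspecified upstream; exposed) |

Degenerate inputs are contracts, not crashes: constant images have no Otsu
threshold; collinear seed triplets and collinear affine targets are
singular; empty masks, unknown hex coordinates, duplicate additions and
recipe mismatches raise informative errors; an empty expansion (mask
covering only the seeds) is a valid result.

The validation harness runs at deliberately moderate problem sizes — flat
patches of 61 facets for exact-recovery checks, curved eyes of roughly 600,
800 and 1500 facets for end-to-end runs, 20 replicates for the
planted-zone localization, 100-1000 random cases for the algebraic and
oracle-backed properties — chosen so the full suite exercises every claim
at biologically realistic scales.

## Known limitations

* The expansion assumes a defect-free lattice: real dislocations force one
  facet to a wrong (or no) hex address locally; counts are barely affected
  but per-address cross-eye averaging blurs around defects.
* The slant estimate comes from the fitted affine of a three-facet
  neighborhood; it is a noisy tilt proxy at the extreme rim, and rim
  spacing values should be treated with caution (flagged, not dropped).
* Grid label images use Euclidean nearest-center assignment restricted to
  the mask; for strongly non-convex masks a geodesic assignment would
  differ near concavities (compound eye masks are convex in practice).
* The classifier transfers across images only within an imaging setup; a
  new modality (SEM vs brightfield) needs retraining, by design.
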