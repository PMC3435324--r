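---
title: "Reconstructing the 3D luminal architecture of cribriform DCIS from serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the 3D luminal architecture of cribriform DCIS from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cribriform ductal carcinoma in situ (DCIS) is diagnosed from 2D histological
sections in which the intraductal cell mass is perforated by many small
luminal holes (cribra, or microlumina). Sections that look essentially
identical in 2D can come from very different 3D structures: isolated,
sponge-like cavities ("bubbles", plausibly left behind by localized
apoptosis) or connected channels that run the length of the duct ("tubes",
plausibly formed by merging papillary fronds into Roman arches). Because the
two architectures suggest different growth mechanisms, telling them apart may
carry prognostic information that 2D grading cannot.

`cribra3d` implements a fully automated route from a stack of H&E-stained
serial section photomicrographs of one duct to an architecture call:

1. **rigid alignment** of consecutive sections by normalized
   cross-correlation (NCC) template matching,
2. **duct segmentation** (cellular region vs background) from a custom
   hue transform,
3. **cribra segmentation** (microlumina within the duct) from adaptive
   equalization, restricted-range Otsu thresholding and mathematical
   morphology,
4. **3D reconstruction**: stacking the binary cribra masks at ~4 µm
   isotropic voxels, 3D connected components, per-voxel run-length
   morphometrics, surface meshes, and the bubble/tube/unclear call.

No human material is distributed with the package. A synthetic phantom
generator reproduces the relevant appearance of the specimens with full
ground truth (masks, applied rigid perturbations, architecture label), so
every stage can be validated quantitatively.

## Alignment

Consecutive sections are individually stained and mounted, so they differ in
position, orientation, and coloration. The registration model is rigid —
rotation plus translation only — which matches the physical acquisition
(sections are not deformed by the algorithm; tissue distortions are accepted
as noise).

Each section is registered to its already-aligned predecessor:

* the search runs at low resolution (longest side scaled to 500 px,
  grayscale with luminance weights 0.3/0.59/0.11 — the same weights as the
  V plane of the segmentation's color transform);
* a 150×150 template is anchored on the centroid of the largest dark object
  in the red channel (Otsu threshold; stained tissue is dark in red);
* rotation is searched first, about that centroid: a coarse sweep of ±20°
  in 1° steps, then refinement of ±1° in 0.1° steps around the best coarse
  angle. No published values exist for the range or step; sections rarely
  rotate more than ~20° on the slide and the two-stage search keeps the
  cost at ~60 correlation surfaces per pair;
* for each candidate angle, the translation maximizing NCC is found over a
  window of at most ±20% of the image side — the published bound that
  prevents false alignments onto background;
* the best (angle, translation) is rescaled (translation × scale factor,
  angle unchanged) and applied to the full-resolution image in a single
  bilinear resampling pass, with exposed areas filled black.

The NCC statistic subtracts the local window mean, so per-section staining
differences (approximately affine intensity changes) do not affect it.
Numerically, the surface is computed by FFT cross-correlation with integral
image window statistics; the brute-force double summation is kept in the
test suite as the oracle and the two agree to 10⁻¹⁰.

Numerical conventions: windows with (numerically) zero variance get γ = 0 so
flat background can never win; ties in the argmax are broken toward the
smallest |angle|, then the smallest shift, making the output deterministic;
a best correlation below 0.2 (configurable) flags the pair as an alignment
failure and substitutes the identity transform so the stack is never
aborted. Angular precision is content-dependent: where the template contains
sharp luminal edges the peak resolves to the 0.1° refinement step, while in
smooth tissue the peak is flat over ~1° and the recovered angle is only
guaranteed to the coarse step. The translation is recovered to within one
low-resolution pixel in either case.

The template is extracted from the unregistered image and scanned over the
base; the opposite convention differs only by the sign of the transform.

## Color transform and duct segmentation

Intensities in H&E photomicrographs typically occupy ~100–255. Each channel
is first stretched linearly onto 0–255. The stretch limits are the 1st/99th
intensity percentiles with two-sided clipping, not the literal extremes: the
minimum of several hundred thousand noisy pixels is an extreme-value
statistic that varies slice to slice and would make the downstream hue of
mid-dark tissue unstable (saturated percentile limits are the standard
convention of image processing toolboxes).

The custom HSV decomposition is

* `V = 0.3·Ir + 0.59·Ig + 0.11·Ib` (luminance),
* `Cr = Ir − V`, `Cb = Ib − V` (chroma),
* `H = arctan2(Cb, Cr)` in radians on (−π, π],
* `S = √(Cr² + Cb²)` (chroma magnitude).

Hematoxylin-stained nuclear tissue is purple: both `Cr` and `Cb` are
positive and `H` lies in the upper part of the first quadrant. The duct gate
keeps `H ≥ 0.7` (radians — the value the formula yields naturally; the cut
selects the purple quadrant) and excludes near-white pixels with stretched
red intensity above 150. The saturation formula is stated as the chroma
magnitude, the natural companion of the `arctan2` hue; no wrapping is
applied at −π (hues near −π are pink/magenta, not purple).

The binary mask is then cleaned with a fixed morphology chain: opening
(disc r=1) against salt noise and false connections, closing (disc r=3) for
small gaps, hole filling (lumina become part of the solid duct), removal of
objects below 2290 px² (about six 10 µm nuclei — too small to be ducts), a
large closing (disc r=9) restoring convexity, and a final hole fill. The
chain is idempotent on its own output.

## Cribra segmentation

Two candidate maps are combined.

**White lumina.** The green channel of the original image is adaptively
equalized over a 4×4 tile grid with bilinear blending (CLAHE). The clip
limit — bins clipped at a multiple of the mean bin count — defaults to 1.5.
The value is a free parameter of the method (none is published): strong
clipping (limit → 1) makes the equalization a no-op and forfeits its
robustness to staining gradients, while weak clipping rank-spreads the
nearly uniform interiors of empty lumina across the intensity range and
destroys them as segmentation targets; 1.5 preserves saturated lumina while
still flattening stain variation. Pixels more than one standard deviation
above the mean of the equalized plane define a restricted high-intensity
range; an Otsu threshold computed within that range, capped at 242,
separates lumina from the remaining bright material. The cap handles the
degenerate case in which the restricted sample is dominated by the lumen
plateau itself, where Otsu would split the plateau in half; empty lumina
image near the top of the 8-bit range, so a fixed 242 reliably keeps them.

**Pink debris.** Cellular debris inside lumina is eosin-stained and would
otherwise punch holes in the white map. The saturation plane of the
stretched image is rescaled to 0–255 and Otsu-binarized; the debris
candidate additionally requires a non-purple hue (`H < 0.7`), because
hematoxylin-stained tissue also carries chroma and a bare saturation
threshold would claim it.

The union is intersected with the duct mask and repaired: hole filling
(debris inside lumina), erosion (disc r=4) compensating the enlargement
produced by thresholding, closing (disc r=3) repairing crescent-shaped gaps
left by debris at the lumen rim, hole filling, opening (disc r=4) smoothing
ragged boundaries, a second hole fill, clearing of border-touching
(incompletely imaged) objects, and removal of objects under 100 px².

The mean+1·SD restriction is computed over the whole equalized slice (not
duct-only), and the red>150 white-exclusion uses the contrast-stretched red
channel — the same image the hue was computed from.

## 3D reconstruction and classification

Cribra masks are stacked and downsampled in-plane by the factor
slice thickness / pixel size (≈ 4.44 at 0.9 µm pixels), so one voxel is
~4 µm on every side — matching the section thickness, which fixes the z
resolution. Downsampling is by block mean with a 0.5 threshold: a voxel is
lumen iff at least half of its source block is lumen, which preserves thin
but real lumina better than nearest-neighbour sampling while suppressing
single-pixel noise.

Connected components use 6-connectivity (face adjacency): inter-slice
connection is overlap between successive sections, which is exactly z-face
adjacency; 26-connectivity is available via configuration. A component's
height is the number of distinct sections it occupies (identical to its
bounding z-extent under 6-connectivity, but stated for determinism). The
architecture call applies the published height rule to the largest
component: below 25 sections (100 µm) → bubble-like; above 35 sections
(140 µm) → tube-like; between → unclear. In-plane downsampling cannot change
the call since height is measured along z only. Stacks shorter than the
40-section inclusion criterion are processed but flagged. An empty lumen
volume yields "unclear" with zero height and a warning.

Morphometrics follow the per-voxel run-length convention: for a lumen voxel,
length/width/height are the maximal contiguous lumen runs through it along
x/y/z and the aspect ratio is height/length. 10 000 lumen voxels are sampled
uniformly **with replacement** under a caller-supplied seed (the sampling
scheme is otherwise unspecified); aspect ratio vs height is summarized by an
ordinary least-squares line reported as slope, intercept and the Euclidean
norm of residuals.

Surfaces are exported as the watertight boundary of the voxel volume (the
0.5 isosurface of the indicator function realized as outward-oriented voxel
faces, two triangles each) with area-weighted smoothed vertex normals, in
micron coordinates with z = section index × 4 µm, written as OBJ and PLY.
Enclosed mesh volumes are exact for this construction, which the tests
exploit.

## Validation metrics

Segmentation accuracy is scored pixelwise against ground-truth masks:
precision = 100·TP/(TP+FP), recall = 100·TP/(TP+FN), computed per image and
then summarized (median, mean, interquartile range with linear-interpolation
percentiles). An empty automatic mask against a non-empty truth scores
precision 0 and is flagged rather than dropped; two empty masks score 100
flagged. Swapping the two masks swaps FP and FN and hence the two scores,
which the tests verify on random mask pairs.

## The phantom generator

The generator emulates the published study material: single pre-cropped
cribriform ducts, 8-bit RGB, ~0.9 µm/pixel, 4 µm sections, at least 40
sections per specimen, image side 500–1500 px (default 700). Its defaults
are the package's study conditions:

* **duct**: a filled tube of roughly circular cross-section (radius
  0.34 × image side) with low-order harmonic boundary irregularity (±~9%)
  and slow axial modulation (±3%);
* **bubble architecture**: up to 8 disjoint rounded lumina with in-plane
  radius 27–42% of the duct radius (65–100 px ≈ 115–180 µm diameter at the
  default geometry — the upper part of the realistic range for cribriform
  microlumina, where boundary-scale segmentation effects stay small
  relative to the object) and a flat-topped
  `√(1−u⁴)` z-profile (punched-out holes resemble capped cylinders more
  than ellipsoids) spanning ≤21 sections — comfortably below the
  25-section rule;
* **tube architecture**: 3 near-vertical channels close to the duct border
  (where tube-like cribra are observed to run), wandering by a few pixels,
  spanning ≥36 of the ≥40 sections;
* **unclear**: one channel spanning exactly 30 sections plus small bubbles;
* **appearance**: four palette classes — purple duct tissue, near-white
  lumina, pale stroma/fat background, pink high-saturation debris placed in
  30% of cribra. The palette is verified programmatically against the
  segmentation constraints (duct hue ≥ 0.7 with margin at red ≤ 150; lumina
  at the top of the 8-bit range, as empty glass images under
  white-balanced microscope exposure) rather than hard-coded blindly.
  Duct tissue is modulated by a deep multiplicative stain-density field
  (amplitude 0.45; its dark tail anchors the contrast stretch the way dark
  nuclear regions do in real slides) and a cell-scale granularity field
  that partially persists between adjacent sections, which is what gives
  the rotation search sharp structure; empty lumina carry almost no
  texture. Each slice receives Gaussian optical blur (σ = 1 px), per-pixel
  channel noise (SD 3, typical of a cooled colour CCD), and a per-slice
  multiplicative stain jitter of ±8% applied to stained classes only —
  lumina follow the (much steadier) illumination;
* **misalignment**: per-slice rigid perturbations, continuous angles up to
  ±4° and integer shifts up to ±5% of the side by default (always below
  the 20% search bound so truth stays recoverable), recorded in the truth.

Determinism: the whole phantom is a pure function of its spec (including the
seed); rendering twice is bit-identical.

A constructor invariant re-applies the height rule to the generated volume
and rejects any spec whose realized geometry contradicts the requested
label.

What the phantom does **not** model: nucleus-level texture realism, stromal
fibre structure, tissue folds/tears, deformable (non-rigid) distortion,
immuno-infiltrate, and out-of-focus or vignetting artifacts. Passing the
phantom suite therefore demonstrates the machinery is correct and the
published constants are honoured under controlled conditions; it does not
certify performance on arbitrary clinical material.

## Problem sizes used by the tests

The test suite and the acceptance script validate at three scales, chosen as
the package's own compromise between coverage and runtime: full-default
phantoms (700 px, 40–60 sections) for segmentation scoring; 500 px phantoms
with ±15° / 15% perturbations for registration recovery over 20 section
pairs; and 320 px phantoms (duct radius 109 px, cribra 30–46 px, 40
sections) for the 12-specimen end-to-end architecture recovery, run with a
reduced search frame (250 px) and ±6° sweep appropriate to their ±4°
perturbations. Oracle equivalence (NCC, Otsu, flood fill, normal equations)
uses exhaustive brute force at small sizes.

## Known limitations

* Rigid alignment only; shrinkage and mounting deformations between
  sections are not corrected, consistent with the published method.
* The alignment failure mode (correlation floor 0.2) is a heuristic; the
  original work reports a failure rate but not a detection rule.
* The hue cut, area cut-offs, Otsu cap and disc radii are the published
  constants for ~0.9 µm/px imaging; material at other magnifications
  requires rescaling them.
* Component height is measured in sections; partial specimens shorter than
  40 sections are flagged, not rescaled, so their calls are conservative.
* The CLAHE clip limit is a free parameter (see above); extreme staining
  artifacts (e.g. heavy immuno-infiltrate) are known to defeat the duct
  segmentation and are excluded rather than repaired.
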