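---
title: "stomapipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stomapipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, numerical choices and design decisions
behind `stomapipe`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic validation does and does
not demonstrate about real images.

## 1. Optical calibration

A `magnification_profile` carries four constants per lens: pixel density
(px/mm on the specimen plane), field-of-view width and height (mm), and
resolving power (um). The three built-in profiles describe a handheld field
microscope's 100x, 200x and 400x objectives (198, 415 and 652 px/mm). All
unit conversions are exact arithmetic on these constants: lengths scale by
`1000 / px_per_mm`, areas by its square. Both the pixel density and the
printed field of view are taken at face value; the sensor's pixel dimensions
are not independently known, so the two cannot be cross-checked against each
other. When an image's pixel extent disagrees with `FOV x px_per_mm` by more
than 5% we warn and proceed with the profile's constants, since capture
software may letterbox or rescale frames.

Stomatal density divides the per-image count by the **full optical field of
view**, not by the pixel extent of a possibly cropped image; an explicit
`area_mm2` override exists for cropped inputs. Units follow stomatal
convention: lengths in um, areas in um^2, densities in mm^-2.

Non-goals: lens distortion and non-square pixels are not modelled.

## 2. Synthetic leaf scenes

The generator produces grayscale 8-bit images plus exact ground truth, and
is deterministic: a `scene_spec` (including its seed) renders bit-identical
output. Two patterning modes cover the major leaf types:

* **rows** (graminoid): stomatal files parallel to the leaf axis at
  `row_pitch_um` spacing. Along each file, positions follow an exact uniform
  hard-core model: to place *k* centres with minimum gap *d* in a file of
  length *L*, we draw *k* sorted uniforms on `[0, L - (k-1)d]` and re-inflate
  by *d* — this reaches the full packing capacity `floor(L/d) + 1` without
  rejection sampling. Orientations align with the file up to Gaussian jitter
  (default sd 5 degrees).
* **scattered** (dicot): sequential random placement with hard-core
  rejection (minimum centre distance `min_spacing_um`), uniform orientations.

The per-scene count is Poisson with mean `target_density x imaged area`, so
realized counts fluctuate as real leaves do. In rows mode a fluctuation
above the hard packing capacity saturates at the capacity; a *target* that
exceeds capacity on average raises a packing error naming the achievable
maximum, as does rejection failure in scattered mode.

Stomatal complexes are ellipses (length x width drawn from truncated
normals, sd 8% of the mean) with a darker outline ring, either a dumbbell
silhouette (end lobes plus a central bar; rows mode) or an inner guard-cell
ellipse (scattered mode), and a dark aperture ellipse whose width is
`openness x complex width`. Openness is drawn per stoma (default mean 0.3,
sd 0.12, truncated to [0, 0.85]); draws at or below 0.05, or apertures
thinner than 1.2 px, render as closed stomata with no aperture polygon.

Degradations, in order: Gaussian optical blur with
`sd_px = resolving_power_um x px_per_mm / 1000 / 2` — resolving power is
read as the FWHM-scale width of the point spread and halved as a
conservative stand-in for the unknown true PSF; bright soft-edged discs
mimicking the air bubbles that plague imprint samples; a multiplicative
left-right illumination ramp; additive Gaussian sensor noise; 8-bit
quantization. Defaults (noise sd 0.02, gradient amplitude 0.15, one bubble
of 15-40 um) define the "moderate degradation" condition used throughout
the tests.

**Archetype dimensions are model defaults, not literature measurements.**
The built-ins (wheat-like 60 x 32 um complexes at 50 mm^-2; rice-like
25 x 14 um at 250 mm^-2; tomato-like 26 x 18 um at 120 mm^-2) respect the
qualitative ordering visible in leaf micrographs — wheat stomata much larger
than rice or tomato, rice the densest — and sit within ranges a plant
physiologist would call plausible for these crops, but no published
per-species dimensions back them and they should be reconfigured when
emulating a specific dataset.

Ground-truth polygons are 64-gons of the underlying ellipses; their
shoelace areas agree with the stored analytic areas (`pi a b`) to well
within the documented 2% rasterization tolerance. The default border policy
culls any complex that would cross the image edge (unambiguous ground
truth); `keep-clipped` retains them with clipped polygons for robustness
tests.

What the generator does **not** emulate: pavement-cell mosaics, trichomes,
focus variation across the leaf, imprint tearing, colour, and the texture
statistics of real epidermis. Passing the synthetic recovery tests therefore
demonstrates the correctness and internal consistency of the chain — not
detector performance on real micrographs, which depends on a trained model
outside this package's scope.

## 3. Classical detection

The built-in detector is a deliberately simple, deterministic stand-in for a
trained deep detector (whose outputs can instead be ingested via the
normalized-box adapter). It renders a small bank of noise-free stoma
templates (one per configured orientation) at the expected complex size,
computes normalized cross-correlation via FFT filtering with local-variance
normalization, takes local score maxima above `match_threshold` (default
0.5), forms boxes at the matching template's extent and applies greedy NMS
at `nms_iou = 0.3` — stomata are non-overlapping organs, so aggressive
suppression is safe. Confidence ties in NMS break by larger area, then
input order, for determinism. Rowed archetypes use a single axis-aligned
template; scattered archetypes a 30-degree fan. An expected length mapping
to fewer than 4 px at the chosen profile is refused with advice to use a
higher magnification — this mirrors practice, where small-stomata species
are only usable at 400x.

Box convention everywhere: 0-based pixel coordinates, half-open
`[x, x+w) x [y, y+h)`, which makes area and IoU arithmetic exact.

## 4. Segmentation and traits

Each detection is cropped with 35% padding per side. Within the crop:

1. Gaussian pre-smoothing (sd 0.6 px) suppresses sensor noise without
   erasing the aperture slit.
2. The complex/background split uses the **iterative intermeans
   (Ridler-Calvard) threshold**. A between-class-variance criterion can cut
   *inside* the complex here, because the foreground is multi-modal (fill,
   guard cells, outline, aperture); intermeans initialized at the crop mean
   settles on the dominant background/foreground split.
3. Morphological closing (5 px disc), hole filling, and selection of the
   most central sufficiently large component.
4. The final outline is re-extracted at **sub-pixel precision** as the
   iso-intensity contour (marching squares) at the midpoint between the
   local background level and the component's boundary-band level. For a
   symmetric point spread the 50% crossing of an edge is its unbiased
   location, and the sub-pixel contour removes the pixel-quantization noise
   that dominates area error for small (10-20 px) stomata.
5. An outline whose bounds span nearly the whole padded crop indicates a
   merge with a neighbouring stoma; such cases are flagged as failed
   measurements rather than reported as fused areas.
6. The aperture is searched only inside the **eroded** complex interior (so
   the dark outline ring cannot masquerade as a pore), at a stricter
   threshold halfway between the interior's 2nd percentile and median. A
   candidate is accepted only if it is large enough (>= 2% of complex
   area), slit-like (moment-ellipse elongation >= 2) and dark enough (mean
   intensity <= 0.7 of the interior mean). The three guards suppress
   specular specks and, on closed stomata, reject the guard-cell region
   whose contrast is far milder than an open pore's.

"Stomatal size" is the area of the **full complex outline including
subsidiary cells**, matching the annotation convention used when outlining
stomata for measurement models; guard-cell-only area is out of scope.
Lengths are full moment-ellipse axes (for a polygon, from exact
Green's-theorem moment integrals; `4 sqrt(eigenvalue)` recovers a true
ellipse's axes). Because no single scalar is canonically "the aperture",
the headline aperture trait is the aperture length, with width and area also
reported and openness defined as aperture width / complex width; comparison
operations accept any trait column.

Detections touching the image border are counted (preserving density) but
excluded from size and aperture statistics, since truncated organs bias
sizes. Whether manual counts include border-truncated stomata is genuinely
ambiguous; counting them is the choice that keeps densities comparable
across methods.

## 5. Evaluation

Matching is greedy in descending confidence (ties: higher best-available
IoU, then input order); each prediction takes the unmatched ground-truth box
of highest IoU if that IoU reaches the threshold (default 0.5, the
convention of the detector family whose outputs the adapters ingest).
Greedy confidence-ordered matching is standard detector-evaluation practice;
an exhaustive maximum-cardinality oracle in the tests confirms it is within
one true positive of optimal on small instances and exactly optimal whenever
no prediction is IoU-feasible for two ground-truth boxes. With zero
predictions, precision is defined as 1 (no false claims were made) and
recall 0; zero-ground-truth images give recall 1. F1 is the harmonic mean,
0 when precision + recall = 0. mAP is deliberately not computed — the
published model statistics the package reproduces are single
precision/recall/F1 operating points, whose matching criterion and
confidence threshold are unstated; those table values are therefore used
only as worked examples for the F1 arithmetic, never as pipeline-reproduction
targets.

Mask-level agreement is polygon IoU via exact polygon clipping.

## 6. Comparison operations

Automated values regress **on** manual values (y on x) so calibration bias
stays visible in the slope and intercept even when R^2 is high; R^2 is the
coefficient of determination `1 - SS_res / SS_tot` of the OLS fit. Counts
compare per image; sizes and apertures compare as per-image means, because
per-stoma pairing across methods has no defined correspondence rule. The
contrast screen ranks images by density, reports the top and bottom
quantile groups (default 0.2; group sizes sum to `ceiling(2 q n)` with ties
broken by image id) and a Spearman-type rank correlation — computed by
explicit rank transform — between density and mean complex area, surfacing
the many-small vs few-large trade-off. Published R^2 values for automated
vs manual agreement on real images are not reproduction targets: they
require the original images and trained models.

## 7. Problem sizes and determinism

The test suite and the acceptance script exercise: 20 scenes per archetype
(three archetypes, ~3,600 stomata) for the recovery experiment; 1,000
random instances (<= 6 x 6) for the matching oracle; and small fixture sets
for the orchestration tests — sizes chosen so a full run stays comfortable
on a single CPU while keeping Monte-Carlo noise well below the test
tolerances. Every random draw flows through per-scene integer seeds;
pipelines re-run bit-identically, and the run manifest (config, package
version, per-image status) suffices to reproduce a batch run exactly.

## 8. Known limitations

* The classical detector assumes roughly elliptical dark-on-light stomata at
  a known scale; it is not expected to match trained models on real images.
* Aperture measurement degrades when the open slit is narrower than about
  2 px after blur — at 400x, roughly 3 um — and apertures below the
  acceptance guards are reported as closed.
* Polygon-based trait extraction assumes simple (non-self-intersecting)
  outlines; exotic morphologies (e.g. cyclocytic complexes) are untested.
* Stomatal conductance modelling and morphotype classification are out of
  scope.
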