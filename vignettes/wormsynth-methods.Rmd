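---
title: "Synthetic worm scenes, self-labeling and replicate statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic worm scenes, self-labeling and replicate statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormsynth)
```

## Scope and intent

`wormsynth` implements, at desk scale and on a CPU, the computational
methodology around generalist *C. elegans* detection: synthetic
detection-dataset generation with automatic bounding-box labels, the
count-filtered supervised self-labeling curation loop, detection evaluation
(precision, recall, AP@0.5), and the small-sample statistics used to compare
detector training methods across replicates. Training of the neural
detectors themselves (YOLO-family networks) and learned appearance models
(GAN image synthesis, style transfer) are deliberately out of scope: they
need GPUs and curated real data. Where such a learned component sits in the
original workflow, this package keeps the identical dataflow but substitutes
a procedural component, so the surrounding logic — auto-labeling, count
filtering, evaluation, statistics — is exercised under controlled,
reproducible conditions.

## Worm shape model

A worm body is modelled as a sinusoidal centerline with a power-law tapered
width profile:

* the centerline is `y = A sin(2πx/λ + φ)`, traced until its arclength
  reaches the body length `L`, resampled to roughly equal arclength spacing
  (about one vertex per 2.5 px), and rigidly rotated by a uniform angle;
* the half-width at normalized arclength `s ∈ [0, 1]` is
  `w(s) = w_max (4 s (1 − s))^τ`, zero at the tips and maximal mid-body;
* the mask is the union of disks along the densified centerline (0.5 px
  spacing), i.e. a stroked variable-width tube, rasterized on a canvas with
  a 2 px background margin.

This is the simplest model that yields the elongated, undulating,
stadium-like silhouettes seen in plate microscopy. It deliberately excludes
coiling, omega turns, self-overlap and 3-D effects; passing tests on these
shapes therefore says nothing about detector performance on coiled or
aggregated animals.

Strain presets encode the two classic mutant morphologies used for
robustness probing. Wild-type worms are 200–400 px long with 8–14 px
half-width; the dumpy-like preset halves the length and multiplies the
half-width by 1.8 ("short and wide"), the long-like preset multiplies
length by 1.5 and half-width by 0.7 ("long and narrow"). The numeric ranges
are this package's own choice, sized so a worm occupies a realistic
fraction of a 640 px field of view at typical plate-camera resolution;
undulation amplitude is 5–20 % and wavelength 40–100 % of body length,
taper exponent 0.8. The ordering contrasts (dumpy squatter than wild type,
wild type squatter than long) hold for *every* draw, not just on average,
and are property-tested.

Self-intersection of a sampled centerline is impossible for a rigidly
transformed sinusoid graph, but the sampler still checks each polyline with
a segment-pair test and redraws up to 20 times, because user-supplied
parameter ranges (amplitude much larger than wavelength) could in principle
produce degenerate geometry; exhausting the budget is an error, never a
silent fallback.

Connected-component arithmetic uses 8-connectivity throughout (a diagonal
step keeps a worm whole). The union-of-disks rasterizer additionally traces
the densified centerline pixel-by-pixel, which guarantees a single
8-connected component even where the tapered radius drops below the pixel
grid near the tips.

## Appearance and scene model

The appearance model is procedural: body pixels are shaded
`N(fg_mean, fg_std)` modulated by band-limited texture, a one-pixel outline
band is darkened by `edge_gain` (lightened for inverted polarity), and the
crop is blurred by `blur_sigma`. Backgrounds are a base intensity with
Gaussian grain, an 8×8 low-frequency mottle field upsampled to the canvas
(uneven agar/illumination), a radial vignette and sparse salt speckle.
Defaults (dark worms at 0.25 on agar at 0.78, grain 0.02, speckle 2×10⁻⁵)
give the high-contrast, low-noise regime of a well-configured plate imager.
What this emulates is the dominant photometric character of such imagery;
what it does not emulate is real optics (depth of focus, condensation,
reflections), real agar artefacts, or the appearance diversity a learned
image-to-image model would produce. Results on these scenes are therefore
an internal consistency check of the pipeline, not evidence about real
data.

Scenes place `n` rendered worms by rejection sampling positions and exact
quarter-turn rotations (continuous rotation is already applied at the
centerline stage; quarter-turn raster rotation is lossless, so the placed
mask — and hence the auto-label — stays exact). The default overlap policy
forbids touching masks, since worm aggregation is a known error source for
detectors and the clean case is the baseline; the pairwise overlap
fraction is configurable. A worm that cannot be placed within 60 tries is
dropped with a warning and the scene is flagged, never silently padded.
Because placement records the final mask of every worm, each label is by
construction the tight bounding box of the rendered object — the property
that makes synthetic data "free" of labeling cost — and the test suite
verifies tightness against a per-pixel oracle on every generated scene it
touches.

## Augmentation conventions

The augmentation defaults mirror the standard single-stage-detector recipe:
HSV gains (0.015, 0.7, 0.4), translation 0.1, scale 0.5, horizontal flip
probability 0.5, mosaic probability 1, and letterboxing to a square
multiple of 32 (default 1728). Points where the convention is
underspecified were resolved as follows: HSV jitter draws one
multiplicative gain per channel with hue wrapping, and degrades to a pure
value gain on grayscale input (most worm imagery is monochrome); the mosaic
split point is drawn uniformly in the central 50 % of each dimension and
boxes with less than 8 px² visible area after clipping are dropped (the
same floor as the affine augmenter); letterbox padding uses the image
median rather than a fixed grey so no artificial high-contrast border is
introduced. The letterbox transform record makes the label mapping exactly
invertible, which the tests exercise round-trip.

## Baseline detector

The baseline detector is a classical, training-free pipeline so that
self-labeling and evaluation can run end-to-end on a CPU: background
flattening (subtract a large-σ Gaussian estimate, default σ = 25 px ≫ worm
half-width), polarity resolution by the sign of the residual's third
moment, Otsu thresholding of the rectified residual floored at a robust
noise level (6 × MAD of the residual — otherwise a worm-free image would be
segmented into noise blobs), 8-connected components, then area
(150–10⁶ px²) and elongation filters. Elongation is the square root of the
ratio of the component's principal second moments; the floor of 1.3
suppresses round speckle (which sits at 1) while keeping strongly curled
worms, whose moment ratio can fall well below the ~2 of an extended
animal. Component confidence is its mean rectified residual, normalized to
(0, 1] per image; `max_detections` keeps the top-confidence boxes, which is
the inference cap the self-labeling procedure relies on.

On the default (easy) synthetic preset this detector clears AP@0.5 ≥ 0.9
over 200 seeded scenes — an internal quality bar that makes the
self-labeling loop meaningful, not a claim about real microscopy.

## Supervised self-labeling

The curation loop takes a pool of unlabeled images with *known* per-image
worm counts: (1) group images by expected count; (2) run inference with the
per-image detection cap set to that count, so overcounting is impossible;
(3) keep an image only if the detected count equals the expected count,
tagging deletions as `zero-detections` or `undercount`; (4) a human reviews
the kept images and accepts or rejects each (the package defines the
decision-file contract rather than automating the judgement); (5) accepted
detections are re-emitted as 5-column label files and the loop repeats with
an improved detector. Two conventions are fixed deliberately: confidence
ties at the cap break by file order (deterministic), and "deleted" is a
logical flag in the filter report rather than file removal, so every
iteration is auditable. The iteration log enforces that cumulative accepted
counts never decrease. Time saved by auto-labeling is reported as
`worms × 5 s / 3600`, at one decimal, 5 s being a realistic manual pace for
drawing one worm box.

## Evaluation metrics

Matching is greedy in descending confidence (PASCAL-VOC convention): each
detection takes the unmatched ground truth of highest IoU at or above the
threshold (default 0.5); ties on confidence break by row order and ties on
IoU by first ground truth. Precision is TP/(TP+FP), recall TP/(TP+FN), with
a zero denominator returning 0 plus an explicit degenerate flag rather than
an error, so batch evaluation is robust. Dataset AP pools all detections
across images under a global confidence ranking and integrates the
right-maximum precision envelope exactly over all curve points; the
101-point interpolated variant used by YOLO tooling is available behind
`method = "interp101"` for comparability (the difference is below 0.01 on
realistic curves). AP is invariant to monotone transforms of confidence and
can only fall when a lowest-confidence false positive is appended — both
property-tested, along with equality against a brute-force threshold-sweep
oracle on all small instances.

## Replicate statistics

Training-method comparisons rest on three test-set AP@0.5 replicates per
method. Normality of each triple is checked with the *exact* n = 3
Shapiro–Wilk form: `W = 0.5 (x₍₃₎ − x₍₁₎)² / Σ(xᵢ − x̄)²` with
`p = (6/π)(asin √W − asin √0.75)`; at n = 3 this closed form is exact and
preferable to the large-n approximation (which `shapiro_wilk()` still
provides for other n). The method comparison then uses a **paired**,
**two-sided** Student's t-test with replicates paired by index
(df = n − 1 = 2); the pairing choice is this package's central inference
about the procedure behind such comparison tables — paired on the bundled
replicate table it reproduces all three published-style p-values
(≈ 0.054, 0.014, 0.007) while unpaired variants do not. For df = 2 the
p-value has the closed form `1 − |t|/√(t² + 2)`, which the tests require to
machine precision. Reproduction tolerances are ±0.001 on t-test p-values
and ±0.005 on the Shapiro–Wilk p, the spread induced by the inputs being
recorded at three decimals. The Wilcoxon signed-rank fallback for
non-normal triples is intentionally not implemented: normality is never
rejected on the bundled table, and at n = 3 the signed-rank test cannot
reach significance anyway.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; a single root seed is expanded into
per-stage streams with a deterministic integer map (`derive_seed`), so the
whole pipeline — masks, appearance, placement, augmentation — is a pure
function of `(config, seed)`, tested down to bit-identical images and JSON
summaries. The bundled demonstration uses 200 evaluation scenes and a
100-image self-labeling pool on a 640×640 canvas with 1–5 worms per scene;
these sizes give stable dataset-level metrics (about 600 worms) while
keeping a full run in the minutes range on one CPU core. Degenerate inputs
are defined, not accidental: zero-amplitude undulation gives a straight
worm, an empty scene returns the background exactly, empty label files
parse to zero objects, and zero-variance triples are errors rather than
NaNs.

## Known limitations

* Shape realism stops at non-self-intersecting tubes; coiled, touching or
  clustered worms are not modelled, and the default scene forbids mask
  overlap entirely.
* The procedural appearance model spans a narrow, parametric slice of real
  imaging variability; it cannot stand in for learned appearance synthesis
  when the question is generalization across capture systems.
* The baseline detector is intentionally simple; its failure modes (merged
  nearby worms, faint worms near the noise floor) differ from those of a
  trained network, so self-labeling yield curves here are illustrative of
  the mechanism, not of any particular detector's behaviour.
* The replicate-statistics harness assumes exactly three replicates in the
  bundled table; the general-n paths exist but the exact n = 3 forms are
  the default and the tested surface.
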