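# wormsynth

Synthetic *C. elegans* detection datasets, supervised self-labeling and
evaluation, in R.

Labeling worms in plate microscopy is the bottleneck of detection-based
assays (lifespan, healthspan, tracking): a trained annotator needs about
5 seconds per worm, and a useful training set contains tens of thousands of
them. `wormsynth` implements the desk-scale computational machinery that
removes that bottleneck and measures whether it worked:

* **Parametric worm masks** — sinusoidal centerline, power-tapered width
  `w(s) = w_max (4s(1−s))^τ`, rasterized as a single 8-connected tube; with
  presets for wild-type, dumpy-like (short, wide) and long-like (long,
  narrow) strain morphologies.
* **Procedural scene rendering with free labels** — worms composited onto
  synthetic agar backgrounds (grain, mottle, vignette, speckle; either
  polarity); because every placed mask is known, each YOLO-format bounding
  box is tight by construction.
* **Detector-style augmentation** — HSV jitter (0.015/0.7/0.4),
  translate/scale/flip, 2×2 mosaic, letterbox resize to a multiple of 32
  with an exactly invertible label transform.
* **A classical CPU baseline detector** — background flattening, Otsu with
  a robust noise floor, component area/elongation filters, per-image
  detection cap (`max_detections`).
* **Supervised self-labeling** — group images by known worm count, run
  count-capped inference, keep only images where detected = expected,
  export a human review queue, re-emit accepted detections as labels, and
  log iterations.
* **Evaluation** — IoU, greedy confidence-ordered matching,
  Precision = TP/(TP+FP), Recall = TP/(TP+FN), and AP@0.5 as the exact area
  under the monotone precision envelope (101-point variant available).
* **Replicate statistics** — exact n = 3 Shapiro–Wilk
  (`W = 0.5(x₍₃₎−x₍₁₎)²/Σ(xᵢ−x̄)²`, `p = (6/π)(asin√W − asin√0.75)`) and
  paired two-sided Student's t-tests for comparing training methods from
  AP@0.5 replicate triples.

## Worked example

```r
library(wormsynth)

# one labelled scene: 4 worms on a 640x640 synthetic agar background
sc <- generate_scene(seed = 5, spec = scene_spec(n_worms = 4))
sc$labels
#>   class        cx        cy         w         h
#> 1     0 0.9218750 0.2367188 0.1468750 0.2890625
#> 2     0 0.3460937 0.4437500 0.4046875 0.1156250
#> 3     0 0.4828125 0.6093750 0.2687500 0.1000000
#> 4     0 0.2804687 0.8093750 0.1921875 0.1718750

# detect and evaluate
det <- detect_worms(sc$image)
evaluate_dataset(list(img1 = det), list(img1 = sc$labels),
                 image_shape = dim(sc$image))
#> Detection evaluation (IoU >= 0.50)
#>   images: 1   TP: 4   FP: 0   FN: 0
#>   Precision: 1.000   Recall: 1.000   AP: 1.000

# compare detector training methods from bundled AP@0.5 replicate triples
compare_methods()
#> Method comparison (paired t-test on AP@0.5 replicates)
#>   style_transfer   p = 0.0544  (t = 4.11, df = 2, mean gain +0.030)
#>   pix2pix          p = 0.0138  (t = 8.44, df = 2, mean gain +0.111)
#>   self_labeling    p = 0.0074  (t = 11.53, df = 2, mean gain +0.073)

# hours of manual annotation avoided by auto-labeling 10,468 worms
estimate_time_saved(10468)
#> [1] 14.5
```

Each label row is one worm in normalized `class cx cy w h` form; the
comparison table says style transfer improves AP@0.5 with borderline
significance (p ≈ 0.054) while mask-conditioned synthesis and
self-labeling improve it significantly (p ≈ 0.014 and 0.007). A
command-line front end with the same functionality is installed under
`exec/wormsynth` (subcommands `generate`, `detect`, `selflabel`,
`selflabel-apply`, `evaluate`, `stats`, `demo`).

See the methods vignette (`vignettes/wormsynth-methods.Rmd`) for the shape
and appearance models, the matching and integration conventions, and the
statistical procedure in detail.

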