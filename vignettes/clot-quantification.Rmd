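---
title: "Quantifying stroke clot composition by trainable pixel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stroke clot composition by trainable pixel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

H&E staining renders the three major components of an acute ischemic stroke
clot in distinct colors: red blood cells red, white-blood-cell nuclei
blue-purple, fibrin pink. Scanned slides additionally contain background
and preparation artefacts, most commonly tissue folds, which must not enter
the quantification. ClotQuant follows the two-stage trainable segmentation
design used in machine-learning histology tools:

1. **Features.** Around every pixel, a `(2r+1) × (2r+1)` window is
   summarized by six scalars per RGB channel: minimum, maximum, mean,
   population variance, edge factor, and the center pixel value — 18
   features, channel-major order. The *edge factor* is the window mean of
   the gradient magnitude, with the gradient taken as horizontal and
   vertical central differences `(f(x+1) − f(x−1))/2` and combined by
   Euclidean norm. Windows near the border are completed by symmetric
   reflection (border pixel repeated), which is defined for any radius.
2. **Classifiers.** A radial-basis-kernel SVM is trained per task on
   standardized features, one-vs-one with majority vote. The *exclusion*
   model separates background / tissue / artefact; the *classification*
   model separates RBC / WBC / fibrin. Combined into the *Main* model, the
   exclusion stage labels every pixel and only its tissue pixels are passed
   to the classification stage, so an excluded pixel can never receive a
   tissue-class label.
3. **Quantification.** Composition percentages are taken over classified
   tissue pixels; background and artefact counts are reported but excluded
   from the denominator. Clots are categorized RBC-rich (≥ 60% RBC),
   fibrin-rich (≥ 60% fibrin), otherwise mixed.

The key assumptions are those of the underlying workflow: classes are
distinguishable from local color and texture at the analysis resolution;
annotated regions are pure (single-class); staining variability across the
batch is represented in the training images.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `windowRadius` | 4 (9 × 9 window) | px | spans a red blood cell at a typical 20x-derived working resolution; the window must be large enough to capture texture but small enough that most windows are single-class |
| `perClass` | 5000 | pixels/class | balanced subsampling bounds training cost and prevents class-imbalance bias; tests use 300–2000 for runtime |
| `cost` (C) | 1 | — | standard reproducible baseline; the synthetic classes are nearly separable, so the fit is insensitive to C |
| `gamma` | 1/18 | — | the common 1/feature-dimension heuristic after standardization |
| `stride` | 1 | px | classify every pixel; larger strides trade accuracy for speed with nearest-neighbor fill (all validation uses 1) |
| `tolerance` (comparator) | 0 | intensity | the manual reference derives bounds from the marked region's min/max; widening is exposed but not default |
| `tileSize` | 8192 | px | images beyond this edge are processed as overlapping tiles (overlap = window diameter) and stitched from tile interiors, keeping memory bounded while leaving results identical to the untiled computation |

Six window descriptors are fixed by the workflow; four of them (maximum,
minimum, variance, edge factor) are canonical, and this implementation
fixes the remaining two as the window mean and the center value — simple
scalars in the same spirit, documented so users know exactly what the
classifier sees. Features are computed per channel rather than on a
combined luminance because the H&E classes are chromatic: red vs. purple
vs. pink differ far more in channel balance than in brightness.

Population (not sample) variance is used: the window is a fixed-size
descriptor, not a sample from a larger population.

## The synthetic world

`generateClotSlide()` emulates the appearance the workflow is designed for,
with exact pixel-level ground truth:

* a connected tissue blob (wobbled ellipse) on near-white background
  (default 30% background);
* WBC discs of radius 5–7 px with a darker nuclear rim, RBC discs of radius
  3–5 px painted (with overlap) until the requested area fractions are
  reached, fibrin as the remaining matrix with a smooth strand-like
  brightness modulation;
* class mean colors RBC (190, 55, 65), WBC (85, 60, 140), fibrin
  (230, 165, 180), background (247, 246, 245), artefact (45, 40, 45);
* per-pixel Gaussian noise (default SD 8, a visually plausible grain for
  8-bit scans) followed by a σ = 0.5 px blur;
* fold artefacts as dark curved bands 5–9 px wide (quadratic Bézier paths),
  drawn last so the fold-free rendering of the same seed is bit-identical
  elsewhere; fold pixels replace the underlying ground-truth label with
  *artefact*, mirroring how folds are excluded from quantification.

Composition is controlled over tissue pixels, not the whole image, matching
how clot percentages are reported. Fractions are realized by painting until
the target pixel count is reached, so the realized fractions track the
targets to well within a percentage point at the default sizes; the
generator reports them exactly and errors with the maximum achievable
fraction if a target cannot be reached.

What the generator does **not** emulate: optical-density stain mixing,
chromatic aberration, scanner compression artefacts, out-of-focus regions,
partial-volume color blending beyond the mild blur, and biological
morphology (real fibrin networks, nucleated cell variety). A green
parameter-recovery test therefore establishes that the pipeline's
machinery — features, SVMs, exclusion composition, denominators — is
correct and unbiased in a world matching its assumptions; it does not
certify accuracy on real scanner output, which still requires the visual
validation loop the workflow prescribes.

Synthetic annotations are pure single-class rectangles (7 × 7 down to
1 × 1) sampled from eroded ground-truth masks, echoing how a user annotates
unambiguous patches; the training and validation sets default to the
workflow's minimum of 5 images each.

## Numerical choices

* **Feature equality.** The accelerated `featureMap()` (integral images,
  separable running extrema) is contractually identical to the naive
  `windowFeatures()` loop; the suite asserts agreement to 1e-9.
* **Determinism.** The SMO solver is deterministic (fixed scan order, no
  randomness); subsampling is seeded; one-vs-one vote ties break by
  `labelSet` order; serialization is canonical, so identical seeds yield
  byte-identical models, label maps and reports. There is deliberately no
  "inter-day variability".
* **Convergence.** SMO stops at a KKT violation below 1e-3 (the usual
  working tolerance) with a 10^6-iteration guard; non-convergence warns
  rather than fails, since the partial solution is still a valid classifier.
* **Zero-variance features** receive scaler SD 1 and are flagged, not
  dropped, keeping the feature layout stable across models.
* **Degenerate inputs.** Training requires ≥ 2 classes and ≥ 50 vectors per
  class; identical-feature training sets error; slides with no classified
  tissue error with "no tissue detected" (and are isolated per-row in batch
  mode); empty annotation masks error naming the class.
* **Model files** are a text header (version, label sets, feature
  configuration, scaler, training metadata as JSON) plus a little-endian
  binary block for the SVM state with a SHA-256 checksum, so a corrupted
  byte fails the load instead of silently mispredicting.
* **16-bit inputs** are linearly rescaled to 8-bit (`round(x/257)`): the
  method is defined on stain color, not absolute intensity. Pyramidal
  multi-page TIFFs are read at a stated level; the analysis resolution is
  the user's choice since the source workflow does not fix one.

## Design decisions that were genuinely open

* **Denominator.** The ML pipeline divides by classified tissue pixels —
  that is the entire point of the exclusion stage. The manual reference
  method divides by all (un-cropped) image pixels; the comparator
  implements both (`whole_image` default mirrors the manual description,
  `tissue` enables apples-to-apples comparison).
* **Multi-match thresholds.** Image-editing software counts each class
  selection independently and can double-count; here overlapping threshold
  matches resolve to the nearest bound-midpoint centroid by default so
  percentages can sum to 100. The single-representative-region constraint
  is kept on purpose — it is the documented weakness of the reference
  method.
* **Mixed rule.** A composition below 60% in both RBC and fibrin is MIXED
  even if WBC dominates; the three-way scheme has no WBC-dominant class.
* **Chi-squared degrees of freedom.** The collapsed RBC-rich vs. other
  table is 2 × 2 and is reported at its true df = 1 (its conventional
  notation in the source literature prints df 2 while the p-values match
  df 1); no continuity correction by default, with Yates' correction as an
  option.
* **Spearman p-values** use the t approximation, standard at n of 30–150;
  an exact permutation p is available for n ≤ 10.
* **Synthetic clinical attenuation.** The demonstration pipeline generates
  mean HU as `38 + 0.28 · true RBC% + N(0, 4)`, chosen once so that
  RBC-rich clots tend to be hyperdense (≥ 50 HU), qualitatively echoing the
  clinical observation the statistics layer is built to test. It is a
  plumbing demonstration, not a claim about CT physics.

## Limitations

* The SVM stack is an in-package SMO implementation (no SVM library is
  assumed); it targets the moderate training sizes of this workflow
  (thousands of vectors per class), not general large-scale SVM use.
* Only PNG and uncompressed baseline TIFF are read natively; vendor slide
  formats must be exported first.
* No probabilistic calibration of SVM outputs, no incremental retraining,
  no immunohistochemistry classes in this version.
* The human accuracy-judgment loop (visually validating segmentations and
  adding annotations until acceptable) is out of scope; the package exposes
  retraining but does not model the judgment.
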