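---
title: "Bag-of-visual-words screening for retinal lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-visual-words screening for retinal lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Diabetic retinopathy (DR) screening asks one question of a colour fundus
photograph: does this eye need specialist review? Two early lesion families
carry most of the signal — *bright lesions* (hard exudates: yellowish
lipid deposits) and *red lesions* (microaneurysms and dot/blot
haemorrhages: small dark-red spots that are the earliest DR sign). A
practical screening classifier must also survive *domain shift*: the
deployment clinic rarely uses the same camera, resolution or population as
the archive the classifier was trained on. `bovwscreen` implements a
classical bag-of-visual-words (BoVW) pipeline for exactly this setting,
with per-lesion binary detectors, an OR-fusion rule for referral, and a
cross-dataset evaluation protocol in which the training and test cohorts
are disjoint by construction.

## Pipeline

1. **Low-level features.** Points of interest (PoIs) are local maxima of
   the scale-normalised determinant of Hessian of the luminance image over
   a 3×3×3 scale-space neighbourhood (`detect_pois()`). Blobs of either
   polarity respond positively (exudates are bright blobs, microaneurysms
   dark ones) while elongated vessels are suppressed, because one of the
   two principal curvatures along a vessel is near zero. Each PoI carries
   an upright SURF-style descriptor: a 16×16 grid of Gaussian-weighted
   gradient samples over a window of half-width `patch_scale` × scale,
   pooled into 4×4 cells of (Σdx, Σdy, Σ|dx|, Σ|dy|), L2-normalised
   (64 values), plus the patch's mean R/G/B (3 values) so that colour
   changes — the distinguishing mark of the two lesion families — are
   described, not only boundaries. On training images with marked lesion
   regions, `restrict_to_rois()` keeps the PoIs inside the region union;
   control images are used whole.

2. **Codebook.** Per lesion family, descriptors from that family's marked
   regions plus descriptors from control images are sampled per class
   (`sample_descriptors()`) and clustered by k-means with Euclidean
   distance (`learn_codebook_kmeans()`: k-means++ seeding, Lloyd updates,
   empty clusters re-seeded from the farthest point, and `kmeans_restarts`
   seeded restarts — default 5, benchmark 2 — keeping the lowest-inertia
   run). The k centroids are the visual words.
   A random-selection codebook (`learn_codebook_random()`) is available as
   the cheap alternative.

3. **Mid-level encoding.** Classical hard/sum coding: each PoI is assigned
   fully and only to its nearest word (`hard_assign()`, ties to the lowest
   index), and an image becomes the k-vector of word activation counts
   (`encode_bovw()`), normalised `l2` by default (`l1`, `none`
   selectable — which normalisation the classical pipeline used is
   genuinely open, so it is a config key; `l2` is the usual companion of a
   margin classifier). Images with no PoIs encode as a flagged zero vector
   and score as the detector's bias, so a blank image can never crash a
   screening run.

4. **Decision models.** One regularized maximum-margin linear scorer per
   lesion family (`train_detector()`, a linear-kernel SVM on the
   histograms; positives are images carrying that lesion, negatives are
   normals). Scores are oriented so higher = more lesion-like.

5. **Fusion.** An image is *referable* iff either detector flags it:
   `fuse(a, b) = a OR b` — the image is called normal only when both
   detectors agree it is normal, the rule that minimises false negatives
   in screening. For a continuous multi-lesion ROC the per-detector scores
   are standardized (median of training normals at zero) and combined by
   `fuse_score = max`, which thresholds identically to the OR of
   per-detector flags at the same cut-off.

6. **Evaluation.** `compute_roc()` sweeps the cut-off over the distinct
   scores with tie grouping; the trapezoidal AUC then equals the
   Mann–Whitney pair statistic with ties counted ½ (this equivalence is
   asserted in the tests against a brute-force pair count and against
   pROC). `operating_point()` reports the best sensitivity under a
   specificity floor; `confusion_metrics()` reports sensitivity over
   lesion-positives and specificity over normals, with empty denominators
   reported as undefined rather than zero. `run_cross_dataset()` wires the
   whole protocol and logs the training ids so test-cohort isolation is
   auditable.

## The synthetic two-cohort benchmark

The package ships a generator (`generate_background()`, `add_lesions()`,
`generate_cohort()`) rather than clinical images. It emulates the
*statistical structure* the pipeline assumes, not fundus photorealism:

* a circular retina-like field on a dark surround, with low-frequency
  colour texture, vignetting, a brighter optic disc and darker vessel
  random walks radiating from it, plus mild sensor noise;
* lesions as elliptical Gaussian-profile blobs — bright ones add a
  yellowish offset (R+G channels), red ones subtract a dark-red offset
  (mostly G+B) — each contributing a ground-truth ROI mask (the 2σ
  ellipse) and driving the image labels;
* two cohorts that differ the way two cameras differ: resolution,
  per-channel colour gain, and JPEG re-encoding quality.

Defaults encode the clinical asymmetry that makes multi-lesion screening
interesting: bright lesions are conspicuous (σ-radius 4–12 px at the
480-px reference field, contrast 0.30–0.60, 3–10 per image), red lesions
subtle (radius 2–5 px, contrast 0.10–0.24, 2–6 per image) and easily
confused with vessel fragments. Radii are declared at a 480-pixel
reference field height and scaled by `min(H, W)/480`, since a camera with
more pixels over the same retina images the same lesion larger. The
packaged benchmark (`study_cohort_configs()`) uses a 60-image training
"archive" at 640×480 (41 normal / 8 bright-only / 5 red-only / 6 both,
JPEG quality 95, neutral gains) and a 30-image shifted "clinic" test
cohort at 800×600 (18 normal / 7 red-only / 5 dual-lesion, JPEG quality
90, gains 1.06/0.97/0.92) — the dual-lesion images count as positives for
both detectors. These sizes keep a full five-seed benchmark tractable on
one CPU while leaving each class populated.

What passing on this generator does **not** show: robustness to real
anatomy (drusen, laser scars, pigmentation), image-quality defects (blur,
glare, under-exposure), lesion appearance diversity, or camera geometry
beyond gain/resolution/JPEG. The generator is a test harness for the
pipeline's mechanics and its domain-shift behaviour, not evidence of
clinical performance.

## Numerical and design choices

* **Detector.** 4 scales from σ = 2.0 px with step 1.6 cover blob radii
  ≈ 1.4–12 px. The response threshold (5e-5 on the σ⁴-normalised
  determinant) is set well below typical lesion responses but above the
  flat-surround floor, so normals still contribute background PoIs — the
  codebook needs those. Sub-pixel refinement is deliberately omitted;
  mask indexing rounds half-up. Coordinates are 0-based, x = column.
* **PoI cap.** `detector_config()` defaults to 500 PoIs per image; the
  benchmark configuration (`study_run_config()`) caps at 100. Lesion PoIs
  sit near the top of the response ranking, so a tight salience cap
  concentrates the histogram on salient structure and raises the lesion
  fraction of the encoded mass — at 60-image training scale this is what
  makes the subtle red-lesion signal usable.
* **Codebook size.** Default k = 500 for archive-scale use; the benchmark
  uses k = 128, and the unit tests use k ∈ {2..32} where oracle checks
  (exact means, multi-restart Lloyd reference) are feasible.
* **Codebook ensemble.** `n_codebooks` (default 1; benchmark 3) re-runs
  sampling + k-means + SVM under derived seeds and averages member scores
  standardized on training statistics. At small training sizes the
  dominant score variance is codebook quantization noise, and three
  members damp it at ~seconds of cost. The flag threshold per lesion is
  calibrated on training scores as the midpoint between the normal median
  (zero after standardization) and the median positive score.
* **Seeding.** Every stochastic step draws from one global seed via
  `derive_seed(seed, stream)`; cohort image i uses stream i, so extending
  a cohort never reshuffles existing images. Identical config ⇒
  bit-identical artifacts (asserted down to file bytes in the CLI test).
* **Problem sizes in tests.** Unit tests run on 192×256–240×320 cohorts
  of ~10–15 images; the cross-dataset acceptance check runs the full
  benchmark five times; the CLI determinism check uses an 11+7-image pair
  at 160×200/180×240 with k = 12.

## Known limitations

* The linear SVM's raw decision threshold does not transfer across
  domains (scores shift under gain/resolution changes); the package
  therefore reports full ROC sweeps and calibrates flag thresholds on
  training scores. Probability calibration is out of scope.
* Red-lesion detection is the weak link, as in real screening systems:
  small low-contrast dots compete with vessel fragments for words.
  Expect AUCs well below the bright-lesion ones when the shift is severe.
* `learn_codebook_kmeans()` is exact Lloyd on an in-memory pool; it is
  not an online/minibatch implementation and is not intended for pools
  beyond ~10⁵ descriptors.
* The CLI stage artifacts carry the run-config hash, and `evaluate`
  refuses mismatched artifacts; but no attempt is made to detect manual
  edits of artifact files.
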