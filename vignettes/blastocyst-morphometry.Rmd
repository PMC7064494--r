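---
title: "Morphometric blastocyst assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric blastocyst assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastometry)
```

# Overview

`blastometry` quantifies single blastocyst micrographs and evaluates
whether the measurements predict the b-hCG pregnancy test. The pipeline is
deliberately "top-down": hand-drawn region boundaries and engineered
features feed classical classifiers, rather than an end-to-end image
model. This vignette documents the scientific model behind each stage, the
parameters that matter, and the design decisions taken where the problem
was genuinely open.

# Inputs and their assumptions

An analysis cohort consists of 8-bit grayscale micrographs with a known
microscope calibration (µm/pixel), a manual annotation of three nested
boundaries — the zona pellucida (ZP) outer boundary, the ZP/trophectoderm
interface and the trophectoderm/inner-area interface — and a manifest
carrying patient age plus either the raw β-hCG titre (mUI/mL) or a binary
outcome. A titre of at least 20 mUI/mL seven days after transfer counts as
a positive test (`label_outcome()`); the threshold is inclusive, so a
measurement of exactly 20.0 is positive.

Annotations are accepted in two dialects: polygon JSON (three closed
vertex lists in 0-based pixel coordinates) or a label-mask PNG
(0 background, 1 inner, 2 TE, 3 ZP). We require three boundaries because
three is the minimum that makes the three region masks computable;
rasterization assigns a pixel to a region by point-in-polygon at the pixel
centre, with centres exactly on a boundary counted inside. These
conventions are arbitrary but fixed, and the rasterizer is tested
pixel-for-pixel against a brute-force oracle.

# The 24-feature vector

Eight metrics per region × three regions gives 24 features. The
composition deserves a note: the metric families we quantify — perimeter,
area, entropy-filter response, its standard deviation, and Canny border
content — naturally yield five values per region (15 total), yet the
pipeline's contract is a 24-vector. We therefore define eight per region:

* `area` (µm²), `perimeter` (µm) — geometry at native calibration;
* `mean_intensity`, `sd_intensity` — raw 8-bit statistics over the region;
* `mean_entropy`, `sd_entropy` (bits) — statistics of the local-entropy
  texture map;
* `edge_length` (µm), `edge_density` (µm⁻¹) — Canny edge content, raw and
  area-normalized.

This treats "pixel information" as the local-entropy statistics and reads
"amount of borders" as both an absolute and an area-normalized quantity.
It is the central reconstruction decision of the package and is declared
as such: other 24-element compositions are conceivable, and nothing
downstream depends on this particular choice beyond the fixed names in
`feature_names()`.

## Texture and edges

The local-entropy map assigns each pixel the Shannon entropy (base 2) of
the 256-bin intensity histogram in a disk neighbourhood, clipped at the
frame. Entropy is 0 exactly for a constant neighbourhood and at most
8 bits. The disk radius defaults to 9 px at the normalized resolution:
small enough to stay inside a ~20 µm tissue layer, large enough
(~250 pixels) for a stable histogram.

Canny detection uses Gaussian smoothing (σ = 1 px), Sobel gradients,
non-maximum suppression and hysteresis. Because acquisition settings were
explicitly not standardized across microscopes, fixed thresholds would be
meaningless; the hysteresis thresholds adapt per image to the 60th/90th
percentiles of the gradient magnitude. A perfectly flat image has no
gradient support and yields an empty edge set.

## Calibration handling

All texture and edge operations run after bilinear resampling to a common
1.0 µm/px grid (masks follow by nearest-neighbour), so a 40× image does
not appear "more textured" than a 20× image of the same embryo merely
because of pixel size. Geometry (area, perimeter) is computed at native
calibration — a pixel count times (µm/px)² loses nothing by staying
native. The invariance test renders the same physical phantom at both
regimes and requires µm-valued geometry to agree within 5 %.

Images deeper than 8 bits are rescaled once at load time by
max-normalization (brightest pixel → 255). With uncalibrated cameras the
absolute scale carries no information, and max-normalization is the least
committal monotone mapping.

# Dimensionality reduction

Features are standardized to zero mean and unit SD before PCA. The raw
features mix µm², µm, bits and 8-bit intensity units, so covariance PCA
would be dominated by whichever feature happens to have the largest
numeric range; correlation PCA is the only defensible default. The
selection rule retains the smallest k whose cumulative explained variance
reaches the threshold (default 0.99); minimality is asserted in tests
against an eigendecomposition oracle. On phantom cohorts of ~200 samples
the rule typically lands on 13–15 of 24 components.

Patient age is the only non-image feature. It never enters the PCA fit —
the rotation matrix has exactly 24 rows — and is appended after
projection, z-scored by its training statistics. Keeping age out of the
image-feature decomposition both matches the stated role of age as an
add-on predictor and keeps the retained-variance bookkeeping purely
image-based.

Component signs are fixed by making each loading's largest-magnitude
element positive, so repeated fits are bit-identical.

## Leakage control

By default the standardization + PCA model is fitted inside each training
fold and applied to the held-out fold. Fitting the reduction once on the
whole table before cross-validation (available as `pca_global = TRUE`)
lets test-fold information shape the components and can inflate apparent
performance; we keep the leak-free variant as the default and the global
variant for comparability experiments.

# Classifiers and evaluation

Five families with fixed hyperparameters:

| family | configuration |
|---|---|
| `naive_bayes` | Gaussian likelihood per feature (inputs are continuous PCA scores) |
| `nu_svm` | RBF kernel, γ = 0.14, ν = 0.5; signed decision value used as the AUC score |
| `neural_net` | hidden layers (30, 30, 30, 10), ReLU, Adam (lr 10⁻³), L2 10⁻⁴, 500 full-batch epochs, seeded He initialization, no early stopping |
| `decision_tree` | unrestricted depth (cp = 0, minsplit = 2) |
| `random_forest` | 100 trees, seeded |

The "ν-SVR" naming in the source domain is internally inconsistent for a
binary outcome (SVR is regression); we implement ν-classification as the
primary mode and provide `svr_mode = TRUE` (ν-SVR on {0, 1} targets,
thresholded at 0.5) for fidelity experiments. ν and the Adam learning rate
are unstated upstream; we use the conventional defaults (0.5 and 10⁻³).

Evaluation is stratified 10-fold cross-validation: per-fold positive
counts are within one of the proportional share and fold sizes within one
of n/k (positively labelled extras fill folds from the front, negative
extras from the back, which guarantees both bounds simultaneously).
Metrics — sensitivity, specificity, precision, accuracy, F1, AUC, FPR,
FNR — are computed per fold and arithmetically averaged; AUC is the
normalized Mann–Whitney statistic (ties half-counted), averaged per fold
rather than pooled, matching the "average of the folds" reporting
convention. A metric whose denominator vanishes in a fold is recorded as 0
with a warning; FPR and FNR are defined as exact complements of
specificity and sensitivity so the identities hold even then.

The permutation control shuffles the outcome labels once (seeded,
class balance preserved) and reruns the identical pipeline. A leak-free
pipeline scores at chance. One behaviour worth knowing: on permuted labels
the ν-SVM drifts toward the majority class, so its chance-level F1 sits
somewhat above the balanced-prediction value and tracks the cohort's class
balance; the control cohorts therefore fix the positive count at the
emulated study's 71/134.

Model selection is by highest fold-averaged F1, ties broken by higher AUC
and then alphabetical family name.

# The phantom generator

The phantom emulates the *structure* of the clinical cohorts, not their
appearance: three concentric elliptical regions (ZP annulus outermost, TE
annulus, inner disk) on a darker background; two calibration regimes
standing in for the 20×/40× objectives (1.0 and 0.5 µm/px, split 90:44 by
default); a nominal 180 µm embryo with 18 µm ZP and 20 µm TE layers;
patient ages of 34.4 ± 5.5 years truncated to (18, 50); and a positive
prevalence targeted at 52.98 %. Region texture is Gaussian-smoothed white
noise (renormalized to the requested SD) added to a region mean — enough
to give regions distinguishable entropy and edge statistics without
modelling cell biology. Region means (background 40, inner 150, TE 110,
ZP 190) and noise SDs (6–14) are free knobs chosen once for plausible
contrast; no quantitative intensity statistics of the real micrographs
exist to estimate them from.

Outcomes follow a logistic model on three z-scored latents — ZP thickness,
TE texture SD and age — with default coefficients (0.8, 0.8, −0.8) and an
intercept at logit(0.5298). Positive samples receive a lognormal β-hCG
above the 20 mUI/mL threshold, negatives a sub-threshold draw; only the
threshold is specified upstream, the titre distributions are invented
plumbing. Per-sample seeds are hashed from the master seed, so cohorts are
reproducible byte-for-byte and samples independent. `generate_cohort()`
can optionally fix the exact number of positives by drawing from the same
model under an acceptance quota, which is how a retrospective cohort with
a known outcome count is emulated.

What passing tests on phantoms do **not** show: robustness to focus
variation, debris, hatching morphology, annotation disagreement between
observers, or any real relationship between blastocyst appearance and
pregnancy — the phantom's outcome signal is injected by construction. The
signal-recovery tests show only that *if* morphology carries outcome
information of the assumed kind, the pipeline recovers it.

# Numerical choices and degenerate inputs

* Pixel coordinates are 0-based with pixel centres at integers; boundary
  pixels count as inside.
* Perimeter is the longest marching-squares contour of the region mask
  (iso-level 0.5 on a zero-padded grid); for an annulus this selects the
  outer boundary. On small squares the estimator reads ~10 % short of the
  taxicab perimeter, which the tolerances acknowledge.
* Bilinear resampling aligns pixel centres (`(i + 0.5)·scale − 0.5`) and
  re-rounds to 8-bit so a resampled image is still a valid micrograph.
* Degenerate annotations (empty trophectoderm annulus, self-intersecting
  or non-nested polygons) and empty regions fail loudly with the offending
  boundary or region named; a training fold with a single class is an
  error rather than a silent skip.
* Every stochastic step (cohort, folds, permutation, forest, network
  initialization) takes an explicit seed, and RNG state is restored after
  each seeded block, so independent pipeline stages cannot perturb each
  other's streams.

# Problem sizes

The test suite exercises unit behaviour on scaled-down phantoms (60 µm
embryos on 96–192 px frames) and study-scale behaviour on full-size
cohorts: 200 samples for the reduction rule and the signal-recovery sweep
(zero / moderate / strong latent coefficients), and 134 samples with 71
positives for the permutation control at 20 permutation seeds. The
acceptance script regenerates the 200- and 134-sample cohorts from its
`--seed` and recomputes the retained cumulative variance and the
permuted-label ν-SVM F1 from scratch.

# Known limitations

* The 8-per-region feature composition is a declared reconstruction, not
  a recovered specification.
* Manual annotations are consumed, never produced: there is no
  segmentation and no inner-cell-mass/blastocoel separation.
* Chance-level F1 of the ν-SVM control depends on class balance (majority
  drift); compare permuted F1 across pipelines only at matched prevalence.
* Phantom realism is structural only; absolute feature values from
  phantoms should not be compared with clinical material.
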