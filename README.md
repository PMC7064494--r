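# blastometry

Morphometric assessment of blastocyst micrographs and cross-validated
prediction of the b-hCG pregnancy-test outcome.

## The problem

In IVF laboratories, the decision of which day-5/6 blastocyst to transfer
still rests on visual grading, which is subjective and hard to reproduce.
`blastometry` implements a quantitative alternative for embryologists and
methods researchers: starting from a single calibrated micrograph in which
the three visible compartments — the zona pellucida (ZP), the trophectoderm
(TE) and the inner area (blastocoel + inner cell mass) — have been manually
delineated, it measures the embryo, reduces the measurements, and asks five
classical classifiers whether the measurements predict a positive pregnancy
test (serum β-hCG ≥ 20 mUI/mL seven days after transfer).

## The method

For each region *r* ∈ {ZP, TE, inner} the package computes eight
µm-calibrated metrics, giving a 24-element feature vector per image:

| metric | definition | units |
|---|---|---|
| area(r) | pixel count × (µm/px)² | µm² |
| perimeter(r) | outer marching-squares contour length | µm |
| mean / SD intensity(r) | raw 8-bit intensity statistics over *r* | — |
| mean / SD entropy(r) | statistics of the local-entropy map H(x) = −Σ p·log₂ p over a disk neighbourhood | bits |
| edge length(r) | Canny edge pixels in *r* × (µm/px) | µm |
| edge density(r) | edge length / area | µm⁻¹ |

Texture and edge maps are computed after resampling every image to a common
1 µm/px grid so the 20× and 40× acquisition regimes are comparable;
geometry uses each image's native calibration. The features are
standardized and reduced by PCA, keeping the smallest set of leading
components whose cumulative explained variance reaches 99 %; patient age is
then appended as the only non-image feature (z-scored, never part of the
PCA). Five classifiers — Gaussian naive Bayes, ν-SVM (RBF kernel,
γ = 0.14), a (30, 30, 30, 10) ReLU network trained with Adam and L2 = 10⁻⁴,
an unrestricted decision tree and a 100-tree random forest — are compared
under stratified 10-fold cross-validation on sensitivity, specificity,
precision, accuracy, F1 and AUC, with a label-permutation control that must
score at chance if the pipeline is free of leakage.

Because clinical image cohorts are access-restricted, the package ships a
phantom generator: concentric-ellipse embryos with per-region textures,
ground-truth masks, ages, and b-hCG outcomes drawn from a logistic model on
latent morphology. Every stage of the pipeline is testable against the
phantom's known ground truth.

## Worked example

```r
library(blastometry)

spec    <- phantom_spec()                        # 180 µm embryo, 2 regimes
cohort  <- generate_cohort(spec, n = 60, seed = 3)
features <- extract_feature_table(cohort)        # 60 x (id + 24 + age + label)

round(features[1, c("area_zp", "perimeter_zp",
                    "mean_entropy_te", "edge_density_inner")], 3)
#>   area_zp perimeter_zp mean_entropy_te edge_density_inner
#> 1    9618      623.127           5.365              0.057

fit_reduction(features, threshold = 0.99)
#> <reduction_model: 24 features -> 14 components (99.34% of variance, threshold 99%)>

results <- lapply(c("naive_bayes", "nu_svm", "random_forest"), function(f)
  cross_validate(features, classifier_spec(f), k = 5, seed = 1))
for (r in results) print(r)
#> <cv_result naive_bayes: 5-fold, F1 = 0.653, AUC = 0.782>
#> <cv_result nu_svm: 5-fold, F1 = 0.697, AUC = 0.755>
#> <cv_result random_forest: 5-fold, F1 = 0.600, AUC = 0.736>

best <- select_best(results)                     # highest fold-averaged F1
best$spec$family
#> [1] "nu_svm"

permutation_control(features, best$spec, k = 5, seed = 1,
                    permutation_seed = 7)
#> <cv_result nu_svm [permuted labels]: 5-fold, F1 = 0.454, AUC = 0.430>
```

The first row's ZP annulus covers 9 618 µm² with a 623 µm outer perimeter;
the trophectoderm's mean local entropy of 5.4 bits reflects its noisy
texture. The 99 % rule keeps 14 of 24 components. On this small
signal-bearing cohort the ν-SVM is the best model by F1 (0.70); after
permuting the outcome labels the same model falls to chance (AUC 0.43),
showing that the cross-validation does not leak.

A command-line front end wrapping the same functions is installed at
`system.file("exec/blastometry", package = "blastometry")` with
`phantom`, `extract`, `train`, `permute` and `evaluate` subcommands.

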