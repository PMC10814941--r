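# dermofuse

Multimodal feature extraction and classification of skin neoplasms:
differentiating the clinical forms of basal cell carcinoma (BCC) from each
other and from benign lesions using three non-invasive screening
modalities — diffuse reflectance spectroscopy (DRS), optical coherence
tomography (OCT) and high-frequency ultrasound (US) — fused into a single
gradient-boosted classifier. The package is aimed at researchers building
quantitative, interpretable skin-lesion screening pipelines, and ships a
seeded synthetic cohort generator so the whole pipeline runs and is tested
without any clinical data.

## What it computes

**DRS (6 features per spectrum).** From the optical density
OD(λ) = −log₁₀ R(λ) of a lesion spectrum, normalized to the volunteer's
healthy skin:

* melanin index M = 100 (OD₆₂₀ − OD₇₀₀)
* erythema index E = 100 [OD₅₆₀ + 1.5 (OD₅₄₅ + OD₅₇₅) − 2 (OD₅₁₀ + OD₆₁₀)]
* hemoglobin index H = (OD₅₄₅ − OD₅₂₉)/16 − (OD₅₇₀ − OD₅₄₅)/25
* Linearity and Error_linearity: OLS slope / RMS residual of reflectance on
  650–800 nm
* malignancy coefficient Rt = (R₅₀₀ʰ R₇₀₀ˡ) / (R₇₀₀ʰ R₅₀₀ˡ)

**OCT (65 features per B-scan ROI).** Shannon entropy of the raw ROI; after
a background-derived threshold filter (mean + SD of a noise region),
3×3 grayscale erosion and Gaussian smoothing (σ = 1.5 px): four first-order
statistics (population mean, SD, skewness, non-excess kurtosis over nonzero
pixels) and five Haralick features (energy, contrast, correlation, entropy,
homogeneity) on each of 12 gray-level co-occurrence matrices (angles 0°,
45°, 90°, 135° × distances 1, 5, 9 px; 256 levels; symmetric; both-nonzero
pairs only).

**US (13 features per lesion).** On the two-annotator consensus mask
(intersection, largest 8-connected component), in physical units: Area,
boundary-chain Perimeter, Circularity = 4πA/P², EquivDiameter = √(4A/π),
Tortuosity = P/A, and the moment-ellipse Eccentricity, Major/MinorAxisLength
and Orientation, plus FilledArea, MaxFeretDiameter, MaxFeretAngle and
Solidity.

**Fusion + evaluation.** Within each tumor the three modality tables are
randomly paired without row reuse into 84-feature observations; features
are min–max scaled (per training fold) and observations weighted inversely
to class frequency. A boosted-tree softmax classifier (xgboost) is
evaluated with leave-one-out cross-validation grouped by tumor, reporting
per-class and macro sensitivity, specificity, precision, F1 and IoU, the
confusion matrix, one-vs-rest threshold (FPR/FNR) and ROC curves, gain
importances and TreeSHAP attributions.

## A worked example

```r
library(dermofuse)

# a full synthetic study: 37 tumors (2/2/15/3/5/10 across the six classes),
# 10 observations per tumor and modality
fused <- simulate_fused(cohort_spec(seed = 7), class_params("well-separated"))
cv <- loocv_by_tumor(fused, boost_config(seed = 7))
cv
#> Tumor-grouped LOOCV: 37 folds, 370 out-of-fold observations
#> argmax accuracy 0.935

loocv_metrics(cv)
#> Per-class metrics:
#>                        class Sens  Spec  Prec    F1   IoU
#>  infiltrative_ulcerative_bcc 0.90 0.989 0.818 0.857 0.750
#>                pigmented_bcc 0.65 0.971 0.565 0.605 0.433
#>              superficial_bcc 1.00 0.991 0.987 0.993 0.987
#>              morpheaform_bcc 0.90 1.000 1.000 0.947 0.900
#>                  nodular_bcc 0.96 1.000 1.000 0.980 0.960
#>                       benign 0.90 0.970 0.918 0.909 0.833
#> Macro (mean +/- across-class sd):
#>   Sens  88.5 +/- 12.2 %
#>   Spec  98.7 +/- 1.3 %
#>   Prec  88.1 +/- 17.0 %
#>   F1    88.2 +/- 14.5 %
#>   IoU   81.1 +/- 20.4 %
```

The numbers say: with the well-separated synthetic preset, the pipeline
recovers the planted six-class structure out of fold; the pigmented form
(2 tumors only) is the hardest, exactly as class sizes suggest, and macro
scores swing by a few points from seed to seed at this cohort size. `binary_view(cv)` collapses the five BCC forms for the
screening-style bcc-vs-benign report, `autoplot(cv)` draws the confusion
heatmap, `plot_threshold_curves(cv)` the FPR/FNR trade-off per class, and
`feature_importance()` / `shap_attributions()` explain the model.

Individual stages are ordinary functions on tibbles and matrices:
`drs_features()`, `oct_features()`, `shape_features()`,
`pair_modalities()`, or manifest-driven from disk via
`write_cohort()` / `*_features_from_manifest()`.

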