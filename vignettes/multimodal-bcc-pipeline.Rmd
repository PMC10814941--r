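---
title: "Multimodal differentiation of skin neoplasms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal differentiation of skin neoplasms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermofuse)
```

## The problem

Basal cell carcinoma (BCC) presents in clinically distinct forms —
infiltrative–ulcerative, pigmented, superficial, morpheaform and nodular —
whose management differs, and all of which must be told apart from benign
neoplasms (nevi, fibromas, dermatofibromas). dermofuse implements a
screening pipeline that quantifies a lesion with three non-invasive
modalities, fuses the quantities into per-observation feature vectors and
classifies them with a gradient-boosted decision-tree model evaluated under
tumor-grouped leave-one-out cross-validation. A seeded synthetic cohort
generator stands in for clinical data, so every stage of the pipeline is
exercised end to end by code alone.

## Diffuse reflectance indices

A diffuse reflectance (DR) spectrum is the ratio $R_\lambda$ of the
intensity reflected by the skin to that of a ~100 % reference, recorded on
450–950 nm. All indices work on the effective optical density
$OD_\lambda = -\log_{10} R_\lambda$:

* melanin pigmentation $M = 100\,(OD_{620} - OD_{700})$;
* erythema $E = 100\,[OD_{560} + 1.5 (OD_{545} + OD_{575}) - 2 (OD_{510} +
  OD_{610})]$ — the Dawson contrast of the oxyhemoglobin double peak
  against its flanks; the coefficients sum to zero and annihilate affine
  trends;
* hemoglobin content $H = (OD_{545} - OD_{529})/16 - (OD_{570} -
  OD_{545})/25$, a curvature estimate at the 545 nm peak that also cancels
  affine trends;
* `Linearity` and `Error_linearity`: the OLS slope of reflectance against
  wavelength on 650–800 nm and the RMS of the fit residuals;
* the malignancy coefficient $R_t = (R^{healthy}_{500} R^{lesion}_{700}) /
  (R^{healthy}_{700} R^{lesion}_{500})$.

Landmark optical densities are linearly interpolated from the instrument
grid (unbiased at ~1 nm pitch). Each of $M, E, H$, `Linearity` and
`Error_linearity` computed for a lesion spectrum is divided by the mean of
that coefficient over the volunteer's healthy-skin spectra, removing the
individual skin baseline. $R_t$ is computed against the pointwise mean
healthy spectrum — the acquisitions are not paired, so a mean reference is
the only well-defined choice — and is not re-normalized, being already a
lesion/healthy contrast. A healthy mean of exactly zero would make the
normalization meaningless, so it aborts with the coefficient named rather
than clipping silently ($E$ and $H$ can legitimately hover near zero on
pale skin).

## OCT texture

B-scans are 8-bit grayscale images. Analysis windows are rectangles of at
least 534 µm (depth) × 400 µm (width) at the scan's pixel pitch. The
processing chain is:

1. **Shannon entropy** of the raw ROI histogram (256 bins, zero pixels
   excluded, $\log_2$ → bits) — computed *before* any filtering;
2. **threshold filter**: the threshold is mean + population SD of a
   background region below the tissue; pixels ≤ threshold become 0;
3. **denoising**: grayscale erosion with a 3×3 square window, then 2-D
   Gaussian smoothing with σ = 1.5 px (kernel truncated at 4σ), re-quantized
   to 8-bit by rounding;
4. **first-order statistics** over nonzero ROI pixels: population mean, SD,
   skewness and non-excess (Pearson) kurtosis — the classical FOS texture
   definitions, so a normal texture scores kurtosis 3. A zero-variance ROI
   reports skewness/kurtosis 0 with a warning;
5. **12 gray-level co-occurrence matrices**: four directions (0°, 45°, 90°,
   135°, rows increasing downward, 45° = up-right) × three interpixel
   distances (1, 5, 9 px) at the full 256 gray levels. A pair counts only
   when both pixels are nonzero (the background-exclusion rule applied
   consistently); matrices are symmetrized (matrix + transpose) and
   normalized to sum 1;
6. **5 Haralick features** per matrix: energy $\sum p^2$, contrast
   $\sum (i-j)^2 p$, correlation (defined as 1 when a marginal variance
   vanishes), entropy $-\sum p \log_2 p$, and homogeneity
   $\sum p / (1 + (i-j)^2)$ (the inverse difference moment; the
   $1/(1+|i-j|)$ variant is a configuration option).

That yields 65 named values per ROI (4 FOS + entropy + 12 × 5), in a fixed
schema `feature_a<angle>_d<distance>`. Down-quantization (e.g. 32 levels)
and the entropy log base are exposed in `glcm_config()` but default to the
raw 8-bit range and bits, respectively.

## Ultrasound shape descriptors

Two annotators outline each lesion independently; the analysis region is
the pixelwise intersection reduced to its largest 8-connected component.
Thirteen descriptors are emitted in physical units (mm / mm²) so
anisotropic pixel spacing is handled by computing in mm coordinates: area;
boundary-chain perimeter (sum of Euclidean steps around the 8-connected
boundary); circularity $4\pi A / P^2$; equivalent diameter
$\sqrt{4A/\pi}$; tortuosity $P/A$; eccentricity, major/minor axis lengths
and orientation of the ellipse with the same normalized second central
moments as the region (eccentricity = focal distance / major axis;
orientation counterclockwise-positive against the horizontal image axis, in
(−90°, 90°]); hole-filled area; maximum Feret diameter and its angle; and
solidity (area / convex-hull area, with the convex region rasterized on the
pixel grid so the ratio cannot exceed 1).

The moment ellipse uses plain central moments of pixel centers (no
pixel-variance correction), so its axes equal $4\sqrt{\lambda}$ of the
empirical moment matrix exactly — the form the test oracles verify — at a
negligible bias for regions tens of pixels across. The boundary-chain
perimeter is the literal "sum of distances between adjacent border pixels"
definition; it systematically over-measures smooth contours by a few
percent (the classical digitization effect), which is why circularity of a
digitized disc is ~0.91, not 1.0, and why test tolerances on
perimeter-derived quantities are a few percent rather than fractions of one.

## Fusion, scaling and weighting

The three modalities are recorded at spatially inconsistent sites of the
same tumor, so rows cannot be co-registered. Instead, for each tumor an
independent uniform random permutation of each modality's rows is drawn
(seeded) and the permutations are zipped: each observation holds one DRS
row (6 features), one OCT row (65) and one ultrasound row (13) — 84
features — and no source row is reused. The pairing seed is recorded on the
result, and the full source-row assignment is kept for audit.

Features are min–max scaled to [0, 1]. Scaling parameters are fit on the
training fold only and applied to the held-out tumor (values may fall
outside [0, 1]; no clipping) — fitting them globally before cross-validation
would leak the held-out tumor's range into training, so the leakage-free
variant is the default and the literal global variant remains available as
`boost_config(scaling = "global")`. Class weights are inversely
proportional to the class observation counts, normalized so the mean weight
over observations is 1; the normalization keeps the loss magnitude
comparable across folds (it is otherwise arbitrary).

## Classifier and evaluation

The model is a gradient-boosted decision-tree ensemble (xgboost) with the
softmax multiclass loss, per-observation class weights, depth-4 trees,
learning rate 0.1, at most 500 rounds, and an overfitting detector that
stops training after 50 non-improving rounds on a held-out validation slice
of the training fold. The validation slice is grouped by tumor (about 20 %
of tumors, stratified by class; a class whose training fold holds a single
tumor keeps it in training): a row-level slice would share tumors with the
training rows, so the detector would never see tumor-level generalization
error and the ensemble would memorize individual tumors — an effect that is
clearly visible as near-uniform held-out probabilities when the slice is
not grouped. All hyperparameters sit in `boost_config()`.

Evaluation is leave-one-out cross-validation grouped by tumor: one fold per
tumor, all of its observations test-only, scaling and weights recomputed
per fold. The confusion matrix is built from the argmax of the out-of-fold
probability vectors. Per class: Sens = tp/(tp+fn), Spec = tn/(tn+fp),
Prec = tp/(tp+fp), F1 the harmonic mean, IoU = tp/(tp+fn+fp); macro scores
are unweighted class means reported with the across-class SD. Undefined
ratios on degenerate folds are reported as 0 and flagged so macro means
stay computable. A binary screening view collapses the five carcinoma
classes on the argmax predictions before re-deriving the matrix.
One-vs-rest FPR/FNR curves are swept on a fixed threshold grid (step 0.01,
configurable), and ROC pairs come from the same sweep, so FNR = 1 − TPR at
matching thresholds by construction. Feature importance uses the ensemble's
gain statistics; local attributions use TreeSHAP, whose additivity
(attributions + base value = prediction margin) is verified to float
precision in the tests.

## The synthetic cohort

The generator emulates the *statistical structure* the pipeline consumes,
not tissue physics:

* **Spectra**: constant OD baseline (0.30) + a melanin ramp scaled so the
  planted `melanin_slope` returns as $M \approx 100\times$ the knob +
  Gaussian oxyhemoglobin dips at 545/575 nm (SD 10 nm) driving $E$ and $H$
  + a near-infrared reflectance slope driving `Linearity`, plus additive
  Gaussian reflectance noise. Because $E$ and $H$ annihilate affine OD
  trends, the knobs map onto their indices with minimal cross-talk. The
  healthy site uses one shared baseline parameter set.
* **B-scans**: a Gaussian random field (white noise smoothed at the class's
  correlation length, rescaled to its contrast, shifted to its mean
  intensity) over a pure-noise background strip; 190 × 90 px at
  5.34 / 7.32 µm pitch, with a fixed 101 × 56 px ROI (539 × 410 µm).
  Contrast at distance 1 decreases in the correlation length — the analytic
  GLCM link ($E[(I_1-I_2)^2] = 2\sigma^2(1-\rho(d))$) that makes the knob
  testable.
* **Masks**: a rotated ellipse with the class's eccentricity and equivalent
  diameter, smooth low-order Fourier boundary roughness, and two
  independently jittered annotator copies (nonempty intersection by
  construction); 128 × 128 px at 0.1 mm spacing.

Class parameter presets encode ordinal clinical relations (melanin highest
for benign and pigmented lesions; erythema/hemoglobin highest for nodular
and lowest for superficial; benign roundest, superficial roughest), never
any clinical performance figure. Two presets exist: *well-separated*
(large class gaps, reflectance noise SD 0.004, 2 % tumor-level parameter
jitter, 2 % annotator jitter) — the regime where a working pipeline must
recover the planted classes almost perfectly — and *overlapping* (class
parameters shrunk 65 % of the way to their common mean, noise quadrupled,
25 % tumor jitter), where performance must degrade. The default cohort
mirrors the study inventory: 37 tumors with class counts 2/2/15/3/5/10 and
10 observations per tumor per modality (370 B-scans, 370 mask pairs, 740
spectra).

What passing tests on this cohort do **not** show: robustness to real OCT
speckle statistics, acoustic shadowing, probe pressure artifacts,
mis-annotation, instrument drift, or class signatures that differ from the
planted ordinal structure. The synthetic cohort validates the plumbing and
the statistical machinery, not clinical performance.

## Numerical choices and degenerate inputs

* Landmark OD sampling: linear interpolation; out-of-range queries error.
* Zero healthy-mean normalizers: error with the coefficient named
  (configurable epsilon, default effectively exact zero).
* Zero-variance ROI: skewness/kurtosis 0 + warning; degenerate GLCM
  correlation: 1; empty co-occurrence offset: error naming the offset.
* Disconnected consensus intersection: largest 8-connected component;
  empty intersection: error.
* Constant features: scale to 0; unseen classes in a fold: logged, fold
  proceeds; single-class training fold: error.
* All randomness is seeded: cohort generation, pairing, validation split
  and the booster itself (single-threaded for bit reproducibility).

## Problem sizes used in the tests

The test-suite and the acceptance script run the full default cohort
(37 tumors × 10 observations) for the audits and inventory checks, and
5 seeds × 2 presets of full cohorts for the recovery study; oracle
equivalence checks (co-occurrence counting, denoising, moments) run on
dozens of small seeded images, where brute-force enumeration is exact and
fast. These sizes were chosen to match the study inventory exactly while
keeping a complete run of the suite in the minutes range on one CPU.

## A worked example

```{r example, eval = FALSE}
library(dermofuse)

spec <- cohort_spec(seed = 7)                       # 37 tumors, 10 obs each
fused <- simulate_fused(spec, class_params("well-separated"))
cv <- loocv_by_tumor(fused, boost_config(seed = 7))

glance(cv)              # folds, accuracy, macro metrics
tidy(loocv_metrics(cv)) # per-class Sens/Spec/Prec/F1/IoU
binary_view(cv)         # bcc-vs-benign screening view
autoplot(cv)            # confusion heatmap
plot_threshold_curves(cv)
```

## Known limitations

* The synthetic spectra are phenomenological; chromophore unmixing or
  radiative transfer modelling is out of scope.
* ROIs are rectangles (OCT) and binary masks (ultrasound); automated lesion
  segmentation and artifact screening are the caller's responsibility.
* The boosted-tree hyperparameters are sensible defaults, not a tuned
  optimum; with 37 tumors the LOOCV estimate has large variance, which is
  why acceptance checks aggregate over seeds.
* Echo-intensity analysis of the ultrasound interior, higher-order texture
  statistics and alternative learners are deliberately not implemented.
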