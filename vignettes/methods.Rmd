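---
title: "Methods: DW-MRI texture analysis for thyroid nodule stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DW-MRI texture analysis for thyroid nodule stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

thyrotex implements a complete texture-analysis pipeline for
stratifying thyroid nodules on diffusion-weighted MRI (DW-MRI): ADC
map computation, a MaZda-style catalogue of 278 texture features,
three-criterion feature ranking with backward elimination, a Fisher
linear discriminant with a trained cutoff, a conservative per-nodule
decision rule, and a seeded synthetic cohort generator used for
calibration and testing. This vignette states the model, the
conventions and the parameter choices; the README shows a worked
end-to-end run.

## Signal model and ADC maps

A two-point DW acquisition measures a baseline image $S_0$ (at
$b = 0$) and a diffusion-weighted image $S_b$ at one nonzero
$b$-value (default $b = 500\ \mathrm{s/mm^2}$). Under monoexponential
decay,

$$S_b = S_0 \exp(-b \cdot \mathrm{ADC}),$$

so the apparent diffusion coefficient is recovered per pixel as
$\mathrm{ADC} = -\log(S_b / S_0) / b$. Magnitude MRI noise is Rician:
its expectation does not vanish at zero signal, which biases ADC
downward in dark regions. `compute_adc()` therefore rectifies both
signals in quadrature before the log, $S' = \sqrt{\max(S^2 -
\mathrm{NF}^2, 0)}$ with noise floor $\mathrm{NF}$, marks pixels whose
rectified signals are non-positive as invalid, and clips rectified
$S_b' > S_0'$ (formally negative ADC) to zero while counting the
event. On noise-free signals the inversion is exact to machine
precision; when signals are constructed as $\sqrt{S_{\rm true}^2 +
\mathrm{NF}^2}$ the rectification is also exact (both properties are
asserted in the test suite).

Each nodule contributes one region of interest (ROI) per slice. The
per-slice mean ADC is averaged over valid in-ROI pixels; a nodule's
summary ADC pools its slices with area weights,

$$\bar{x} = \frac{\sum_i w_i x_i}{\sum_i w_i},$$

where $w_i$ is the ROI pixel area of slice $i$
(`weighted_mean_adc()`).

## Texture feature catalogue

`extract_all()` computes, per slice ROI, the feature families below
(278 features at the default configuration; `feature_registry()`
enumerates the exact names).

* **Co-occurrence (GLCM), 220 features.** Intensities inside the ROI
  are quantized to $G = 2^{\text{bits}}$ gray levels (default 6 bits,
  64 levels) with a choice of window: `mu3sigma` ($\mu \pm 3\sigma$,
  the default), `minmax`, or `perc1_99` (1st-99th percentile). For
  each of 20 offsets — four directions (0°, 45°, 90°, 135°) times
  distances 1-5 — a symmetric normalized co-occurrence matrix over
  in-ROI pixel pairs yields 11 Haralick features (angular second
  moment, contrast, correlation, sum of squares, inverse difference
  moment, sum average/variance/entropy, entropy, difference
  variance/entropy; natural logarithms, $0 \log 0 \equiv 0$).
  Feature names carry the offset, e.g. `S(1,-1)Entropy`.
* **Run-length (RLM), 20 features.** Maximal same-level runs fully
  inside the ROI along the four directions give short/long-run
  emphasis, gray-level and run-length non-uniformity, and the
  fraction of image in runs, with prefixes `Horzl_`, `45dgr_`,
  `Vertl_`, `135dr_`.
* **Histogram, 9 features.** Population moments (mean, variance,
  skewness, excess kurtosis) and the 1/10/50/90/99th percentiles
  (linear-interpolation quantiles) of the raw in-ROI intensities.
* **Gradient, 5 features.** Central-difference gradient magnitude at
  pixels whose four edge neighbours are in-ROI; its moments plus the
  nonzero fraction.
* **Autoregressive model, 5 features.** A causal four-neighbour AR
  model on mean-centred intensities fitted by least squares
  (`Teta1`-`Teta4` and the residual SD `Sigma`); aliased coefficients
  are reported as 0, and ROIs with fewer than 5 usable pixels yield
  `NA`.
* **Haar wavelet, 12 features.** A decimated orthonormal Haar
  transform over the ROI bounding box (edge-replicated to dyadic
  size) gives mean squared coefficients per subband (LL, LH, HL, HH)
  and scale 1-3, restricted to coefficients whose support overlaps
  the mask; a bounding box smaller than $2^s$ yields `NA` at scale
  $s$.
* **Geometry, 7 features.** Mask centroid, its offsets from the
  bounding box, and normalized second moments.

Conventions: matrices are indexed `[row, column]` with row 1 at the
top; pixel coordinates are 1-based (a deliberate deviation from
0-based conventions elsewhere, recorded in the feature definitions —
it only shifts the centroid features `GeoX`/`GeoY` by one).
Co-occurrence offsets are written `(dx, dy)` with `dx` rightward
along columns and `dy` downward along rows. Under a constant
intensity shift, all quantized and gradient features are invariant,
while `Mean`, the percentiles and the `WavEnLL_*` energies are
shift-*equivariant*; the test suite asserts exactly this partition.

Slices for which any configured feature is undefined (e.g. a
three-pixel end slice that cannot support scale-3 wavelets) are
excluded from the feature table with a recorded reason, mirroring the
exclusion bookkeeping of a clinical analysis.

## Feature selection

Given the labeled slice table, `run_training()` ranks every
non-constant feature by three criteria:

1. **Fisher coefficient** $F = (\mu_1 - \mu_2)^2 / (s_1^2 + s_2^2)$;
2. **mutual information** between the feature (equal-frequency
   10-bin discretized; features with at most 10 distinct values use
   the values themselves as bins) and the class label;
3. **POE+ACC**: greedy selection by the probability of classification
   error of a nearest-class-mean rule on the standardized feature,
   penalized by the average absolute Pearson correlation to features
   already selected.

The top 10 per criterion are merged into a candidate list ordered by
mean rank (a feature missing from a list counts rank 11; ties break
by Fisher coefficient). Backward elimination then removes the weakest
candidate one at a time, scoring each subset size by the
resubstitution misclassification of a refitted linear discriminant,
and returns the smallest subset attaining the minimal error.

## Classification

`fit_lda()` standardizes the selected features, pools the class
covariances, and regularizes with a small ridge (grown by factors of
10 from $10^{-8} \cdot \overline{\mathrm{diag}}$ until the condition
number falls below $10^8$ — necessary because candidate features are
highly correlated). The unit-norm discriminant direction
$w \propto S_w^{-1}(\mu_1 - \mu_0)$ is oriented so malignant scores
are positive, and the score offset places the midpoint of the class
means at zero, so the one-dimensional score (called MDF1, *most
discriminant factor*) has a natural cutoff near 0. The operational
cutoff is then trained on the slice scores: the error-minimizing
threshold over score midpoints, ties resolved toward the larger
Youden index and then the smaller cutoff.

A nodule is called malignant only if its **lowest-scoring slice**
exceeds the cutoff. This minimum rule is never more aggressive than
an any-slice rule (asserted over random score sets in the acceptance
tests) and suppresses false positives from single atypical slices.

`run_test()` applies a frozen model — standardization, weights,
cutoff and texture configuration — to an independent cohort; no
statistic of the test data enters the model, which the test suite
verifies by mutation.

## Evaluation

Reported per run: slice misclassification percentage (one decimal),
sensitivity and specificity with exact Clopper-Pearson 95% intervals,
the ROC curve with the Mann-Whitney AUC (ties half-weighted) and its
Hanley-McNeil standard error, nodule accuracy under the minimum rule,
and a Welch $t$ test comparing the class distributions of the pooled
nodule ADC.

## Synthetic cohort generator

Because the package must be testable without patient data,
`generate_cohort()` simulates a two-site study whose population
parameters are the package's reference study conditions:

| Quantity | Benign | Malignant |
|---|---|---|
| mean ADC (mm²/s) | $2.24\times10^{-3}$ | $1.92\times10^{-3}$ |
| between-nodule ADC SD | $0.30\times10^{-3}$ | same |
| max diameter (mm) | $29.3 \pm 8.0$ | $33.3 \pm 10.4$ |
| texture correlation length (mm) | 1.8 | 4.5 |
| texture heterogeneity SD (mm²/s) | $0.10\times10^{-3}$ | $0.28\times10^{-3}$ |

Shared settings: 256×256 matrix over a 220 mm field of view,
$b = 500\ \mathrm{s/mm^2}$, baseline signal 500 with a mild planar
shading, Rician noise SD 5 (training site) and 6 (test site), 1-7
slices per nodule (1 + Binomial(6, ½), mean 4), elliptical ROIs with
eccentricity U(0.6, 1) shrinking toward the nodule ends with an
ellipsoidal profile, and a minimum admissible diameter of 12 mm.
Slice ROIs below 17 pixels trigger a redraw of the geometry.
Intranodular texture is a Gaussian random field (separable Gaussian
kernel, unit marginal variance) scaled by the class heterogeneity SD
and added to the slice mean ADC, so the classes differ in texture as
well as in mean. Nodule position is uniform and **independent of
class** — a guard against the classifier learning placement, verified
by a chi-squared association test in the suite. Cohort sizes (16/8
training, 10/8 test nodules by default) are the package's own choice
of a small-study regime; all sizes and parameters are arguments.

Generation is fully seeded and bit-reproducible; `generate_nodule()`
with an explicit seed uses a local RNG state and restores the global
stream.

## Resubstitution bias and the null calibration

With ~100 slices, 278 candidate features and selection plus
elimination tuned on the same data, *resubstitution* metrics are
strongly optimistic: on a no-effect cohort (identical class
parameters) the pipeline still reaches a resubstitution slice AUC of
roughly 0.85. That is a property of the procedure, not a bug — and it
is why the null calibration in the acceptance suite evaluates the
trained model on a *held-out* no-effect split, where a sound
implementation must collapse to AUC ≈ 0.5. Both numbers are written
by `scripts/acceptance.R` so the bias is visible rather than hidden.
The same logic motivates reporting the independent-site test metrics
alongside the training metrics in every run.

## Limitations

* The generator is a phantom, not tissue: it encodes monoexponential
  decay, elliptical ROIs and Gaussian-field texture. Absolute
  classification numbers on synthetic cohorts say nothing about
  clinical performance; they calibrate the *software*.
* The small-study regime (tens of nodules) makes selected feature
  subsets unstable across seeds; only the pipeline's behavior, not a
  particular feature list, is reproducible.
* Only two $b$-values are modeled; perfusion (IVIM) effects at low
  $b$ are out of scope.
* The AR and wavelet families can be undefined on very small end
  slices; such slices are excluded rather than imputed.
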