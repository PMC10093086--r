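---
title: "Methods: temporal parenchymal texture analysis with mammotrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal parenchymal texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mammotrend)
```

## Scientific setting

Serial screening mammograms form a per-woman time series of parenchymal
texture. The working hypothesis behind this package is that tissue destined
to harbour a malignancy — and, via a *field effect*, tissue well beyond it,
including the contralateral breast — undergoes slow textural change in the
years before the lesion is detected. If true, a classifier that integrates a
woman's whole sequence of antecedent images should discriminate future
malignant from future benign findings, while a classifier restricted to the
single exam closest to diagnosis should not. `mammotrend` implements both
arms of that comparison plus the statistical machinery to judge it, and a
synthetic-cohort generator that encodes exactly this hypothesis so the whole
pipeline can be validated end to end.

## The synthetic cohort generator

The generator's defaults emulate a two-institution case-control screening
cohort: 99 women (49 future-malignant / 50 future-benign by exact-count
allocation), 2–9 craniocaudal exams per woman with most women contributing
2–4 (length probabilities 0.45, 0.25, 0.13, 0.07, 0.045, 0.03, 0.015, 0.01
over 2–9, giving ≈3.2 exams/woman), and irregular inter-exam intervals drawn
from a truncated normal with mean 1.27 years, SD 0.3 years, floored at 0.5
years. Both breasts are generated per exam; the affected laterality of the
future finding is random.

**The drift model.** Future-malignant cases drift in two texture parameters
(spectral slope β and lump density) at `drift_per_year` between-woman SDs
per year. Two design choices isolate the temporal hypothesis:

1. **Anchoring.** The drift is anchored at the *last* antecedent exam: the
   texture at that exam equals the woman's own baseline, and earlier exams
   are offset by `-drift × elapsed-years`. Consequently the marginal feature
   distribution at the exam a single-timepoint classifier uses is
   label-independent *by construction*, not merely swamped by noise.
2. **Baseline jitter.** Each woman's baseline parameters are drawn with a
   between-woman spread (`baseline_jitter`) that is large relative to the
   drift accumulated over typical spans, so marginals at earlier fixed
   timepoints also stay close to uninformative.

With `field_effect = TRUE` (default) the contralateral breast receives
*identical* drift; with `FALSE` it receives none. The same skeleton drives a
feature-level fast path (`generate_feature_sequences()`): AR(1) trajectories
(coefficient 0.6, stationary SD 0.3) around jittered baselines, with the
anchored drift added to a 5-feature informative subspace. The fast path is
what the statistical tests and the headline experiment use; the image path
(`render_texture()`) exercises the feature extractors.

**What the generator does not emulate:** scanner/processing differences
between institutions, breast positioning and registration error, density
changes with age or hormonal status, focal precancerous lesions, or any
nonlinear drift. A pipeline that passes on these cohorts is validated as
*machinery* — the biological claim can only be tested on real serial
mammograms.

## The texture model

`render_texture()` produces a unit-variance Gaussian field whose radially
averaged power spectrum falls as `f^-β` (spectral synthesis with random
phases), adds Poisson-placed Gaussian lumps (density 2×10⁻⁴ px⁻², radius
6 px, unit amplitude by default) emulating focal fibroglandular densities,
adds white detector noise (SD 0.15), and min–max rescales to the 12-bit
range. β ≈ 2.8 is typical of mammographic parenchyma; the generator accepts
β ∈ [0, 4] (β = 0 gives white noise, used for spectral calibration).

`fbm_surface()` provides fractional-Brownian calibration phantoms
(FD = 3 − H). It synthesizes the `f^-(2H+2)` field on a 4× finer grid and
point-decimates. The oversampling matters: a band-limited field synthesized
at the target grid is smooth at lag 1 (no super-Nyquist power) and does not
behave like sampled fBm at pixel scale, which would make fractal estimators
look biased for reasons that have nothing to do with the estimators.

## The radiomic bank: numerical conventions

All 50 features are deterministic functions of a single ROI. Conventions
chosen once and frozen:

* **Quantization** (GLCM, NGTDM, histogram entropy): linear min–max binning
  of the patch's own range into 16 levels, top bin closed. This makes every
  quantized-domain feature exactly invariant to additive intensity offsets.
* **GLCM**: distance 1, four angles (0°, 45°, 90°, 135°) accumulated,
  symmetrized, normalized. Haralick's 14 statistics with 0-based level
  indices, base-2 logarithms, `0·log 0 ≡ 0`; correlation defined as 0 at
  zero marginal variance; sum variance centred at the sum average; the
  maximal correlation coefficient is the square root of the second-largest
  eigenvalue of `Q[i,j] = Σ_k P(i,k)P(j,k)/(p_x(i)p_y(k))`, 0 for degenerate
  matrices. ε = 10⁻¹² guards every ratio (so a constant patch has NGTDM
  coarseness 10¹²).
* **Spectra**: mean subtraction, optional Hann window, annuli of width one
  frequency sample; the fitted band starts 3 samples above DC to avoid
  leakage. The 8 power-law features are −slope of log₂ power vs log₂
  frequency for {Hann, none} × {full band, low/middle/high linear-frequency
  third}.
* **Fractal estimators.** Differential box counting uses box sizes
  2–128 px with per-block count `max(ceil(range/s), 1)` on a surface
  rescaled to `[0, 4·(side−1)]`. Two textbook biases compress naive
  estimates toward 2: tiny blocks measure finite-sample extremes of 4–16
  pixels rather than the scaling law, and coarse boxes sit on the one-box
  floor when the surface amplitude is small. The ×4 vertical exaggeration
  addresses the floor; the headline FD is fitted over s ≥ 8 (the fine-half
  feature, s = 2–16, retains the fine scales as a separate descriptor).
  The blanket (Minkowski) estimator grows upper/lower envelopes by unit
  steps and cross-shaped dilation for ε = 1–16 and fits over ε = 8–16 for
  the same reason. Both were calibrated once against `fbm_surface()`
  phantoms with H ∈ {0.3, 0.5, 0.7}; residual biases after freezing are
  −0.15 to +0.02 (box counting) and −0.17 to −0.07 (blanket), inside the
  ±0.2 envelope the validation suite asserts. Calibration used exactly the
  phantom family the tests use; on other surface families the absolute FD
  may be offset, though ordering in H is preserved.

## Pooled convolutional features

`extract_deep()` is backbone-agnostic: VGG-style stages of 3×3
convolutions + ReLU, 2×2 max pooling, with *global average pooling* of each
stage's output appended to the feature vector. The VGG-19 layout
(64/128/256/512/512 channels) gives 64+128+256+512+512 = 1472 features.
Grayscale patches are min–max scaled and replicated to three channels.
Weights are seeded-random by default (He initialization): the package's test
suite never downloads pretrained weights, and the tiny-test layout (8+16
channels) keeps forward passes fast. Random-weight features are still
informative texture summaries, but users studying transfer learning should
load their own weights. Fully-convolutional native-resolution inference is
the default; `input_size` resizes first (the structural checks use 32 px,
the smallest side that survives five poolings).

## The LSTM sequence classifier

Single layer; logistic gates, tanh cell activation, per-step sigmoid
read-out. Sequences are ordered oldest→newest and zero-*post*-padded to the
batch maximum with a validity mask. The loss is binary cross-entropy of
every *valid* step's read-out against the case label, summed and divided by
the batch's valid-step count (`loss = "sequence"` instead averages within
case first). A per-step loss was chosen over a final-step-only loss because
masking then has real semantics — padded steps are excluded from the loss —
and every prefix of the sequence is pushed toward the label, which
regularizes short sequences. The per-case score is the read-out at the last
valid step, making predictions exactly padding-invariant; this exactness and
an analytic-vs-finite-difference gradient check at 10⁻⁵ are asserted in the
tests.

Features are z-scored with statistics from the *training* portion of each
fold only, and padded cells re-zeroed. Optimization is plain minibatch SGD
(no momentum, no decay, no early stopping), batch size 8. Package defaults
follow the reference operating point — hidden dimension 512, learning rate
10⁻⁴, 100 epochs — selected from a {512, 1024, 2048} × {10⁻³, 10⁻⁴, 10⁻⁵}
grid in the study design this package implements. The validation suite and
the worked examples run a scaled-down operating point (hidden 8–16, learning
rate 0.05, 20–60 epochs, 10–20 features, 100–160 cases): small recurrent
networks need proportionally larger steps, and these sizes keep the full
suite in minutes while leaving the learning dynamics intact. Forget-gate
biases initialize at 1 (standard practice, helps gradient flow over long
sequences); all other initializations are scaled normal with seeded RNG, so
training is bit-reproducible given the config.

## Single-timepoint baseline

Features of the chronologically last antecedent exam only (per breast) are
z-scored, reduced to 25 principal components (capped at the training rank),
and classified with an RBF-kernel SVM, C = 1. Choices worth noting: features
are standardized before PCA because the bank mixes scales differing by
orders of magnitude (an unscaled PCA would be dominated by a handful of
features); the ROC uses the raw SVM margin, since AUC is rank-based and
calibration would be a no-op; the kernel and C are frozen defaults, exposed
in `svm_config()`. All preprocessing is fit inside the cross-validation
loop — the PCA never sees held-out cases.

## Evaluation design

One stratified, case-grouped fold assignment (seeded shuffle within class,
round-robin deal) is shared by every classifier, so paired comparisons see
identical splits; all images/breasts of a case share its fold. AUC
inference is DeLong's nonparametric method (variance, 95% CI, two-sided
z-test against 0.5); paired comparisons use the covariance-aware DeLong
test. This is a deliberate substitution for proprietary binormal
ROC-fitting software used in older workflows — both are AUC inference
procedures, and the nonparametric one is reproducible from scratch. The
pre-registered comparison set is limited to the four scientifically
motivated pairs (feature set A vs B per laterality, affected vs
contralateral per feature set), Holm–Bonferroni corrected; merged
classifiers (per-case score averaging across breasts or feature sets) are
reported without tests to preserve family-wise power.

## Degenerate inputs and tie-breaking

Constant patches: quantize to level 0, GLCM energy 1/entropy 0, NGTDM
coarseness 10¹², histogram skewness/kurtosis defined as 0, Sobel features 0,
blanket FD exactly 2. Zero-variance features: left unscaled with a warning
(both in batch standardization and PCA). Constant score vectors: AUC 0.5,
p = 1. PCA component signs: largest-magnitude loading positive. LSTM
read-outs are clipped to [10⁻⁷, 1−10⁻⁷] inside the loss only.

## Problem sizes used by the validation suite

Spectral-slope recovery uses 512×512 fields, 20 seeds per β ∈ {1.5, 2.0,
2.8} (observed |bias| < 0.02); fractal recovery uses 256×256 phantoms, 6
seeds per H. Null calibration runs five 100-case zero-drift cohorts through
both cross-validated classifiers; the headline experiment runs three
160-case drift cohorts (δ = 0.4/year, field effect on). These sizes are the
package's chosen desk-scale operating points; the machinery is unchanged at
larger sizes.

## Known limitations

* The drift model is a hypothesis-shaped surrogate: linear in time,
  anchored at the last exam, equal in both breasts. Real pre-malignant
  texture change — if present — is uncharacterized and need not look like
  this.
* Absolute fractal-dimension values depend on the amplitude convention and
  fit bands documented above; compare FDs only within this package.
* Random-weight CNN features are a structural stand-in for pretrained
  transfer learning.
* The DICOM reader covers uncompressed explicit-VR little-endian files
  only; anything else errors with instructions to convert.
* With ~100–160 cases, cross-validated AUCs carry standard errors near
  0.04–0.05; single-cohort results (like any single real cohort of this
  size) can sit 2–3 SE from their expectation, which is why the suite
  averages over seeds.
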