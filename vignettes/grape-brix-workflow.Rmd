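---
title: "Predicting wine-grape sugar content from VNIR-SWIR spectra: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting wine-grape sugar content from VNIR-SWIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Grape ripeness is tracked in practice by crushing berries and reading the
total soluble solids — essentially sugars — on a refractometer, in degrees
Brix. A contact-probe spectrometer covering the visible to short-wave
infrared range (350–2500 nm) offers a non-destructive alternative: the
O–H and C–H overtone and combination bands of glucose and fructose leave
their mark on the diffuse reflectance of the berry, so a regression model
can, in principle, read the sugar content straight off the spectrum. This
package implements that modelling workflow end to end: spectral library
management, spectral pre-treatments, four regression families under
nested cross-validation, and wavelength-importance analysis — together
with a synthetic spectra generator that stands in for field data.

# Data model and grids

A `spectral_library` couples a reflectance matrix (samples x bands) to a
strictly increasing wavelength grid and per-sample metadata (variety,
campaign year, bunch label, Brix ground truth). Brix values are validated
against a plausibility window defaulting to the 0–32 °Bx range of a field
refractometer. Spectrometers record at a 1 nm step (2151 points over
350–2500 nm), but their true optical resolution is several nm, so
modelling uses the decimated grid {350 + 10k, k = 0..215} — 216 bands.

**Downsampling operator.** Downsampling could subsample or average; we
average over centred half-open windows [λ − s/2, λ + s/2), truncated at
the recorded range. Averaging suppresses recording noise consistent with
the instrument's coarser true bandwidth; plain decimation is retained as
an option (`method = "decimate"`) for sensitivity checks. On a grid
already at the target step the operator is the identity.

**Quartile convention.** All quartiles — the library summaries and the
RPIQ numerator — use linear interpolation between order statistics
(R's default type 7), stated once here so every reported number is
reproducible to the last digit.

# The nine spectral inputs

Eight pre-treatments plus raw reflectance give nine model inputs:
`Ref`, `Ref+SNV`, `Ref+SG1`, `Abs`, `Abs+SNV`, `Abs+SG1`, `Abs+SG1+SNV`,
`Abs+SG2+SNV`, `CR`. Choices worth stating:

* **SNV** uses the sample (n − 1) standard deviation, so tests are
  deterministic about the normalization.
* **Savitzky–Golay** filters use window 5, polynomial order 3. Derivative
  outputs are scaled per nm (divided by the grid step to the derivative
  power), making them invariant to the sampling step. At the spectrum
  edges the polynomial fitted to the nearest full window is evaluated
  asymmetrically, which keeps the output length equal to the input
  length — a requirement for feeding all nine inputs to the same models.
* **Pseudo-absorbance** is −log10(R); reflectance below 1e−4 (possible as
  noise in field spectra) is clamped to that floor with a warning rather
  than failing a whole library.
* **Continuum removal** divides by the upper convex hull of the spectrum
  in (wavelength, reflectance) coordinates, computed by a monotone-chain
  scan that *retains collinear points*, so any band lying exactly on the
  continuum gets the value 1 exactly; both endpoints are always 1. It is
  applied to reflectance (not absorbance), where the convex-hull
  continuum has its usual interpretation.
* Chains compose left to right; all nine are per-spectrum (stateless)
  transforms, which is why applying them before fold splitting cannot
  leak information across samples.

# Model families and their search spaces

All four families sit behind one `grape_model()` fit/predict contract.

* **PLS** — univariate-response NIPALS, 1–100 latent variables (capped at
  min(p, n − 1) at fit time, the cap being recorded). The kernel is
  written in-package because model selection needs held-out predictions
  for *all* latent-variable counts from one fit, and VIP needs the
  weights, scores and response loadings directly; tests verify both
  predictions and VIP against an independent implementation.
* **RF** — trees in {50, 100, 150, 200} x max-features in
  {"max", "sqrt", "log2"}, with "max" read as all features.
* **SVR** — RBF kernel, epsilon in {0.01, 0.025, 0.05, 0.075, 0.10,
  0.15, 0.20} x cost in {2^−2 … 2^9}. The kernel width is not part of
  the printed grid; we fix it to the "scale" heuristic 1/p on
  standardized inputs and record it with the chosen hyperparameters.
* **Features are standardized internally** (training statistics only)
  for PLS and SVR — without this the cost grid would mean different
  things for different pre-treatments whose scales differ by orders of
  magnitude.
* **CNN** — a 1-D convolutional network: per-band input standardization
  (none / min–max to [−1, 1] / standard score, statistics frozen on the
  training partition), 1–3 conv layers (8–32 filters, kernel 3/5/7,
  optional batch normalization, optional max pooling with window 2),
  1–3 dense layers (8–64 units) with an L2 penalty of 0.0004 on dense
  weights, and a single linear output. Training uses Adam (learning rate
  sampled log-uniformly in [1e−4, 1e−2]), mean-squared-error loss, batch
  sizes 4/6/8, a step decay halving the learning rate every 60 epochs,
  early stopping on validation loss with patience 40 and best-weight
  restore, and at most 200 epochs. Hidden activation is ReLU and the
  loss is MSE (choices this package fixes); the response is centred and
  scaled internally purely for optimizer conditioning and mapped back at
  prediction time. The engine is written in matrix form (activations
  kept as (batch x length) x channels), with one small C kernel for the
  fused in-place Adam update; gradient correctness is verified against
  finite differences in the test suite, and seeded training is
  bit-reproducible.

**Hyperband.** CNN tuning samples configurations uniformly from the
search space and races them by successive halving: with budget R = 200
epochs and reduction factor eta = 3, eight sampled configurations train
for 22 epochs, the best three for 66, the best one for 200, scored by
RMSE on a fixed internal validation split (20% of the calibration set).
Both the number of sampled configurations and eta are configurable; the
defaults form a single bracket, which is the budget-reduced regime this
package targets. Configurations that are structurally impossible on a
given input length (too much pooling before a large kernel) score
infinitely bad rather than aborting the search.

# Nested cross-validation

The outer 5-fold loop holds out each fold once; within each calibration
set, grid families run a full internal 5-fold cross-validation scoring
every grid point, and the configuration minimizing *mean internal
validation RMSE* is refit on the whole calibration set and evaluated on
the held-out fold. R² and RPIQ are reported but never used for
selection. For the CNN, the internal loop is replaced by Hyperband with
one fixed internal validation split per external fold rather than an
internal 5-fold per Hyperband iteration — one fifth the cost, the same
selection criterion, and lower variance than re-randomizing per
candidate. Per-fold RPIQ uses that fold's observed quartiles (so
fold-mean RPIQ is not the global IQR over the mean RMSE; the report
carries the per-fold predictions, from which any variant can be
recomputed). Fold assignment is a seeded uniform shuffle into folds
whose sizes differ by at most one; stratification by response quantile
is available but off by default.

Every report stores, per fold, the held-out predictions and the index
sets of the test fold and calibration set, so the absence of selection
leakage is an auditable property, not a promise — the test suite checks
the intersections are empty.

Best-pre-treatment selection across chains (`select_best`) is keyed on
mean internal-validation RMSE; ties go to the chain with fewer steps,
then alphabetically.

# Importance analysis

* **Mutual information** (pre-hoc): Kraskov k-nearest-neighbour
  estimator with k = 3, per band, with a seeded 1e−10-scale jitter to
  break ties. Estimates are clamped at zero; constant bands are flagged.
  One practical caveat established on the synthetic generator: strong
  multiplicative scatter masks per-band dependence in raw reflectance,
  so the pre-hoc screen is best run on scatter-corrected (SNV)
  reflectance — the estimator is unchanged, only its input.
* **VIP** (PLS): the standard formula over retained latent variables;
  mean squared VIP is 1 by construction. On inputs with uncorrected
  scatter, PLS legitimately assigns high VIP to signal-free "scatter
  probe" bands (low-albedo regions that pin down the per-sample scatter
  factors); profiles are therefore most interpretable on
  scatter-corrected or derivative inputs.
* **Impurity importance** (RF): normalized total variance-reduction per
  feature; non-negative, sums to 1.
* **SAGE** (SVR/CNN, or any predictor): Shapley-fair contribution of
  each band to the reduction in expected squared-error loss, estimated
  by sampled permutations with hidden features marginalized by drawing
  background rows from the training fold (background capped at 128
  rows; default 256 permutations). The telescoping construction makes
  the scores sum exactly to baseline loss minus full-model loss per
  permutation, and Monte-Carlo standard errors over permutations are
  returned as the convergence diagnostic. Band grouping is not applied:
  profiles stay per-wavelength.
* **Cross-fold mean ranking**: per-band means of fold scores and of fold
  ranks are both exported; averaging makes profiles less sparse but more
  robust, and on derivative inputs apparent peaks sit offset from true
  band centers by roughly one band width.

# The synthetic generator

No public grape spectral library with Brix ground truth exists for this
design, so the package generates one with the statistical structure the
pipeline assumes:

R(λ) = B(λ) · exp(−Σ_b d_b(x) G(λ; c_b, w_b)) · (1 + m0 + m1 s(λ)) + a + ε(λ)

a smooth baseline albedo B multiplied by exponentiated Gaussian
absorption bands — a Beer–Lambert-like form that keeps reflectance
positive, which additive Gaussians would not — with band depths linear
in the Brix value x, a multiplicative scatter offset and tilt
(m0, m1 ~ N(0, 0.05)), an additive offset (a ~ N(0, 0.01)), and
heteroscedastic noise with standard deviations 0.002 / 0.004 / 0.006
reflectance units over 350–1000 / 1000–1900 / 1900–2500 nm, echoing the
three detector regions of field spectrometers. Fixed (Brix-independent)
bands sit at 680, 970, 1200, 1440 and 1920 nm; sugar-coupled bands at
680, 730, 920, 960 and 1150 nm carry 0.003 depth units per °Bx, placing
the usable signal in the 550–1300 nm range. The red-variety preset
(Syrah) adds an anthocyanin-like absorption lowering the 450–700 nm
baseline. Brix values are truncated-normal draws per variety with the
field-study moments (e.g. Syrah mean 17.22, sd 5.04, range 4.9–30.0),
sampled by inverse-CDF so generation is deterministic under its seed.

The coupling strength was fixed once so that a plain linear model on
absorbance spectra attains out-of-fold R² well above 0.8 at default
noise — a signal ceiling consistent with the accuracy regime the best
spectroscopic Brix models reach — and the generator is *not* a model of
berry optics: couplings are stand-ins, there is no radiative transfer,
no skin/pulp structure, no temperature or water-status confounders, and
scatter is a two-parameter affine effect. Passing the pipeline's tests
on synthetic data therefore demonstrates correctness of the machinery
and recoverability of a known signal — not field accuracy.

# Problem sizes and numerical choices

The reference benchmark (also recomputed by `scripts/acceptance.R`) is a
single-variety Syrah-like library of n = 240 on the 216-band grid, the
first-derivative reflectance input, and the CNN family under 5-fold CV
with a reduced Hyperband budget of 8 sampled configurations — sizes
chosen so the whole benchmark runs in minutes on one CPU while leaving
the conclusions (fold-mean R² above 0.8, RPIQ above 4) comfortably
reproducible. The test suite uses smaller libraries (n = 50–160) for
structural and property checks. Other numerical choices: zero-variance
features receive unit scale before standardization; a PLS residual below
1e−12 stops component extraction; RPIQ is undefined for a perfect fit
(an error, rather than infinity); and all seeds fan out from one master
seed through a labelled hash (`derive_seed`), so any subcomputation can
be reproduced in isolation.

# Known limitations

* The generator's simplicity means synthetic accuracies overstate what
  field spectra yield; conclusions about *relative* merits of
  pre-treatments or families transfer only qualitatively.
* SAGE on 216 bands with expensive predictors is costly; the default
  permutation budget is modest and the Monte-Carlo standard errors
  should be consulted before reading small score differences.
* The CNN engine is deliberately compact (no GPU, no convolutional
  padding options, ReLU/MSE fixed); it targets the small-sample regime
  of spectroscopic calibration, not large-scale deep learning.
* Campaign years are pooled; the year column is retained so users can
  stratify or split by year themselves.
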