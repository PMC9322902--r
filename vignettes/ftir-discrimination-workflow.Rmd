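---
title: "Discriminating two herbal classes from ATR-FTIR fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating two herbal classes from ATR-FTIR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Lonicerae japonicae Flos* (LJF) and *Lonicerae Flos* (LF) are flower-bud
herbs from the same genus with similar appearance but different
pharmacology, and they are routinely substituted for one another in
commercial preparations. Mid-infrared ATR-FTIR spectroscopy gives a fast,
non-destructive fingerprint of the powdered material: percent transmittance
recorded from 4000 down to 600 cm⁻¹ at 4 cm⁻¹ resolution. The two classes
share almost all of their absorption bands (O–H, C–H, C=O, amide I,
C–O fingerprint region); what separates them are a handful of
class-restricted bands — an amide II band near 1545 cm⁻¹, saccharide modes
near 1400 and 930 cm⁻¹ on one side, and an aromatic band near 1528 cm⁻¹
plus a saponin band near 781 cm⁻¹ on the other.

`ftirdisc` implements the complete chemometric workflow for this problem:
spectral pretreatment, deterministic calibration/validation splitting,
three pattern-recognition models with their tuning procedures,
confusion-matrix evaluation, wavenumber-region and variable-importance
experiments, and frozen-model prediction of external "prescription"
spectra (compound formulations containing one of the two classes).

## The synthetic study conditions

No measured spectra ship with the package; every analysis runs on a
synthetic generator (`generate_spectra()`, `make_fixture()`) that emulates
the statistical structure the workflow has to cope with:

* **Band structure.** Clean absorbance is a sum of Gaussian bands from a
  fixed catalogue (`default_bands()`): twelve shared bands at
  3350, 2920, 2851, 1730, 1630, 1440, 1374, 1320, 1260, 1150, 1050 and
  815 cm⁻¹, three class-A bands (1545, 1400, 930 cm⁻¹) and two class-B
  bands (1528, 781 cm⁻¹). Per-sample band amplitudes get log-normal jitter
  with a 15 % coefficient of variation.
* **Amplitude scaling.** Discriminating bands are 15–30 % of the strongest
  shared band, so the classes are separable but not trivially so, and the
  pretreatment comparison is informative.
* **Band widths.** Shared bands use widths from σ ≈ 8 cm⁻¹ (sharp C–H
  features) to σ = 90 cm⁻¹ (the broad O–H envelope). The five
  class-restricted bands are sharp minor-component bands, σ = 5 cm⁻¹
  (FWHM ≈ 12 cm⁻¹). This keeps essentially all of their information —
  including the two lobes a first derivative produces at roughly ±2σ —
  inside the ±10–12 cm⁻¹ windows the band catalogue and the
  importance-localization analysis use, mirroring how sharp marker bands
  behave under derivative pretreatment.
* **Instrumental artifacts.** Each sample receives a smooth random baseline
  (quadratic polynomial plus a broad Gaussian hump), a multiplicative
  log-normal scatter factor and an additive offset (the particle-size and
  thickness effects scatter correction exists to remove), and white noise
  (0.005 AU for the default/"easy" condition). Absorbance is clipped to
  [0, 4] and emitted as %T = 10^(2−A).
* **Fixtures.** `"easy"` is the main condition (100 samples per class,
  851-point grid). `"hard"` shrinks the discriminating amplitudes to 30 %,
  quadruples amplitude variability and raises noise to 0.08 AU, producing
  genuinely overlapping classes. `"prescription"` pairs an easy-style
  training set with an external set that adds five shared "excipient"
  bands at low noise — formulations containing one of the two classes plus
  other ingredients. Sample counts default to 100 per class (no counts are
  fixed by the study design; 100 makes the 4/5 split exact) with 20 per
  class in external sets.

What the generator does **not** emulate: Lorentzian/Voigt line shapes,
instrument line-spread functions, wavelength-dependent noise, water-vapor
interference structure, or correlated chemical composition across bands.
Passing tests therefore demonstrate the correctness and robustness of the
*workflow*, not field performance on real herbal material.

## Pretreatment recipes

`preset_recipe()` provides the eleven pretreatments compared in the model
grid; every chain starts with `to_absorbance()` (A = 2 − log10 %T):

| preset | chain after absorbance |
|---|---|
| `none` | — |
| `vector_first` | Savitzky–Golay 1st derivative (window 9, order 2) → Euclidean normalization |
| `vector_second` | SG 2nd derivative → Euclidean normalization |
| `minmax` | ATR correction → x/(max−min) |
| `area` | ATR correction → trapezoid-area normalization |
| `ewma` | exponentially weighted moving average, λ = 0.2 |
| `msc` | multiplicative scatter correction |
| `rc` | row centering |
| `sg` | SG smoothing (window 9, order 2) |
| `snv` | standard normal variate |
| `airpls` | airPLS baseline removal |

Design choices that had to be fixed:

* **SG polynomial order** is 2 (the standard chemometrics default; only the
  nine-point window is dictated by convention), and derivatives are taken
  with respect to point index — a constant factor relative to d/dν that the
  subsequent vector normalization absorbs.
* **The `sg` preset is smoothing only** (derivative 0); derivatives appear
  only inside the two vector presets.
* **Min–max normalization** defaults to the range-only form x/(max−min);
  the conventional (x−min)/(max−min) is available as a variant. The
  range-only form is not shift-invariant, which is intentional — it is the
  scaling convention of the acquisition software this workflow mirrors.
* **EWMA** has no conventional constant; λ = 0.2 (one forward pass) is the
  default and configurable.
* **ATR correction** is the simple penetration-depth model
  A′(ν) = A(ν)·ν/ν₀ with ν₀ = 1000 cm⁻¹. The vendor's exact algorithm is
  proprietary; the proportional model captures the 1/ν path-length
  dependence and is applied only inside the `area` and `minmax` presets.
* **airPLS** uses λ = 1e5, a second-order difference penalty, at most 15
  iterations and termination ratio 0.001 — the defaults of the algorithm's
  reference-implementation tradition. The iteratively reweighted Whittaker
  smoother drives weights to zero over peaks, so the smooth fit settles
  onto the baseline; on synthetic peaks over a known linear baseline it
  recovers the baseline to well under 5 % RMSE.
* **Leakage control.** `fit_recipe()` freezes every data-dependent
  statistic (the MSC reference = mean calibration spectrum at its point in
  the chain) on the calibration rows; validation and external sets are
  transformed with the frozen state. The only stage that ever sees the
  pooled data is the Kennard–Stone distance computation, which is
  unsupervised sample selection performed before any statistic is learned.

## Splitting and models

**Kennard–Stone** (`kennard_stone()`) selects 4/5 of the samples per class
for calibration by the classic max–min rule: seed with the most distant
pair, then repeatedly add the sample farthest from the selected set. Ties
break toward the lowest index, so the split is fully deterministic.
Stratifying by class keeps both sets balanced for the per-class metrics;
distances are computed on the same pretreatment under evaluation.

**Random forest** (`fit_rf()`, via `randomForest`) is tuned the way the
study prescribes: ensemble size over {100, 200, 300, 500, 800, 1000} by
lowest OOB misclassification, then m_try over eight values spaced by 2 and
centered on floor(√p) at the chosen size. Permutation accuracy importance
is rescaled so the top variable scores 1, which makes cutoff values like
0.01–0.05 meaningful regardless of p; `select_by_vip()` thresholds on that
scale and refits.

**SVM** (`fit_svm_rbf()`, via `e1071`/libsvm) uses the RBF kernel on
±1-coded classes. When grid search is requested, C ∈ 2^(−3..7) and
γ ∈ 2^(−10..2) are chosen by 5-fold cross-validated accuracy with ties
toward smaller C then smaller γ. At the pretreatment-grid stage the
defaults are C = 1, γ = 1/p — deep tuning is reserved for the RF, matching
the study workflow.

**PLS-DA** (`fit_plsda()`) first screens calibration outliers by PCA (95 %
cumulative variance) plus the Mahalanobis distance of the scores against
the χ² 0.975 quantile, then regresses the 0/1 class code on the spectra by
NIPALS PLS1, choosing the number of components by 5-fold cross-validated
misclassification (ties toward fewer). Class 1 is predicted when the
fitted response reaches 0.5 — the fixed threshold the 0/1 coding implies;
no ROC-optimized threshold is used.

All stochastic steps take explicit seeds (default 20220720), and a given
configuration and seed reproduce every table bit-identically.

## Evaluation

`metrics()` implements the four confusion-matrix parameters — sensitivity
TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total, and the
Matthews correlation (TP·TN−FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A
vanishing denominator yields 0 with a flag rather than an error, so grid
runs never abort. AUC is the rank-based Mann–Whitney statistic with
midrank tie handling, equivalent to the trapezoidal ROC area and invariant
under monotone score transforms; model scores are vote fractions (RF),
logistic-rescaled decision values (SVM) or the fitted response (PLS-DA).
The positive class defaults to the first class alphabetically ("A", the
LJF-like class) and is configurable.

Calibration-set metrics are reported from 5-fold cross-validated
predictions, not resubstitution, which would be trivially optimistic for
separable data.

## The full study

`run_study()` chains the stages: generate/load → 11 × 3
pretreatment-by-model grid → best cell by validation accuracy (ties by
MCC) → RF deep tuning (n_tree, m_try) → wavenumber-region experiment
(full range; full minus the water-vapor 4000–3500 and CO₂ 2442–2208 bands;
2000–600; 4000–2000) → importance-cutoff experiment
({0.05, 0.01, 0.015, 0.020}) → final refit on the surviving variables →
validation metrics, band report, serialized model, log and manifest.
`predict_external()` applies the frozen recipe and model to new spectra,
interpolating linearly onto the training grid when the new grid covers the
training range, and appends the four evaluation parameters when the
external file carries labels.

On the default conditions the study runs in roughly two minutes on one
CPU; the problem sizes used throughout (100 + 100 training spectra,
851 grid points, 20 + 20 external spectra) were chosen as comfortable
desk-scale analyses.

## Numerical choices and degenerate inputs

* %T ≤ 0 is rejected on conversion to absorbance; an opt-in floor clips at
  a configurable minimum instead.
* Constant or zero rows are rejected by the transforms whose definitions
  divide by a row statistic (SNV, vector, min–max, area), naming the
  offending sample.
* Kennard–Stone ties (including exactly duplicated rows) resolve to the
  lowest index; the selection provably contains the maximal-distance pair.
* Importance rescaling divides by the maximum raw drop; if no variable has
  positive importance the scores are all zero with a warning. Variable
  selection keeps at least the top two variables.
* PLS components are truncated at the effective rank of the calibration
  matrix (with a warning); PCA's numerical null space is dropped before
  the Mahalanobis screen.
* airPLS returns its last iterate with a warning when the iteration cap is
  reached.

## Known limitations

* The m_try screening grid is centered on floor(√p); the alternative of an
  arbitrary absolute grid (e.g. 82–96 regardless of p) is available via
  `rf_config(m_try_grid=)` but is not the default, because it is not
  consistent with the √p rule for any plausible p on this grid.
* Only two-class problems are supported; the OVO machinery in libsvm
  degenerates to the single binary machine here, and PLS-DA uses a single
  0/1 response.
* JCAMP-DX support is read-only and limited to uncompressed (AFFN)
  `(X++(Y..Y))` blocks.
* Model serialization stores structured-text metadata next to an opaque
  binary state blob; the guarantee is bit-identical predictions after a
  round trip within one package version, not a portable text codec for
  the tree ensemble.
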