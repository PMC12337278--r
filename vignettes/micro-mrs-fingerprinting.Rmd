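---
title: "Micro-MRS metabolic fingerprinting: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-MRS metabolic fingerprinting: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the data model,
the synthetic-cohort generator and what it does and does not emulate, the
biomarker definitions, the statistical and machine-learning procedures with
their leakage guards, the numerical choices, and the known limitations.

## 1. The problem and the data model

Single preimplantation embryos and single oocytes can be measured with
microcoil ¹H NMR. A measurement yields a free-induction decay (FID) per
sample; its Fourier transform is a 1D spectrum $I(\delta)$ on a
chemical-shift axis $\delta$ (ppm). The informative signal comes from mobile
lipids — fatty-acid protons tumbling freely inside lipid droplets — whose
resonances all fall inside the 0.83–2.8 ppm window, plus the unsuppressed
water line near 4.7 ppm which acts as a stable internal shift reference.

The package stores spectra as S4 `Spectrum` objects (strictly ascending ppm
axis; NMR's descending display convention is a plotting matter), FIDs as
`FID` objects carrying the acquisition bookkeeping (dwell time, spectrometer
frequency in MHz, averages, repetition time), and the analysis windows as a
`RegionSet`:

| region    | ppm          | chemistry                         |
|-----------|--------------|-----------------------------------|
| PLC       | [0.83, 2.8]  | all mobile-lipid protons          |
| Saturate  | [1.1, 1.5]   | saturated methylene (CH₂)ₙ        |
| S1        | [0.83, 1.03] | terminal methyl                   |
| S3        | [2.23, 2.36] | α-carboxyl methylene              |
| SaturateL | [1.3, 1.5]   | high-ppm half of Saturate         |
| SaturateR | [1.1, 1.3]   | low-ppm half of Saturate          |

A bin belongs to a region when its ppm center lies in the closed interval;
`SaturateL ∪ SaturateR = Saturate` and S1, S3, Saturate ⊂ PLC are enforced
by the class validity.

Preprocessing is deliberately minimal: `fidToSpectrum()` applies exponential
apodization, optional zero filling and either zero-order phasing (the phase
is chosen analytically to maximize the real integral over PLC, which
preserves the absorption lineshape the biomarker layer models) or magnitude
calculation; `referenceToWater()` rigidly shifts the axis so the global
maximum — water, by far the tallest line in these water-unsuppressed
acquisitions — sits at 4.70 ppm; `baselineCorrect()` subtracts the median of
a signal-free window (default 9–10 ppm). Whether acquisition produced
phased-real or magnitude spectra is not determined by the data model; both
are supported and phased-real is the default, because the Lorentzian-fit
biomarkers assume an absorption lineshape. The water shift is fixed at
4.70 ppm by convention and configurable; only axis differences matter
downstream, since all biomarkers are computed on regions tied to the same
reference.

## 2. The synthetic-cohort generator

Every downstream stage is tested against synthetic cohorts, so the generator
is first-class, tested code. One sample is generated as

$$I(\delta) = s \sum_k A_k\, \mathrm{pV}\!\left(\delta;\ \delta_k,\
\mathrm{FWHM}_k,\ \lambda_k\right) + \varepsilon(\delta),$$

where $\mathrm{pV}$ is an area-matched pseudo-Voigt line (Lorentzian tail
weight $\lambda \in [0,1]$; the Gaussian component has the same FWHM and the
same integrated area as the Lorentzian it replaces), and:

* the **peak table** defaults to standard fatty-acid assignments placed
  inside the canonical regions — methyl 0.90, bulk methylene 1.30 (the
  dominant lipid line), 1.59, allylic 2.02, α-carboxyl 2.28, water 4.70 —
  with placeholder relative amplitudes. Exact per-peak amplitude ratios of
  bovine embryo lipid spectra vary between preparations, so the table is
  configuration, not code;
* the **global scale** $s$ is log-normal with $\sigma_{\log}$ calibrated so
  that the *expected* max/min intensity ratio across a cohort of the
  configured size is ≈13-fold
  ($\sigma_{\log} = \log 13 / (2\,E[\max_n z])$, with $E[\max_n z]$ the exact
  expectation of the maximum of $n$ standard normals by quadrature);
* **per-peak FWHM** is drawn from a truncated normal (mean 0.12 ppm, SD
  0.04 ppm, lower bound 0.02 ppm), reproducing the reported
  0.12 ± 0.04 ppm linewidth spread;
* **noise** is i.i.d. Gaussian with SD set to (noiseless saturate-region
  maximum) / (target SNR), the target SNR drawn per sample from a truncated
  normal (mean 22, SD 8, lower bound 3) — reproducing the reported
  22 ± 8 SNR under the same estimator the package measures with
  (`spectrumSNR()`: saturate peak maximum over the SD of a 9–10 ppm noise
  window);
* **cohort effects** multiply the amplitude of peaks inside Saturate
  (concentration), the amplitude of peaks inside S1, the Lorentzian tail
  weight of Saturate peaks (lineshape at constant area), and rigidly shift
  lipid peak centers (skewness against the fixed windows).

Sample seeds derive deterministically from the master seed and the sample
id, so cohorts are bit-reproducible and independent of generation order, and
each spectrum carries its generating parameters in `meta(spec)$truth` for
recovery tests.

**Presets.** `embryo61` (54 ARR / 7 DEV) and `oocyte102` (63 IMM / 39 MAT)
reproduce the two experimental cohort shapes. The effect sizes are the
package's chosen "strong planted effect" conditions, picked once from measured
standardized marker responses: DEV carries saturate amplitude ×1.5, tail
weight ×0.2 and S1 ×1.2; MAT carries saturate amplitude ×2.0 (its dominant
reported effect, driving Saturate-Int p ≪ 10⁻⁴ with MAT > IMM), tail ×0.9
and S1 ×1.3.

**Why a tail-weight knob drives the kurtosis biomarker.** The biomarker the
embryo analysis singles out is the kurtosis of the low-ppm half of the
saturate line. Direct mechanisms fail a requirement the attribution analysis
imposes — that the planted effect move *that* marker more than any other, in
standardized units. A flank-width multiplier moves the region's skewness
about 2.5× more than its kurtosis (flank asymmetry *is* skewness), and a
symmetric width multiplier moves the fitted width most. Tail weight is the
shape property that kurtosis actually measures: blending the line between
Lorentzian ($\lambda = 1$, heavy tails) and Gaussian character at constant
area and constant FWHM moves Kurt-SaturateR roughly twice as strongly as the
next-most-responsive marker while leaving integrals nearly unchanged. It is
also real spectroscopy: transverse relaxation gives Lorentzian lines, field
inhomogeneity adds Gaussian character.

**Sign of the embryo lineshape effect.** The baseline cohort is pure
Lorentzian and the DEV effect *lightens* the tails (raising Kurt-SaturateR).
The reason is identifiability, not biology: the kurtosis of a
region-truncated Lorentzian is nearly invariant to its FWHM, so a pure
Lorentzian baseline gives the majority cohort a tight kurtosis distribution
against which a lineshape shift is statistically visible; the opposite
arrangement buries the effect in the baseline's own kurtosis variance. The
synthetic conditions emulate the *kind* and *strength* of the reported
kurtosis effect, not its sign, and nothing downstream assumes a direction.

**What the generator does not emulate:** measured per-peak amplitude
ratios, J-coupling multiplets and peak overlap beyond six singlet
lines, baseline drift and phase errors, coil-sensitivity or temperature
artifacts, and any dependence between samples measured on one chip. Passing
tests therefore demonstrate that the *pipeline* is correct and calibrated on
spectra with the study's summary statistics — not that real embryos are
classifiable at these accuracies.

## 3. The fourteen biomarkers

`biomarkerRegistry()` defines, in order: PLC/Saturate/S1/S3/SaturateL/
SaturateR-Int, PLC/Saturate/SaturateR-Skew, PLC/Saturate/SaturateR-Kurt,
Saturate-Ampl, Saturate-Width. Two QC quantities (SNR and the fitted
saturate linewidth) ride along in every feature table. The choice of the
Saturate and SaturateR windows for the remaining skew/kurt slots is the
package's own; the registry is a plain data.frame precisely so the panel can
be re-configured without touching code.

* **Intensity** is the trapezoidal integral of the region, with negative
  bins clipped to zero first. "Intensity" could also mean region mean or
  maximum; the integral was chosen because it is the physically meaningful
  (concentration-proportional) quantity, and alternatives are a one-line
  registry change.
* **Skewness and kurtosis** treat the clipped intensity $w(\delta) = \max(I
  (\delta), 0)$ as an unnormalized density *on the chemical shift* and
  return its standardized third and fourth central moments. They are
  lineshape descriptors — a sharper line concentrates weight and raises
  kurtosis — not moments of the intensity-value histogram; this reading
  follows from interpreting higher kurtosis as a sharper spectral profile.
  Kurtosis is Pearson (non-excess), so a flat profile gives exactly 9/5 and
  a Gaussian profile 3. Clipping is required because moment weights must be
  non-negative; otherwise baseline noise dips corrupt the moments.
* **Lorentzian fit**: nonlinear least squares of
  $A\gamma^2/((\delta-\delta_0)^2+\gamma^2)+c$ by Levenberg–Marquardt,
  initialized at the region argmax, max-minus-median amplitude and the
  half-maximum crossing width, with box constraints keeping $\delta_0$ in
  the region and $\gamma$ positive. Non-convergence (or a width pinned at
  its bound) yields `converged = FALSE` and `NA` values, which the ML layer
  imputes with the *training-fold* median — never a pooled statistic, to
  preserve the leakage guarantees.
* Intensities are raw integrals by default: single-cell acquisitions show
  ~13-fold raw between-sample variation and water serves only as a shift
  reference, so water normalization (`normalize = "water"`) is an option,
  not the default.

Scale equivariance (intensities and amplitude scale, shape statistics do
not) and shift equivariance (rigid ppm shifts with co-shifted regions change
nothing) are property-tested.

## 4. Cohort statistics

`compareCohorts()` follows the standard two-cohort scheme for these data: a Lilliefors
normality gate on each group, Welch's *t* if both pass at α = 0.05, a
two-sided Mann–Whitney *U* otherwise. Two implementation choices matter:

* the Lilliefors null (KS distance to a normal with *estimated* parameters)
  is simulated — ≥5000 seeded Monte-Carlo replicates, each re-estimating
  mean and SD — so the gate is deterministic given the seed and exact in
  calibration; the analytic approximation in `nortest::lillie.test` is used
  as an independent cross-check in tests only. Groups below n = 4 cannot be
  assessed and fail the gate (the rank test is the safe default).
* the Mann–Whitney *U* uses midranks; when both groups have ≤10
  observations the null is enumerated exactly over all rank splits (ties
  handled exactly), otherwise a tie-corrected normal approximation with
  continuity correction is used. The implementation is verified against a
  brute-force pair-counting oracle for all group sizes ≤7 and against
  `wilcox.test` where the latter is exact.

## 5. The leakage-controlled classification stack

With 7 positives among 61 samples there is no room for a held-out test set;
everything rests on leave-one-out cross-validation being honest. The order
of operations inside `loocv()` is the entire point:

1. remove the held-out sample;
2. impute missing biomarkers with the training fold's medians;
3. standardize with the training fold's means and SDs;
4. SMOTE the minority class up to the majority count — each synthetic row is
   $x + u(x' - x)$, $u \sim U(0,1)$, between a minority row and one of its
   $k$ nearest minority neighbors ($k = 5$, auto-reduced to
   $n_\text{minority}-1$) in the standardized space;
5. PCA on the balanced standardized training data (all non-degenerate
   components by default);
6. RBF SVM (C = 1, γ = 1/d) on the PC scores;
7. transform the held-out sample with the *frozen* fold parameters and
   record its label and signed decision value.

Whether SMOTE should run before or after PCA is genuinely open — both
orders keep validation clean — so both are implemented behind
`pipelineConfig(pcaBeforeSmote = )`, with standardize → SMOTE → PCA as the
default (balancing in the original standardized feature space keeps the PCA
basis interpretable against the biomarkers). The SVM kernel and
hyperparameters are likewise open; RBF with C = 1 and the 1/d bandwidth
heuristic is the standard small-n default, exposed in the config.

Structural guards: synthetic rows are named `synthetic_*` and an assertion
fails the run if such an id ever reaches a validation fold; per-fold RNG
seeds derive from the master seed and the held-out sample id, and folds are
processed in canonical id order, so predictions are bit-identical under row
permutation; fold models are fit from the training rows alone, so the
held-out row cannot influence any parameter (tested by hash equality).

Metrics pool the held-out confusion counts across folds (matching an
aggregated cross-validation confusion matrix, not per-fold averaging):
accuracy, balanced accuracy, sensitivity, specificity, precision, NPV, F1
and AUC. AUC uses the Mann–Whitney rank formulation with midrank ties on the
signed SVM decision values — LOOCV yields exactly one score per sample, and
the rank form equals trapezoidal ROC integration. Undefined panel entries
(e.g. precision with zero predicted positives) are `NaN` and flagged, never
0. The `dummyBaseline()` predicts the majority class with a constant score,
which gives AUC exactly 0.5 under midranks.

**Leakage sentinel.** On null-effect cohorts (all multipliers 1, labels
carry no signal) the cross-validated AUC must be chance-level. At 54/7 the
null AUC of a *correct* pipeline has SD ≈ 0.13 (7 positives), so single
seeds legitimately land outside [0.3, 0.7]; the sentinel therefore asserts
the mean over 20 seeded replicates (measured ≈ 0.47). Pipelines that fit the
scaler, SMOTE or PCA on all data before splitting shift this mean upward.

**PCA views.** `pcaScatterData()` standardizes, SMOTE-balances and fits PCA
on the *whole* dataset — explicitly a visualization of cohort structure,
never an inferential step — with a deterministic sign convention (the
largest-|loading| entry of each component is positive).

## 6. Exact Shapley attribution

`exactShapley()` computes interventional Shapley values by full coalition
enumeration: $v(S)$ is the background-mean model score of the hybrid input
taking features in $S$ from the explained sample and the rest from a
background row, and $\phi_i = \sum_S \frac{|S|!(n-|S|-1)!}{n!}(v(S \cup
\{i\}) - v(S))$. With at most 16 features the $2^n$ enumeration is cheap and
removes any sampling approximation, so efficiency
($\text{base} + \sum_i \phi_i = f(x)$), linearity, symmetry and the null
player axiom hold to numerical precision and are property-tested, including
against a permutation-average oracle.

`shapSummary()` produces the whole-model interpretability summary: the
pipeline is refit on the full dataset (pooled standardization, SMOTE
balance, PCA), an SVM is trained on the first 8 PC scores, and every
original sample's decision score is attributed over those PCs; features are
ranked by mean $|\phi|$. A full-data refit was chosen over fold-wise
aggregation because it explains one model rather than 61; fold-wise
attribution remains available by calling `exactShapley()` on any
`fitFold()` model. The
background is the balanced training score matrix, deterministically
subsampled to 64 rows for speed (the interventional convention; the cap is
configurable).

On planted-effect cohorts the PC carrying the largest Kurt-SaturateR loading
is the top-ranked feature in most cohort draws; at 54/7 the PC basis itself
is sampling-noisy, so the recovery test asserts a majority across seeded
replicates rather than every draw.

## 7. Numerical choices and degenerate inputs

* Regions are closed intervals on bin centers; <4 bins is a resolution
  error (<8 for fits).
* Tied global maxima in referencing resolve to the higher ppm with a
  warning; zero noise SD gives SNR = +∞ with a warning; an all-zero or
  all-clipped region is an error for moments, a flagged `NA` in extraction.
* The truncated-normal sampler resamples up to 100 times per draw and then
  aborts, so impossible configurations fail loudly.
* Fit convergence additionally requires the width to stay off its upper
  bound and a positive amplitude; everything else is `converged = FALSE`.
* CSV spectra are written with `%.17g`, so write→read round trips are exact
  for doubles; only scalar metadata survive the flat header format.
* All stochastic steps (generation, SMOTE, Lilliefors null, fold fitting)
  take seeds derived from a master seed by a 31-bit rolling hash of the
  relevant id, which keeps results independent of processing order and all
  seeds below 2³¹.

## 8. Problem sizes used by the tests

The suite uses the cohort sizes the presets define (61 and 102 samples),
200-spectrum calibration runs for the linewidth and SNR closures, 20 seeded
replicates for the leakage sentinel and 5 for the attribution recovery —
sizes at which the stochastic assertions are comfortably stable while the
whole suite stays in the low minutes on a single CPU.

## 9. Known limitations

* The biomarker moment definitions are one defensible reading of
  region-level "skewness/kurtosis"; the registry keeps them configurable.
* The single-Lorentzian-plus-offset fit is not a deconvolution; overlapping
  lines bias the width upward slightly (visible as the ≈0.117 ppm mean
  fitted width against the 0.12 ppm generating mean).
* Balanced accuracy is always the confusion-matrix identity
  (sensitivity + specificity)/2; externally reported panels sometimes
  compute it differently, so exact cross-comparison of that one metric may
  require care.
* Replication on real acquisitions requires externally deposited feature
  tables; `loocv()` accepts any feature table with the documented columns,
  but the package ships no downloader and runs fully offline.
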