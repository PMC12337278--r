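#' @import methods
NULL

#' Free-induction decay (FID)
#'
#' Complex time-domain signal acquired by a single micro-coil, together with
#' the acquisition bookkeeping needed to reconstruct a chemical-shift axis:
#' the dwell time (seconds per complex point) and the spectrometer frequency
#' (MHz, the proton Larmor frequency; about 300 MHz at 7 T).
#'
#' The `metadata` list carries acquisition and sample annotations
#' (`sample_id`, `channel_index`, `sensor_id`, `n_averages`,
#' `repetition_time_s`, and `ref_ppm`, the chemical shift assigned to the
#' zero-frequency edge of the spectral window).
#'
#' @slot samples complex vector of time-domain points.
#' @slot dwellTime seconds per point; must be positive.
#' @slot spectrometerFreq proton Larmor frequency in MHz; must be positive.
#' @slot metadata named list of annotations.
#'
#' @seealso [fidToSpectrum()], [spectrumToFid()]
#' @export
setClass("FID", representation(
  samples = "complex",
  dwellTime = "numeric",
  spectrometerFreq = "numeric",
  metadata = "list"
))

setValidity("FID", function(object) {
  msg <- character()
  if (length(object@dwellTime) != 1L || !is.finite(object@dwellTime) || object@dwellTime <= 0)
    msg <- c(msg, "dwellTime must be a single positive number")
  if (length(object@spectrometerFreq) != 1L || !is.finite(object@spectrometerFreq) ||
      object@spectrometerFreq <= 0)
    msg <- c(msg, "spectrometerFreq must be a single positive number (MHz)")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be non-empty")
  if (length(msg)) msg else TRUE
})

#' One-dimensional 1H spectrum
#'
#' A real-valued spectrum on a strictly monotone chemical-shift axis (ppm).
#' The axis is stored ascending; NMR display convention (descending ppm) is a
#' plotting concern, not a storage one. `referenced` records whether the axis
#' has been anchored to the water resonance.
#'
#' @slot ppm strictly increasing chemical-shift axis in ppm.
#' @slot intensity real intensities, same length as `ppm`.
#' @slot metadata named list (`sample_id`, `cohort_label`, `channel_index`,
#'   `sensor_id`, ...). Synthetic spectra carry their generating parameters
#'   under `metadata$truth`.
#' @slot referenced logical flag set by [referenceToWater()].
#'
#' @export
setClass("Spectrum", representation(
  ppm = "numeric",
  intensity = "numeric",
  metadata = "list",
  referenced = "logical"
))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2L && any(diff(object@ppm) <= 0))
    msg <- c(msg, "ppm axis must be strictly increasing")
  if (anyNA(object@ppm) || any(!is.finite(object@ppm)))
    msg <- c(msg, "ppm axis must be finite")
  if (length(object@referenced) != 1L)
    msg <- c(msg, "referenced must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Named chemical-shift regions
#'
#' Closed ppm intervals on which the biomarkers are computed. The default set
#' ([defaultRegionSet()]) holds the six windows used throughout: PLC
#' [0.83, 2.8] (the full protein-lipid complex window), Saturate [1.1, 1.5]
#' (saturated methylene protons), S1 [0.83, 1.03] (terminal methyl), S3
#' [2.23, 2.36] (alpha-carboxyl methylene), and the two halves SaturateL
#' [1.3, 1.5] and SaturateR [1.1, 1.3]. A bin belongs to a region when its
#' ppm center lies inside the closed interval.
#'
#' @slot regions named list of length-2 numeric vectors `c(lo, hi)`, lo < hi.
#'
#' @export
setClass("RegionSet", representation(regions = "list"))

setValidity("RegionSet", function(object) {
  msg <- character()
  r <- object@regions
  if (is.null(names(r)) || any(!nzchar(names(r))))
    msg <- c(msg, "all regions must be named")
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      msg <- c(msg, sprintf("region '%s' must be c(lo, hi) with lo < hi", nm))
  }
  # structural relations, enforced when the canonical names are present
  canon <- c("PLC", "Saturate", "S1", "S3", "SaturateL", "SaturateR")
  if (all(canon %in% names(r)) && !length(msg)) {
    eps <- 1e-9
    sat <- r$Saturate
    if (abs(r$SaturateR[1] - sat[1]) > eps || abs(r$SaturateL[2] - sat[2]) > eps ||
        abs(r$SaturateR[2] - r$SaturateL[1]) > eps)
      msg <- c(msg, "SaturateL and SaturateR must partition Saturate")
    for (nm in c("S1", "S3", "Saturate")) {
      if (r[[nm]][1] < r$PLC[1] - eps || r[[nm]][2] > r$PLC[2] + eps)
        msg <- c(msg, sprintf("%s must lie inside PLC", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic-cohort generator configuration
#'
#' The generative contract for labeled synthetic single-sample spectra:
#' a Lorentzian peak table, per-cohort effect multipliers, and the noise /
#' linewidth / intensity-variation calibration. Defaults reproduce the
#' spectral statistics of single-embryo micro-MRS acquisitions: linewidths
#' 0.12 +/- 0.04 ppm, SNR 22 +/- 8 (saturate-region peak maximum over noise
#' SD), and roughly 13-fold between-sample intensity variation.
#'
#' @slot peakTable data.frame with columns `assignment`, `center_ppm`,
#'   `fwhm_ppm`, `amplitude` and optionally `lorentz_frac` (pseudo-Voigt
#'   Lorentzian tail weight in [0, 1], default 1). See [defaultPeakTable()].
#' @slot cohortEffects named list of [cohortEffect()] lists, one per label.
#' @slot nPerClass named integer vector of cohort sizes.
#' @slot targetSnrMean,targetSnrSd SNR calibration; per-sample target SNR is
#'   drawn from a truncated normal (lower bound 3). `targetSnrMean = Inf`
#'   switches noise off.
#' @slot fwhmMean,fwhmSd linewidth calibration in ppm; per-peak FWHM is drawn
#'   from a truncated normal (lower bound 0.02 ppm).
#' @slot intensityLognormalSd sd of the log-normal per-sample global scale.
#'   `NA` means: calibrate at build time so the expected max/min intensity
#'   ratio across the cohort is `intensityFold`.
#' @slot intensityFold target fold-change for the calibration (default 13).
#' @slot axisRange,axisBins ppm axis specification (default 0-10 ppm, 4096).
#' @slot waterPpm water resonance position used for the reference peak.
#' @slot seed master seed; all per-sample seeds derive from it.
#'
#' @seealso [synthConfig()], [cohortPreset()], [generateCohort()]
#' @export
setClass("SynthConfig", representation(
  peakTable = "data.frame",
  cohortEffects = "list",
  nPerClass = "integer",
  targetSnrMean = "numeric",
  targetSnrSd = "numeric",
  fwhmMean = "numeric",
  fwhmSd = "numeric",
  intensityLognormalSd = "numeric",
  intensityFold = "numeric",
  axisRange = "numeric",
  axisBins = "integer",
  waterPpm = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  pt <- object@peakTable
  need <- c("assignment", "center_ppm", "fwhm_ppm", "amplitude")
  if (!all(need %in% names(pt)))
    msg <- c(msg, paste("peakTable must have columns", paste(need, collapse = ", ")))
  else {
    if (any(pt$fwhm_ppm <= 0)) msg <- c(msg, "peak fwhm_ppm must be positive")
    if (any(pt$amplitude < 0)) msg <- c(msg, "peak amplitude must be non-negative")
    if ("lorentz_frac" %in% names(pt) &&
        (any(pt$lorentz_frac < 0) || any(pt$lorentz_frac > 1)))
      msg <- c(msg, "lorentz_frac must lie in [0, 1]")
    plc <- c(0.83, 2.8)
    lip <- pt$center_ppm[pt$assignment != "water"]
    if (length(lip) && (any(lip < plc[1]) || any(lip > plc[2])))
      msg <- c(msg, "every non-water peak center must lie inside PLC [0.83, 2.8]")
  }
  if (any(object@nPerClass < 1L)) msg <- c(msg, "nPerClass entries must be >= 1")
  if (!all(names(object@nPerClass) %in% names(object@cohortEffects)))
    msg <- c(msg, "every label in nPerClass needs a cohortEffects entry")
  for (ce in object@cohortEffects) {
    mult <- unlist(ce[c("saturate_amp_multiplier", "saturate_tail_multiplier",
                        "s1_amp_multiplier")])
    if (any(!is.finite(mult)) || any(mult <= 0))
      msg <- c(msg, "cohort effect multipliers must be positive")
  }
  if (length(object@axisRange) != 2L || object@axisRange[1] >= object@axisRange[2])
    msg <- c(msg, "axisRange must be c(lo, hi) with lo < hi")
  if (object@axisBins < 64L) msg <- c(msg, "axisBins must be at least 64")
  if (length(msg)) msg else TRUE
})

#' Leave-one-out cross-validation result
#'
#' Per-fold held-out predictions: exactly one row per sample, each sample
#' held out exactly once, and never a synthetic (SMOTE) row. `folds` keeps
#' per-fold summaries (PCA explained variance, a hash of the scaler
#' parameters) for leakage auditing.
#'
#' @slot predictions data.frame with columns `sample_id`, `truth`,
#'   `predicted`, `score` (signed decision value for the positive class).
#' @slot positiveClass label treated as positive.
#' @slot folds list of per-fold summaries.
#'
#' @export
setClass("CVResult", representation(
  predictions = "data.frame",
  positiveClass = "character",
  folds = "list"
))

setValidity("CVResult", function(object) {
  msg <- character()
  p <- object@predictions
  need <- c("sample_id", "truth", "predicted", "score")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("predictions must have columns", paste(need, collapse = ", ")))
  else if (anyDuplicated(p$sample_id))
    msg <- c(msg, "each sample must be held out exactly once")
  if (length(msg)) msg else TRUE
})

#' Confusion-matrix metric panel
#'
#' Pooled confusion matrix over all held-out predictions plus the derived
#' panel: accuracy, balanced accuracy, sensitivity, specificity, precision,
#' negative predictive value, F1 and ROC AUC (rank formulation, midrank tie
#' handling). Metrics undefined for a given matrix (e.g. precision with zero
#' predicted positives) are `NaN` and listed in `flags`, never reported as 0.
#'
#' @slot tp,fp,fn,tn confusion-matrix counts (positive class given by
#'   `positiveClass`).
#' @slot accuracy,balancedAccuracy,sensitivity,specificity,precision,npv,f1,auc
#'   the metric panel, all in [0, 1] when defined.
#' @slot positiveClass label counted as positive.
#' @slot flags names of metrics that were undefined.
#'
#' @export
setClass("MetricsReport", representation(
  tp = "integer", fp = "integer", fn = "integer", tn = "integer",
  accuracy = "numeric", balancedAccuracy = "numeric",
  sensitivity = "numeric", specificity = "numeric",
  precision = "numeric", npv = "numeric", f1 = "numeric", auc = "numeric",
  positiveClass = "character",
  flags = "character"
))

setValidity("MetricsReport", function(object) {
  msg <- character()
  n <- object@tp + object@fp + object@fn + object@tn
  if (n < 1L) msg <- c(msg, "empty confusion matrix")
  chk <- function(x) is.nan(x) || (is.finite(x) && x >= 0 && x <= 1 + 1e-12)
  for (nm in c("accuracy", "balancedAccuracy", "sensitivity", "specificity",
               "precision", "npv", "f1", "auc")) {
    if (!chk(slot(object, nm))) msg <- c(msg, sprintf("%s outside [0, 1]", nm))
  }
  if (!is.nan(object@accuracy) &&
      abs(object@accuracy - (object@tp + object@tn) / n) > 1e-12)
    msg <- c(msg, "accuracy != (TP + TN) / N")
  if (length(msg)) msg else TRUE
})

#' Exact Shapley attribution report
#'
#' Per-sample, per-feature Shapley values of a fitted model's decision score
#' over principal-component features, computed by full coalition enumeration
#' (interventional value function). Satisfies the efficiency axiom: for every
#' sample, `baseValue + sum(values[i, ])` equals the model score.
#'
#' @slot values numeric matrix, samples x features.
#' @slot baseValue background mean score.
#' @slot scores model score per sample.
#' @slot ranking feature names ordered by decreasing mean absolute Shapley
#'   value.
#' @slot featureNames column names of `values`.
#'
#' @export
setClass("ShapleyReport", representation(
  values = "matrix",
  baseValue = "numeric",
  scores = "numeric",
  ranking = "character",
  featureNames = "character"
))

setValidity("ShapleyReport", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@scores))
    msg <- c(msg, "one score per sample required")
  if (length(object@scores) &&
      max(abs(object@baseValue + rowSums(object@values) - object@scores)) > 1e-6)
    msg <- c(msg, "efficiency violated: base + sum(values) != score")
  if (length(msg)) msg else TRUE
})
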