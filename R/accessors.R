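#' @include AllClasses.R
NULL

#' Construct a Spectrum
#'
#' @param ppm strictly increasing chemical-shift axis (ppm).
#' @param intensity real intensities, same length as `ppm`.
#' @param metadata named list of annotations.
#' @param referenced whether the axis is already water-referenced.
#' @return A [Spectrum-class] object.
#' @examples
#' sp <- newSpectrum(seq(0, 10, length.out = 256), rnorm(256))
#' sp
#' @export
newSpectrum <- function(ppm, intensity, metadata = list(), referenced = FALSE) {
  new("Spectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      metadata = metadata, referenced = referenced)
}

#' Construct an FID
#'
#' @param samples complex time-domain samples.
#' @param dwellTime seconds per point.
#' @param spectrometerFreq proton Larmor frequency in MHz.
#' @param metadata named list; `ref_ppm` gives the ppm value of the
#'   zero-frequency edge of the spectral window (default 0).
#' @return An [FID-class] object.
#' @export
newFID <- function(samples, dwellTime, spectrometerFreq, metadata = list()) {
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("FID contains non-finite samples")
  new("FID", samples = as.complex(samples), dwellTime = dwellTime,
      spectrometerFreq = spectrometerFreq, metadata = metadata)
}

#' Construct a RegionSet
#'
#' @param ... named length-2 numeric vectors, e.g. `Saturate = c(1.1, 1.5)`.
#' @return A [RegionSet-class].
#' @export
regionSet <- function(...) new("RegionSet", regions = list(...))

#' The canonical biomarker regions
#'
#' PLC [0.83, 2.8], Saturate [1.1, 1.5], S1 [0.83, 1.03], S3 [2.23, 2.36],
#' SaturateL [1.3, 1.5], SaturateR [1.1, 1.3].
#'
#' @return A [RegionSet-class] with the six canonical windows.
#' @export
defaultRegionSet <- function() {
  regionSet(
    PLC = c(0.83, 2.8),
    Saturate = c(1.1, 1.5),
    S1 = c(0.83, 1.03),
    S3 = c(2.23, 2.36),
    SaturateL = c(1.3, 1.5),
    SaturateR = c(1.1, 1.3)
  )
}

#' @rdname Spectrum-class
#' @param object,x a `Spectrum`.
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))
#' @rdname Spectrum-class
#' @export
setMethod("ppm", "Spectrum", function(x) x@ppm)

#' @rdname Spectrum-class
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname Spectrum-class
#' @export
setMethod("intensity", "Spectrum", function(x) x@intensity)

#' @rdname Spectrum-class
#' @export
setGeneric("isReferenced", function(x) standardGeneric("isReferenced"))
#' @rdname Spectrum-class
#' @export
setMethod("isReferenced", "Spectrum", function(x) x@referenced)

#' Metadata accessor
#' @param x an object with a metadata slot.
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))
#' @rdname meta
#' @export
setMethod("meta", "Spectrum", function(x) x@metadata)
#' @rdname meta
#' @export
setMethod("meta", "FID", function(x) x@metadata)

#' @rdname Spectrum-class
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))
#' @rdname Spectrum-class
#' @export
setMethod("sampleID", "Spectrum", function(x) {
  id <- x@metadata$sample_id
  if (is.null(id)) NA_character_ else as.character(id)
})

#' @rdname RegionSet-class
#' @param x a `RegionSet`.
#' @param name region name.
#' @export
setGeneric("region", function(x, name) standardGeneric("region"))
#' @rdname RegionSet-class
#' @export
setMethod("region", "RegionSet", function(x, name) {
  if (!name %in% names(x@regions))
    stop("unknown region '", name, "'; available: ",
         paste(names(x@regions), collapse = ", "))
  x@regions[[name]]
})

#' @rdname RegionSet-class
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname RegionSet-class
#' @export
setMethod("regionNames", "RegionSet", function(x) names(x@regions))

#' @rdname CVResult-class
#' @param x a `CVResult`.
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
#' @rdname CVResult-class
#' @export
setMethod("predictions", "CVResult", function(x) x@predictions)

#' Metric panel as a named numeric vector
#' @param x a `MetricsReport`.
#' @export
setGeneric("metricPanel", function(x) standardGeneric("metricPanel"))
#' @rdname metricPanel
#' @export
setMethod("metricPanel", "MetricsReport", function(x) {
  c(accuracy = x@accuracy, balanced_accuracy = x@balancedAccuracy,
    sensitivity = x@sensitivity, specificity = x@specificity,
    precision = x@precision, npv = x@npv, f1 = x@f1, auc = x@auc)
})

#' Shapley values accessor
#' @param x a `ShapleyReport`.
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))
#' @rdname shapValues
#' @export
setMethod("shapValues", "ShapleyReport", function(x) x@values)

#' @rdname shapValues
#' @export
setGeneric("shapRanking", function(x) standardGeneric("shapRanking"))
#' @rdname shapValues
#' @export
setMethod("shapRanking", "ShapleyReport", function(x) x@ranking)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@ppm)
  cat(sprintf("Spectrum '%s': %d bins, %.3f-%.3f ppm, %s\n",
              sampleID(object), length(object@ppm), rng[1], rng[2],
              if (object@referenced) "referenced" else "unreferenced"))
  lbl <- object@metadata$cohort_label
  if (!is.null(lbl)) cat("  cohort:", lbl, "\n")
})

setMethod("show", "FID", function(object) {
  cat(sprintf("FID: %d complex points, dwell %.3g s, %.1f MHz\n",
              length(object@samples), object@dwellTime, object@spectrometerFreq))
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet with", length(object@regions), "regions:\n")
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    cat(sprintf("  %-10s [%.2f, %.2f] ppm\n", nm, r[1], r[2]))
  }
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", nrow(object@peakTable), "peaks;",
      paste(sprintf("%s=%d", names(object@nPerClass), object@nPerClass),
            collapse = ", "),
      sprintf("; SNR %.3g +/- %.3g; FWHM %.3g +/- %.3g ppm; seed %d\n",
              object@targetSnrMean, object@targetSnrSd,
              object@fwhmMean, object@fwhmSd, object@seed))
})

setMethod("show", "CVResult", function(object) {
  p <- object@predictions
  cat(sprintf("CVResult: %d leave-one-out folds, positive class '%s', %d correct\n",
              nrow(p), object@positiveClass, sum(p$truth == p$predicted)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (positive = '%s')\n", object@positiveClass))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              object@tp, object@fp, object@fn, object@tn))
  m <- metricPanel(object)
  cat(" ", paste(sprintf("%s=%.3f", names(m), m), collapse = " "), "\n")
  if (length(object@flags))
    cat("  undefined:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ShapleyReport", function(object) {
  cat(sprintf("ShapleyReport: %d samples x %d features, base value %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
  cat("  ranking:", paste(utils::head(object@ranking, 8L), collapse = " > "), "\n")
})
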