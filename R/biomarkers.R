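#' @include AllClasses.R accessors.R spectra.R
NULL

# bins whose ppm centers lie in the closed interval
regionIndices <- function(spec, reg) {
  which(spec@ppm >= reg[1] & spec@ppm <= reg[2])
}

#' The default biomarker registry
#'
#' Fourteen per-sample biomarkers: region integrals (`Int`) for PLC,
#' Saturate, S1, S3, SaturateL and SaturateR; lineshape skewness (`Skew`) for
#' PLC, Saturate and SaturateR; lineshape kurtosis (`Kurt`, Pearson,
#' non-excess) for the same three windows; and the amplitude and linewidth of
#' a Lorentzian fit in the Saturate region. The registry is a plain
#' data.frame and fully configurable.
#'
#' @return data.frame with columns `name`, `region`, `kind`.
#' @export
biomarkerRegistry <- function() {
  data.frame(
    name = c("PLC-Int", "Saturate-Int", "S1-Int", "S3-Int",
             "SaturateL-Int", "SaturateR-Int",
             "PLC-Skew", "Saturate-Skew", "SaturateR-Skew",
             "PLC-Kurt", "Saturate-Kurt", "SaturateR-Kurt",
             "Saturate-Ampl", "Saturate-Width"),
    region = c("PLC", "Saturate", "S1", "S3", "SaturateL", "SaturateR",
               "PLC", "Saturate", "SaturateR",
               "PLC", "Saturate", "SaturateR",
               "Saturate", "Saturate"),
    kind = c(rep("Int", 6), rep("Skew", 3), rep("Kurt", 3),
             "LorentzAmpl", "LorentzWidth"),
    stringsAsFactors = FALSE
  )
}

#' Region intensity (trapezoidal integral)
#'
#' Integrates the non-negative part of the intensity over the region's bins
#' by the trapezoid rule. Negative bins (baseline noise dips) are clipped to
#' zero first, so intensities are always non-negative.
#'
#' @param spec a baseline-corrected, referenced [Spectrum-class].
#' @param reg length-2 ppm interval `c(lo, hi)`.
#' @return numeric integral (intensity x ppm units).
#' @export
regionIntensity <- function(spec, reg) {
  idx <- regionIndices(spec, reg)
  if (length(idx) < 4L)
    stop(sprintf("region [%g, %g] covers only %d bins; need >= 4",
                 reg[1], reg[2], length(idx)))
  x <- spec@ppm[idx]
  y <- pmax(spec@intensity[idx], 0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Lineshape skewness and kurtosis of a region
#'
#' Treats the clipped intensity `w(ppm) = max(I, 0)` over the region as an
#' unnormalized density on the chemical shift and returns the standardized
#' third (skewness) or fourth (kurtosis, Pearson non-excess: a uniform
#' profile gives 1.8, a normal profile 3) weighted central moment of the
#' shift. These are lineshape descriptors: a narrower peak inside the region
#' concentrates weight and raises kurtosis ("sharper spectral profile").
#'
#' @param spec a [Spectrum-class].
#' @param reg length-2 ppm interval.
#' @param kind `"Skew"` or `"Kurt"`.
#' @return numeric statistic.
#' @export
regionMomentStat <- function(spec, reg, kind = c("Skew", "Kurt")) {
  kind <- match.arg(kind)
  idx <- regionIndices(spec, reg)
  if (length(idx) < 4L)
    stop(sprintf("region [%g, %g] covers only %d bins; need >= 4",
                 reg[1], reg[2], length(idx)))
  x <- spec@ppm[idx]
  w <- pmax(spec@intensity[idx], 0)
  sw <- sum(w)
  if (sw <= 0) stop("all-clipped region: moment statistic undefined")
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  if (v <= 0) stop("zero variance: moment statistic undefined")
  if (kind == "Skew") sum(w * (x - m)^3) / sw / v^1.5
  else sum(w * (x - m)^4) / sw / v^2
}

#' Lorentzian fit in a region
#'
#' Nonlinear least squares of `A * g^2 / ((ppm - c0)^2 + g^2) + offset`
#' (Levenberg-Marquardt), initialized from the region maximum, the
#' max-minus-median amplitude and the half-maximum crossing width. Returns
#' `fwhm_ppm = 2 g`. On non-convergence all estimates are `NaN` and
#' `converged` is `FALSE`; downstream imputes (training-fold median in the
#' ML pipeline).
#'
#' @param spec a [Spectrum-class].
#' @param reg length-2 ppm interval with at least 8 bins.
#' @return list with `ampl`, `fwhm_ppm`, `center_ppm`, `offset`, `converged`.
#' @export
lorentzianFit <- function(spec, reg) {
  idx <- regionIndices(spec, reg)
  if (length(idx) < 8L)
    stop(sprintf("region [%g, %g] covers only %d bins; need >= 8 for a fit",
                 reg[1], reg[2], length(idx)))
  x <- spec@ppm[idx]
  y <- spec@intensity[idx]

  med <- stats::median(y)
  a0 <- max(y) - med
  d0 <- x[which.max(y)]
  fail <- list(ampl = NaN, fwhm_ppm = NaN, center_ppm = NaN, offset = NaN,
               converged = FALSE)
  if (a0 <= 0) return(fail)
  above <- which(y >= med + a0 / 2)
  g0 <- if (length(above) >= 2L) (x[max(above)] - x[min(above)]) / 2 else diff(reg) / 8
  g0 <- max(g0, diff(reg) / 100)

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * g^2 / ((x - d0)^2 + g^2) + c,
      data = dat,
      start = list(A = a0, g = g0, d0 = d0, c = med),
      lower = c(A = 0, g = diff(reg) / 1e4, d0 = reg[1], c = -Inf),
      upper = c(A = Inf, g = 10 * diff(reg), d0 = reg[2], c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  p <- stats::coef(fit)
  conv <- fit$convInfo$isConv && p[["g"]] < 5 * diff(reg) && p[["A"]] > 0
  if (!conv) return(fail)
  list(ampl = unname(p[["A"]]), fwhm_ppm = unname(2 * p[["g"]]),
       center_ppm = unname(p[["d0"]]), offset = unname(p[["c"]]),
       converged = TRUE)
}

#' Signal-to-noise ratio
#'
#' Peak maximum in the saturate region divided by the intensity SD over a
#' signal-free noise window.
#'
#' @param spec a referenced [Spectrum-class].
#' @param satRegion saturate window (default [1.1, 1.5] ppm).
#' @param noiseWindow signal-free window (default [9, 10] ppm).
#' @return numeric SNR; `+Inf` with a warning when the noise SD is zero.
#' @export
spectrumSNR <- function(spec, satRegion = c(1.1, 1.5), noiseWindow = c(9, 10)) {
  sIdx <- regionIndices(spec, satRegion)
  nIdx <- regionIndices(spec, noiseWindow)
  if (length(sIdx) < 2L || length(nIdx) < 2L)
    stop("saturate region or noise window outside the axis")
  peak <- max(spec@intensity[sIdx])
  noiseSd <- stats::sd(spec@intensity[nIdx])
  if (noiseSd == 0) {
    if (peak <= 0) stop("SNR undefined: zero signal and zero noise")
    warning("zero noise SD; SNR reported as +Inf")
    return(Inf)
  }
  peak / noiseSd
}

#' Extract the biomarker vector of one spectrum
#'
#' Computes every registry entry plus the two QC quantities (SNR and the
#' Saturate Lorentzian linewidth). Statistics that are undefined on this
#' spectrum (all-zero region, non-converged fit) come back as `NA` with their
#' names recorded in the `flags` attribute -- never as a silent zero.
#'
#' @param spec a referenced, baseline-corrected [Spectrum-class].
#' @param registry biomarker definitions, see [biomarkerRegistry()].
#' @param regions a [RegionSet-class].
#' @param normalize `"none"` (raw integrals, default) or `"water"` (divide
#'   intensities and fit amplitude by the water-region integral).
#' @param waterRegion region used by `normalize = "water"`.
#' @return named numeric vector (registry order) with attributes `qc`
#'   (named: `snr`, `linewidth_ppm`) and `flags`.
#' @export
extractBiomarkers <- function(spec, registry = biomarkerRegistry(),
                              regions = defaultRegionSet(),
                              normalize = c("none", "water"),
                              waterRegion = c(4.5, 4.9)) {
  normalize <- match.arg(normalize)
  vals <- structure(rep(NA_real_, nrow(registry)), names = registry$name)
  flags <- character(0)

  fits <- list()  # one Lorentzian fit per region, shared by Ampl/Width
  getFit <- function(rname) {
    if (is.null(fits[[rname]]))
      fits[[rname]] <<- lorentzianFit(spec, region(regions, rname))
    fits[[rname]]
  }

  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    reg <- region(regions, registry$region[i])
    res <- tryCatch(
      switch(registry$kind[i],
             Int = regionIntensity(spec, reg),
             Skew = regionMomentStat(spec, reg, "Skew"),
             Kurt = regionMomentStat(spec, reg, "Kurt"),
             LorentzAmpl = {
               f <- getFit(registry$region[i])
               if (f$converged) f$ampl else NA_real_
             },
             LorentzWidth = {
               f <- getFit(registry$region[i])
               if (f$converged) f$fwhm_ppm else NA_real_
             },
             stop("unknown biomarker kind: ", registry$kind[i])),
      error = function(e) NA_real_
    )
    vals[nm] <- res
    if (is.na(res)) flags <- c(flags, nm)
  }

  if (normalize == "water") {
    wInt <- tryCatch(regionIntensity(spec, waterRegion), error = function(e) NA_real_)
    if (is.na(wInt) || wInt <= 0) {
      flags <- c(flags, "water-normalization")
    } else {
      sc <- registry$kind %in% c("Int", "LorentzAmpl")
      vals[sc] <- vals[sc] / wInt
    }
  }

  snrVal <- tryCatch(spectrumSNR(spec, region(regions, "Saturate")),
                     error = function(e) NA_real_)
  satFit <- tryCatch(getFit("Saturate"), error = function(e) list(converged = FALSE))
  lw <- if (isTRUE(satFit$converged)) satFit$fwhm_ppm else NA_real_
  attr(vals, "qc") <- c(snr = snrVal, linewidth_ppm = lw)
  attr(vals, "flags") <- unique(flags)
  vals
}

#' Build the per-sample feature table
#'
#' Runs water referencing and baseline correction (unless `preprocess =
#' FALSE`), extracts the biomarker vector of every spectrum and assembles the
#' feature table: one row per sample with columns `sample_id`, the 14
#' biomarkers, `snr`, `linewidth_ppm` and `label`. Missing values stay `NA`
#' here; the ML pipeline imputes them fold-locally.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param labels cohort labels aligned with `spectra`.
#' @param registry,regions,normalize see [extractBiomarkers()].
#' @param preprocess apply [referenceToWater()] and [baselineCorrect()] first.
#' @return data.frame (`check.names = FALSE`).
#' @export
buildFeatureTable <- function(spectra, labels,
                              registry = biomarkerRegistry(),
                              regions = defaultRegionSet(),
                              normalize = "none",
                              preprocess = TRUE) {
  stopifnot(length(spectra) == length(labels))
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (preprocess) sp <- baselineCorrect(referenceToWater(sp))
    v <- extractBiomarkers(sp, registry, regions, normalize = normalize)
    qc <- attr(v, "qc")
    id <- sampleID(sp)
    if (is.na(id)) id <- sprintf("sample_%03d", i)
    rows[[i]] <- c(list(sample_id = id), as.list(v),
                   list(snr = unname(qc["snr"]),
                        linewidth_ppm = unname(qc["linewidth_ppm"]),
                        label = labels[i]))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Names of the biomarker feature columns in a feature table
#' @param table a feature table from [buildFeatureTable()].
#' @return character vector of feature column names.
#' @export
featureColumns <- function(table) {
  setdiff(names(table), c("sample_id", "snr", "linewidth_ppm", "label"))
}
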