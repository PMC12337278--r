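#' @include AllClasses.R accessors.R utils.R
NULL

#' Lorentzian and pseudo-Voigt lineshapes
#'
#' `dlorentz()` evaluates the absorption Lorentzian
#' `A * g^2 / ((x - x0)^2 + g^2)` with `g = fwhm / 2`; its maximum is `A` at
#' `x0`. `dpseudoVoigt()` is the area-matched Lorentzian/Gaussian blend used
#' by the generator: natural (T2) relaxation gives Lorentzian lines while
#' field-inhomogeneity broadening adds Gaussian character, so real lines fall
#' in between. `lorentzFrac` is the Lorentzian tail weight; the Gaussian
#' component has the same FWHM and the same integrated area as the Lorentzian
#' it replaces, so varying `lorentzFrac` redistributes tail weight (the
#' kurtosis of the line) at constant area.
#'
#' @param x evaluation points (ppm).
#' @param amplitude Lorentzian-equivalent peak amplitude `A` (the pseudo-Voigt
#'   maximum is `A * (lorentzFrac + 1.4757 * (1 - lorentzFrac))`).
#' @param fwhm full width at half maximum (ppm).
#' @param center peak position `x0` (ppm).
#' @param lorentzFrac Lorentzian fraction in [0, 1]; 1 is a pure Lorentzian.
#' @return numeric vector of intensities.
#' @export
dlorentz <- function(x, amplitude, fwhm, center) {
  g <- fwhm / 2
  amplitude * g^2 / ((x - center)^2 + g^2)
}

#' @rdname dlorentz
#' @export
dpseudoVoigt <- function(x, amplitude, fwhm, center, lorentzFrac = 1) {
  lf <- min(max(lorentzFrac, 0), 1)
  if (lf >= 1) return(dlorentz(x, amplitude, fwhm, center))
  # Gaussian with the same FWHM and the same area as the Lorentzian:
  # area_L = A * pi * fwhm / 2, area_G = B * fwhm * sqrt(pi / (4 log 2))
  b <- amplitude * (pi / 2) / sqrt(pi / (4 * log(2)))
  g <- b * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
  lf * dlorentz(x, amplitude, fwhm, center) + (1 - lf) * g
}

#' Default fatty-acid peak table
#'
#' Standard 1H assignments of mobile-lipid resonances, all inside the PLC
#' window, plus the unsuppressed water reference. Relative amplitudes are
#' placeholders with the bulk methylene line dominant among the lipid peaks
#' and water far taller than any lipid signal; they are configuration, not
#' code, and can be replaced wholesale.
#'
#' @return data.frame with columns `assignment`, `center_ppm`, `fwhm_ppm`,
#'   `amplitude`, `lorentz_frac` (pseudo-Voigt Lorentzian tail weight; the
#'   default lines are pure Lorentzians).
#' @export
defaultPeakTable <- function() {
  data.frame(
    assignment = c("methyl CH3", "methylene (CH2)n", "CH2CH2CO", "allylic CH2",
                   "alpha-carboxyl CH2", "water"),
    center_ppm = c(0.90, 1.30, 1.59, 2.02, 2.28, 4.70),
    fwhm_ppm   = c(0.12, 0.12, 0.12, 0.12, 0.12, 0.10),
    amplitude  = c(0.55, 1.00, 0.15, 0.25, 0.20, 30.0),
    lorentz_frac = c(1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Cohort effect multipliers
#'
#' The knobs through which a cohort label alters the generated lineshape:
#' an amplitude multiplier on peaks inside Saturate (a concentration effect);
#' a tail-weight multiplier on those peaks (a pure lineshape effect: it
#' multiplies the Lorentzian fraction of the pseudo-Voigt line, clamped to
#' [0, 1], at constant integrated area -- lighter tails concentrate the
#' profile inside the fixed region windows and raise Kurt-SaturateR, so this
#' is the knob that drives that biomarker); an amplitude multiplier on peaks
#' inside S1;
#' and a rigid ppm shift of all lipid peak centers (which perturbs PLC
#' skewness against the fixed region boundaries).
#'
#' @param saturate_amp_multiplier,saturate_tail_multiplier,s1_amp_multiplier
#'   positive ratios (1 = no effect).
#' @param plc_skew_shift ppm shift of lipid peak centers (0 = no effect).
#' @return named list.
#' @export
cohortEffect <- function(saturate_amp_multiplier = 1,
                         saturate_tail_multiplier = 1,
                         s1_amp_multiplier = 1,
                         plc_skew_shift = 0) {
  list(saturate_amp_multiplier = saturate_amp_multiplier,
       saturate_tail_multiplier = saturate_tail_multiplier,
       s1_amp_multiplier = s1_amp_multiplier,
       plc_skew_shift = plc_skew_shift)
}

# Expected maximum of n iid standard normals (exact, by quadrature).
expectedNormalMax <- function(n) {
  stats::integrate(function(z) z * n * stats::dnorm(z) * stats::pnorm(z)^(n - 1),
                   -Inf, Inf, rel.tol = 1e-9)$value
}

# sd(log scale) such that E[max/min] of the per-sample log-normal global
# scale over n samples is about `fold`.
calibrateLognormalSd <- function(fold, n) {
  if (n < 2L) return(0)
  log(fold) / (2 * expectedNormalMax(n))
}

#' Build a synthetic-cohort configuration
#'
#' @param peakTable see [defaultPeakTable()].
#' @param cohortEffects named list of [cohortEffect()]s, one per label.
#' @param nPerClass named integer vector, e.g. `c(ARR = 54, DEV = 7)`.
#' @param targetSnrMean,targetSnrSd per-sample SNR calibration (default
#'   22 / 8; lower bound 3). `targetSnrMean = Inf` disables noise.
#' @param fwhmMean,fwhmSd linewidth calibration in ppm (default 0.12 / 0.04;
#'   lower bound 0.02).
#' @param intensityLognormalSd sd of the log global scale, or `NA` to
#'   calibrate so the expected cohort max/min intensity ratio is
#'   `intensityFold`.
#' @param intensityFold target fold-change for that calibration (default 13).
#' @param axisRange,axisBins ppm axis (default 0-10 ppm, 4096 bins).
#' @param waterPpm water resonance position (default 4.70).
#' @param seed master seed.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(peakTable = defaultPeakTable(),
                        cohortEffects = list(CTRL = cohortEffect()),
                        nPerClass = c(CTRL = 10L),
                        targetSnrMean = 22, targetSnrSd = 8,
                        fwhmMean = 0.12, fwhmSd = 0.04,
                        intensityLognormalSd = NA_real_,
                        intensityFold = 13,
                        axisRange = c(0, 10), axisBins = 4096L,
                        waterPpm = 4.70,
                        seed = 0L) {
  nPerClass <- structure(as.integer(nPerClass), names = names(nPerClass))
  if (is.na(intensityLognormalSd))
    intensityLognormalSd <- calibrateLognormalSd(intensityFold, sum(nPerClass))
  new("SynthConfig",
      peakTable = peakTable, cohortEffects = cohortEffects,
      nPerClass = nPerClass,
      targetSnrMean = targetSnrMean, targetSnrSd = targetSnrSd,
      fwhmMean = fwhmMean, fwhmSd = fwhmSd,
      intensityLognormalSd = intensityLognormalSd,
      intensityFold = intensityFold,
      axisRange = as.numeric(axisRange), axisBins = as.integer(axisBins),
      waterPpm = waterPpm, seed = as.integer(seed))
}

#' Preset cohort configurations
#'
#' `"embryo61"` emulates the Day-2 embryo study arm: 54 arrested (ARR) and 7
#' developed (DEV) samples, with the DEV cohort carrying a higher saturate
#' amplitude, a sharper (lighter-tailed) saturate lineshape -- a strong
#' Kurt-SaturateR effect -- and a mildly raised methyl amplitude. `"oocyte102"` emulates the oocyte arm:
#' 63 immature (IMM) and 39 mature (MAT) samples, with MAT carrying a strong
#' saturate-intensity increase, a raised methyl amplitude and a slightly
#' sharper lineshape.
#'
#' @param name `"embryo61"` or `"oocyte102"`.
#' @param seed master seed.
#' @return A [SynthConfig-class].
#' @export
cohortPreset <- function(name, seed = 0L) {
  presets <- c("embryo61", "oocyte102")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ", paste(presets, collapse = ", "))
  if (name == "embryo61") {
    synthConfig(
      cohortEffects = list(
        ARR = cohortEffect(),
        DEV = cohortEffect(saturate_amp_multiplier = 1.5,
                           saturate_tail_multiplier = 0.2,
                           s1_amp_multiplier = 1.2)
      ),
      nPerClass = c(ARR = 54L, DEV = 7L),
      seed = seed
    )
  } else {
    synthConfig(
      cohortEffects = list(
        IMM = cohortEffect(),
        MAT = cohortEffect(saturate_amp_multiplier = 2.0,
                           saturate_tail_multiplier = 0.9,
                           s1_amp_multiplier = 1.3)
      ),
      nPerClass = c(IMM = 63L, MAT = 39L),
      seed = seed
    )
  }
}

#' Strip all cohort effects from a configuration
#'
#' Sets every multiplier to 1 and every shift to 0, so labels carry no
#' signal. Used as the null model for leakage sentinels. Idempotent.
#'
#' @param cfg a [SynthConfig-class].
#' @return The null-effect configuration.
#' @export
nullEffectConfig <- function(cfg) {
  cfg@cohortEffects <- lapply(cfg@cohortEffects, function(e) cohortEffect())
  cfg
}

#' Generate one synthetic spectrum
#'
#' Draws a per-sample log-normal global scale, per-peak linewidths from a
#' truncated normal, applies the label's cohort effects, sums the (split)
#' Lorentzians plus the water reference peak, and adds iid Gaussian noise
#' with SD equal to the noiseless saturate-region maximum divided by a
#' per-sample target SNR draw. Bit-reproducible for a fixed `seed`. The true
#' generating parameters are stored under `meta(spec)$truth` for recovery
#' tests.
#'
#' @param cfg a [SynthConfig-class].
#' @param label cohort label; must have a `cohortEffects` entry.
#' @param seed integer seed for this sample.
#' @param sampleId identifier stored in the metadata.
#' @return An unreferenced [Spectrum-class].
#' @export
generateSpectrum <- function(cfg, label, seed, sampleId = paste0(label, "_x")) {
  stopifnot(is(cfg, "SynthConfig"))
  ce <- cfg@cohortEffects[[label]]
  if (is.null(ce)) stop("no cohort effect entry for label '", label, "'")

  withSeed(seed, {
    ax <- seq(cfg@axisRange[1], cfg@axisRange[2], length.out = cfg@axisBins)
    sat <- c(1.1, 1.5); s1 <- c(0.83, 1.03)

    scale <- stats::rlnorm(1L, 0, cfg@intensityLognormalSd)

    pt <- cfg@peakTable
    isWater <- pt$assignment == "water"
    fwhm <- pt$fwhm_ppm
    if (cfg@fwhmSd > 0 && any(!isWater)) {
      draws <- rtruncnorm(sum(!isWater), cfg@fwhmMean, cfg@fwhmSd, lo = 0.02)
      fwhm[!isWater] <- pt$fwhm_ppm[!isWater] * draws / cfg@fwhmMean
    }

    center <- pt$center_ppm
    center[!isWater] <- center[!isWater] + ce$plc_skew_shift
    amp <- pt$amplitude
    lf <- if ("lorentz_frac" %in% names(pt)) pt$lorentz_frac else rep(1, nrow(pt))
    inSat <- !isWater & center >= sat[1] & center <= sat[2]
    inS1 <- !isWater & center >= s1[1] & center <= s1[2]
    amp[inSat] <- amp[inSat] * ce$saturate_amp_multiplier
    amp[inS1] <- amp[inS1] * ce$s1_amp_multiplier
    # lineshape knob: tail weight at constant area; concentration changes go
    # through saturate_amp_multiplier instead
    lf[inSat] <- pmin(pmax(lf[inSat] * ce$saturate_tail_multiplier, 0), 1)

    y0 <- numeric(length(ax))
    for (i in seq_len(nrow(pt))) {
      y0 <- y0 + dpseudoVoigt(ax, scale * amp[i], fwhm[i], center[i], lf[i])
    }

    satIdx <- ax >= sat[1] & ax <= sat[2]
    if (is.finite(cfg@targetSnrMean)) {
      snrTarget <- rtruncnorm(1L, cfg@targetSnrMean, cfg@targetSnrSd, lo = 3)
      noiseSd <- max(y0[satIdx]) / snrTarget
    } else {
      snrTarget <- Inf
      noiseSd <- 0
    }
    y <- y0 + if (noiseSd > 0) stats::rnorm(length(ax), 0, noiseSd) else 0

    truth <- list(
      scale = scale, snr_target = snrTarget, noise_sd = noiseSd,
      peaks = data.frame(assignment = pt$assignment, center_ppm = center,
                         fwhm_ppm = fwhm, lorentz_frac = lf,
                         amplitude = scale * amp, stringsAsFactors = FALSE)
    )
    newSpectrum(ax, y,
                metadata = list(sample_id = sampleId, cohort_label = label,
                                truth = truth),
                referenced = FALSE)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Class counts are exactly `nPerClass`; each sample's seed derives
#' deterministically from the master seed and the sample id, so outputs are
#' bit-reproducible and independent of generation order.
#'
#' @param cfg a [SynthConfig-class] (e.g. from [cohortPreset()]).
#' @return list with `spectra` (list of [Spectrum-class]) and `labels`
#'   (character vector aligned with `spectra`).
#' @examples
#' cohort <- generateCohort(cohortPreset("embryo61", seed = 1))
#' table(cohort$labels)
#' @export
generateCohort <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  spectra <- list()
  labels <- character(0)
  for (label in names(cfg@nPerClass)) {
    for (i in seq_len(cfg@nPerClass[[label]])) {
      id <- sprintf("%s_%03d", label, i)
      spectra[[id]] <- generateSpectrum(cfg, label,
                                        seed = deriveSeed(cfg@seed, id),
                                        sampleId = id)
      labels <- c(labels, label)
    }
  }
  list(spectra = spectra, labels = labels, config = cfg)
}

#' Inverse-synthesize an FID from a spectrum
#'
#' Inverse discrete Fourier transform of the (real) intensities on a uniform
#' ppm axis; [fidToSpectrum()] on the result recovers the spectrum exactly
#' (no apodization, zero fill 1). Used for round-trip testing of the
#' processing chain.
#'
#' @param spec a [Spectrum-class] on a uniform ppm axis.
#' @param spectrometerFreq proton Larmor frequency in MHz (default 300, the
#'   1H frequency at 7 T).
#' @return An [FID-class] whose metadata carries `ref_ppm = min(ppm)`.
#' @export
spectrumToFid <- function(spec, spectrometerFreq = 300) {
  stopifnot(is(spec, "Spectrum"))
  d <- diff(spec@ppm)
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1]))
    stop("spectrumToFid requires a uniform ppm axis")
  if (!spec@referenced)
    warning("synthesizing an FID from an unreferenced spectrum")
  n <- length(spec@ppm)
  samples <- stats::fft(as.complex(spec@intensity), inverse = TRUE) / n
  dwell <- 1 / (n * d[1] * spectrometerFreq)
  md <- spec@metadata
  md$truth <- NULL
  md$ref_ppm <- spec@ppm[1]
  newFID(samples, dwellTime = dwell, spectrometerFreq = spectrometerFreq,
         metadata = md)
}
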