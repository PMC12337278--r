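test_that("the default registry defines the 14 biomarkers over valid regions", {
  reg <- biomarkerRegistry()
  expect_identical(nrow(reg), 14L)
  expect_true(all(reg$region %in% regionNames(defaultRegionSet())))
  expect_true(all(reg$kind %in% c("Int", "Skew", "Kurt", "LorentzAmpl", "LorentzWidth")))
  expect_identical(sum(reg$kind == "Int"), 6L)
})

test_that("region set validity enforces the structural relations", {
  expect_error(regionSet(PLC = c(2.8, 0.83)), "lo < hi")
  expect_error(
    regionSet(PLC = c(0.83, 2.8), Saturate = c(1.1, 1.5), S1 = c(0.83, 1.03),
              S3 = c(2.23, 2.36), SaturateL = c(1.25, 1.5), SaturateR = c(1.1, 1.3)),
    "partition")
  expect_error(
    regionSet(PLC = c(0.83, 2.8), Saturate = c(1.1, 1.5), S1 = c(0.5, 1.03),
              S3 = c(2.23, 2.36), SaturateL = c(1.3, 1.5), SaturateR = c(1.1, 1.3)),
    "inside PLC")
  expect_s4_class(defaultRegionSet(), "RegionSet")
})

test_that("region intensity integrates clipped intensity by the trapezoid rule", {
  ax <- uniformAxis(4096)
  binW <- diff(ax)[1]

  # unit rectangle spanning exactly the Saturate window
  y <- as.numeric(ax >= 1.1 & ax <= 1.5)
  sp <- newSpectrum(ax, y, referenced = TRUE)
  expect_lt(abs(regionIntensity(sp, c(1.1, 1.5)) - 0.4), 2 * binW)

  # zero spectrum
  expect_equal(regionIntensity(newSpectrum(ax, numeric(4096)), c(1.1, 1.5)), 0)

  # analytic truncated-Lorentzian integral
  A <- 1; fwhm <- 0.12; d0 <- 1.30; g <- fwhm / 2
  spL <- lorentzSpectrum(A, fwhm, d0)
  truth <- A * g * (atan((1.5 - d0) / g) + atan((d0 - 1.1) / g))
  expect_lt(abs(regionIntensity(spL, c(1.1, 1.5)) - truth) / truth, 0.005)

  # negative bins are clipped, not subtracted
  yn <- y; yn[ax < 1.1] <- -10
  expect_equal(regionIntensity(newSpectrum(ax, yn), c(1.1, 1.5)),
               regionIntensity(sp, c(1.1, 1.5)))

  expect_error(regionIntensity(sp, c(1.1, 1.1005)), ">= 4")
})

test_that("lineshape moments behave like weighted moments of the shift", {
  ax <- uniformAxis(4096)

  # symmetric peak centered in the region: zero skewness (up to the
  # asymmetry of the discrete bin grid around 1.30)
  spL <- lorentzSpectrum(1, 0.12, 1.30)
  expect_lt(abs(regionMomentStat(spL, c(1.1, 1.5), "Skew")), 0.01)

  # flat profile: kurtosis of a uniform distribution, 9/5
  flat <- newSpectrum(ax, rep(1, 4096), referenced = TRUE)
  expect_equal(regionMomentStat(flat, c(1.1, 1.5), "Kurt"), 1.8, tolerance = 1e-3)

  # sharper peaks have higher kurtosis (numeric oracle over an FWHM grid)
  kurts <- vapply(c(0.20, 0.14, 0.10, 0.06), function(fw)
    regionMomentStat(lorentzSpectrum(1, fw, 1.30), c(1.1, 1.5), "Kurt"), 0)
  expect_true(all(diff(kurts) > 0))

  # undefined statistics raise, never return silently
  z <- newSpectrum(ax, numeric(4096))
  expect_error(regionMomentStat(z, c(1.1, 1.5), "Kurt"), "undefined")
  neg <- newSpectrum(ax, rep(-1, 4096))
  expect_error(regionMomentStat(neg, c(1.1, 1.5), "Skew"), "all-clipped")
})

test_that("the Lorentzian fit is exact on in-class inputs and flags degenerate ones", {
  sp <- lorentzSpectrum(3.0, 0.12, 1.30)
  fit <- lorentzianFit(sp, c(1.1, 1.5))
  expect_true(fit$converged)
  expect_lt(abs(fit$ampl - 3.0) / 3.0, 1e-6)
  expect_lt(abs(fit$fwhm_ppm - 0.12) / 0.12, 1e-6)
  expect_lt(abs(fit$center_ppm - 1.30), 1e-7)
  expect_lt(abs(fit$offset), 1e-6)

  # with a constant offset
  ax <- uniformAxis(4096)
  spc <- newSpectrum(ax, dlorentz(ax, 2, 0.10, 1.25) + 0.7, referenced = TRUE)
  fitc <- lorentzianFit(spc, c(1.1, 1.5))
  expect_lt(abs(fitc$offset - 0.7), 1e-6)
  expect_lt(abs(fitc$fwhm_ppm - 0.10) / 0.10, 1e-6)

  # pure noise: non-convergence or a flagged degenerate fit, never a silent value
  noise <- microMRS:::withSeed(8, newSpectrum(ax, rnorm(4096), referenced = TRUE))
  fn <- lorentzianFit(noise, c(1.1, 1.5))
  expect_true(!fn$converged || fn$fwhm_ppm > 0)

  expect_error(lorentzianFit(sp, c(1.1, 1.105)), ">= 8")
})

test_that("noisy fits recover the generating linewidth within 10%", {
  cfg <- singlePeakConfig(fwhmSd = 0, intensityLognormalSd = 0,
                          targetSnrSd = 0, nPerClass = c(CTRL = 1L))
  sp <- generateSpectrum(cfg, "CTRL", seed = 3)
  fit <- lorentzianFit(baselineCorrect(referenceToWater(sp)), c(1.1, 1.5))
  truth <- meta(sp)$truth$peaks$fwhm_ppm[1]
  expect_true(fit$converged)
  expect_lt(abs(fit$fwhm_ppm - truth) / truth, 0.10)
})

test_that("SNR is saturate peak maximum over noise-window SD", {
  ax <- uniformAxis(4096)
  nIdx <- ax >= 9 & ax <= 10
  y <- dlorentz(ax, 22, 0.12, 1.30)
  y[nIdx] <- rep(c(1, -1), length.out = sum(nIdx))   # sd very close to 1
  sp <- newSpectrum(ax, y, referenced = TRUE)
  # peak maximum ~22 (off-bin by less than 0.2%), noise SD ~1
  expect_equal(spectrumSNR(sp), 22, tolerance = 5e-3)

  expect_error(spectrumSNR(newSpectrum(ax, numeric(4096))), "undefined")
  yc <- dlorentz(ax, 5, 0.12, 1.3); yc[ax >= 8.5] <- 0
  clean <- newSpectrum(ax, yc, referenced = TRUE)
  expect_warning(v <- spectrumSNR(clean), "zero noise")
  expect_identical(v, Inf)
})

test_that("biomarkers are scale-equivariant and shift-equivariant", {
  cfg <- cohortPreset("embryo61", seed = 2)
  sp <- baselineCorrect(referenceToWater(generateSpectrum(cfg, "DEV", seed = 11)))
  v1 <- extractBiomarkers(sp)
  reg <- biomarkerRegistry()

  # scale: x3 multiplies Int and Ampl, leaves Skew/Kurt/Width unchanged
  sp3 <- newSpectrum(ppm(sp), 3 * intensity(sp), meta(sp), referenced = TRUE)
  v3 <- extractBiomarkers(sp3)
  scaled <- reg$kind %in% c("Int", "LorentzAmpl")
  expect_equal(unname(v3[scaled]), unname(3 * v1[scaled]), tolerance = 1e-6)
  expect_equal(unname(v3[!scaled]), unname(v1[!scaled]), tolerance = 1e-6)

  # rigid shift of axis and regions together changes nothing
  eps <- 0.37
  spS <- newSpectrum(ppm(sp) + eps, intensity(sp), meta(sp), referenced = TRUE)
  r0 <- defaultRegionSet()@regions
  rS <- do.call(regionSet, lapply(r0, function(r) r + eps))
  vS <- extractBiomarkers(spS, regions = rS)
  skewed <- reg$kind == "Skew"
  expect_equal(unname(vS[!skewed]), unname(v1[!skewed]), tolerance = 1e-6)
  # skewness is a central moment of the shift: invariant too
  expect_equal(unname(vS[skewed]), unname(v1[skewed]), tolerance = 1e-6)
  # the fitted center moves by exactly the shift
  f0 <- lorentzianFit(sp, r0$Saturate)
  fS <- lorentzianFit(spS, region(rS, "Saturate"))
  expect_equal(fS$center_ppm - f0$center_ppm, eps, tolerance = 1e-6)
})

test_that("identical spectra give identical biomarker vectors and NAs are flagged", {
  sp <- baselineCorrect(referenceToWater(
    generateSpectrum(cohortPreset("embryo61", seed = 5), "ARR", seed = 2)))
  expect_identical(extractBiomarkers(sp), extractBiomarkers(sp))

  # an all-noise spectrum yields flagged missing values, not silent zeros
  ax <- uniformAxis(4096)
  flat <- newSpectrum(ax, rep(-1, 4096), metadata = list(sample_id = "f"),
                      referenced = TRUE)
  v <- extractBiomarkers(flat)
  expect_true(all(is.na(v[c("PLC-Skew", "PLC-Kurt")])))
  expect_true(all(c("PLC-Skew", "PLC-Kurt") %in% attr(v, "flags")))
})

test_that("water normalization divides intensities by the water integral", {
  sp <- baselineCorrect(referenceToWater(
    generateSpectrum(cohortPreset("embryo61", seed = 6), "ARR", seed = 4)))
  raw <- extractBiomarkers(sp)
  nrm <- extractBiomarkers(sp, normalize = "water")
  w <- regionIntensity(sp, c(4.5, 4.9))
  reg <- biomarkerRegistry()
  sc <- reg$kind %in% c("Int", "LorentzAmpl")
  expect_equal(unname(nrm[sc]), unname(raw[sc] / w), tolerance = 1e-9)
  expect_equal(unname(nrm[!sc]), unname(raw[!sc]))
})

test_that("the feature table aligns rows, labels and QC columns", {
  co <- generateCohort(synthConfig(
    cohortEffects = list(A = cohortEffect(), B = cohortEffect()),
    nPerClass = c(A = 3L, B = 2L), seed = 8))
  ft <- buildFeatureTable(co$spectra, co$labels)
  expect_identical(dim(ft), c(5L, 18L))
  expect_identical(ft$label, co$labels)
  expect_identical(ft$sample_id, names(co$spectra))
  expect_identical(featureColumns(ft), biomarkerRegistry()$name)
  expect_true(all(c("snr", "linewidth_ppm") %in% names(ft)))
})
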