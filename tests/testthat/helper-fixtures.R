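# Shared fixtures, all built in code.

uniformAxis <- function(n = 4096, lo = 0, hi = 10) seq(lo, hi, length.out = n)

# a spectrum that is a pure Lorentzian plus (optionally) a water peak
lorentzSpectrum <- function(amplitude = 1, fwhm = 0.12, center = 1.30,
                            water = FALSE, n = 4096, id = "fix") {
  ax <- uniformAxis(n)
  y <- dlorentz(ax, amplitude, fwhm, center)
  if (water) y <- y + dlorentz(ax, 30, 0.10, 4.70)
  newSpectrum(ax, y, metadata = list(sample_id = id), referenced = TRUE)
}

# single-saturate-peak generator config: the Lorentzian fit's model class,
# so recovery is exact in the noiseless limit
singlePeakConfig <- function(..., seed = 1L) {
  pt <- data.frame(assignment = c("methylene (CH2)n", "water"),
                   center_ppm = c(1.30, 4.70),
                   fwhm_ppm = c(0.12, 0.10),
                   amplitude = c(1.0, 30.0),
                   lorentz_frac = c(1, 1),
                   stringsAsFactors = FALSE)
  synthConfig(peakTable = pt, ..., seed = seed)
}

# small well-separated feature table for pipeline unit tests (no spectra)
toyFeatureTable <- function(nA = 8, nB = 8, d = 6, gap = 8, seed = 99) {
  set.seed(seed)
  xA <- matrix(rnorm(nA * d), nA, d)
  xB <- matrix(rnorm(nB * d), nB, d)
  xB[, 1] <- xB[, 1] + gap
  X <- rbind(xA, xB)
  colnames(X) <- paste0("f", seq_len(d))
  out <- data.frame(sample_id = sprintf("s%02d", seq_len(nA + nB)), X,
                    snr = 20, linewidth_ppm = 0.12,
                    label = c(rep("A", nA), rep("B", nB)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

# brute-force Mann-Whitney oracle: enumerate value splits, count pairs
mwOracle <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  uOf <- function(a, b) {
    u <- 0
    for (i in seq_along(a)) u <- u + sum(a[i] > b) + 0.5 * sum(a[i] == b)
    u
  }
  uObs <- uOf(x, y)
  mu <- nx * length(y) / 2
  splits <- utils::combn(length(vals), nx)
  us <- apply(splits, 2L, function(idx) uOf(vals[idx], vals[-idx]))
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}
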