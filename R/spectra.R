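#' @include AllClasses.R accessors.R
NULL

#' Fourier-transform an FID into a 1D spectrum
#'
#' Applies exponential apodization, optional zero filling, a discrete Fourier
#' transform, and either zero-order phasing (default) or magnitude
#' calculation. The ppm axis is derived from the dwell time and the
#' spectrometer frequency; its origin is the FID's `ref_ppm` metadata entry
#' (the chemical shift of the zero-frequency edge, default 0 ppm).
#'
#' In `"real"` mode the zero-order phase is chosen analytically to maximize
#' the integral of the real part over the PLC window (falling back to the
#' whole spectrum when the axis does not cover PLC), which preserves the
#' absorption-Lorentzian lineshape that the biomarker layer models.
#' `"magnitude"` mode returns the modulus.
#'
#' @param fid an [FID-class].
#' @param apodizationHz exponential line-broadening rate in Hz (>= 0).
#' @param zeroFillFactor 1, 2 or 4; the FID is zero-padded to this multiple
#'   of its length before the transform.
#' @param mode `"real"` (phased real part, default) or `"magnitude"`.
#' @return A [Spectrum-class] on an ascending ppm axis (`referenced = FALSE`).
#' @examples
#' sp0 <- newSpectrum(seq(0, 10, length.out = 512),
#'                    dlorentz(seq(0, 10, length.out = 512), 1, 0.12, 1.3))
#' fid <- spectrumToFid(sp0, spectrometerFreq = 300)
#' sp1 <- fidToSpectrum(fid)
#' @export
fidToSpectrum <- function(fid, apodizationHz = 0, zeroFillFactor = 1L,
                          mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  stopifnot(is(fid, "FID"))
  if (any(!is.finite(Re(fid@samples))) || any(!is.finite(Im(fid@samples))))
    stop("FID contains non-finite samples; refusing to transform")
  if (apodizationHz < 0) stop("apodizationHz must be >= 0")
  if (!zeroFillFactor %in% c(1L, 2L, 4L)) stop("zeroFillFactor must be 1, 2 or 4")

  n <- length(fid@samples)
  t <- (seq_len(n) - 1L) * fid@dwellTime
  x <- fid@samples * exp(-pi * apodizationHz * t)
  nz <- n * as.integer(zeroFillFactor)
  if (nz > n) x <- c(x, complex(nz - n))
  S <- stats::fft(x)

  df <- 1 / (nz * fid@dwellTime)                  # Hz per bin
  refPpm <- fid@metadata$ref_ppm
  if (is.null(refPpm)) refPpm <- 0
  ax <- refPpm + (seq_len(nz) - 1L) * df / fid@spectrometerFreq

  if (mode == "magnitude") {
    y <- Mod(S)
  } else {
    plc <- c(0.83, 2.8)
    idx <- which(ax >= plc[1] & ax <= plc[2])
    if (length(idx) < 4L) idx <- seq_len(nz)
    z <- sum(S[idx])
    phi <- if (Mod(z) > 0) Arg(z) else 0
    y <- Re(S * exp(-1i * phi))
  }
  if (any(!is.finite(y))) stop("non-finite spectrum after transform")

  md <- fid@metadata
  md$ref_ppm <- NULL
  newSpectrum(ax, y, metadata = md, referenced = FALSE)
}

#' Anchor the ppm axis to the water resonance
#'
#' Unsuppressed water is the tallest peak in these acquisitions and serves as
#' the internal chemical-shift reference. The axis is rigidly shifted so the
#' global intensity maximum sits exactly at `waterPpm`. Idempotent: once the
#' maximum is at `waterPpm`, the shift is zero.
#'
#' @param spec a [Spectrum-class].
#' @param waterPpm assigned water shift (default 4.70 ppm).
#' @return The referenced spectrum (`referenced = TRUE`).
#' @export
referenceToWater <- function(spec, waterPpm = 4.70) {
  stopifnot(is(spec, "Spectrum"))
  mx <- max(spec@intensity)
  imax <- which(spec@intensity == mx)
  if (length(imax) > 1L) {
    warning("tied global maxima; using the one at higher ppm")
    imax <- imax[length(imax)]
  }
  shift <- spec@ppm[imax] - waterPpm
  out <- spec
  out@ppm <- spec@ppm - shift
  out@referenced <- TRUE
  out
}

#' Constant baseline correction from a signal-free window
#'
#' Subtracts the median intensity over a signal-free window (default
#' 9-10 ppm, well above any lipid or water resonance), so that window's
#' median is zero afterwards. Idempotent.
#'
#' @param spec a [Spectrum-class].
#' @param window length-2 ppm window assumed free of signal.
#' @return The corrected spectrum.
#' @export
baselineCorrect <- function(spec, window = c(9, 10)) {
  stopifnot(is(spec, "Spectrum"))
  idx <- which(spec@ppm >= window[1] & spec@ppm <= window[2])
  if (length(idx) < 2L)
    stop(sprintf("signal-free window [%g, %g] ppm is outside the axis", window[1], window[2]))
  out <- spec
  out@intensity <- spec@intensity - stats::median(spec@intensity[idx])
  out
}

# ---- readers / writers -----------------------------------------------------

fmtNum <- function(x) sprintf("%.17g", x)

sanitizeFilename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

writeSpectrumCsv <- function(spec, file) {
  md <- spec@metadata
  md <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(md)) {
    v <- md[[nm]]
    if (is.numeric(v)) v <- fmtNum(v)
    writeLines(sprintf("# %s: %s", nm, as.character(v)), con)
  }
  writeLines(sprintf("# referenced: %s", spec@referenced), con)
  writeLines("ppm,intensity", con)
  writeLines(paste(fmtNum(spec@ppm), fmtNum(spec@intensity), sep = ","), con)
}

readSpectrumCsv <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop("empty spectrum file: ", file)
  hdr <- grepl("^#", lines)
  nHdr <- if (any(!hdr)) which(!hdr)[1] - 1L else length(lines)
  md <- list()
  referenced <- FALSE
  for (ln in lines[seq_len(nHdr)]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      parsed <- utils::type.convert(val, as.is = TRUE)
      if (key == "referenced") referenced <- isTRUE(as.logical(parsed))
      else md[[key]] <- parsed
    }
  }
  body <- lines[(nHdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (!length(body) || body[1] != "ppm,intensity")
    stop("missing 'ppm,intensity' header in ", file)
  rows <- body[-1L]
  if (!length(rows)) stop("empty spectrum file (no data rows): ", file)
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s", nHdr + 1L + bad[1], file))
  ax <- as.numeric(vapply(parts, `[[`, "", 1L))
  y <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(ax) || anyNA(y))
    stop("non-numeric data row in ", file)
  nonmono <- which(diff(ax) <= 0)
  if (length(nonmono))
    stop(sprintf("non-monotone ppm axis at line %d of %s",
                 nHdr + 2L + nonmono[1], file))
  newSpectrum(ax, y, metadata = md, referenced = referenced)
}

readJcamp <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop("empty JCAMP file: ", file)
  getLabel <- function(lbl) {
    hit <- grep(paste0("^##", lbl, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^##", lbl, "="), "", hit[1]))
  }
  xf <- as.numeric(getLabel("XFACTOR")); if (!length(xf) || is.na(xf)) xf <- 1
  yf <- as.numeric(getLabel("YFACTOR")); if (!length(yf) || is.na(yf)) yf <- 1
  npt <- as.numeric(getLabel("NPOINTS"))
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA table in ", file)
  form <- trimws(sub("^##XYDATA=", "", lines[start[1]]))
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop("unsupported XYDATA form '", form, "' (only X++(Y..Y), AFFN)")
  end <- grep("^##", lines)
  end <- end[end > start[1]]
  end <- if (length(end)) end[1] - 1L else length(lines)
  tbl <- lines[(start[1] + 1L):end]
  tbl <- tbl[nzchar(trimws(tbl))]
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_along(tbl)) {
    tok <- strsplit(trimws(tbl[i]), "[\\s,]+", perl = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      stop(sprintf("non-AFFN token at XYDATA line %d of %s", i, file))
    if (length(v) < 2L)
      stop(sprintf("XYDATA line %d of %s has no Y values", i, file))
    xs <- c(xs, v[1])
    ys <- c(ys, v[-1])
  }
  first <- as.numeric(getLabel("FIRSTX"))
  last <- as.numeric(getLabel("LASTX"))
  n <- length(ys)
  if (!is.null(npt) && !is.na(npt) && npt != n)
    stop(sprintf("NPOINTS=%d but %d Y values in %s", as.integer(npt), n, file))
  if (length(first) && length(last) && !is.na(first) && !is.na(last)) {
    ax <- seq(first, last, length.out = n)
  } else {
    dx <- if (length(xs) >= 2L) (xs[2] - xs[1]) / (length(ys) / length(xs)) else 1
    ax <- (xs[1] + (seq_len(n) - 1L) * dx) * xf
  }
  y <- ys * yf
  if (ax[1] > ax[n]) { ax <- rev(ax); y <- rev(y) }
  md <- list()
  ttl <- getLabel("TITLE")
  if (!is.null(ttl)) md$sample_id <- ttl
  newSpectrum(ax, y, metadata = md, referenced = FALSE)
}

#' Read spectra from disk
#'
#' CSV dialect: `# key: value` metadata header lines followed by a
#' `ppm,intensity` table (lossless round trip with [writeSpectra()]).
#' JCAMP-DX: read-only support for `##XYDATA=(X++(Y..Y))` tables in AFFN
#' form. `path` may be a single file or a directory of CSV files.
#'
#' @param path file or directory.
#' @param format `"csv"` or `"jcamp"`.
#' @return A list of [Spectrum-class] objects.
#' @export
readSpectra <- function(path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (dir.exists(path)) {
    ext <- if (format == "csv") "\\.csv$" else "\\.(jdx|dx|jcamp)$"
    files <- sort(list.files(path, pattern = ext, full.names = TRUE))
    if (!length(files)) stop("no ", format, " spectra found in ", path)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    files <- path
  }
  reader <- if (format == "csv") readSpectrumCsv else readJcamp
  lapply(files, reader)
}

#' Write spectra to a directory of CSV files
#'
#' One file per spectrum, named after its `sample_id`. Only scalar metadata
#' fields are serialized (the CSV dialect is a flat key-value header);
#' structured entries such as generator truth are dropped.
#'
#' @param specs list of [Spectrum-class] objects.
#' @param path output directory (created if needed).
#' @param format only `"csv"` is supported for writing.
#' @return Invisibly, the written file paths.
#' @export
writeSpectra <- function(specs, path, format = "csv") {
  if (format != "csv") stop("only csv writing is supported")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- character(length(specs))
  for (i in seq_along(specs)) {
    id <- sampleID(specs[[i]])
    if (is.na(id)) id <- sprintf("spectrum_%03d", i)
    out[i] <- file.path(path, paste0(sanitizeFilename(id), ".csv"))
    writeSpectrumCsv(specs[[i]], out[i])
  }
  invisible(out)
}
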