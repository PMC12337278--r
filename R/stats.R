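#' @include utils.R
NULL

# Lilliefors KS statistic: distance between the ecdf and the normal with
# estimated mean and sd.
lillieforsStat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Lilliefors normality test (Monte-Carlo null)
#'
#' Kolmogorov-Smirnov distance to the normal distribution with estimated
#' parameters, calibrated against a seeded Monte-Carlo null (composite
#' normality: each null replicate re-estimates mean and sd), so the decision
#' is deterministic for a fixed seed.
#'
#' @param x numeric sample, length >= 4.
#' @param nreps Monte-Carlo replicates (>= 5000).
#' @param seed RNG seed for the null simulation.
#' @return list with `statistic` and `p_value`.
#' @export
lillieforsTest <- function(x, nreps = 5000L, seed = 0L) {
  if (length(x) < 4L) stop("Lilliefors test needs n >= 4")
  if (stats::sd(x) == 0) return(list(statistic = NA_real_, p_value = 0))
  d <- lillieforsStat(x)
  n <- length(x)
  dnull <- withSeed(seed, {
    vapply(seq_len(nreps), function(i) lillieforsStat(stats::rnorm(n)), 0)
  })
  list(statistic = d, p_value = (1 + sum(dnull >= d)) / (nreps + 1))
}

# U statistic of x against y using midranks.
uStatistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both groups have at most 10 observations the
#' null distribution of U is enumerated exactly over all rank splits
#' (midranks, so ties are handled exactly); otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic of `x`), `p_value`, `method`.
#' @export
mannWhitneyU <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  u <- uStatistic(x, y)
  mu <- nx * ny / 2

  if (nx <= 10L && ny <= 10L) {
    r <- rank(c(x, y))
    splits <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, p_value = p, method = "exact"))
  }

  n <- nx + ny
  ties <- table(c(x, y))
  tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tieCorr)
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal-approx"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-z)), method = "normal-approx")
}

#' Compare one biomarker between two cohorts
#'
#' Gate: Lilliefors normality on each group (seeded Monte-Carlo null). If
#' both groups are compatible with normality at `alpha`, an unpaired Welch t
#' test is used; otherwise a Mann-Whitney U test (exact for small groups).
#' Two-sided throughout.
#'
#' @param table a feature table from [buildFeatureTable()].
#' @param biomarker feature column name.
#' @param alpha normality-gate level (default 0.05).
#' @param nreps,seed Monte-Carlo null settings for the Lilliefors gate.
#' @return one-row data.frame: biomarker, group names, n/mean/sd per group,
#'   normality p per group, `test_used`, `p_value`.
#' @export
compareCohorts <- function(table, biomarker, alpha = 0.05,
                           nreps = 5000L, seed = 0L) {
  if (!biomarker %in% names(table)) stop("no such biomarker column: ", biomarker)
  groups <- sort(unique(table$label))
  if (length(groups) != 2L) stop("exactly two cohorts required")
  x <- table[[biomarker]][table$label == groups[1]]
  y <- table[[biomarker]][table$label == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("insufficient data: both groups need n >= 3")

  # normality is not assessable below n = 4; such a group fails the gate
  p1 <- if (length(x) >= 4L)
    lillieforsTest(x, nreps, seed = deriveSeed(seed, paste0(biomarker, ":1")))$p_value
  else 0
  p2 <- if (length(y) >= 4L)
    lillieforsTest(y, nreps, seed = deriveSeed(seed, paste0(biomarker, ":2")))$p_value
  else 0

  if (p1 >= alpha && p2 >= alpha) {
    testUsed <- "Welch-t"
    pv <- stats::t.test(x, y, var.equal = FALSE)$p.value
  } else {
    testUsed <- "Mann-Whitney-U"
    pv <- mannWhitneyU(x, y)$p_value
  }

  data.frame(
    biomarker = biomarker,
    group1 = groups[1], n1 = length(x), mean1 = mean(x), sd1 = stats::sd(x),
    group2 = groups[2], n2 = length(y), mean2 = mean(y), sd2 = stats::sd(y),
    normality_p1 = p1, normality_p2 = p2,
    test_used = testUsed, p_value = pv,
    stringsAsFactors = FALSE
  )
}

#' Compare all biomarkers between two cohorts
#'
#' @param table a feature table.
#' @param biomarkers columns to compare (default: all feature columns).
#' @param ... passed to [compareCohorts()].
#' @return data.frame, one row per biomarker.
#' @export
compareAllCohorts <- function(table, biomarkers = featureColumns(table), ...) {
  out <- lapply(biomarkers, function(b) compareCohorts(table, b, ...))
  do.call(rbind, out)
}
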