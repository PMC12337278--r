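#' @include AllClasses.R mlpipe.R
NULL

#' Exact Shapley values by coalition enumeration
#'
#' Interventional Shapley attribution of a scalar model score. The value of a
#' coalition S is the background-mean score of the hybrid input that takes
#' the features in S from `x` and the rest from a background row; the Shapley
#' value of feature i is the weighted sum of its marginal contributions over
#' all 2^n coalitions:
#' `phi_i = sum_S |S|! (n - |S| - 1)! / n! * (v(S + i) - v(S))`.
#' Exact (no sampling), so the efficiency, symmetry, linearity and
#' null-player axioms hold to numerical precision; refuses more than 16
#' features.
#'
#' @param scoreFn function taking a numeric matrix (rows = inputs) and
#'   returning a numeric score per row.
#' @param background numeric matrix of background rows (non-empty).
#' @param x numeric vector, the input to explain.
#' @return list with `phi` (one value per feature), `base` (the background
#'   mean score, v of the empty coalition) and `score` (v of the full
#'   coalition, equal to `scoreFn(x)`).
#' @examples
#' sf <- function(m) m %*% c(2, -1, 0.5)
#' exactShapley(sf, matrix(0, 1, 3), c(1, 1, 1))$phi  # a_i * (x_i - b_i)
#' @export
exactShapley <- function(scoreFn, background, x) {
  background <- as.matrix(background)
  n <- length(x)
  if (n > 16L)
    stop("exact enumeration limited to 16 features (2^n coalitions); got ", n)
  if (nrow(background) < 1L) stop("background must be non-empty")
  if (ncol(background) != n) stop("background and x disagree on feature count")

  nc <- 2L^n
  bits <- 2L^(seq_len(n) - 1L)
  masks <- matrix(FALSE, nc, n)
  for (i in seq_len(n))
    masks[, i] <- bitwAnd(seq_len(nc) - 1L, bits[i]) != 0L

  # v(S): mean over background rows of the score of the hybrid input
  v <- numeric(nc)
  xm <- matrix(x, nc, n, byrow = TRUE)
  for (b in seq_len(nrow(background))) {
    hyb <- matrix(background[b, ], nc, n, byrow = TRUE)
    hyb[masks] <- xm[masks]
    v <- v + as.numeric(scoreFn(hyb))
  }
  v <- v / nrow(background)

  sizes <- rowSums(masks)
  w <- exp(lfactorial(0:(n - 1)) + lfactorial(n - 1 - (0:(n - 1))) - lfactorial(n))
  phi <- numeric(n)
  for (i in seq_len(n)) {
    idx0 <- which(!masks[, i])
    idx1 <- idx0 + bits[i]
    phi[i] <- sum(w[sizes[idx0] + 1L] * (v[idx1] - v[idx0]))
  }
  names(phi) <- colnames(background)
  list(phi = phi, base = v[1L], score = v[nc])
}

#' Shapley summary over principal-component features
#'
#' Mirrors the interpretability analysis: the pipeline is refit on the full
#' dataset (pooled standardization, SMOTE balancing, PCA), an SVM is trained
#' on the first `top` PC scores, and every original (non-synthetic) sample's
#' decision score is attributed exactly over those PC features by
#' [exactShapley()]. The background is the balanced training score matrix
#' (deterministically subsampled to `backgroundMax` rows for speed).
#' Features are ranked by mean absolute Shapley value.
#'
#' @param table a feature table from [buildFeatureTable()].
#' @param cfg a [pipelineConfig()].
#' @param top number of leading principal components to model and attribute
#'   (default 8).
#' @param backgroundMax cap on background rows (default 64).
#' @return a [ShapleyReport-class]; the PCA loadings of the underlying fit
#'   are available as `attr(report@values, "loadings")`.
#' @export
shapSummary <- function(table, cfg = pipelineConfig(), top = 8L,
                        backgroundMax = 64L) {
  f <- wholeDataFit(table, cfg)
  k <- min(as.integer(top), ncol(f$scores), 16L)
  scores <- f$scores[, seq_len(k), drop = FALSE]

  yAll <- factor(f$labels)
  gamma <- if (is.null(cfg$gamma)) 1 / k else cfg$gamma
  fit <- withSeed(deriveSeed(cfg$seed, "shap-refit"),
                  e1071::svm(x = scores, y = yAll, kernel = cfg$kernel,
                             cost = cfg$cost, gamma = gamma, scale = FALSE))

  counts <- base::table(f$labels[!f$synthetic])
  positive <- cfg$positiveClass
  if (is.null(positive)) positive <- names(counts)[which.min(counts)]
  scoreFn <- function(m) svmScore(fit, m, positive)$score

  bg <- scores
  if (nrow(bg) > backgroundMax) {
    keep <- unique(round(seq(1L, nrow(bg), length.out = backgroundMax)))
    bg <- bg[keep, , drop = FALSE]
  }

  orig <- which(!f$synthetic)
  values <- matrix(0, length(orig), k,
                   dimnames = list(f$sample_id[orig], colnames(scores)))
  modelScores <- numeric(length(orig))
  base <- NA_real_
  for (r in seq_along(orig)) {
    sh <- exactShapley(scoreFn, bg, scores[orig[r], ])
    values[r, ] <- sh$phi
    modelScores[r] <- sh$score
    base <- sh$base
  }

  ranking <- colnames(values)[order(colMeans(abs(values)), decreasing = TRUE)]
  attr(values, "loadings") <- f$loadings[, seq_len(k), drop = FALSE]
  new("ShapleyReport", values = values, baseValue = base,
      scores = modelScores, ranking = ranking,
      featureNames = colnames(scores))
}
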