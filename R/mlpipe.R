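#' @include AllClasses.R utils.R biomarkers.R
NULL

#' Classification pipeline configuration
#'
#' Settings for the leakage-controlled LOOCV stack. Within every fold the
#' training set is standardized, SMOTE-balanced, reduced by PCA and fed to an
#' SVM; the held-out sample is transformed with the training fold's
#' parameters and never refits anything.
#'
#' @param smoteK SMOTE neighbor count (default 5; auto-reduced to
#'   `n_minority - 1` when the minority is smaller).
#' @param pcaComponents `NULL` keeps every train-rank component; a fraction
#'   in (0, 1) keeps components up to that cumulative variance; an integer
#'   keeps that many.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM cost parameter C (> 0).
#' @param gamma RBF width; `NULL` uses `1 / n_features`.
#' @param pcaBeforeSmote if `TRUE`, PCA is fitted on the standardized
#'   training data and SMOTE runs in PC-score space; the default `FALSE`
#'   order is standardize, SMOTE, PCA.
#' @param positiveClass label counted as positive; `NULL` picks the minority
#'   class.
#' @param seed master seed; per-fold seeds derive from it and the held-out
#'   sample id, so predictions are invariant to row order.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(smoteK = 5L, pcaComponents = NULL,
                           kernel = c("radial", "linear"), cost = 1,
                           gamma = NULL, pcaBeforeSmote = FALSE,
                           positiveClass = NULL, seed = 0L) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  if (smoteK < 1L) stop("smoteK must be >= 1")
  structure(list(smoteK = as.integer(smoteK), pcaComponents = pcaComponents,
                 kernel = kernel, cost = cost, gamma = gamma,
                 pcaBeforeSmote = isTRUE(pcaBeforeSmote),
                 positiveClass = positiveClass, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Each synthetic row is `x + u * (x' - x)` with `u ~ U(0, 1)`, `x` a
#' minority row drawn at random and `x'` one of its `k` nearest minority
#' neighbors (Euclidean distance in the standardized feature space). With a
#' single minority row no interpolation is possible; the row is duplicated
#' with a warning.
#'
#' @param x matrix of minority-class rows (standardized space).
#' @param k neighbor count; auto-reduced to `nrow(x) - 1`.
#' @param nNew number of synthetic rows to generate.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return matrix of `nNew` synthetic rows, rownames `synthetic_<i>`.
#' @export
smote <- function(x, k = 5L, nNew, seed = NULL) {
  x <- as.matrix(x)
  nm <- nrow(x)
  if (nm < 1L) stop("no minority rows")
  gen <- function() {
    if (nNew == 0L) return(x[0L, , drop = FALSE])
    if (nm == 1L) {
      warning("single minority sample: duplicating instead of interpolating")
      out <- matrix(rep(x[1L, ], nNew), nrow = nNew, byrow = TRUE)
    } else {
      kk <- min(k, nm - 1L)
      d <- as.matrix(stats::dist(x))
      nbrs <- apply(d, 1L, function(row) order(row)[2:(kk + 1L)])
      nbrs <- matrix(nbrs, ncol = nm)   # kk x nm
      base <- sample.int(nm, nNew, replace = TRUE)
      pick <- sample.int(kk, nNew, replace = TRUE)
      u <- stats::runif(nNew)
      out <- matrix(0, nNew, ncol(x))
      for (j in seq_len(nNew)) {
        b <- x[base[j], ]
        nb <- x[nbrs[pick[j], base[j]], ]
        out[j, ] <- b + u[j] * (nb - b)
      }
    }
    colnames(out) <- colnames(x)
    rownames(out) <- sprintf("synthetic_%d", seq_len(nNew))
    out
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

# column medians for fold-local NA imputation
colMedians <- function(x) apply(x, 2L, stats::median, na.rm = TRUE)

imputeWith <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- med[j]
  }
  x
}

# number of non-degenerate principal components to keep
resolveNcomp <- function(pca, spec) {
  rank <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  if (is.null(spec)) return(rank)
  if (spec > 0 && spec < 1) {
    v <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    return(min(which(v >= spec)))
  }
  min(as.integer(spec), rank)
}

#' Fit one training fold
#'
#' Imputes missing biomarkers with the training-fold median, standardizes
#' with training means/SDs, balances the minority class up to the majority
#' count by SMOTE, fits PCA and then an SVM on the PC scores (order
#' configurable via `pcaBeforeSmote`). All parameters are estimated on the
#' training rows only; [predictFold()] applies them without refitting.
#'
#' @param trainX numeric matrix of training features (held-out row excluded).
#' @param trainY training labels aligned with `trainX`.
#' @param cfg a [pipelineConfig()].
#' @return a `foldModel` list (scaler, PCA rotation, SVM, bookkeeping and a
#'   hash of the scaler parameters for leakage audits).
#' @export
fitFold <- function(trainX, trainY, cfg = pipelineConfig()) {
  trainX <- as.matrix(trainX)
  trainY <- factor(trainY)
  if (nlevels(trainY) < 2L) stop("degenerate training fold: a single class")

  med <- colMedians(trainX)
  x <- imputeWith(trainX, med)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  counts <- table(trainY)
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  nNew <- as.integer(counts[majority] - counts[minority])

  balance <- function(feat) {
    if (nNew <= 0L) return(list(x = feat, y = trainY))
    syn <- smote(feat[trainY == minority, , drop = FALSE], cfg$smoteK, nNew)
    list(x = rbind(feat, syn),
         y = factor(c(as.character(trainY), rep(minority, nNew)),
                    levels = levels(trainY)))
  }

  if (cfg$pcaBeforeSmote) {
    pca <- stats::prcomp(xs, center = TRUE, scale. = FALSE)
    ncomp <- resolveNcomp(pca, cfg$pcaComponents)
    scoresTrain <- pca$x[, seq_len(ncomp), drop = FALSE]
    bal <- balance(scoresTrain)
    svmX <- bal$x
  } else {
    bal <- balance(xs)
    pca <- stats::prcomp(bal$x, center = TRUE, scale. = FALSE)
    ncomp <- resolveNcomp(pca, cfg$pcaComponents)
    svmX <- pca$x[, seq_len(ncomp), drop = FALSE]
  }

  gamma <- if (is.null(cfg$gamma)) 1 / ncol(svmX) else cfg$gamma
  fit <- e1071::svm(x = svmX, y = bal$y, kernel = cfg$kernel,
                    cost = cfg$cost, gamma = gamma, scale = FALSE)

  positive <- cfg$positiveClass
  if (is.null(positive)) positive <- minority

  structure(list(
    imputeMedians = med, center = ctr, scale = scl,
    pca = list(center = pca$center,
               rotation = pca$rotation[, seq_len(ncomp), drop = FALSE]),
    explainedVariance = pca$sdev^2 / sum(pca$sdev^2),
    pcaBeforeSmote = cfg$pcaBeforeSmote,
    svm = fit, positive = positive, levels = levels(trainY),
    scalerHash = objectHash(list(med, ctr, scl))
  ), class = "foldModel")
}

# signed decision value oriented so that higher favors `positive`
svmScore <- function(fit, scores, positive) {
  pr <- stats::predict(fit, scores, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  s <- as.numeric(dv[, 1])
  if (pair[1] != positive) s <- -s
  list(label = as.character(pr), score = s)
}

#' Predict a held-out row with a fitted fold
#'
#' Applies the training fold's imputation, scaler and PCA projection, then
#' the SVM. Never refits.
#'
#' @param model a `foldModel` from [fitFold()].
#' @param x numeric vector or single-row matrix of raw features.
#' @return list with `label` and `score` (signed decision value for the
#'   positive class).
#' @export
predictFold <- function(model, x) {
  x <- matrix(as.numeric(x), nrow = if (is.matrix(x)) nrow(x) else 1L,
              byrow = !is.matrix(x))
  x <- imputeWith(x, model$imputeMedians)
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  sc <- sweep(xs, 2L, model$pca$center) %*% model$pca$rotation
  out <- svmScore(model$svm, sc, model$positive)
  list(label = out$label, score = out$score)
}

#' Leave-one-out cross-validation
#'
#' Each sample is held out once; the remaining rows are fitted with
#' [fitFold()] under a fold-local seed derived from the master seed and the
#' held-out sample id (so predictions do not depend on row order), and the
#' held-out row is predicted with the frozen fold parameters. Synthetic SMOTE
#' rows exist only inside training folds; a structural assertion guarantees
#' none is ever scored as a validation sample.
#'
#' @param table a feature table from [buildFeatureTable()].
#' @param cfg a [pipelineConfig()].
#' @return a [CVResult-class].
#' @export
loocv <- function(table, cfg = pipelineConfig()) {
  feat <- featureColumns(table)
  X <- as.matrix(table[, feat, drop = FALSE])
  y <- as.character(table$label)
  ids <- as.character(table$sample_id)
  n <- nrow(X)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  counts <- base::table(y)
  if (length(counts) < 2L) stop("both classes must be present")
  if (min(counts) < 2L)
    stop("minority class has a single sample: it would vanish from its own training fold")
  if (any(grepl("^synthetic_", ids)))
    stop("input table contains synthetic sample ids")

  positive <- cfg$positiveClass
  if (is.null(positive)) positive <- names(counts)[which.min(counts)]

  # canonical sample order inside the folds, so predictions are invariant to
  # the row order of the input table (per-fold seeds also derive from ids)
  ord <- order(ids)
  Xs <- X[ord, , drop = FALSE]; ys <- y[ord]; idss <- ids[ord]

  preds <- data.frame(sample_id = idss, truth = ys,
                      predicted = NA_character_, score = NA_real_,
                      stringsAsFactors = FALSE)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    foldSeed <- deriveSeed(cfg$seed, idss[i])
    model <- withSeed(foldSeed,
                      fitFold(Xs[-i, , drop = FALSE], ys[-i], cfg))
    out <- predictFold(model, Xs[i, ])
    preds$predicted[i] <- out$label
    preds$score[i] <- out$score
    folds[[i]] <- list(sample_id = idss[i],
                       explainedVariance = model$explainedVariance,
                       scalerHash = model$scalerHash)
  }
  # report in the input table's row order
  back <- match(ids, idss)
  preds <- preds[back, , drop = FALSE]
  rownames(preds) <- NULL
  folds <- folds[back]
  stopifnot(identical(preds$sample_id, ids),
            !any(grepl("^synthetic_", preds$sample_id)))
  new("CVResult", predictions = preds, positiveClass = positive, folds = folds)
}

#' ROC AUC from decision scores (rank formulation)
#'
#' Mann-Whitney statistic with midrank tie handling: equivalent to the area
#' under the ROC curve with ties contributing half.
#'
#' @param scores numeric decision scores (higher favors positive).
#' @param isPositive logical vector of true positives.
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(scores, isPositive) {
  np <- sum(isPositive); nn <- sum(!isPositive)
  if (np < 1L || nn < 1L) stop("AUC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[isPositive]) - np * (np + 1) / 2) / (np * nn)
}

buildMetrics <- function(tp, fp, fn, tn, auc, positiveClass) {
  n <- tp + fp + fn + tn
  div <- function(num, den) if (den == 0) NaN else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN
        else 2 * prec * sens / (prec + sens)
  bal <- if (is.nan(sens) || is.nan(spec)) NaN else (sens + spec) / 2
  panel <- c(accuracy = (tp + tn) / n, balancedAccuracy = bal,
             sensitivity = sens, specificity = spec, precision = prec,
             npv = npv, f1 = f1, auc = auc)
  new("MetricsReport",
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      accuracy = panel[["accuracy"]], balancedAccuracy = panel[["balancedAccuracy"]],
      sensitivity = panel[["sensitivity"]], specificity = panel[["specificity"]],
      precision = panel[["precision"]], npv = panel[["npv"]],
      f1 = panel[["f1"]], auc = panel[["auc"]],
      positiveClass = positiveClass,
      flags = names(panel)[is.nan(panel)])
}

#' Metric panel from a confusion matrix
#'
#' Accuracy, balanced accuracy, sensitivity, specificity, precision, NPV and
#' F1 from pooled counts. Metrics whose denominator is zero are `NaN` and
#' flagged, never reported as 0.
#'
#' @param tp,fp,fn,tn pooled confusion-matrix counts.
#' @param auc optionally, a pre-computed AUC to carry in the panel.
#' @param positiveClass label counted as positive (bookkeeping only).
#' @return a [MetricsReport-class].
#' @export
metricsFromConfusion <- function(tp, fp, fn, tn, auc = NaN,
                                 positiveClass = "positive") {
  buildMetrics(tp, fp, fn, tn, auc, positiveClass)
}

#' Metric panel of a cross-validation result
#'
#' Pools the held-out predictions into a single confusion matrix and computes
#' the panel; AUC comes from the decision scores via [aucFromScores()].
#'
#' @param cv a [CVResult-class].
#' @return a [MetricsReport-class].
#' @export
cvMetrics <- function(cv) {
  stopifnot(is(cv, "CVResult"))
  p <- cv@predictions
  pos <- cv@positiveClass
  tp <- sum(p$truth == pos & p$predicted == pos)
  fp <- sum(p$truth != pos & p$predicted == pos)
  fn <- sum(p$truth == pos & p$predicted != pos)
  tn <- sum(p$truth != pos & p$predicted != pos)
  auc <- aucFromScores(p$score, p$truth == pos)
  buildMetrics(tp, fp, fn, tn, auc, pos)
}

#' Majority-class dummy baseline
#'
#' Predicts the most frequent class for every sample with a constant decision
#' score, giving AUC = 0.5 by construction (all scores tie, midranks).
#'
#' @param table a feature table, or a vector of labels.
#' @param positiveClass label counted as positive; `NULL` picks the minority.
#' @return a [MetricsReport-class].
#' @export
dummyBaseline <- function(table, positiveClass = NULL) {
  y <- if (is.data.frame(table)) as.character(table$label) else as.character(table)
  counts <- base::table(y)
  if (length(counts) < 2L) stop("both classes must be present")
  majority <- names(counts)[which.max(counts)]
  if (is.null(positiveClass)) positiveClass <- names(counts)[which.min(counts)]
  pred <- rep(majority, length(y))
  tp <- sum(y == positiveClass & pred == positiveClass)
  fp <- sum(y != positiveClass & pred == positiveClass)
  fn <- sum(y == positiveClass & pred != positiveClass)
  tn <- sum(y != positiveClass & pred != positiveClass)
  auc <- aucFromScores(rep(0, length(y)), y == positiveClass)
  buildMetrics(tp, fp, fn, tn, auc, positiveClass)
}

# Whole-dataset standardize -> SMOTE -> PCA fit shared by the PCA views and
# the Shapley summary. Explicitly non-inferential: for visualization and
# post-hoc attribution only, never for the cross-validated metrics.
wholeDataFit <- function(table, cfg = pipelineConfig()) {
  feat <- featureColumns(table)
  # canonical order: results do not depend on the input row order
  table <- table[order(as.character(table$sample_id)), , drop = FALSE]
  X <- as.matrix(table[, feat, drop = FALSE])
  y <- as.character(table$label)
  med <- colMedians(X)
  x <- imputeWith(X, med)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  counts <- base::table(y)
  minority <- names(counts)[which.min(counts)]
  nNew <- as.integer(max(counts) - min(counts))
  syn <- smote(xs[y == minority, , drop = FALSE], cfg$smoteK, nNew,
               seed = deriveSeed(cfg$seed, "wholedata-smote"))
  all <- rbind(xs, syn)
  yAll <- c(y, rep(minority, nNew))
  synthetic <- c(rep(FALSE, nrow(xs)), rep(TRUE, nNew))

  pca <- stats::prcomp(all, center = TRUE, scale. = FALSE)
  if (sum(pca$sdev > max(pca$sdev) * 1e-8) < 2L)
    stop("feature matrix has rank < 2; PCA scatter undefined")
  rot <- pca$rotation
  # deterministic sign: the largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  ids <- c(as.character(table$sample_id), sprintf("synthetic_%d", seq_len(nNew)))
  list(scores = pca$x, loadings = rot,
       explainedVariance = pca$sdev^2 / sum(pca$sdev^2),
       labels = yAll, synthetic = synthetic, sample_id = ids,
       center = ctr, scale = scl, pcaCenter = pca$center,
       imputeMedians = med, minority = minority)
}

#' Whole-dataset PCA scatter (visualization view)
#'
#' Standardizes the full table, balances it with SMOTE and fits PCA --
#' the exploratory view of the cohort structure. This whole-dataset
#' balancing is for visualization only and plays no part in the
#' cross-validated metrics.
#'
#' @param table a feature table.
#' @param cfg a [pipelineConfig()].
#' @return list with `scores` (data.frame: PC1, PC2, label, synthetic,
#'   sample_id), `loadings` (orthonormal matrix, deterministic sign
#'   convention), `explainedVariance`, and the full fit as `fit`.
#' @export
pcaScatterData <- function(table, cfg = pipelineConfig()) {
  f <- wholeDataFit(table, cfg)
  list(scores = data.frame(PC1 = f$scores[, 1], PC2 = f$scores[, 2],
                           label = f$labels, synthetic = f$synthetic,
                           sample_id = f$sample_id, stringsAsFactors = FALSE),
       loadings = f$loadings,
       explainedVariance = f$explainedVariance,
       fit = f)
}

#' PCA loadings of a whole-dataset fit
#'
#' @param x the result of [pcaScatterData()] (or a feature table, in which
#'   case the fit is computed with `cfg`).
#' @param cfg a [pipelineConfig()], used when `x` is a table.
#' @return loading matrix (features x components), orthonormal columns.
#' @export
pcaLoadings <- function(x, cfg = pipelineConfig()) {
  if (is.data.frame(x) && "label" %in% names(x)) x <- pcaScatterData(x, cfg)
  x$loadings
}
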