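test_that("SMOTE interpolates on segments between minority neighbors", {
  # two points, k = 1: every synthetic point lies on the open segment
  x <- rbind(c(0, 0), c(1, 1))
  syn <- smote(x, k = 1, nNew = 25, seed = 1)
  expect_identical(nrow(syn), 25L)
  expect_true(all(abs(syn[, 1] - syn[, 2]) < 1e-12))
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))

  # n_new = 0: empty output with the right shape
  expect_identical(dim(smote(x, 1, nNew = 0L)), c(0L, 2L))

  # 6 minority rows in 14 dimensions: every synthetic row is a convex
  # combination of some pair of minority rows (segment test over all pairs)
  set.seed(42)
  m <- matrix(rnorm(6 * 14), 6, 14)
  syn14 <- smote(m, k = 5, nNew = 40, seed = 42)
  onSegment <- function(p) {
    for (a in 1:5) for (b in (a + 1):6) {
      v <- m[b, ] - m[a, ]
      u <- sum((p - m[a, ]) * v) / sum(v * v)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((m[a, ] + u * v - p)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn14, 1L, onSegment)))

  # single minority row: duplication with a warning
  expect_warning(dup <- smote(m[1, , drop = FALSE], 5, nNew = 3, seed = 1),
                 "duplicating")
  expect_true(all(apply(dup, 1L, function(r) all(r == m[1, ]))))
  expect_true(all(grepl("^synthetic_", rownames(syn14))))
})

test_that("a fitted fold separates trivially separable data and predicts deterministically", {
  x <- rbind(c(0, 0), c(0.2, 0.1), c(5, 5), c(5.2, 5.1))
  y <- c("neg", "neg", "pos", "pos")
  model <- microMRS:::withSeed(1, fitFold(x, y, pipelineConfig()))
  labs <- vapply(1:4, function(i) predictFold(model, x[i, ])$label, "")
  expect_identical(labs, y)
  p1 <- predictFold(model, x[1, ])
  p2 <- predictFold(model, x[1, ])
  expect_identical(p1$score, p2$score)
  expect_error(fitFold(x, rep("neg", 4), pipelineConfig()), "single class")
})

test_that("fold parameters never depend on the held-out row", {
  tbl <- toyFeatureTable()
  feat <- as.matrix(tbl[, featureColumns(tbl)])
  m1 <- microMRS:::withSeed(5, fitFold(feat[-1, ], tbl$label[-1], pipelineConfig()))
  tbl2 <- tbl
  tbl2[1, featureColumns(tbl)] <- tbl2[1, featureColumns(tbl)] + 1000
  feat2 <- as.matrix(tbl2[, featureColumns(tbl2)])
  m2 <- microMRS:::withSeed(5, fitFold(feat2[-1, ], tbl2$label[-1], pipelineConfig()))
  expect_identical(m1$scalerHash, m2$scalerHash)
  expect_identical(m1$pca$rotation, m2$pca$rotation)
})

test_that("LOOCV holds out each sample once and solves an obvious problem", {
  # two tight, far-apart pairs: every fold must classify its held-out point
  tbl <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                    f1 = c(0, 0.3, 10, 10.2), f2 = c(0, 0.2, 10, 9.8),
                    snr = 20, linewidth_ppm = 0.12,
                    label = c("A", "A", "B", "B"), check.names = FALSE)
  cv <- suppressWarnings(loocv(tbl, pipelineConfig(seed = 1)))
  p <- predictions(cv)
  expect_identical(nrow(p), 4L)
  expect_identical(sort(p$sample_id), sort(tbl$sample_id))
  expect_identical(p$predicted, p$truth)

  # structural guards
  expect_error(loocv(tbl[1:3, ][c(1, 1, 1), ], pipelineConfig()),
               "at least 4")
  one <- toyFeatureTable(nA = 5, nB = 1)
  expect_error(loocv(one, pipelineConfig()), "single sample")
})

test_that("LOOCV predictions are invariant to the row order of the table", {
  tbl <- toyFeatureTable(nA = 10, nB = 6, gap = 2)
  cv1 <- loocv(tbl, pipelineConfig(seed = 3))
  set.seed(1)
  perm <- sample(nrow(tbl))
  cv2 <- loocv(tbl[perm, ], pipelineConfig(seed = 3))
  p1 <- predictions(cv1)
  p2 <- predictions(cv2)
  p2 <- p2[match(p1$sample_id, p2$sample_id), ]
  expect_identical(p1$predicted, p2$predicted)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})

test_that("metric identities hold for arbitrary confusion matrices", {
  set.seed(10)
  for (i in 1:60) {
    cm <- as.integer(rmultinom(1, sample(4:200, 1), prob = runif(4, 0.02, 1)))
    rep <- metricsFromConfusion(cm[1], cm[2], cm[3], cm[4])
    n <- sum(cm)
    expect_equal(rep@accuracy, (cm[1] + cm[4]) / n)
    panel <- metricPanel(rep)
    def <- panel[!is.nan(panel)]
    expect_true(all(def >= 0 & def <= 1 + 1e-12))
    if (!is.nan(rep@precision) && !is.nan(rep@sensitivity) &&
        rep@precision + rep@sensitivity > 0) {
      expect_equal(rep@f1, 2 * rep@precision * rep@sensitivity /
                     (rep@precision + rep@sensitivity))
    }
    if (!is.nan(rep@sensitivity) && !is.nan(rep@specificity)) {
      expect_equal(rep@balancedAccuracy, (rep@sensitivity + rep@specificity) / 2)
    }
    # every NaN is flagged, never reported as 0
    expect_identical(sort(rep@flags), sort(names(panel)[is.nan(panel)]))
  }
  # undefined precision with zero predicted positives
  r0 <- metricsFromConfusion(0, 0, 7, 54)
  expect_true(is.nan(r0@precision))
  expect_true("precision" %in% r0@flags)
})

test_that("AUC follows the rank formulation with midrank ties", {
  expect_equal(aucFromScores(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(aucFromScores(rep(0, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  # equals trapezoidal ROC integration on tie-free scores
  set.seed(4)
  s <- rnorm(60)
  lab <- rep(c(TRUE, FALSE), 30)
  trapAuc <- function(scores, pos) {
    th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    tpr <- vapply(th, function(t) mean(scores[pos] >= t), 0)
    fpr <- vapply(th, function(t) mean(scores[!pos] >= t), 0)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(aucFromScores(s, lab), trapAuc(s, lab), tolerance = 1e-12)
  expect_equal(aucFromScores(s, lab),
               as.numeric(suppressMessages(pROC::auc(lab, s))),
               tolerance = 1e-12)
  expect_error(aucFromScores(1:3, c(TRUE, TRUE, TRUE)), "one positive and one negative")
})

test_that("the dummy baseline predicts the majority class with chance-level AUC", {
  labs <- rep(c("ARR", "DEV"), c(54, 7))
  rep <- dummyBaseline(labs)
  expect_identical(rep@positiveClass, "DEV")
  expect_identical(c(rep@tp, rep@fp, rep@fn, rep@tn), c(0L, 0L, 7L, 54L))
  expect_identical(rep@auc, 0.5)
  expect_equal(rep@accuracy, 54 / 61)

  balanced <- dummyBaseline(rep(c("A", "B"), 10), positiveClass = "B")
  expect_equal(balanced@accuracy, 0.5)
  expect_equal(balanced@balancedAccuracy, 0.5)
  expect_identical(balanced@auc, 0.5)
})

test_that("whole-data PCA views are orthonormal and reconstruct the data", {
  tbl <- toyFeatureTable(nA = 14, nB = 6, d = 6, gap = 3)
  pc <- pcaScatterData(tbl, pipelineConfig(seed = 2))
  L <- pc$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign convention
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)

  # reconstruction with all components equals the standardized balanced data
  f <- pc$fit
  recon <- f$scores %*% t(f$loadings)
  recon <- sweep(recon, 2L, f$pcaCenter, "+")
  tblS <- tbl[order(tbl$sample_id), ]
  X <- as.matrix(tblS[, featureColumns(tblS)])
  xs <- sweep(sweep(X, 2L, f$center), 2L, f$scale, "/")
  expect_equal(recon[!f$synthetic, ], xs, tolerance = 1e-8, ignore_attr = TRUE)

  # SMOTE balanced the visualization set exactly
  expect_identical(sum(f$labels == "A"), sum(f$labels == "B"))
  expect_error(pcaScatterData(toyFeatureTable(nA = 3, nB = 3, d = 1),
                              pipelineConfig()), "rank")
})

test_that("planted cohort structure is visible on the first two components", {
  # the balanced (SMOTE-augmented) scatter shows the DEV cluster; silhouette
  # of the DEV class on PC1-2 is positive for typical cohort draws
  sils <- vapply(0:4, function(s) {
    co <- generateCohort(cohortPreset("embryo61", seed = s))
    ft <- buildFeatureTable(co$spectra, co$labels)
    pc <- pcaScatterData(ft, pipelineConfig(seed = s))
    sc <- pc$scores
    d2 <- as.matrix(dist(sc[, c("PC1", "PC2")]))
    dev <- sc$label == "DEV"
    mean(vapply(which(dev), function(i) {
      a <- mean(d2[i, dev & seq_len(nrow(sc)) != i])
      b <- mean(d2[i, !dev])
      (b - a) / max(a, b)
    }, 0))
  }, 0)
  expect_gt(median(sils), 0)
})
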