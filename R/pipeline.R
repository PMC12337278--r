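#' @include synthdata.R biomarkers.R stats.R mlpipe.R attribution.R
NULL

pipelineConfigFromYaml <- function(conf) {
  pl <- conf$pipeline
  if (is.null(pl)) pl <- list()
  kernel <- pl$kernel
  if (is.null(kernel)) kernel <- "radial"
  if (kernel == "rbf") kernel <- "radial"
  pipelineConfig(
    smoteK = if (is.null(pl$smote_k)) 5L else pl$smote_k,
    pcaComponents = pl$pca_components,
    kernel = kernel,
    cost = if (is.null(pl$cost)) 1 else pl$cost,
    gamma = pl$gamma,
    pcaBeforeSmote = isTRUE(pl$pca_before_smote),
    positiveClass = pl$positive_class,
    seed = if (is.null(conf$seed)) 0L else conf$seed
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> extract -> compare -> classify -> attribute from
#' a YAML configuration and writes all artifacts plus a reproducibility
#' manifest. Identical configurations (same seed) produce byte-identical data
#' artifacts; only the manifest timestamps differ.
#'
#' Config schema (YAML):
#' \preformatted{
#' seed: 0
#' preset: embryo61        # or oocyte102
#' null_effects: false     # strip cohort effects (leakage sentinel runs)
#' out_dir: runs/demo
#' stages: [simulate, extract, compare, classify, attribute]
#' normalize: none         # or water
#' pipeline:
#'   smote_k: 5
#'   kernel: rbf           # or linear
#'   cost: 1.0
#'   pca_components: null  # all; or an integer / variance fraction
#'   pca_before_smote: false
#' attribution:
#'   top: 8
#' }
#'
#' Artifacts: `spectra/` (CSV spectra), `labels.csv`, `features.csv`,
#' `comparisons.csv`, `metrics.json` (SVM panel, dummy baseline, per-fold
#' predictions), `shap.csv`, `shap_ranking.csv`, `manifest.json`.
#'
#' @param configPath path to the YAML configuration.
#' @param outDir optional override of the config's `out_dir`.
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(configPath, outDir = NULL) {
  conf <- yaml::read_yaml(configPath)
  stages <- conf$stages
  if (is.null(stages) || !length(stages))
    stop("config error at 'stages': stage list must be non-empty")
  known <- c("simulate", "extract", "compare", "classify", "attribute")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("config error at 'stages': unknown stage(s) ", paste(bad, collapse = ", "))
  if (is.null(conf$preset))
    stop("config error at 'preset': a cohort preset is required")

  out <- if (!is.null(outDir)) outDir else conf$out_dir
  if (is.null(out)) stop("config error at 'out_dir': output directory required")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  seed <- if (is.null(conf$seed)) 0L else as.integer(conf$seed)
  scfg <- cohortPreset(conf$preset, seed = seed)
  if (isTRUE(conf$null_effects)) scfg <- nullEffectConfig(scfg)
  mlcfg <- pipelineConfigFromYaml(conf)
  normalize <- if (is.null(conf$normalize)) "none" else conf$normalize

  artifacts <- list()
  cohort <- NULL
  features <- NULL

  if ("simulate" %in% stages) {
    cohort <- generateCohort(scfg)
    sdir <- file.path(out, "spectra")
    writeSpectra(cohort$spectra, sdir)
    utils::write.csv(
      data.frame(sample_id = names(cohort$spectra), label = cohort$labels),
      file.path(out, "labels.csv"), row.names = FALSE)
    artifacts$spectra <- sdir
    artifacts$labels <- file.path(out, "labels.csv")
  }

  loadCohort <- function() {
    if (!is.null(cohort)) return(cohort)
    sdir <- file.path(out, "spectra")
    lfile <- file.path(out, "labels.csv")
    if (!dir.exists(sdir) || !file.exists(lfile))
      stop("extract needs spectra: run the simulate stage first (or provide ",
           sdir, " and ", lfile, ")")
    specs <- readSpectra(sdir)
    lab <- utils::read.csv(lfile, stringsAsFactors = FALSE)
    ids <- vapply(specs, sampleID, "")
    cohort <<- list(spectra = specs,
                    labels = lab$label[match(ids, lab$sample_id)])
    cohort
  }

  if (any(c("extract", "compare", "classify", "attribute") %in% stages)) {
    co <- loadCohort()
    features <- buildFeatureTable(co$spectra, co$labels, normalize = normalize)
    if ("extract" %in% stages) {
      utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
      artifacts$features <- file.path(out, "features.csv")
    }
  }

  if ("compare" %in% stages) {
    cmp <- compareAllCohorts(features, seed = seed)
    utils::write.csv(cmp, file.path(out, "comparisons.csv"), row.names = FALSE)
    artifacts$comparisons <- file.path(out, "comparisons.csv")
  }

  if ("classify" %in% stages) {
    cv <- loocv(features, mlcfg)
    report <- cvMetrics(cv)
    dum <- dummyBaseline(features, positiveClass = report@positiveClass)
    payload <- list(
      positive_class = report@positiveClass,
      confusion = list(tp = report@tp, fp = report@fp, fn = report@fn, tn = report@tn),
      metrics = as.list(metricPanel(report)),
      undefined_metrics = report@flags,
      dummy_baseline = as.list(metricPanel(dum)),
      n_folds = nrow(predictions(cv)),
      predictions = predictions(cv)
    )
    jsonlite::write_json(payload, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$metrics <- file.path(out, "metrics.json")
  }

  if ("attribute" %in% stages) {
    topK <- if (is.null(conf$attribution$top)) 8L else conf$attribution$top
    shap <- shapSummary(features, mlcfg, top = topK)
    vals <- shapValues(shap)
    attr(vals, "loadings") <- NULL
    shapDf <- data.frame(sample_id = rownames(vals), vals,
                         check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(shapDf, file.path(out, "shap.csv"), row.names = FALSE)
    rk <- data.frame(rank = seq_along(shapRanking(shap)),
                     feature = shapRanking(shap),
                     mean_abs_shapley = colMeans(abs(vals))[shapRanking(shap)])
    utils::write.csv(rk, file.path(out, "shap_ranking.csv"), row.names = FALSE)
    artifacts$shap <- file.path(out, "shap.csv")
    artifacts$shap_ranking <- file.path(out, "shap_ranking.csv")
  }

  manifest <- list(
    config_hash = unname(tools::md5sum(configPath)),
    seed = seed,
    preset = conf$preset,
    stages = stages,
    package_version = as.character(utils::packageVersion("microMRS")),
    r_version = R.version.string,
    artifacts = lapply(artifacts, normalizePath),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  artifacts$manifest <- file.path(out, "manifest.json")
  invisible(artifacts)
}
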