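#' Configure a full prediction analysis
#'
#' Bundles everything [runAnalysis()] needs: the data (an in-memory
#' [BiomarkerExperiment-class] or CSV + group-config paths), the list of
#' (dataset, target) analyses, CV settings, repeat-rate settings and an
#' optional output directory.
#'
#' @param experiment a [BiomarkerExperiment-class] whose `colData` holds the
#'   target columns; alternatively give `tablePath`/`groupsPath`.
#' @param tablePath,groupsPath CSV feature table and group config, read with
#'   [readBiomarkerTable()] when `experiment` is `NULL`.
#' @param analyses list of `list(dataset =, target =)` pairs; `NULL` runs
#'   every declared dataset against every target column.
#' @param targetColumns target column names (needed with `tablePath`).
#' @param folds,maxOrder,normScope cross-validation settings
#'   (see [crossValidate()]).
#' @param nRepeats,fraction,reselectOrder repeat-rate settings
#'   (see [repeatRates()]).
#' @param seed master seed; per-analysis child seeds are derived from it.
#' @param outDir if non-`NULL`, report files are written there.
#' @return config list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(experiment = NULL, tablePath = NULL,
                           groupsPath = NULL, analyses = NULL,
                           targetColumns = NULL, folds = 10L, maxOrder = 15L,
                           normScope = "global", nRepeats = 100L,
                           fraction = 0.9, reselectOrder = FALSE, seed = 1L,
                           outDir = NULL) {
  if (is.null(experiment) && (is.null(tablePath) || is.null(groupsPath)))
    stop("configuration error: give either 'experiment' or both 'tablePath' and 'groupsPath'")
  cfg <- list(experiment = experiment, tablePath = tablePath,
              groupsPath = groupsPath, analyses = analyses,
              targetColumns = targetColumns, folds = as.integer(folds),
              maxOrder = as.integer(maxOrder), normScope = normScope,
              nRepeats = as.integer(nRepeats), fraction = fraction,
              reselectOrder = reselectOrder, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Run the full prediction pipeline over datasets and targets
#'
#' For every (dataset, target) pair: cross-validated order selection
#' ([crossValidate()]), a final full-data [fosFit()] at the chosen order,
#' and a repeat-rate stability analysis ([repeatRates()]) at that order.
#' Afterwards, validation R values of different datasets predicting the
#' same target are compared pairwise with the dependent-correlation
#' Steiger test ([compareR()]), using pooled out-of-fold predictions to
#' estimate the inter-prediction correlation. Writes Table-style reports
#' (R matrix, p-value matrix, rank-indexed repeat rates, model JSON and a
#' manifest) to `config$outDir` when set.
#'
#' @param config an [analysisConfig()].
#' @return an `AnalysisBundle`: list with `results` (per-analysis list of
#'   `cv`, `model`, `repeatRates`, `seeds`), `rTable`
#'   (datasets x targets overall validation R), `comparisons` (data.frame
#'   of pairwise dataset comparisons per target), and `config`.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  be <- config$experiment %||%
    readBiomarkerTable(config$tablePath, config$groupsPath,
                       targetColumns = config$targetColumns %||% character())
  targetsAvail <- colnames(colData(be))
  analyses <- config$analyses
  if (is.null(analyses)) {
    dsNames <- names(S4Vectors::metadata(be)$datasets)
    analyses <- do.call(c, lapply(targetsAvail, function(tn)
      lapply(dsNames, function(d) list(dataset = d, target = tn))))
  }
  for (an in analyses) {
    if (!an$target %in% targetsAvail)
      stop("analysis error: unknown target '", an$target, "'")
    metricsForDataset(be, an$dataset)   # errors if the dataset is unknown
  }
  seeds <- childSeeds(config$seed, 2L * length(analyses))
  results <- vector("list", length(analyses))
  names(results) <- vapply(analyses, function(an)
    paste(an$dataset, an$target, sep = " | "), character(1L))
  for (i in seq_along(analyses)) {
    an <- analyses[[i]]
    cols <- metricsForDataset(be, an$dataset)
    spec <- fimTargetSpec(an$target, colData(be)[[an$target]])
    cv <- crossValidate(be, cols, spec, maxOrder = config$maxOrder,
                        folds = config$folds, seed = seeds[2L * i - 1L],
                        normScope = config$normScope)
    params <- fitNormalization(be, cols)
    cs <- expandCandidates(
      normalizeValues(metricMatrix(be)[, cols, drop = FALSE], params))
    model <- fosFit(cs, spec@values, order = chosenOrder(cv),
                    targetName = spec@name)
    rr <- repeatRates(be, cols, spec, order = chosenOrder(cv),
                      nRepeats = config$nRepeats, fraction = config$fraction,
                      seed = seeds[2L * i], normScope = config$normScope,
                      reselectOrder = config$reselectOrder)
    results[[i]] <- list(dataset = an$dataset, target = an$target, cv = cv,
                         model = model, repeatRates = rr,
                         seeds = c(cv = seeds[2L * i - 1L],
                                   repeats = seeds[2L * i]))
  }
  bundle <- list(results = results,
                 rTable = .rTable(results),
                 comparisons = .comparisonTable(results),
                 config = config)
  class(bundle) <- "AnalysisBundle"
  if (!is.null(config$outDir)) writeAnalysisReports(bundle, config$outDir)
  bundle
}

#' @noRd
.rTable <- function(results) {
  datasets <- unique(vapply(results, `[[`, character(1L), "dataset"))
  targets <- unique(vapply(results, `[[`, character(1L), "target"))
  tab <- matrix(NA_real_, length(datasets), length(targets),
                dimnames = list(datasets, targets))
  for (res in results)
    tab[res$dataset, res$target] <- overallR(res$cv)
  tab
}

#' Pairwise Steiger comparisons of datasets predicting the same target,
#' using pooled out-of-fold predictions at each chosen order.
#' @noRd
.comparisonTable <- function(results) {
  targets <- unique(vapply(results, `[[`, character(1L), "target"))
  rows <- list()
  for (tn in targets) {
    sub <- Filter(function(r) r$target == tn, results)
    if (length(sub) < 2L) next
    for (i in seq_len(length(sub) - 1L)) {
      for (j in seq((i + 1L), length(sub))) {
        cvi <- sub[[i]]$cv; cvj <- sub[[j]]$cv
        predI <- cvi@diagnostics$pooledPredictions[, cvi@chosenOrder]
        predJ <- cvj@diagnostics$pooledPredictions[, cvj@chosenOrder]
        r12 <- if (stats::sd(predI) > 0 && stats::sd(predJ) > 0)
          stats::cor(predI, predJ) else 0
        cmp <- compareR(min(cvi@pooledR, 1 - 1e-8),
                        min(cvj@pooledR, 1 - 1e-8), n = length(predI),
                        dependency = "dependent", r12 = r12)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, dataset1 = sub[[i]]$dataset,
          dataset2 = sub[[j]]$dataset, r1 = cvi@pooledR, r2 = cvj@pooledR,
          r12 = r12, z = cmp$z, pValue = cmp$pValue, method = cmp$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Write an analysis bundle as report files
#'
#' Emits `r_table.csv` (datasets x targets validation R),
#' `comparisons.csv` (pairwise dataset p-values per target), one
#' `repeat_rates_<i>.csv` per analysis (rank, metric, count, percent), one
#' `model_<i>.json` per analysis, and a `manifest.json` stamping seeds and
#' settings so every number is traceable. Identical seeds and config
#' reproduce the files byte-identically.
#'
#' @param bundle an `AnalysisBundle` from [runAnalysis()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeAnalysisReports <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(bundle$rTable),
                   file.path(outDir, "r_table.csv"))
  utils::write.csv(bundle$comparisons, file.path(outDir, "comparisons.csv"),
                   row.names = FALSE)
  manifest <- list(seed = bundle$config$seed,
                   folds = bundle$config$folds,
                   maxOrder = bundle$config$maxOrder,
                   normScope = bundle$config$normScope,
                   nRepeats = bundle$config$nRepeats,
                   fraction = bundle$config$fraction,
                   reselectOrder = bundle$config$reselectOrder,
                   analyses = list())
  for (i in seq_along(bundle$results)) {
    res <- bundle$results[[i]]
    writeRepeatRates(res$repeatRates,
                     file.path(outDir, sprintf("repeat_rates_%d.csv", i)))
    writeFOSModel(res$model, file.path(outDir, sprintf("model_%d.json", i)))
    manifest$analyses[[i]] <- list(
      index = i, dataset = res$dataset, target = res$target,
      chosenOrder = chosenOrder(res$cv), overallR = overallR(res$cv),
      pooledR = res$cv@pooledR, seeds = as.list(res$seeds))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' @export
print.AnalysisBundle <- function(x, ...) {
  cat("AnalysisBundle:", length(x$results), "analyses\n")
  print(round(x$rTable, 3))
  if (nrow(x$comparisons)) {
    cat("\npairwise comparisons (Steiger z):\n")
    print(x$comparisons[, c("target", "dataset1", "dataset2", "pValue")],
          digits = 3)
  }
  invisible(x)
}
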