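#' Configure a synthetic biomarker cohort
#'
#' Defines a seeded synthetic cohort with the statistical structure the FOS
#' pipeline assumes: a latent per-subject severity factor drives
#' equicorrelated Gaussian metric blocks within each task group, metrics are
#' affinely mapped to plausible ranges, ordinal-like clinical scores are
#' produced by binning, and the outcome is generated by a known sparse
#' nonlinear model of a few normalized metrics plus Gaussian noise, rescaled
#' to the configured moments and clipped into the target's valid range.
#' It stands in for clinical cohorts (default scale: 85 subjects,
#' FIM-Total-2w mean 96.3, sd 24.3) and provides ground truth for recovery
#' benchmarks.
#'
#' @param nSubjects number of subjects (default 85).
#' @param groups named integer vector of robotic metric counts per group
#'   (default `RA:13, RU:13, RI:13, M:9, OH:14`; names become metric
#'   prefixes).
#' @param clinical add the clinical panel (Purdue `PP`, `BIT`, ordinal
#'   Chedoke `CMS-A`/`CMS-U` on 1-7, ordinal Modified Ashworth
#'   `MAS-A`/`MAS-U` on 0-4 with 1+ recoded 1.5). Default `TRUE`.
#' @param withinGroupCorrelation equicorrelation of metrics within a group,
#'   in `[0, 1)` (default 0.3).
#' @param severityLoading share of each group factor's variance explained by
#'   the common latent severity (default 0.5); between-group metric
#'   correlation is `withinGroupCorrelation * severityLoading`.
#' @param trueModel list of `list(metric =, kind =, coefficient =)` terms
#'   defining the generative model on normalized metrics; empty list gives a
#'   pure-noise target.
#' @param intercept generative intercept before rescaling.
#' @param noiseSd Gaussian noise SD on the pre-rescaling target scale; if
#'   `NULL`, derived from `generativeR`.
#' @param generativeR intended correlation between noiseless signal and
#'   noisy target (default 0.85), used to derive `noiseSd` when that is
#'   `NULL` and the model has terms.
#' @param targetName outcome name; FIM ranges/moments are filled in by name
#'   (see [fimTargetSpec()]).
#' @param targetMean,targetSd moments the (pre-clipping) target is rescaled
#'   to; defaults by target name from typical post-stroke cohorts
#'   (e.g. FIM-Total-2w: 96.3 / 24.3, FIM-Motor-2w: 66.5 / 21.5).
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   bit-identically.
#' @return validated config list of class `SyntheticCohortConfig`.
#' @seealso [generateCohort()]
#' @export
syntheticCohortConfig <- function(nSubjects = 85L,
    groups = c(RA = 13L, RU = 13L, RI = 13L, M = 9L, OH = 14L),
    clinical = TRUE, withinGroupCorrelation = 0.3, severityLoading = 0.5,
    trueModel = list(
      list(metric = "M3", kind = "cube", coefficient = -35),
      list(metric = "M5", kind = "square", coefficient = -25),
      list(metric = "OH11", kind = "sin", coefficient = -20)),
    intercept = 0, noiseSd = NULL, generativeR = 0.85,
    targetName = "FIM-Total-2w", targetMean = NULL, targetSd = NULL,
    seed = 1L) {
  if (nSubjects < 2L) stop("configuration error: nSubjects must be >= 2")
  if (is.null(names(groups)) || any(groups < 1L))
    stop("configuration error: groups must be a named vector of positive counts")
  if (withinGroupCorrelation < 0 || withinGroupCorrelation >= 1)
    stop("configuration error: withinGroupCorrelation must be in [0, 1)")
  if (severityLoading < 0 || severityLoading > 1)
    stop("configuration error: severityLoading must be in [0, 1]")
  if (!is.null(noiseSd) && noiseSd < 0)
    stop("configuration error: noiseSd must be >= 0")
  metricNames <- unlist(lapply(names(groups), function(g)
    paste0(g, seq_len(groups[[g]]))), use.names = FALSE)
  clinNames <- if (clinical) c("PP", "BIT", "CMS-A", "CMS-U", "MAS-A", "MAS-U")
               else character()
  for (term in trueModel) {
    if (!all(c("metric", "kind", "coefficient") %in% names(term)))
      stop("configuration error: each trueModel term needs metric, kind, coefficient")
    if (!term$metric %in% c(metricNames, clinNames))
      stop("configuration error: trueModel metric '", term$metric,
           "' is not generated")
    if (!term$kind %in% .transformKinds)
      stop("configuration error: unknown transform kind '", term$kind, "'")
  }
  moments <- .defaultTargetMoments(targetName)
  cfg <- list(nSubjects = as.integer(nSubjects), groups = groups,
              clinical = clinical,
              withinGroupCorrelation = withinGroupCorrelation,
              severityLoading = severityLoading, trueModel = trueModel,
              intercept = intercept, noiseSd = noiseSd,
              generativeR = generativeR, targetName = targetName,
              targetMean = targetMean %||% moments[["mean"]],
              targetSd = targetSd %||% moments[["sd"]],
              seed = as.integer(seed))
  class(cfg) <- "SyntheticCohortConfig"
  cfg
}

#' @noRd
.defaultTargetMoments <- function(targetName) {
  defaults <- list(
    "FIM-Total-2w" = c(mean = 96.3, sd = 24.3),
    "FIM-Motor-2w" = c(mean = 66.5, sd = 21.5),
    "FIM-Total-3m" = c(mean = 118.5, sd = 12.8),
    "FIM-Motor-3m" = c(mean = 85.9, sd = 10.1))
  defaults[[targetName]] %||% c(mean = 96.3, sd = 24.3)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the cohort described by a [syntheticCohortConfig()]: severity
#' factor, group-factor structure, metric blocks, ordinal clinical scores,
#' and the target `intercept + sum(coef * transform(z(metric))) + noise`,
#' affinely rescaled to the configured moments and clipped into the valid
#' FIM range. The returned ground truth is on the rescaled target scale and
#' suffices to recompute the target values from the metric table.
#'
#' @param config a `SyntheticCohortConfig`.
#' @return list with elements
#'   `experiment` (a [BiomarkerExperiment-class]; the target is also stored
#'   in `colData`), `target` (a [TargetSpec-class] with values), and
#'   `truth` (list: rescaled `terms`, `intercept`, `noise`, `signal`
#'   (noiseless rescaled values), `preclip`, `params`
#'   (the [NormalizationParams-class] used by the generative model),
#'   `generativeR` (realized, see [realizedGenerativeR()]), `config`).
#' @examples
#' cohort <- generateCohort(syntheticCohortConfig(nSubjects = 40, seed = 7))
#' cohort$experiment
#' realizedGenerativeR(cohort)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  withSeed(config$seed, .generateCohortImpl(config))
}

#' @noRd
.generateCohortImpl <- function(config) {
  n <- config$nSubjects
  rho <- config$withinGroupCorrelation
  a <- config$severityLoading
  u <- stats::rnorm(n)                       # latent severity
  groupNames <- names(config$groups)
  clinGroups <- if (config$clinical)
    c(`CLIN-S` = 2L, `CLIN-A` = 2L, `CLIN-U` = 2L) else integer()
  allGroups <- c(config$groups, clinGroups)
  std <- list()
  for (g in names(allGroups)) {
    fg <- sqrt(a) * u + sqrt(1 - a) * stats::rnorm(n)
    k <- allGroups[[g]]
    eps <- matrix(stats::rnorm(n * k), n, k)
    std[[g]] <- sqrt(rho) * fg + sqrt(1 - rho) * eps
  }
  metrics <- do.call(cbind, std[groupNames])
  metricNames <- unlist(lapply(groupNames, function(g)
    paste0(g, seq_len(config$groups[[g]]))), use.names = FALSE)
  # affine map to plausible, metric-specific ranges
  j <- seq_len(ncol(metrics))
  metrics <- sweep(metrics, 2L, 1 + (j %% 5) * 0.6, "*")
  metrics <- sweep(metrics, 2L, 10 + (j * 7) %% 45, "+")
  colnames(metrics) <- metricNames
  groupsMap <- stats::setNames(rep(groupNames, config$groups), metricNames)
  if (config$clinical) {
    clin <- cbind(
      PP      = 15 - 4 * std[["CLIN-S"]][, 1L],
      BIT     = 134 - 12 * std[["CLIN-S"]][, 2L],
      `CMS-A` = .binOrdinal(std[["CLIN-A"]][, 1L], 1:7,
                            c(.13, .11, .09, .04, .19, .09, .35)),
      `CMS-U` = .binOrdinal(std[["CLIN-U"]][, 1L], 1:7,
                            c(.0, .0, .0, .0, .05, .13, .82)),
      `MAS-A` = .binOrdinal(-std[["CLIN-A"]][, 2L], c(0, 1, 1.5, 2, 3, 4),
                            c(.80, .07, .05, .06, .01, .01)),
      `MAS-U` = .binOrdinal(-std[["CLIN-U"]][, 2L], c(0, 1, 1.5, 2, 3, 4),
                            c(.90, .05, .03, .01, .005, .005)))
    metrics <- cbind(metrics, clin)
    groupsMap <- c(groupsMap,
      stats::setNames(c("CLIN-S", "CLIN-S", "CLIN-A", "CLIN-U",
                        "CLIN-A", "CLIN-U"), colnames(clin)))
  }
  rownames(metrics) <- sprintf("S%03d", seq_len(n))
  datasets <- list(
    "Reach-Affected" = "RA", "Reach-Unaffected" = "RU",
    "Reach-Interlimb" = "RI", "Match" = "M", "Object-Hit" = "OH",
    "All-Robotic" = c("RA", "RU", "RI", "M", "OH"))
  if (config$clinical)
    datasets <- c(datasets, list(
      "Clinical-Affected" = c("CLIN-A", "CLIN-S"),
      "Clinical-Unaffected" = c("CLIN-U", "CLIN-S"),
      "Clinical-All" = c("CLIN-A", "CLIN-U", "CLIN-S")))
  datasets <- datasets[vapply(datasets, function(gs)
    all(gs %in% groupsMap), logical(1L))]
  # generative target on normalized metrics
  spec0 <- fimTargetSpec(config$targetName)
  trueMetrics <- vapply(config$trueModel, `[[`, character(1L), "metric")
  params <- if (length(trueMetrics))
    fitNormalization(metrics, unique(trueMetrics)) else NULL
  signal0 <- rep(config$intercept, n)
  if (length(trueMetrics)) {
    z <- normalizeValues(metrics[, unique(trueMetrics), drop = FALSE], params)
    for (term in config$trueModel)
      signal0 <- signal0 +
        term$coefficient * realizeTransform(term$kind, z[, term$metric])
  }
  noiseSd <- config$noiseSd
  if (is.null(noiseSd)) {
    noiseSd <- if (length(trueMetrics) && stats::sd(signal0) > 0)
      stats::sd(signal0) * sqrt(1 / config$generativeR^2 - 1) else 1
  }
  noise <- stats::rnorm(n, 0, noiseSd)
  raw <- signal0 + noise
  alpha <- if (stats::sd(raw) > 0) config$targetSd / stats::sd(raw) else 1
  beta <- config$targetMean - alpha * mean(raw)
  preclip <- alpha * raw + beta
  values <- pmin(pmax(preclip, spec0@validMin), spec0@validMax)
  target <- targetSpec(config$targetName, values, spec0@validMin,
                       spec0@validMax)
  truth <- list(
    terms = lapply(config$trueModel, function(term)
      list(metric = term$metric, kind = term$kind,
           coefficient = alpha * term$coefficient)),
    intercept = alpha * config$intercept + beta,
    noise = alpha * noise, noiseSd = alpha * noiseSd,
    signal = alpha * signal0 + beta, preclip = preclip, params = params,
    config = config)
  truth$generativeR <- computeR(truth$signal, values)
  targets <- stats::setNames(data.frame(values), config$targetName)
  experiment <- BiomarkerExperiment(metrics, groups = groupsMap,
                                    datasets = datasets, targets = targets)
  list(experiment = experiment, target = target, truth = truth)
}

#' @noRd
.binOrdinal <- function(latent, levels, probs) {
  probs <- probs / sum(probs)
  cuts <- stats::qnorm(pmin(cumsum(probs[-length(probs)]), 1 - 1e-12))
  levels[findInterval(latent, cuts) + 1L]
}

#' Realized generative R of a synthetic cohort
#'
#' Correlation (on the `[0, 1]` convention of [computeR()]) between the
#' noiseless generative model values and the final noisy, clipped target.
#'
#' @param cohort a list returned by [generateCohort()].
#' @return single numeric value.
#' @export
realizedGenerativeR <- function(cohort) {
  computeR(cohort$truth$signal, cohort$target@values)
}

#' Recompute cohort targets from the ground-truth record
#'
#' Round-trip check helper: rebuilds
#' `intercept + sum(coef * transform(z(metric))) + noise`, clipped into the
#' valid range, from the metric table and the stored ground truth.
#'
#' @param cohort a list returned by [generateCohort()].
#' @return numeric vector that reproduces `cohort$target@values`.
#' @export
recomputeTargets <- function(cohort) {
  truth <- cohort$truth
  m <- metricMatrix(cohort$experiment)
  values <- rep(truth$intercept, nrow(m))
  if (length(truth$terms)) {
    mets <- unique(vapply(truth$terms, `[[`, character(1L), "metric"))
    z <- normalizeValues(m[, mets, drop = FALSE], truth$params)
    for (term in truth$terms)
      values <- values +
        term$coefficient * realizeTransform(term$kind, z[, term$metric])
  }
  spec <- cohort$target
  unname(pmin(pmax(values + truth$noise, spec@validMin), spec@validMax))
}

#' Write a synthetic cohort to portable files
#'
#' Emits the standard CSV feature table (first column `subject`, one column
#' per metric, plus the target column), a YAML group configuration with the
#' dataset unions, and a JSON ground-truth record.
#'
#' @param cohort list from [generateCohort()].
#' @param tablePath CSV output path.
#' @param groupsPath YAML group-config output path.
#' @param truthPath optional JSON ground-truth output path.
#' @export
writeCohort <- function(cohort, tablePath, groupsPath, truthPath = NULL) {
  m <- metricMatrix(cohort$experiment)
  df <- data.frame(subject = rownames(m), m, check.names = FALSE)
  df[[cohort$target@name]] <- cohort$target@values
  utils::write.csv(df, tablePath, row.names = FALSE)
  yaml::write_yaml(
    list(groups = as.list(groupMap(cohort$experiment)),
         datasets = lapply(S4Vectors::metadata(cohort$experiment)$datasets,
                           as.list)),
    groupsPath)
  if (!is.null(truthPath)) {
    truth <- cohort$truth
    jsonlite::write_json(
      list(terms = truth$terms, intercept = truth$intercept,
           noise = truth$noise, noiseSd = truth$noiseSd,
           generativeR = truth$generativeR,
           normalization = if (!is.null(truth$params)) list(
             metric = names(truth$params@xmin),
             xmin = unname(truth$params@xmin),
             xmax = unname(truth$params@xmax))),
      truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tablePath)
}
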