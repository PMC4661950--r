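#' Construct a BiomarkerExperiment from a subjects x metrics matrix
#'
#' @param metrics numeric matrix, rows = subjects, columns = metrics, with
#'   rownames (subject ids) and colnames (metric names).
#' @param groups named character vector mapping every metric name to a task
#'   group label.
#' @param datasets named list of character vectors; each entry defines a
#'   dataset as a union of group labels (e.g.
#'   `list("All-Robotic" = c("RA","RU","RI","M","OH"))`). Single groups are
#'   always addressable by their own label.
#' @param targets optional data.frame of per-subject outcome values
#'   (e.g. FIM scores), one row per subject.
#' @return a [BiomarkerExperiment-class] object.
#' @examples
#' x <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("s", 1:5), c("M1", "M2", "OH1", "OH2")))
#' be <- BiomarkerExperiment(x, groups = c(M1 = "M", M2 = "M",
#'                                         OH1 = "OH", OH2 = "OH"))
#' metricsForDataset(be, "M")
#' @export
BiomarkerExperiment <- function(metrics, groups, datasets = list(),
                                targets = NULL) {
  metrics <- as.matrix(metrics)
  if (is.null(colnames(metrics)))
    stop("metric columns must be named")
  if (is.null(rownames(metrics)))
    rownames(metrics) <- paste0("subject", seq_len(nrow(metrics)))
  missing <- setdiff(colnames(metrics), names(groups))
  if (length(missing))
    stop("configuration error: metric(s) not mapped to a group: ",
         paste(missing, collapse = ", "))
  rd <- S4Vectors::DataFrame(group = unname(groups[colnames(metrics)]),
                             row.names = colnames(metrics))
  cd <- if (is.null(targets)) {
    S4Vectors::DataFrame(row.names = rownames(metrics))
  } else {
    S4Vectors::DataFrame(targets, row.names = rownames(metrics),
                         check.names = FALSE)
  }
  se <- SummarizedExperiment(assays = list(metrics = t(metrics)),
                             rowData = rd, colData = cd)
  S4Vectors::metadata(se)$datasets <- datasets
  methods::new("BiomarkerExperiment", se)
}

#' Read a biomarker feature table and its group configuration
#'
#' Loads a CSV (header row of metric names, first column the subject id)
#' and a YAML or JSON group configuration with two top-level fields:
#' `groups`, mapping every metric column to a task group label, and an
#' optional `datasets` list of named group unions. Subjects with a missing
#' value in any mapped metric column are removed listwise and the exclusion
#' count is reported via `message()`.
#'
#' @param path CSV file path (UTF-8, '.' decimal).
#' @param groupConfig YAML (`.yaml`/`.yml`) or JSON group-config file path.
#' @param targetColumns optional character vector of CSV columns to treat as
#'   outcome targets (stored in `colData`, exempt from group mapping).
#' @return a [BiomarkerExperiment-class].
#' @export
readBiomarkerTable <- function(path, groupConfig, targetColumns = character()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L)
    stop("parse error: expected a subject-id column plus metric columns")
  subjectIds <- raw[[1L]]
  cfg <- readGroupConfig(groupConfig)
  metricCols <- setdiff(colnames(raw)[-1L], targetColumns)
  unmapped <- setdiff(metricCols, names(cfg$groups))
  if (length(unmapped))
    stop("configuration error: column(s) missing from group config: ",
         paste(unmapped, collapse = ", "))
  num <- lapply(c(metricCols, intersect(targetColumns, colnames(raw))),
    function(cn) {
      v <- trimws(raw[[cn]])
      out <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & nzchar(v) & v != "NA" & is.na(out))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1L]], bad[1L], cn))
      out[!nzchar(v) | v == "NA"] <- NA_real_
      out
    })
  names(num) <- c(metricCols, intersect(targetColumns, colnames(raw)))
  mat <- do.call(cbind, num[metricCols])
  rownames(mat) <- subjectIds
  keep <- stats::complete.cases(mat)
  if (any(!keep))
    message(sum(!keep), " subject(s) excluded listwise for missing metric values")
  targets <- NULL
  if (length(targetColumns)) {
    targets <- as.data.frame(num[intersect(targetColumns, colnames(raw))],
                             check.names = FALSE)[keep, , drop = FALSE]
  }
  BiomarkerExperiment(mat[keep, , drop = FALSE],
                      groups = unlist(cfg$groups),
                      datasets = cfg$datasets %||% list(),
                      targets = targets)
}

#' @keywords internal
#' @noRd
readGroupConfig <- function(path) {
  cfg <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$groups))
    stop("configuration error: group config needs a 'groups' mapping")
  cfg$groups <- lapply(cfg$groups, as.character)
  cfg$datasets <- lapply(cfg$datasets %||% list(), as.character)
  cfg
}

# ---- accessors ---------------------------------------------------------

#' @describeIn BiomarkerExperiment subjects x metrics matrix (transposed assay).
#' @param object,x a `BiomarkerExperiment`.
#' @export
metricMatrix <- function(object) t(assay(object, "metrics"))

#' @describeIn BiomarkerExperiment named character vector metric -> group.
#' @export
groupMap <- function(object) {
  stats::setNames(rowData(object)$group, rownames(object))
}

#' @describeIn BiomarkerExperiment subject identifiers.
#' @export
subjectIds <- function(object) colnames(object)

#' Resolve a dataset name to its metric columns
#'
#' A dataset is either a group label (`"M"`, `"OH"`, ...) or a named union
#' of groups declared in `metadata(x)$datasets` (e.g. `"All-Robotic"`).
#' Metrics are returned in table order.
#'
#' @param x a [BiomarkerExperiment-class].
#' @param dataset dataset or group name.
#' @return character vector of metric names.
#' @export
metricsForDataset <- function(x, dataset) {
  gm <- groupMap(x)
  ds <- S4Vectors::metadata(x)$datasets %||% list()
  groups <- if (dataset %in% names(ds)) {
    ds[[dataset]]
  } else if (dataset %in% gm) {
    dataset
  } else {
    stop("unknown dataset: '", dataset, "' (not a dataset union or group label)")
  }
  unknown <- setdiff(groups, gm)
  if (length(unknown))
    stop("dataset '", dataset, "' references unknown group(s): ",
         paste(unknown, collapse = ", "))
  names(gm)[gm %in% groups]
}

setMethod("show", "BiomarkerExperiment", function(object) {
  cat("BiomarkerExperiment:", ncol(object), "subjects x", nrow(object),
      "metrics\n")
  grp <- table(rowData(object)$group)
  cat("groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = " "), "\n")
  ds <- S4Vectors::metadata(object)$datasets
  if (length(ds)) cat("datasets:", paste(names(ds), collapse = ", "), "\n")
  if (ncol(colData(object)))
    cat("targets:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

# ---- normalization -----------------------------------------------------

#' Fit min-max normalization parameters
#'
#' Records the observed minimum and maximum of each requested metric so
#' values can be scaled to `[0, 1]` via `z(x) = (x - xmin) / (xmax - xmin)`.
#' All candidate metrics (robotic and clinical alike) are normalized
#' identically, giving the nonlinear transforms a common bounded domain.
#'
#' @param x a [BiomarkerExperiment-class] or subjects x metrics matrix.
#' @param columns metric names to fit (default: all).
#' @param scope `"global"` (fit once on the full table) or `"train_fold"`
#'   (caller fits on CV training subjects only); recorded for provenance.
#' @return a [NormalizationParams-class].
#' @examples
#' m <- cbind(a = c(2, 4, 10), b = c(0, 1, 2))
#' p <- fitNormalization(m)
#' normalizeValues(m, p)
#' @export
fitNormalization <- function(x, columns = NULL,
                             scope = c("global", "train_fold")) {
  scope <- match.arg(scope)
  m <- if (methods::is(x, "BiomarkerExperiment")) metricMatrix(x) else as.matrix(x)
  columns <- columns %||% colnames(m)
  m <- m[, columns, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 subjects to fit normalization")
  xmin <- apply(m, 2L, min)
  xmax <- apply(m, 2L, max)
  degen <- xmax <= xmin
  if (any(degen))
    stop("degenerate metric(s) with constant values: ",
         paste(columns[degen], collapse = ", "))
  methods::new("NormalizationParams", xmin = xmin, xmax = xmax, scope = scope)
}

#' Apply min-max normalization
#'
#' Scales raw metric values to `[0, 1]`; the training minimum maps exactly
#' to 0 and the maximum exactly to 1, affinely in between. Values outside
#' the training range (new data at prediction time) are clipped into
#' `[0, 1]` so downstream log/sin transforms stay on their intended domain.
#'
#' @param x numeric vector (one metric, named in `params`) or a matrix /
#'   [BiomarkerExperiment-class] whose columns are a subset of the fitted
#'   metrics.
#' @param params a [NormalizationParams-class].
#' @param metric metric name, required when `x` is a bare vector.
#' @return normalized values in `[0, 1]`, same shape as the input selection.
#' @export
normalizeValues <- function(x, params, metric = NULL) {
  stopifnot(methods::is(params, "NormalizationParams"))
  if (is.null(dim(x)) && !methods::is(x, "BiomarkerExperiment")) {
    if (is.null(metric)) {
      if (length(params@xmin) != 1L)
        stop("specify 'metric' when normalizing a bare vector")
      metric <- names(params@xmin)
    }
    if (!metric %in% names(params@xmin))
      stop("no normalization parameters for metric '", metric, "'")
    z <- (x - params@xmin[[metric]]) /
      (params@xmax[[metric]] - params@xmin[[metric]])
    return(pmin(pmax(z, 0), 1))
  }
  m <- if (methods::is(x, "BiomarkerExperiment")) metricMatrix(x) else as.matrix(x)
  cols <- colnames(m)
  missing <- setdiff(cols, names(params@xmin))
  if (length(missing))
    stop("no normalization parameters for metric(s): ",
         paste(missing, collapse = ", "))
  z <- sweep(m, 2L, params@xmin[cols], "-")
  z <- sweep(z, 2L, params@xmax[cols] - params@xmin[cols], "/")
  pmin(pmax(z, 0), 1)
}

setMethod("show", "NormalizationParams", function(object) {
  cat("NormalizationParams:", length(object@xmin), "metric(s), scope =",
      object@scope, "\n")
})

#' Serialize / restore normalization parameters as JSON
#'
#' @param params a [NormalizationParams-class].
#' @param path file path.
#' @return `readNormalizationParams` returns a [NormalizationParams-class]
#'   identical to the one written.
#' @export
writeNormalizationParams <- function(params, path) {
  jsonlite::write_json(
    list(scope = params@scope,
         metrics = lapply(seq_along(params@xmin), function(i)
           list(metric = names(params@xmin)[i],
                xmin = params@xmin[[i]], xmax = params@xmax[[i]]))),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeNormalizationParams
#' @export
readNormalizationParams <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nm <- vapply(obj$metrics, `[[`, character(1L), "metric")
  methods::new("NormalizationParams",
    xmin = stats::setNames(vapply(obj$metrics, `[[`, numeric(1L), "xmin"), nm),
    xmax = stats::setNames(vapply(obj$metrics, `[[`, numeric(1L), "xmax"), nm),
    scope = obj$scope)
}

# ---- target specifications --------------------------------------------

#' Define a prediction target with a valid score range
#'
#' @param name target name.
#' @param values numeric per-subject outcome values (optional).
#' @param validMin,validMax valid range of the scale; out-of-range
#'   predictions are later clipped to these bounds.
#' @return a [TargetSpec-class].
#' @export
targetSpec <- function(name, values = numeric(), validMin, validMax) {
  methods::new("TargetSpec", name = name, validMin = validMin,
               validMax = validMax, values = as.numeric(values))
}

#' FIM target specification by name
#'
#' Builds a [TargetSpec-class] with the standard Functional Independence
#' Measure ranges: FIM-Total on 18-126 (18 items scored 1-7) and FIM-Motor
#' on 13-91 (13 motor items). Any name containing `"Motor"` gets the motor
#' range, otherwise the total range.
#'
#' @param name e.g. `"FIM-Total-2w"`, `"FIM-Motor-3m"`.
#' @param values per-subject scores (optional).
#' @return a [TargetSpec-class].
#' @export
fimTargetSpec <- function(name, values = numeric()) {
  if (grepl("Motor", name, ignore.case = TRUE)) {
    targetSpec(name, values, validMin = 13, validMax = 91)
  } else {
    targetSpec(name, values, validMin = 18, validMax = 126)
  }
}

setMethod("show", "TargetSpec", function(object) {
  cat(sprintf("TargetSpec '%s': valid range [%g, %g], %d value(s)\n",
              object@name, object@validMin, object@validMax,
              length(object@values)))
})
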