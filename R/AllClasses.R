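#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' BiomarkerExperiment: subjects x metrics biomarker panel
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay named `"metrics"` (rows = metrics, columns = subjects), a
#' `group` column in `rowData()` assigning each metric to a task group
#' (e.g. `RA`, `RU`, `RI`, `M`, `OH`, clinical groups), and named dataset
#' unions (e.g. `All-Robotic = RA + RU + RI + M + OH`) in
#' `metadata()$datasets`. Outcome scales (FIM targets) live in `colData()`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [BiomarkerExperiment()], [readBiomarkerTable()],
#'   [metricMatrix()], [metricsForDataset()]
#' @export
setClass("BiomarkerExperiment", contains = "SummarizedExperiment")

setValidity("BiomarkerExperiment", function(object) {
  msg <- character()
  if (!"metrics" %in% assayNames(object))
    msg <- c(msg, "assay 'metrics' is required")
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 subjects are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate metric names are not allowed")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "metric names (rownames) and subject ids (colnames) are required")
  if (!"group" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain a 'group' column mapping every metric")
  } else {
    grp <- rowData(object)$group
    if (anyNA(grp) || any(!nzchar(grp)))
      msg <- c(msg, "every metric must have a non-empty group label")
  }
  if ("metrics" %in% assayNames(object) &&
      !all(is.finite(assay(object, "metrics"))))
    msg <- c(msg, "all metric values must be finite (apply the missing-data policy first)")
  if (length(msg)) msg else TRUE
})

#' NormalizationParams: per-metric min-max scaling parameters
#'
#' Stores the observed minimum and maximum of each metric used by the
#' 0-1 min-max normalization `z(x) = (x - xmin) / (xmax - xmin)`, plus the
#' scope under which they were fit (`"global"` = whole table, or
#' `"train_fold"` = training subjects of a CV fold only).
#'
#' @slot xmin,xmax named numeric vectors, one entry per metric.
#' @slot scope character scalar, `"global"` or `"train_fold"`.
#' @seealso [fitNormalization()], [normalizeValues()]
#' @export
setClass("NormalizationParams",
  representation(xmin = "numeric", xmax = "numeric", scope = "character"),
  prototype(scope = "global"))

setValidity("NormalizationParams", function(object) {
  msg <- character()
  if (length(object@xmin) != length(object@xmax))
    msg <- c(msg, "xmin and xmax must have equal length")
  if (is.null(names(object@xmin)) || is.null(names(object@xmax)) ||
      !identical(names(object@xmin), names(object@xmax)))
    msg <- c(msg, "xmin and xmax must share metric names")
  if (any(object@xmax <= object@xmin))
    msg <- c(msg, sprintf("degenerate metric(s): %s (xmax <= xmin)",
      paste(names(object@xmin)[object@xmax <= object@xmin], collapse = ", ")))
  if (!length(object@scope) == 1L || !object@scope %in% c("global", "train_fold"))
    msg <- c(msg, "scope must be 'global' or 'train_fold'")
  if (length(msg)) msg else TRUE
})

#' TargetSpec: an outcome scale with its valid range
#'
#' Describes a prediction target: its name, valid score range (used to clip
#' out-of-range predictions back to the scale), and the per-subject values.
#' FIM-Total is valid on 18-126 and FIM-Motor on 13-91.
#'
#' @slot name character scalar.
#' @slot validMin,validMax numeric scalars with `validMin < validMax`.
#' @slot values numeric vector, one value per subject (may be empty for a
#'   range-only spec).
#' @seealso [targetSpec()], [fimTargetSpec()], [clipToRange()]
#' @export
setClass("TargetSpec",
  representation(name = "character", validMin = "numeric",
                 validMax = "numeric", values = "numeric"))

setValidity("TargetSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@validMin) != 1L || length(object@validMax) != 1L ||
      !is.finite(object@validMin) || !is.finite(object@validMax) ||
      object@validMin >= object@validMax)
    msg <- c(msg, "validMin must be finite and < validMax")
  if (length(msg)) msg else TRUE
})

#' CandidateSet: realized pool of candidate basis functions
#'
#' The candidate pool offered to FOS: for each normalized metric the six
#' transforms identity, square, cube, sin, cos, log (natural log of
#' `z + epsilon`), realized as columns of a subjects x candidates design
#' matrix. The constant term is not part of the pool; FOS injects it as the
#' mandatory first model term.
#'
#' @slot candidates data.frame with columns `kind`, `metric`, `label`, one
#'   row per candidate, in deterministic order (metrics in table order,
#'   transforms in the fixed order above).
#' @slot design numeric matrix, subjects x candidates, all entries finite.
#' @slot epsilon offset making the log transform total on `[0, 1]`.
#' @seealso [expandCandidates()], [fosFit()]
#' @export
setClass("CandidateSet",
  representation(candidates = "data.frame", design = "matrix",
                 epsilon = "numeric"))

setValidity("CandidateSet", function(object) {
  msg <- character()
  if (!all(c("kind", "metric", "label") %in% colnames(object@candidates)))
    msg <- c(msg, "candidates needs columns kind, metric, label")
  if (nrow(object@candidates) != ncol(object@design))
    msg <- c(msg, "design must have one column per candidate")
  if (anyDuplicated(object@candidates$label))
    msg <- c(msg, "candidate labels must be unique")
  if ("constant" %in% object@candidates$kind)
    msg <- c(msg, "the constant term must not be in the candidate pool")
  if (length(object@design) && !all(is.finite(object@design)))
    msg <- c(msg, "realized design matrix must be finite")
  if (length(msg)) msg else TRUE
})

#' FOSModel: a fitted Fast Orthogonal Search model
#'
#' An ordered additive model `S = sum_m a_m p_m + e`: the first term is
#' always the constant, subsequent terms are the candidates picked greedily
#' for largest reduction in training mean squared error. Coefficients are
#' the ordinary-least-squares solution on the selected columns, and
#' `trainMsePath[m]` is the training MSE of the m-term model.
#'
#' @slot terms data.frame (`kind`, `metric`, `label`), first row the
#'   constant term.
#' @slot coefficients numeric, aligned with `terms`.
#' @slot trainMsePath numeric, non-increasing, same length as `terms`.
#' @slot targetName name of the predicted outcome.
#' @slot epsilon log-transform offset used when realizing candidates.
#' @seealso [fosFit()], [greedyForwardOLS()], [predict()][predictTargets()]
#' @export
setClass("FOSModel",
  representation(terms = "data.frame", coefficients = "numeric",
                 trainMsePath = "numeric", targetName = "character",
                 epsilon = "numeric"))

setValidity("FOSModel", function(object) {
  msg <- character()
  nt <- nrow(object@terms)
  if (nt < 1L || object@terms$kind[1L] != "constant")
    msg <- c(msg, "first selected term must be the constant")
  if (anyDuplicated(object@terms$label))
    msg <- c(msg, "a candidate may be selected at most once")
  if (length(object@coefficients) != nt)
    msg <- c(msg, "one coefficient per selected term is required")
  if (length(object@trainMsePath) != nt)
    msg <- c(msg, "trainMsePath must have one entry per term")
  if (length(object@trainMsePath) > 1L) {
    d <- diff(object@trainMsePath)
    if (any(d > 1e-8 * max(object@trainMsePath[1L], 1)))
      msg <- c(msg, "training MSE path must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' CVResult: cross-validated model-order selection
#'
#' Validation performance of FOS models of order 1..maxOrder under k-fold
#' cross-validation. Performance is the R value (Pearson correlation between
#' actual and range-clipped predicted scores, clamped at 0) averaged over
#' folds; the chosen order maximizes mean validation R, with ties resolved
#' toward the smaller (more parsimonious) order.
#'
#' @slot foldR folds x orders matrix of per-fold validation R values.
#' @slot meanR mean validation R per order.
#' @slot chosenOrder selected number of model terms (constant included).
#' @slot overallR mean validation R at the chosen order.
#' @slot pooledR diagnostic: R of out-of-fold predictions pooled over folds,
#'   at the chosen order.
#' @slot foldAssignments integer fold index per subject (named).
#' @slot seed seed that generated the fold assignment.
#' @slot normScope normalization scope used (`"global"` or `"train_fold"`).
#' @slot diagnostics list: `rawR` (signed, unclamped fold correlations),
#'   `pooledPredictions` (subjects x orders out-of-fold predictions),
#'   `targetName`.
#' @seealso [crossValidate()]
#' @export
setClass("CVResult",
  representation(foldR = "matrix", meanR = "numeric", chosenOrder = "integer",
                 overallR = "numeric", pooledR = "numeric",
                 foldAssignments = "integer", seed = "integer",
                 normScope = "character", diagnostics = "list"))

setValidity("CVResult", function(object) {
  msg <- character()
  if (length(object@meanR) != ncol(object@foldR))
    msg <- c(msg, "meanR must have one entry per order")
  if (object@chosenOrder < 1L || object@chosenOrder > length(object@meanR))
    msg <- c(msg, "chosenOrder out of range")
  k <- nrow(object@foldR)
  if (length(object@foldAssignments) &&
      !setequal(unique(object@foldAssignments), seq_len(k)))
    msg <- c(msg, "fold assignments must partition subjects into the k folds")
  if (length(msg)) msg else TRUE
})

#' RepeatRateReport: selection stability over subject resamples
#'
#' For `nRepeats` random subsets of the subjects (a `fraction` of them,
#' drawn without replacement) a FOS model of fixed order is refit and the
#' metric underlying each selected non-constant term is recorded per rank.
#' Counts are transform-collapsed: a metric is "picked" whichever of its
#' transforms carried it.
#'
#' @slot counts named integer vector, total selections per metric (all ranks).
#' @slot byRank list, one data.frame (`metric`, `count`, `percent`) per
#'   non-constant rank, counts summing to `nRepeats` within each rank.
#' @slot nRepeats,order integers; @slot fraction subsample fraction.
#' @slot seed integer seed. @slot detail per-(metric, transform) diagnostics.
#' @seealso [repeatRates()]
#' @export
setClass("RepeatRateReport",
  representation(counts = "integer", byRank = "list", nRepeats = "integer",
                 fraction = "numeric", order = "integer", seed = "integer",
                 detail = "list"))

setValidity("RepeatRateReport", function(object) {
  msg <- character()
  if (any(object@counts < 0L) || any(object@counts > object@nRepeats * max(1L, object@order - 1L)))
    msg <- c(msg, "metric counts must lie in [0, nRepeats * (order - 1)]")
  if (!isTRUE(object@detail$reselectOrder)) {
    bad <- vapply(object@byRank, function(df) sum(df$count) != object@nRepeats,
                  logical(1L))
    if (any(bad))
      msg <- c(msg, "per-rank counts must sum to nRepeats")
  }
  if (length(msg)) msg else TRUE
})
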