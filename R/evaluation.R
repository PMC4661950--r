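#' Validation R value between actual and predicted scores
#'
#' Pearson correlation between actual and predicted values, reported on the
#' `[0, 1]` convention: negative correlations are clamped to 0, and a
#' constant vector (zero variance on either side) scores 0. `R^2` can then
#' be read as the explained fraction of variance. Set `clamp = FALSE` for
#' the raw signed correlation (NA if either vector is constant), kept for
#' diagnostics.
#'
#' @param actual,predicted numeric vectors of equal length `>= 2`.
#' @param clamp clamp at 0 and apply the constant-vector convention
#'   (default `TRUE`).
#' @return a single numeric value.
#' @examples
#' computeR(1:10, 1:10)        # 1
#' computeR(1:10, -(1:10))     # 0 (clamped)
#' computeR(1:10, rep(3, 10))  # 0 (constant convention)
#' @export
computeR <- function(actual, predicted, clamp = TRUE) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (length(actual) < 2L) stop("need at least 2 observations")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    return(if (clamp) 0 else NA_real_)
  r <- stats::cor(actual, predicted)
  if (clamp) max(r, 0) else r
}

#' Clip predictions to the valid range of a target scale
#'
#' Predicted scores below the scale minimum are set to the minimum and
#' scores above the maximum to the maximum (e.g. FIM-Total outside
#' `[18, 126]`). Clipping never worsens the absolute error against an
#' in-range actual value.
#'
#' @param pred numeric predictions.
#' @param spec a [TargetSpec-class] carrying `validMin` / `validMax`.
#' @return clipped predictions.
#' @examples
#' spec <- fimTargetSpec("FIM-Total-2w")
#' clipToRange(c(130, 100, 5), spec)  # 126 100 18
#' @export
clipToRange <- function(pred, spec) {
  stopifnot(methods::is(spec, "TargetSpec"))
  pmin(pmax(pred, spec@validMin), spec@validMax)
}

#' Cross-validated model-order selection for FOS models
#'
#' Randomly partitions subjects into `folds` folds (seeded, unstratified).
#' For each fold, a FOS model is grown on the training subjects up to
#' `maxOrder` terms; for every order `1..maxOrder` the order-m prefix is
#' refit by OLS, held-out subjects are predicted, predictions are clipped
#' into the target's valid range, and the validation R is computed. The
#' chosen order maximizes the across-fold mean validation R, resolving ties
#' toward the smallest order; `overallR` is the mean validation R at that
#' order. Greedy selection is nested, so the order-m model is the m-term
#' prefix of the full path.
#'
#' With `normScope = "global"` the min-max normalization is fit once on all
#' subjects (one normalization pass over the table); with `"train_fold"` it
#' is refit inside each training fold so no statistic of the held-out
#' subjects can influence training.
#'
#' @param x a [BiomarkerExperiment-class] or subjects x metrics raw matrix.
#' @param columns metric names forming the candidate dataset (default: all).
#' @param target a [TargetSpec-class] with one value per subject.
#' @param maxOrder largest model order tried (default 15).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param normScope `"global"` or `"train_fold"`.
#' @param epsilon log-transform offset.
#' @param includeIdentity include untransformed metrics as candidates.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(x, columns = NULL, target, maxOrder = 15L,
                          folds = 10L, seed = 1L,
                          normScope = c("global", "train_fold"),
                          epsilon = 1e-6, includeIdentity = TRUE) {
  normScope <- match.arg(normScope)
  m <- if (methods::is(x, "BiomarkerExperiment")) metricMatrix(x) else as.matrix(x)
  columns <- columns %||% colnames(m)
  m <- m[, columns, drop = FALSE]
  stopifnot(methods::is(target, "TargetSpec"))
  y <- target@values
  n <- nrow(m)
  if (length(y) != n) stop("target values must match the number of subjects")
  if (n < folds) stop("fewer subjects than folds")
  maxOrder <- as.integer(maxOrder)
  nCand <- ncol(m) * (5L + includeIdentity)
  if (maxOrder > nCand + 1L)
    stop("maxOrder exceeds the candidate pool size + 1")
  foldId <- withSeed(seed, sample(rep(seq_len(folds), length.out = n)))
  names(foldId) <- rownames(m) %||% paste0("subject", seq_len(n))
  globalParams <- if (normScope == "global") fitNormalization(m) else NULL
  foldR <- rawR <- matrix(NA_real_, folds, maxOrder)
  pooled <- matrix(NA_real_, n, maxOrder)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    te <- !tr
    params <- if (normScope == "global") globalParams else
      fitNormalization(m[tr, , drop = FALSE], scope = "train_fold")
    ztr <- normalizeValues(m[tr, , drop = FALSE], params)
    zte <- normalizeValues(m[te, , drop = FALSE], params)
    cs <- expandCandidates(ztr, epsilon = epsilon,
                           includeIdentity = includeIdentity)
    sel <- .fosSelect(cs@design, y[tr], maxOrder)
    teDesign <- cbind(rep(1, sum(te)),
      vapply(sel$selected, function(j)
        realizeTransform(cs@candidates$kind[j], zte[, cs@candidates$metric[j]],
                         epsilon),
        numeric(sum(te))))
    trDesign <- cbind(rep(1, sum(tr)), cs@design[, sel$selected, drop = FALSE])
    for (ord in seq_len(maxOrder)) {
      coefs <- stats::lm.fit(trDesign[, seq_len(ord), drop = FALSE], y[tr])$coefficients
      coefs[is.na(coefs)] <- 0
      pred <- clipToRange(drop(teDesign[, seq_len(ord), drop = FALSE] %*% coefs),
                          target)
      pooled[te, ord] <- pred
      foldR[f, ord] <- computeR(y[te], pred)
      rawR[f, ord] <- computeR(y[te], pred, clamp = FALSE)
    }
  }
  meanR <- colMeans(foldR)
  chosen <- min(which(meanR >= max(meanR) - 1e-9))
  methods::new("CVResult",
    foldR = foldR, meanR = meanR, chosenOrder = as.integer(chosen),
    overallR = meanR[chosen],
    pooledR = computeR(y, pooled[, chosen]),
    foldAssignments = as.integer(foldId), seed = as.integer(seed),
    normScope = normScope,
    diagnostics = list(rawR = rawR, pooledPredictions = pooled,
                       targetName = target@name))
}

#' @describeIn crossValidate mean validation R per model order.
#' @param object a [CVResult-class].
#' @export
meanValidationR <- function(object) object@meanR

#' @describeIn crossValidate chosen model order (constant term included).
#' @export
chosenOrder <- function(object) object@chosenOrder

#' @describeIn crossValidate mean validation R at the chosen order.
#' @export
overallR <- function(object) object@overallR

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult '%s': %d folds x %d orders (scope %s, seed %d)\n",
              object@diagnostics$targetName %||% "target",
              nrow(object@foldR), ncol(object@foldR), object@normScope,
              object@seed))
  cat(sprintf("chosen order %d, overall R %.3f (pooled R %.3f)\n",
              object@chosenOrder, object@overallR, object@pooledR))
})

#' Compare two validation R values
#'
#' Tests whether two correlation-based performance values differ. For two
#' models predicting the same target on the same subjects
#' (`dependency = "dependent"`), a Steiger-type z-test on Fisher-transformed
#' correlations is used, which accounts for the correlation `r12` between
#' the two prediction vectors. For unrelated samples
#' (`dependency = "independent"`), the two-sample Fisher z-test is used.
#'
#' @param r1,r2 the two R values, each in `[0, 1)`.
#' @param n number of subjects (first sample).
#' @param dependency `"dependent"` (overlapping, same subjects; needs `r12`)
#'   or `"independent"`.
#' @param r12 correlation between the two prediction vectors
#'   (dependent case only).
#' @param n2 second sample size (independent case; defaults to `n`).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `pValue`, `z`, and `method`.
#' @examples
#' compareR(0.9, 0.1, n = 100, dependency = "independent")$pValue  # < 0.001
#' @export
compareR <- function(r1, r2, n, dependency = c("dependent", "independent"),
                     r12 = NULL, n2 = n,
                     alternative = c("two.sided", "less", "greater")) {
  dependency <- match.arg(dependency)
  alternative <- match.arg(alternative)
  if (any(c(r1, r2) < 0) || any(c(r1, r2) >= 1))
    stop("r1 and r2 must lie in [0, 1)")
  if (n < 10L) stop("need n >= 10")
  dz <- atanh(r1) - atanh(r2)
  if (dependency == "independent") {
    if (n2 < 10L) stop("need n2 >= 10")
    z <- dz / sqrt(1 / (n - 3) + 1 / (n2 - 3))
    method <- "independent Fisher z"
  } else {
    if (is.null(r12))
      stop("dependent comparison needs r12, the inter-prediction correlation")
    rbar <- (r1 + r2) / 2
    psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
    sbar <- psi / (1 - rbar^2)^2
    z <- dz * sqrt((n - 3) / (2 - 2 * sbar))
    method <- "Steiger z for dependent overlapping correlations"
  }
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    less = stats::pnorm(z),
    greater = stats::pnorm(-z))
  list(pValue = p, z = z, method = method)
}

#' Plot the validation-R versus model-order curve
#'
#' The over-fitting curve: mean validation R rises while added terms carry
#' signal and falls once extra terms fit training noise. Requires ggplot2.
#'
#' @param object a [CVResult-class].
#' @return a ggplot object.
#' @export
plotOrderCurve <- function(object) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(order = seq_along(object@meanR), meanR = object@meanR)
  ggplot2::ggplot(df, ggplot2::aes(x = order, y = meanR)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object@chosenOrder, linetype = 2) +
    ggplot2::labs(x = "model order (terms incl. constant)",
                  y = "mean validation R",
                  title = object@diagnostics$targetName %||% NULL) +
    ggplot2::theme_minimal()
}
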