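#' Fast Orthogonal Search model fitting
#'
#' Greedy forward selection of `order` model terms from a candidate pool.
#' The first term is always the constant. At each subsequent step the
#' candidate whose Gram-Schmidt-orthogonalized component (against all
#' previously selected terms) yields the largest reduction in residual mean
#' squared error is added; the search is implemented as modified
#' Gram-Schmidt recursions over the candidate columns, so each step costs
#' one pass over the remaining pool. Candidates whose orthogonalized
#' squared norm falls below `tol` times their raw squared norm are skipped
#' as collinear with the current model; exact ties in MSE reduction (within
#' `tieTol` relative) resolve to the lowest candidate index. A selected
#' candidate leaves the pool. Final coefficients are the
#' ordinary-least-squares solution on the selected columns, so the training
#' MSE at each model order is minimal given the selection.
#'
#' @param x a [CandidateSet-class] (from [expandCandidates()]) or a plain
#'   subjects x candidates numeric matrix with column names.
#' @param target numeric outcome vector `S`, one value per subject.
#' @param order total number of model terms `M` (constant included),
#'   `1 <= order <= ncandidates + 1`.
#' @param targetName stored in the returned model.
#' @param tol relative collinearity tolerance (default `1e-10`).
#' @param tieTol relative tie tolerance on MSE reduction (default `1e-12`).
#' @return a [FOSModel-class].
#' @examples
#' z <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("m", 1:4)))
#' cs <- expandCandidates(z)
#' y <- 2 + 3 * z[, "m2"]^3 + rnorm(50, sd = 0.01)
#' fosFit(cs, y, order = 2)
#' @seealso [greedyForwardOLS()] for the brute-force reference
#'   implementation, [predictTargets()] for prediction.
#' @export
setGeneric("fosFit", function(x, target, order, ...) standardGeneric("fosFit"))

#' @rdname fosFit
#' @param ... passed on to the matrix method.
#' @export
setMethod("fosFit", "CandidateSet", function(x, target, order,
                                             targetName = "target",
                                             tol = 1e-10, tieTol = 1e-12) {
  sel <- .fosSelect(x@design, target, order, tol, tieTol)
  .buildModel(x@candidates, x@design, sel, target, targetName, x@epsilon)
})

#' @rdname fosFit
#' @export
setMethod("fosFit", "matrix", function(x, target, order,
                                       targetName = "target",
                                       tol = 1e-10, tieTol = 1e-12) {
  info <- .columnCandidates(x)
  sel <- .fosSelect(x, target, order, tol, tieTol)
  .buildModel(info, x, sel, target, targetName, 1e-6)
})

#' Brute-force greedy forward OLS (reference oracle for FOS)
#'
#' Mathematically equivalent to [fosFit()]: at each step every remaining
#' candidate is appended to the selected columns, a full OLS model is refit,
#' and the candidate minimizing residual MSE is kept. The explained variance
#' of a candidate's orthogonalized component equals the drop in residual sum
#' of squares of the refit, so selection sequences and MSE paths agree with
#' the orthogonal-search recursions up to floating-point noise. Same
#' collinearity-skip and tie-break rules as [fosFit()]. Intended as an
#' independent correctness check; it is O(pool size) full refits per step
#' and therefore much slower.
#'
#' @inheritParams fosFit
#' @return a [FOSModel-class].
#' @export
greedyForwardOLS <- function(x, target, order, targetName = "target",
                             tol = 1e-10, tieTol = 1e-12) {
  if (methods::is(x, "CandidateSet")) {
    info <- x@candidates; design <- x@design; eps <- x@epsilon
  } else {
    design <- as.matrix(x); info <- .columnCandidates(design); eps <- 1e-6
  }
  y <- as.numeric(target)
  n <- length(y)
  .checkFitContract(design, y, order)
  rawNorm2 <- colSums(design^2)
  active <- rep(TRUE, ncol(design))
  selected <- integer(0)
  Xsel <- matrix(1, n, 1L)
  msePrev <- mean((y - mean(y))^2)
  msePath <- msePrev
  for (m in seq_len(order - 1L)) {
    qrS <- qr(Xsel)
    red <- rep(NA_real_, ncol(design))
    for (j in which(active)) {
      if (rawNorm2[j] <= 0) next
      rj <- qr.resid(qrS, design[, j])
      if (sum(rj^2) < tol * rawNorm2[j]) next
      fit <- stats::lm.fit(cbind(Xsel, design[, j]), y)
      red[j] <- msePrev - mean(fit$residuals^2)
    }
    if (all(is.na(red)))
      stop(sprintf(
        "rank error: order %d exceeds the linearly independent candidates; achievable order is %d",
        order, m))
    best <- max(red, na.rm = TRUE)
    j <- min(which(!is.na(red) & red >= best - tieTol * max(abs(best), msePath[1L])))
    selected <- c(selected, j)
    active[j] <- FALSE
    Xsel <- cbind(Xsel, design[, j])
    msePrev <- msePrev - red[j]
    msePath <- c(msePath, msePrev)
  }
  .buildModel(info, design, list(selected = selected, msePath = msePath),
              y, targetName, eps)
}

# ---- internals ---------------------------------------------------------

#' @noRd
.checkFitContract <- function(design, y, order) {
  if (nrow(design) != length(y))
    stop("design rows must match target length")
  if (order < 1L) stop("order must be >= 1")
  if (length(y) < order + 1L)
    stop("need at least order + 1 subjects")
  if (order > ncol(design) + 1L)
    stop(sprintf(
      "rank error: order %d exceeds the linearly independent candidates; achievable order is %d",
      order, ncol(design) + 1L))
  invisible(TRUE)
}

#' Greedy orthogonal selection via modified Gram-Schmidt recursions.
#' Returns selected candidate indices (constant excluded) and the training
#' MSE path (constant included).
#' @noRd
.fosSelect <- function(design, target, order, tol = 1e-10, tieTol = 1e-12) {
  y <- as.numeric(target)
  n <- length(y)
  .checkFitContract(design, y, order)
  rawNorm2 <- colSums(design^2)
  # term 1: the constant; orthogonalize everything against it (centering)
  yres <- y - mean(y)
  msePath <- mean(yres^2)
  V <- sweep(design, 2L, colMeans(design))
  active <- rep(TRUE, ncol(design))
  selected <- integer(0)
  for (m in seq_len(order - 1L)) {
    v2 <- colSums(V^2)
    elig <- active & rawNorm2 > 0 & v2 > tol * rawNorm2
    if (!any(elig))
      stop(sprintf(
        "rank error: order %d exceeds the linearly independent candidates; achievable order is %d",
        order, m))
    num <- as.numeric(crossprod(V, yres))
    red <- rep(NA_real_, ncol(design))
    red[elig] <- num[elig]^2 / v2[elig] / n   # MSE reduction of each candidate
    best <- max(red, na.rm = TRUE)
    j <- min(which(elig & red >= best - tieTol * max(abs(best), msePath[1L])))
    selected <- c(selected, j)
    active[j] <- FALSE
    w <- V[, j]
    w2 <- v2[j]
    yres <- yres - (sum(w * yres) / w2) * w
    msePath <- c(msePath, mean(yres^2))
    if (any(active)) {
      idx <- which(active)
      proj <- as.numeric(crossprod(V[, idx, drop = FALSE], w)) / w2
      V[, idx] <- V[, idx, drop = FALSE] - outer(w, proj)
    }
  }
  list(selected = selected, msePath = msePath)
}

#' @noRd
.columnCandidates <- function(design) {
  if (is.null(colnames(design)))
    colnames(design) <- paste0("c", seq_len(ncol(design)))
  data.frame(kind = "column", metric = colnames(design),
             label = colnames(design), stringsAsFactors = FALSE)
}

#' @noRd
.buildModel <- function(info, design, sel, y, targetName, epsilon) {
  constantRow <- data.frame(kind = "constant", metric = NA_character_,
                            label = "constant", stringsAsFactors = FALSE)
  terms <- rbind(constantRow, info[sel$selected, c("kind", "metric", "label")])
  rownames(terms) <- NULL
  X <- cbind(constant = rep(1, length(y)),
             design[, sel$selected, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  methods::new("FOSModel", terms = terms, coefficients = unname(coefs),
               trainMsePath = sel$msePath, targetName = targetName,
               epsilon = epsilon)
}

# ---- model accessors and prediction ------------------------------------

#' @describeIn fosFit data.frame of selected terms with coefficients and
#'   the training-MSE trajectory.
#' @param object a [FOSModel-class].
#' @export
modelTerms <- function(object) {
  cbind(object@terms, coefficient = object@coefficients,
        trainMSE = object@trainMsePath)
}

#' Predict outcomes from a fitted FOS model
#'
#' Computes `sum_m a_m p_m(n)` per subject. Raw metric values are min-max
#' normalized with `params` (values outside the training range are clipped
#' into `[0, 1]`), transformed per selected term, and combined with the
#' model coefficients. Predictions are unclipped; apply [clipToRange()] to
#' map them onto the valid scale of the target.
#'
#' @param object a [FOSModel-class].
#' @param newdata a [BiomarkerExperiment-class] or subjects x metrics matrix
#'   containing every metric the model uses. For models fit on a plain
#'   column matrix (oracle-style), the columns are used as-is.
#' @param params a [NormalizationParams-class]; required for transform-based
#'   models.
#' @return numeric vector of predictions, one per subject (row).
#' @export
predictTargets <- function(object, newdata, params = NULL) {
  stopifnot(methods::is(object, "FOSModel"))
  m <- if (methods::is(newdata, "BiomarkerExperiment"))
    metricMatrix(newdata) else as.matrix(newdata)
  terms <- object@terms
  nonconst <- terms$kind != "constant"
  pred <- rep(object@coefficients[1L], nrow(m))
  if (!any(nonconst)) return(pred)
  needed <- unique(terms$metric[nonconst])
  missing <- setdiff(needed, colnames(m))
  if (length(missing))
    stop("metric(s) required by the model are absent: ",
         paste(missing, collapse = ", "))
  transMetrics <- unique(terms$metric[nonconst & terms$kind != "column"])
  z <- NULL
  if (length(transMetrics)) {
    if (is.null(params))
      stop("normalization params are required to predict with transform terms")
    noPar <- setdiff(transMetrics, names(params@xmin))
    if (length(noPar))
      stop("no normalization parameters for metric(s): ",
           paste(noPar, collapse = ", "))
    z <- normalizeValues(m[, transMetrics, drop = FALSE], params)
  }
  for (i in which(nonconst)) {
    col <- if (terms$kind[i] == "column") m[, terms$metric[i]]
           else realizeTransform(terms$kind[i], z[, terms$metric[i]],
                                 object@epsilon)
    pred <- pred + object@coefficients[i] * col
  }
  pred
}

#' @rdname predictTargets
#' @param ... passed to [predictTargets()].
#' @export
setMethod("predict", "FOSModel", function(object, ...) predictTargets(object, ...))

setMethod("show", "FOSModel", function(object) {
  cat(sprintf("FOSModel for '%s': %d term(s), training MSE %.4g\n",
              object@targetName, nrow(object@terms),
              utils::tail(object@trainMsePath, 1L)))
  print(modelTerms(object), digits = 4)
})

#' Serialize a FOS model as JSON
#'
#' Writes `{target, terms: [{kind, metric, coefficient}], train_mse_path}`.
#'
#' @param model a [FOSModel-class].
#' @param path output file.
#' @export
writeFOSModel <- function(model, path) {
  jsonlite::write_json(
    list(target = model@targetName,
         terms = lapply(seq_len(nrow(model@terms)), function(i)
           list(kind = model@terms$kind[i],
                metric = if (is.na(model@terms$metric[i])) NULL
                         else model@terms$metric[i],
                coefficient = model@coefficients[i])),
         train_mse_path = model@trainMsePath),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
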