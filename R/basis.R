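#' Transform kinds applied to each normalized metric, in pool order
#' @keywords internal
#' @noRd
.transformKinds <- c("identity", "square", "cube", "sin", "cos", "log")

#' Realize a basis-function transform on normalized values
#'
#' Transforms are defined on the normalized domain `[0, 1]`:
#' identity `z`, square `z^2`, cube `z^3`, `sin(z)` and `cos(z)` in radians
#' with no frequency scaling, and natural log `ln(z + epsilon)` with a small
#' offset making it total at `z = 0`. `constant` realizes to 1.
#'
#' @param kind one of `"constant", "identity", "square", "cube", "sin",
#'   "cos", "log"`.
#' @param z numeric values in `[0, 1]`.
#' @param epsilon log offset (default `1e-6`).
#' @return numeric vector of realized values (all finite).
#' @examples
#' realizeTransform("square", 0.5)  # 0.25
#' realizeTransform("log", 1)       # ~1e-6
#' @export
realizeTransform <- function(kind, z, epsilon = 1e-6) {
  switch(kind,
    constant = rep(1, length(z)),
    identity = z,
    square   = z^2,
    cube     = z^3,
    sin      = sin(z),
    cos      = cos(z),
    log      = log(z + epsilon),
    stop("unknown transform kind: ", kind))
}

#' Expand normalized metrics into the FOS candidate pool
#'
#' For each of the P metrics, emits exactly six candidates (identity,
#' square, cube, sin, cos, log) in a fixed deterministic order: metrics in
#' column order, transforms in the order above. The constant term is not a
#' pool member; [fosFit()] injects it as the mandatory first model term.
#'
#' @param z subjects x metrics matrix of normalized values in `[0, 1]`
#'   (see [normalizeValues()]).
#' @param epsilon log-transform offset.
#' @param includeIdentity include the untransformed metric as a candidate
#'   (default `TRUE`).
#' @return a [CandidateSet-class] with `6 * P` candidates (`5 * P` if
#'   `includeIdentity = FALSE`).
#' @examples
#' z <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("M1", "M2", "M3")))
#' cs <- expandCandidates(z)
#' nrow(candidateInfo(cs))  # 18
#' @export
expandCandidates <- function(z, epsilon = 1e-6, includeIdentity = TRUE) {
  z <- as.matrix(z)
  if (is.null(colnames(z))) stop("normalized matrix must have metric names")
  if (any(z < -1e-9) || any(z > 1 + 1e-9))
    stop("candidate expansion requires values normalized to [0, 1]")
  z <- pmin(pmax(z, 0), 1)
  kinds <- if (includeIdentity) .transformKinds else
    setdiff(.transformKinds, "identity")
  info <- do.call(rbind, lapply(colnames(z), function(m)
    data.frame(kind = kinds, metric = m,
               label = sprintf("%s(%s)", kinds, m),
               stringsAsFactors = FALSE)))
  design <- matrix(NA_real_, nrow(z), nrow(info),
                   dimnames = list(rownames(z), info$label))
  for (i in seq_len(nrow(info)))
    design[, i] <- realizeTransform(info$kind[i], z[, info$metric[i]], epsilon)
  methods::new("CandidateSet", candidates = info, design = design,
               epsilon = epsilon)
}

#' @describeIn expandCandidates candidate metadata (`kind`, `metric`,
#'   `label`), one row per pool member in pool order.
#' @param x a [CandidateSet-class].
#' @export
candidateInfo <- function(x) x@candidates

#' @describeIn expandCandidates realized subjects x candidates design matrix.
#' @export
candidateDesign <- function(x) x@design

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet:", nrow(object@candidates), "candidates from",
      length(unique(object@candidates$metric)), "metrics x",
      length(unique(object@candidates$kind)), "transforms;",
      nrow(object@design), "subjects\n")
})

#' Dump the candidate pool as JSON
#'
#' @param x a [CandidateSet-class].
#' @param path output file.
#' @export
writeCandidatePool <- function(x, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(x@candidates)), function(i)
      list(label = x@candidates$label[i], kind = x@candidates$kind[i],
           metric = x@candidates$metric[i])),
    path, auto_unbox = TRUE)
  invisible(path)
}
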