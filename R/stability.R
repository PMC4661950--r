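#' Repeat-rate stability analysis of FOS metric selection
#'
#' Repeatedly refits a FOS model of fixed order on random subsets of the
#' subjects (a `fraction` of them, drawn without replacement) and reports
#' how often each metric is picked, per selection rank. Counts are
#' transform-collapsed: a metric counts as picked whichever of its six
#' transforms carried it; per-(metric, transform) detail is kept in the
#' `detail` slot. By default the model order is fixed (typically the order
#' chosen by [crossValidate()] on the full data); with
#' `reselectOrder = TRUE` the order is re-chosen by CV inside every repeat.
#'
#' @param x a [BiomarkerExperiment-class] or subjects x metrics raw matrix.
#' @param columns metric names forming the candidate dataset (default: all).
#' @param target a [TargetSpec-class] with one value per subject.
#' @param order model order for each refit (constant included).
#' @param nRepeats number of resamples (default 100).
#' @param fraction subject fraction per resample (default 0.9);
#'   `floor(fraction * n)` must exceed `order + 1`.
#' @param seed integer seed.
#' @param normScope normalization scope for each refit; `"global"` refits
#'   min-max parameters on the drawn subset.
#' @param reselectOrder re-run CV order selection within each repeat.
#' @param epsilon,includeIdentity candidate-pool settings, as in
#'   [expandCandidates()].
#' @param cvFolds,cvMaxOrder CV settings used when `reselectOrder = TRUE`.
#' @return a [RepeatRateReport-class].
#' @export
repeatRates <- function(x, columns = NULL, target, order, nRepeats = 100L,
                        fraction = 0.9, seed = 1L,
                        normScope = c("global", "train_fold"),
                        reselectOrder = FALSE, epsilon = 1e-6,
                        includeIdentity = TRUE, cvFolds = 10L,
                        cvMaxOrder = 15L) {
  normScope <- match.arg(normScope)
  m <- if (methods::is(x, "BiomarkerExperiment")) metricMatrix(x) else as.matrix(x)
  columns <- columns %||% colnames(m)
  m <- m[, columns, drop = FALSE]
  stopifnot(methods::is(target, "TargetSpec"))
  y <- target@values
  n <- nrow(m)
  if (length(y) != n) stop("target values must match the number of subjects")
  sub <- floor(fraction * n)
  if (sub <= order + 1L)
    stop("infeasible subset size: floor(fraction * n) must exceed order + 1")
  nRepeats <- as.integer(nRepeats)
  order <- as.integer(order)
  metricNames <- columns
  repSeeds <- childSeeds(seed, nRepeats)
  picks <- vector("list", nRepeats)          # per repeat: metric per rank
  pickKinds <- vector("list", nRepeats)
  orders <- integer(nRepeats)
  for (r in seq_len(nRepeats)) {
    idx <- withSeed(repSeeds[r], sample(n, sub))
    ord <- order
    if (reselectOrder) {
      sp <- targetSpec(target@name, y[idx], target@validMin, target@validMax)
      cv <- crossValidate(m[idx, , drop = FALSE], target = sp,
                          maxOrder = cvMaxOrder, folds = cvFolds,
                          seed = repSeeds[r], normScope = normScope,
                          epsilon = epsilon, includeIdentity = includeIdentity)
      ord <- chosenOrder(cv)
    }
    params <- fitNormalization(m[idx, , drop = FALSE])
    cs <- expandCandidates(normalizeValues(m[idx, , drop = FALSE], params),
                           epsilon = epsilon,
                           includeIdentity = includeIdentity)
    sel <- .fosSelect(cs@design, y[idx], ord)
    picks[[r]] <- cs@candidates$metric[sel$selected]
    pickKinds[[r]] <- cs@candidates$kind[sel$selected]
    orders[r] <- ord
  }
  nRanks <- if (reselectOrder) max(orders) - 1L else order - 1L
  byRank <- lapply(seq_len(nRanks), function(rank) {
    sel <- vapply(picks, function(p)
      if (length(p) >= rank) p[rank] else NA_character_, character(1L))
    tab <- table(factor(sel[!is.na(sel)], levels = metricNames))
    df <- data.frame(metric = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, match(df$metric, metricNames)), ]
    df$percent <- 100 * df$count / nRepeats
    rownames(df) <- NULL
    df
  })
  allPicks <- unlist(picks)
  counts <- table(factor(allPicks, levels = metricNames))
  detail <- table(metric = factor(unlist(picks), levels = metricNames),
                  transform = factor(unlist(pickKinds),
                                     levels = .transformKinds))
  methods::new("RepeatRateReport",
    counts = stats::setNames(as.integer(counts), names(counts)),
    byRank = byRank, nRepeats = nRepeats, fraction = fraction,
    order = order, seed = as.integer(seed),
    detail = list(byTransform = detail, ordersUsed = orders,
                  reselectOrder = reselectOrder))
}

#' @describeIn repeatRates transform-collapsed total selections per metric.
#' @param object a [RepeatRateReport-class].
#' @export
repeatCounts <- function(object) object@counts

#' @describeIn repeatRates list of per-rank data.frames
#'   (`metric`, `count`, `percent`), counts summing to `nRepeats`.
#' @export
repeatRatesByRank <- function(object) object@byRank

setMethod("show", "RepeatRateReport", function(object) {
  cat(sprintf(
    "RepeatRateReport: order %d, %d repeats on %.0f%% subsets (seed %d)\n",
    object@order, object@nRepeats, 100 * object@fraction, object@seed))
  for (rank in seq_along(object@byRank)) {
    top <- utils::head(object@byRank[[rank]][object@byRank[[rank]]$count > 0, ], 3L)
    cat(sprintf("  rank %d: %s\n", rank,
                paste(sprintf("%s %d%%", top$metric, round(top$percent)),
                      collapse = ", ")))
  }
})

#' Write a repeat-rate report as a Table 5/6-style CSV
#'
#' One row per (rank, metric) with columns `rank`, `metric`, `count`,
#' `percent`, metrics ordered by count within rank. `minPercent` is a
#' display threshold only; all picks are retained in the report object.
#'
#' @param object a [RepeatRateReport-class].
#' @param path output CSV path.
#' @param minPercent drop rows below this percentage (default 0 = keep all).
#' @export
writeRepeatRates <- function(object, path, minPercent = 0) {
  rows <- do.call(rbind, lapply(seq_along(object@byRank), function(rank) {
    df <- object@byRank[[rank]]
    df <- df[df$percent >= minPercent & df$count > 0, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    cbind(rank = rank, df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
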