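# Fixtures are built in code at test time; nothing is stored on disk.

# Write a tiny CSV + YAML group config; returns the two paths.
writeToyTable <- function(dir = NULL, missingCell = FALSE, badCell = FALSE,
                          unmappedColumn = FALSE) {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  df <- data.frame(subject = c("s1", "s2", "s3"),
                   M1 = c(1.5, 2.0, 3.5), OH1 = c(10, 20, 30),
                   check.names = FALSE)
  if (missingCell) df$M1[2] <- NA
  if (badCell) df$OH1 <- c("10", "oops", "30")
  csv <- file.path(dir, "table.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  groups <- list(M1 = "M", OH1 = "OH")
  if (unmappedColumn) groups$OH1 <- NULL
  yml <- file.path(dir, "groups.yaml")
  yaml::write_yaml(list(groups = groups,
                        datasets = list(All = c("M", "OH"))), yml)
  list(csv = csv, groups = yml)
}

# Random normalized metric matrix with named columns.
randomZ <- function(n, p, prefix = "m") {
  z <- matrix(stats::runif(n * p), n, p)
  colnames(z) <- paste0(prefix, seq_len(p))
  z
}

# Random selection-problem instance for FOS/oracle comparisons.
randomInstance <- function(n, nCand, duplicate = FALSE) {
  X <- matrix(stats::rnorm(n * nCand), n, nCand)
  if (duplicate && nCand >= 2L) {
    ij <- sample(nCand, 2L)
    X[, ij[2L]] <- X[, ij[1L]]
  }
  colnames(X) <- paste0("c", seq_len(nCand))
  X
}

# Small correlated cohort with a known sparse nonlinear target.
toyCohort <- function(n = 60, seed = 11, generativeR = 0.9,
                      groups = c(M = 5L, OH = 5L)) {
  generateCohort(syntheticCohortConfig(
    nSubjects = n, groups = groups, clinical = FALSE,
    trueModel = list(
      list(metric = "M3", kind = "cube", coefficient = -35),
      list(metric = "OH2", kind = "square", coefficient = -25)),
    generativeR = generativeR, seed = seed))
}
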