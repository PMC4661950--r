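test_that("the default cohort mirrors the intended study structure", {
  cohort <- generateCohort(syntheticCohortConfig(seed = 1))
  be <- cohort$experiment
  expect_equal(ncol(be), 85L)            # subjects
  expect_equal(nrow(be), 13 + 13 + 13 + 9 + 14 + 6)
  expect_equal(length(metricsForDataset(be, "Match")), 9L)
  expect_equal(length(metricsForDataset(be, "Object-Hit")), 14L)
  expect_equal(length(metricsForDataset(be, "All-Robotic")), 62L)
  expect_equal(length(metricsForDataset(be, "Clinical-All")), 6L)
  expect_true(all(cohort$target@values >= 18 & cohort$target@values <= 126))
  # ordinal clinical scores stay on their scales
  m <- metricMatrix(be)
  expect_true(all(m[, "CMS-A"] %in% 1:7))
  expect_true(all(m[, "MAS-A"] %in% c(0, 1, 1.5, 2, 3, 4)))
})

test_that("the same config and seed reproduce the cohort bit-identically", {
  cfg <- syntheticCohortConfig(nSubjects = 30, seed = 41)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(metricMatrix(a$experiment), metricMatrix(b$experiment))
  expect_identical(a$target@values, b$target@values)
  expect_identical(a$truth$noise, b$truth$noise)
  cc <- generateCohort(syntheticCohortConfig(nSubjects = 30, seed = 42))
  expect_false(identical(a$target@values, cc$target@values))
})

test_that("zero noise gives a perfectly correlated pre-clipping target", {
  cohort <- generateCohort(syntheticCohortConfig(nSubjects = 50, noiseSd = 0,
                                                 seed = 43))
  expect_equal(stats::cor(cohort$truth$signal, cohort$truth$preclip), 1)
  expect_gt(realizedGenerativeR(cohort), 0.99)
  # heavy noise drives the realized generative R toward zero
  noisy <- generateCohort(syntheticCohortConfig(nSubjects = 400,
                                                noiseSd = 1e4, seed = 44))
  expect_lt(realizedGenerativeR(noisy), 0.2)
})

test_that("realized generative R is the documented correlation", {
  cohort <- generateCohort(syntheticCohortConfig(nSubjects = 60, seed = 45))
  expect_identical(realizedGenerativeR(cohort),
                   computeR(cohort$truth$signal, cohort$target@values))
  expect_identical(realizedGenerativeR(cohort), cohort$truth$generativeR)
})

test_that("the ground truth reconstructs the targets from the table", {
  for (seed in c(46, 47)) {
    cohort <- generateCohort(syntheticCohortConfig(nSubjects = 70,
                                                   seed = seed))
    expect_equal(recomputeTargets(cohort), cohort$target@values,
                 tolerance = 1e-9)
  }
  # pure-noise config round-trips too
  null <- generateCohort(syntheticCohortConfig(nSubjects = 40,
                                               trueModel = list(),
                                               noiseSd = 1, seed = 48))
  expect_equal(recomputeTargets(null), null$target@values, tolerance = 1e-9)
})

test_that("empirical within-group correlations approach the configured value", {
  rho <- 0.4
  cohort <- generateCohort(syntheticCohortConfig(
    nSubjects = 2000, groups = c(RA = 8L, M = 6L), clinical = FALSE,
    trueModel = list(), noiseSd = 1,
    withinGroupCorrelation = rho, seed = 49))
  m <- metricMatrix(cohort$experiment)
  for (g in c("RA", "M")) {
    cols <- metricsForDataset(cohort$experiment, g)
    cm <- stats::cor(m[, cols])
    offdiag <- cm[upper.tri(cm)]
    expect_lt(abs(mean(offdiag) - rho), 0.05)
    expect_lt(max(abs(offdiag - rho)), 0.1)
  }
})

test_that("configuration errors are caught up front", {
  expect_error(syntheticCohortConfig(withinGroupCorrelation = 1), "in \\[0, 1\\)")
  expect_error(syntheticCohortConfig(noiseSd = -1), "noiseSd")
  expect_error(syntheticCohortConfig(trueModel = list(
    list(metric = "ZZ9", kind = "cube", coefficient = 1))), "not generated")
  expect_error(syntheticCohortConfig(trueModel = list(
    list(metric = "M1", kind = "tanh", coefficient = 1))), "transform kind")
})

test_that("a written cohort reloads identically through the CSV interface", {
  cohort <- generateCohort(syntheticCohortConfig(nSubjects = 25, seed = 50))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cohort.csv")
  yml <- file.path(dir, "groups.yaml")
  truth <- file.path(dir, "truth.json")
  writeCohort(cohort, csv, yml, truthPath = truth)
  be <- readBiomarkerTable(csv, yml, targetColumns = cohort$target@name)
  expect_equal(metricMatrix(be), metricMatrix(cohort$experiment),
               tolerance = 1e-12)
  expect_equal(S4Vectors::metadata(be)$datasets,
               S4Vectors::metadata(cohort$experiment)$datasets)
  expect_equal(colData(be)[[cohort$target@name]], cohort$target@values,
               tolerance = 1e-12)
  expect_true(file.exists(truth))
})
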