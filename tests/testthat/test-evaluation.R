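test_that("validation R follows the clamped-correlation convention", {
  expect_equal(computeR(1:10, 1:10), 1)
  expect_equal(computeR(1:10, -(1:10)), 0)           # clamped at 0
  expect_equal(computeR(1:10, rep(3, 10)), 0)        # constant convention
  expect_equal(computeR(1:10, -(1:10), clamp = FALSE), -1)  # raw diagnostic
  expect_true(is.na(computeR(1:10, rep(3, 10), clamp = FALSE)))
  expect_error(computeR(1:5, 1:4), "equal length")
  # invariant to a common affine rescaling of both vectors
  set.seed(1)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(computeR(2 * a + 5, 2 * b + 5), computeR(a, b))
})

test_that("predictions are clipped onto the valid scale", {
  total <- fimTargetSpec("FIM-Total-2w")
  motor <- fimTargetSpec("FIM-Motor-2w")
  expect_equal(clipToRange(130, total), 126)
  expect_equal(clipToRange(10, motor), 13)
  expect_equal(clipToRange(100, total), 100)
  expect_equal(clipToRange(c(-5, 60, 200), total), c(18, 60, 126))
  # clipping never worsens the error against an in-range actual value
  set.seed(2)
  actual <- runif(50, 18, 126)
  pred <- actual + rnorm(50, sd = 60)
  expect_true(all(abs(clipToRange(pred, total) - actual) <=
                  abs(pred - actual) + 1e-12))
})

test_that("a noise-free representable target saturates R and picks the parsimonious order", {
  set.seed(3)
  m <- matrix(rnorm(400, sd = 4), 100, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  z <- normalizeValues(m, fitNormalization(m))
  y <- 5 + 3 * z[, "x1"]^3 - 2 * log(z[, "x3"] + 1e-6)
  spec <- targetSpec("toy", y, validMin = -100, validMax = 100)
  cv <- crossValidate(m, target = spec, maxOrder = 5, folds = 5, seed = 9,
                      normScope = "global")
  expect_equal(meanValidationR(cv)[3:5], rep(1, 3), tolerance = 1e-6)
  expect_equal(chosenOrder(cv), 3L)
  expect_equal(overallR(cv), 1, tolerance = 1e-6)
})

test_that("cross-validation checks its contract and partitions subjects", {
  cohort <- toyCohort(25)
  expect_error(crossValidate(cohort$experiment, target = cohort$target,
                             folds = 30), "fewer subjects than folds")
  cv <- crossValidate(cohort$experiment, target = cohort$target,
                      maxOrder = 4, folds = 5, seed = 2)
  folds <- cv@foldAssignments
  expect_equal(length(folds), 25L)
  expect_setequal(unique(folds), 1:5)
  expect_true(all(table(folds) %in% 5L))   # each fold used once, equal sizes
})

test_that("train_fold scope shields training from held-out subjects", {
  cohort <- toyCohort(40, seed = 21)
  m <- metricMatrix(cohort$experiment)
  spec <- cohort$target
  ref <- crossValidate(m, target = spec, maxOrder = 4, folds = 5, seed = 31,
                       normScope = "train_fold")
  s <- 7L                                   # corrupt one subject's metrics
  f <- ref@foldAssignments[s]
  mOut <- m
  mOut[s, ] <- mOut[s, ] * 1000
  alt <- crossValidate(mOut, target = spec, maxOrder = 4, folds = 5,
                       seed = 31, normScope = "train_fold")
  peers <- which(ref@foldAssignments == f & seq_len(40) != s)
  # peers share subject s's test fold: their predictions depend only on the
  # training fit, which never saw s
  expect_equal(alt@diagnostics$pooledPredictions[peers, ],
               ref@diagnostics$pooledPredictions[peers, ])
  # under global scope the outlier leaks through the normalization
  refG <- crossValidate(m, target = spec, maxOrder = 4, folds = 5, seed = 31,
                        normScope = "global")
  altG <- crossValidate(mOut, target = spec, maxOrder = 4, folds = 5,
                        seed = 31, normScope = "global")
  expect_false(isTRUE(all.equal(altG@diagnostics$pooledPredictions[peers, ],
                                refG@diagnostics$pooledPredictions[peers, ])))
})

test_that("extending the order sweep never lowers the best mean validation R", {
  cohort <- toyCohort(50, seed = 5)
  cv4 <- crossValidate(cohort$experiment, target = cohort$target,
                       maxOrder = 4, folds = 5, seed = 8)
  cv8 <- crossValidate(cohort$experiment, target = cohort$target,
                       maxOrder = 8, folds = 5, seed = 8)
  expect_equal(meanValidationR(cv8)[1:4], meanValidationR(cv4))
  expect_gte(max(meanValidationR(cv8)), max(meanValidationR(cv4)) - 1e-12)
})

test_that("equal R values compare as indistinguishable", {
  out <- compareR(0.5, 0.5, n = 80, dependency = "dependent", r12 = 0.6)
  expect_equal(out$pValue, 1)
  expect_equal(out$z, 0)
})

test_that("clearly different independent R values are detected", {
  out <- compareR(0.9, 0.1, n = 100, dependency = "independent")
  expect_lt(out$pValue, 0.001)
  expect_error(compareR(1, 0.5, n = 50, dependency = "independent"),
               "\\[0, 1\\)")
  expect_error(compareR(0.5, 0.4, n = 5, dependency = "independent"),
               "n >= 10")
  expect_error(compareR(0.5, 0.4, n = 50, dependency = "dependent"), "r12")
})

test_that("the dependent test approaches the independent form as r12 -> 0", {
  dep <- compareR(0.1, 0.3, n = 100, dependency = "dependent", r12 = 0)
  ind <- compareR(0.1, 0.3, n = 100, dependency = "independent")
  expect_equal(dep$z, ind$z, tolerance = 0.02)
  # and gains power as the predictions correlate
  depHi <- compareR(0.1, 0.3, n = 100, dependency = "dependent", r12 = 0.8)
  expect_gt(abs(depHi$z), abs(dep$z))
})

test_that("the independent z-test is calibrated under the null", {
  set.seed(12)
  n <- 60
  p <- replicate(400, {
    x1 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
    x2 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
    r1 <- max(cor(x1)[1, 2], 0)
    r2 <- max(cor(x2)[1, 2], 0)
    compareR(r1, r2, n = n, dependency = "independent")$pValue
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})
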