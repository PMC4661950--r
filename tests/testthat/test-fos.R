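test_that("a constant target is absorbed by the mandatory first term", {
  set.seed(1)
  cs <- expandCandidates(randomZ(20, 3))
  y <- rep(7.5, 20)
  m <- fosFit(cs, y, order = 1)
  expect_equal(m@terms$kind, "constant")
  expect_equal(m@coefficients, 7.5)
  expect_lt(m@trainMsePath[1], 1e-20)
})

test_that("an exactly representable target is recovered with zero residual", {
  set.seed(2)
  z <- randomZ(30, 5)
  cs <- expandCandidates(z)
  y <- 3 * z[, "m4"]^3
  m <- fosFit(cs, y, order = 2)
  expect_equal(m@terms$label[2], "cube(m4)")
  expect_lt(tail(m@trainMsePath, 1), 1e-12 * stats::var(y))
  # noise-free k-term model: all k generating candidates recovered at k+1.
  # generators use well-separated transforms (cube, log) on distinct metrics;
  # sin/cos are near-collinear with identity/square on [0, 1], so label
  # recovery for those is not identifiable by any selection rule.
  zz <- randomZ(200, 6)
  css <- expandCandidates(zz)
  y3 <- 2 + 1.5 * zz[, "m1"]^3 - 3 * log(zz[, "m3"] + 1e-6) + 0.8 * zz[, "m5"]^3
  m3 <- fosFit(css, y3, order = 4)
  expect_setequal(m3@terms$label[-1],
                  c("cube(m1)", "log(m3)", "cube(m5)"))
  expect_lt(tail(m3@trainMsePath, 1), 1e-12 * stats::var(y3))
})

test_that("orthogonal search matches the brute-force OLS oracle", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(10:50, 1); nc <- sample(5:40, 1)
    X <- randomInstance(n, nc, duplicate = runif(1) < 0.3)
    ord <- min(sample(1:6, 1), n - 2, nc)
    y <- rnorm(n)
    a <- fosFit(X, y, ord)
    b <- greedyForwardOLS(X, y, ord)
    expect_identical(a@terms$label, b@terms$label)
    expect_lt(max(abs(a@trainMsePath - b@trainMsePath)),
              1e-10 * max(1, a@trainMsePath[1]))
    expect_lt(max(abs(a@coefficients - b@coefficients)),
              1e-8 * max(1, max(abs(a@coefficients))))
  }
})

test_that("order-1 models reduce to the target mean and variance", {
  set.seed(4)
  y <- rnorm(25)
  m <- greedyForwardOLS(randomInstance(25, 6), y, 1)
  expect_equal(m@coefficients, mean(y))
  expect_equal(m@trainMsePath, mean((y - mean(y))^2))
})

test_that("exact duplicates of a selected candidate are never reselected", {
  set.seed(5)
  X <- randomInstance(30, 6)
  X[, 4] <- X[, 2]
  y <- X[, 2] + rnorm(30, sd = 0.1)
  m <- fosFit(X, y, 4)
  expect_true("c2" %in% m@terms$label)
  expect_false("c4" %in% m@terms$label)
  o <- greedyForwardOLS(X, y, 4)
  expect_false("c4" %in% o@terms$label)
})

test_that("the training MSE path never increases with model order", {
  set.seed(6)
  for (i in 1:10) {
    X <- randomInstance(40, 12)
    m <- fosFit(X, rnorm(40), 8)
    expect_true(all(diff(m@trainMsePath) <= 1e-12))
  }
})

test_that("coefficients solve the normal equations on the selected columns", {
  set.seed(7)
  X <- randomInstance(35, 10)
  y <- rnorm(35)
  m <- fosFit(X, y, 5)
  sel <- m@terms$label[-1]
  ref <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  expect_equal(m@coefficients, unname(ref$coefficients), tolerance = 1e-10)
  # residual orthogonal to the selected span
  resid <- y - predictTargets(m, X)
  expect_lt(max(abs(crossprod(cbind(1, X[, sel]), resid))), 1e-8)
})

test_that("candidate order only matters for exact ties", {
  set.seed(8)
  X <- randomInstance(30, 10)
  y <- rnorm(30)
  perm <- sample(10)
  m1 <- fosFit(X, y, 5)
  m2 <- fosFit(X[, perm], y, 5)
  expect_identical(m1@terms$label, m2@terms$label)
})

test_that("requesting more terms than the rank supports reports the achievable order", {
  X <- cbind(c1 = rnorm(20))
  X <- cbind(X, c2 = 2 * X[, "c1"])          # rank 1 pool
  y <- rnorm(20)
  expect_error(fosFit(X, y, 3), "achievable order is 2")
  expect_error(greedyForwardOLS(X, y, 3), "achievable order is 2")
  expect_error(fosFit(X, y, 10), "achievable order")
})

test_that("prediction applies coefficients row-wise and checks its inputs", {
  set.seed(9)
  # constant-only model predicts its coefficient everywhere
  mConst <- fosFit(randomInstance(20, 4), rep(7, 20), 1)
  expect_equal(predictTargets(mConst, randomInstance(5, 4)), rep(7, 5))
  # full-rank exact fit reproduces training targets
  m <- matrix(rnorm(40, sd = 3), 20, 2, dimnames = list(NULL, c("M1", "M2")))
  params <- fitNormalization(m)
  z <- normalizeValues(m, params)
  y <- 1 + 2 * z[, "M1"]^2
  fit <- fosFit(expandCandidates(z), y, 2)
  expect_equal(predictTargets(fit, m, params), y, tolerance = 1e-8)
  # permuting rows permutes predictions identically
  perm <- sample(20)
  expect_equal(predictTargets(fit, m[perm, ], params),
               predictTargets(fit, m, params)[perm])
  # missing metric is a contract error
  expect_error(predictTargets(fit, m[, "M2", drop = FALSE], params),
               "absent: M1")
})

test_that("fitted models serialize to the documented JSON shape", {
  set.seed(10)
  z <- randomZ(25, 3)
  fit <- fosFit(expandCandidates(z), rnorm(25), 3, targetName = "FIM-Total-2w")
  path <- withr::local_tempfile(fileext = ".json")
  writeFOSModel(fit, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(obj$target, "FIM-Total-2w")
  expect_equal(length(obj$terms), 3L)
  expect_equal(obj$terms[[1]]$kind, "constant")
  expect_equal(unlist(obj$train_mse_path), fit@trainMsePath)
})
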