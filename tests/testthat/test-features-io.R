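test_that("a complete table loads with all subjects and group labels", {
  paths <- writeToyTable()
  be <- readBiomarkerTable(paths$csv, paths$groups)
  expect_s4_class(be, "BiomarkerExperiment")
  expect_equal(ncol(be), 3L)                      # subjects
  expect_equal(sort(rownames(be)), c("M1", "OH1"))
  expect_equal(unname(groupMap(be)[c("M1", "OH1")]), c("M", "OH"))
  expect_equal(metricsForDataset(be, "All"), c("M1", "OH1"))
})

test_that("rows with missing values are removed listwise and logged", {
  paths <- writeToyTable(missingCell = TRUE)
  expect_message(be <- readBiomarkerTable(paths$csv, paths$groups),
                 "1 subject\\(s\\) excluded")
  expect_equal(ncol(be), 2L)
  expect_equal(subjectIds(be), c("s1", "s3"))
})

test_that("configuration and parse errors are reported with context", {
  paths <- writeToyTable(unmappedColumn = TRUE)
  expect_error(readBiomarkerTable(paths$csv, paths$groups), "OH1")
  paths <- writeToyTable(badCell = TRUE)
  expect_error(readBiomarkerTable(paths$csv, paths$groups),
               "row 2, column 'OH1'")
  expect_error(metricsForDataset(toyCohort(20)$experiment, "Nope"),
               "unknown dataset")
})

test_that("normalization parameters store observed extremes per column", {
  m <- cbind(a = c(2, 4, 10), b = c(0, 5, 1))
  p <- fitNormalization(m)
  expect_equal(unname(p@xmin), c(2, 0))
  expect_equal(unname(p@xmax), c(10, 5))
  p2 <- fitNormalization(cbind(m, cc = c(1, 2, 3)), columns = c("a", "b"))
  expect_equal(names(p2@xmin), c("a", "b"))
  expect_error(fitNormalization(cbind(k = c(5, 5, 5))), "degenerate.*k")
})

test_that("normalization maps extremes to 0/1, is affine and clips new data", {
  p <- fitNormalization(cbind(a = c(2, 4, 10)))
  expect_identical(normalizeValues(2, p, "a"), 0)
  expect_identical(normalizeValues(10, p, "a"), 1)
  expect_identical(normalizeValues(6, p, "a"), 0.5)
  expect_identical(normalizeValues(c(-100, 100), p, "a"), c(0, 1))
  # strictly increasing inside the observed range
  x <- seq(2, 10, length.out = 50)
  expect_true(all(diff(normalizeValues(x, p, "a")) > 0))
})

test_that("normalized training columns span exactly [0, 1]", {
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rnorm(40, sd = 10), 10, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    z <- normalizeValues(m, fitNormalization(m))
    expect_equal(unname(apply(z, 2, min)), rep(0, 4))
    expect_equal(unname(apply(z, 2, max)), rep(1, 4))
  }
})

test_that("normalization parameters round-trip through JSON exactly", {
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- fitNormalization(m, scope = "global")
  path <- withr::local_tempfile(fileext = ".json")
  writeNormalizationParams(p, path)
  p2 <- readNormalizationParams(path)
  expect_identical(p2@xmin, p@xmin)
  expect_identical(p2@xmax, p@xmax)
  expect_identical(p2@scope, p@scope)
})

test_that("FIM target specs carry the scale ranges", {
  expect_equal(c(fimTargetSpec("FIM-Total-2w")@validMin,
                 fimTargetSpec("FIM-Total-2w")@validMax), c(18, 126))
  expect_equal(c(fimTargetSpec("FIM-Motor-3m")@validMin,
                 fimTargetSpec("FIM-Motor-3m")@validMax), c(13, 91))
  expect_error(targetSpec("x", validMin = 5, validMax = 5), "validMin")
})
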