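test_that("beta value formula matches direct arithmetic", {
  expect_identical(betaFromIntensities(0, 0), 0)
  expect_identical(betaFromIntensities(900, 0), 0.9)
  expect_identical(betaFromIntensities(-50, 300), 0)

  set.seed(11)
  M <- runif(1000, -500, 5000)
  U <- runif(1000, -500, 5000)
  oracle <- pmax(M, 0) / (pmax(M, 0) + pmax(U, 0) + 100)
  expect_identical(betaFromIntensities(M, U), oracle)
  expect_true(all(oracle >= 0 & oracle < 1))

  # the +100 offset makes the value scale-sensitive by design
  expect_false(isTRUE(all.equal(betaFromIntensities(2 * 300, 2 * 500),
                                betaFromIntensities(300, 500))))
  expect_error(betaFromIntensities(NA, 1), "finite")
})

test_that("age transform is a calibrated, invertible map", {
  expect_equal(transformAge(20, 20), 0)
  expect_equal(transformAge(41, 20), 1.0)
  expect_equal(inverseTransformAge(0, 20), 20)
  expect_equal(inverseTransformAge(1.0, 20), 41)

  ages <- c(-0.89, seq(-0.8, 120, by = 0.37), 5, 20, 65.34, 120)
  expect_lt(max(abs(inverseTransformAge(transformAge(ages, 20), 20) - ages)),
            1e-10)
  # continuity at the knot
  expect_equal(inverseTransformAge(-1e-12, 20), 20, tolerance = 1e-9)
  expect_equal(inverseTransformAge(1e-12, 20), 20, tolerance = 1e-9)
  expect_true(all(diff(transformAge(seq(-0.5, 100, 0.1), 20)) > 0))
  expect_error(transformAge(-1), "age")
})

test_that("applyClock evaluates the linear predictor by probe ID", {
  model <- ClockModel(c("cg1", "cg2", "cg3"), c(0.5, -0.2, 0.1),
                      intercept = 0.3)
  b <- matrix(1, 3, 2, dimnames = list(c("cg1", "cg2", "cg3"),
                                       c("s1", "s2")))
  expect_equal(unname(applyClock(b, model)),
               rep(inverseTransformAge(0.7, 20), 2))

  b0 <- matrix(0, 3, 1, dimnames = list(c("cg1", "cg2", "cg3"), "s"))
  expect_equal(unname(applyClock(b0, model)), inverseTransformAge(0.3, 20))

  # invariant to probe order and to extraneous probes
  set.seed(3)
  bx <- matrix(runif(20), 5, 4,
               dimnames = list(c("cg9", "cg2", "cg1", "cg3", "cg8"),
                               paste0("s", 1:4)))
  a1 <- applyClock(bx, model)
  a2 <- applyClock(bx[sample(5), ], model)
  expect_identical(a1, a2)

  noOverlap <- matrix(0.5, 2, 1, dimnames = list(c("cgX", "cgY"), "s"))
  expect_error(applyClock(noOverlap, model), "overlap")
})

test_that("missing clock probes are mean-imputed or flagged per sample", {
  model <- ClockModel(paste0("cg", 1:10), rep(0.1, 10), intercept = 0)
  set.seed(4)
  b <- matrix(runif(30), 10, 3,
              dimnames = list(paste0("cg", 1:10), c("s1", "s2", "s3")))
  b["cg5", "s2"] <- NA                       # one missing: imputed
  b[1:8, "s3"] <- NA                         # 80% missing: failed
  expect_warning(ages <- applyClock(b, model), "below")
  expect_true(is.na(ages["s3"]))
  imputed <- mean(b["cg5", c("s1", "s3")], na.rm = TRUE)
  lp <- 0.1 * (sum(b[-5, "s2"]) + imputed)
  expect_equal(unname(ages["s2"]), inverseTransformAge(lp, 20))

  expect_error(applyClock(b[, 1:2], model, missingPolicy = "error"),
               "missing")
})

test_that("applyClock inverts a known clock exactly on constructed betas", {
  set.seed(21)
  model <- ClockModel(sprintf("cg%03d", 1:20), runif(20, 0.3, 0.6),
                      intercept = -2.7)
  ages <- c(5, 20, 30, 65.34, 90)
  b <- simulateClockBetas(model, ages)
  expect_true(all(b >= 0 & b <= 1))
  expect_lt(max(abs(unname(applyClock(b, model)) - ages)), 1e-8)
})

test_that("elastic-net training recovers a noiseless linear clock", {
  set.seed(7)
  n <- 60
  b <- matrix(runif(21 * n), 21, n,
              dimnames = list(sprintf("cg%03d", 1:21), paste0("s", 1:n)))
  tAge <- 0.4 * b[1, ] + 0.1
  ages <- inverseTransformAge(tAge, 20)

  # OLS oracle on the same data recovers 0.4 exactly
  ols <- lm.fit(cbind(1, t(b)), transformAge(ages, 20))
  expect_equal(unname(ols$coefficients[2]), 0.4, tolerance = 1e-8)

  model <- trainClock(b, ages, alpha = 0.5, lambda = 1e-6)
  expect_lt(abs(clockCoefficients(model)[["cg001"]] - 0.4), 1e-3)

  # at a strong lasso penalty the pure-noise probes get zero coefficients
  tStrong <- 2 * b[1, ] + 0.1
  m2 <- trainClock(b, inverseTransformAge(tStrong, 20), alpha = 1,
                   lambda = 0.1)
  expect_true(all(probeIds(m2) == "cg001"))

  expect_error(trainClock(b, rep(50, n)), "constant")
  expect_error(trainClock(b[, 1:10], ages[1:10]), "20 samples")
})

test_that("clock coefficient CSV round-trips and rejects malformed files", {
  tmp <- tempfile(fileext = ".csv")
  set.seed(8)
  model <- ClockModel(sprintf("cg%05d", 1:353), rnorm(353), intercept = 0.7)
  writeClockModel(model, tmp)
  back <- readClockModel(tmp)
  expect_identical(probeIds(back), probeIds(model))
  expect_equal(unname(clockCoefficients(back)),
               unname(clockCoefficients(model)), tolerance = 1e-12)
  expect_equal(clockIntercept(back), 0.7, tolerance = 1e-12)

  one <- tempfile(fileext = ".csv")
  writeLines(c("CpG,coefficient", "(Intercept),0.7", "cg000001,0.5"), one)
  m1 <- readClockModel(one)
  expect_identical(probeIds(m1), "cg000001")
  expect_equal(clockIntercept(m1), 0.7)

  noInt <- tempfile(fileext = ".csv")
  writeLines(c("CpG,coefficient", "cg000001,0.5"), noInt)
  expect_error(readClockModel(noInt), "Intercept")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("CpG,coefficient", "(Intercept),0.7",
               "cg000001,0.5", "cg000001,0.2"), dup)
  expect_error(readClockModel(dup), "duplicate")
})
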