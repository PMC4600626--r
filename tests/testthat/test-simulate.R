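test_that("reference signatures: range, determinism, marker separation", {
  cfg2 <- simConfig(nSubjects = 10, nProbes = 10, nClockProbes = 2,
                    nDiscProbes = 4, nCellTypes = 2, seed = 1)
  sig <- simulateReferenceSignatures(cfg2)
  v <- signatureValues(sig)
  expect_equal(dim(v), c(10L, 2L))
  expect_true(all(v >= 0 & v <= 1))

  sig2 <- simulateReferenceSignatures(cfg2)
  expect_identical(signatureValues(sig2), v)

  # every cell-type pair separated by >= 0.3 on the discriminative subset
  sig7 <- simulateReferenceSignatures(tiny_config(nDiscProbes = 28))
  d <- signatureValues(sig7)[discriminativeProbes(sig7), ]
  for (a in seq_len(ncol(d) - 1)) {
    for (b in seq((a + 1), ncol(d))) {
      expect_gte(max(abs(d[, a] - d[, b])), 0.3)
    }
  }

  expect_error(simConfig(nCellTypes = 1), "nCellTypes")
})

test_that("subject simulation honours acceleration, smoking, pack-years", {
  sub0 <- simulateSubjects(tiny_config(accelerationSd = 0))
  expect_true(all(sub0$truth$true_acceleration == 0))

  big <- simulateSubjects(tiny_config(nSubjects = 10000, seed = 4))
  ph <- big$phenotypes
  expect_true(all(ph$pack_years[ph$smoking == "never"] == 0))
  expect_true(all(ph$pack_years[ph$smoking != "never"] > 0))
  freq <- table(ph$smoking) / nrow(ph)
  expect_lt(abs(freq[["never"]] - 0.544), 0.02)
  expect_lt(abs(freq[["former"]] - 0.352), 0.02)
  expect_lt(abs(freq[["current"]] - 0.104), 0.02)

  f <- as.matrix(big$truth[, grep("^frac_", names(big$truth))])
  expect_true(all(f >= 0))
  expect_lt(max(abs(rowSums(f) - 1)), 1e-12)
  expect_true(all(ph$age >= 50 & ph$age <= 79))
})

test_that("beta generation: degenerate mixtures, range, exact logit shift", {
  # pure sample with zero slopes and zero noise reproduces a reference column
  cfg <- simConfig(nSubjects = 2, nProbes = 20, nClockProbes = 5,
                   nDiscProbes = 6, nCellTypes = 2, betaNoiseSd = 0,
                   clockSlopeRange = c(0, 0), seed = 9)
  sig <- simulateReferenceSignatures(cfg)
  truth <- data.frame(sample_id = c("A", "B"), true_age = c(60, 60),
                      true_acceleration = c(0, 0),
                      frac_cell1 = c(1, 0), frac_cell2 = c(0, 1))
  bs <- simulateBetas(truth, truth, sig, cfg)
  b <- betaValues(bs)
  expect_equal(unname(b[, "A"]), unname(signatureValues(sig)[, 1]),
               tolerance = 1e-12)
  expect_true(all(b > 0 & b < 1))

  # +10y acceleration shifts clock-probe logits by exactly slope * 10
  cfg2 <- simConfig(nSubjects = 2, nProbes = 30, nClockProbes = 10,
                    nDiscProbes = 14, betaNoiseSd = 0, seed = 5)
  sig2 <- simulateReferenceSignatures(cfg2)
  fr <- as.list(cfg2@cellMeans)
  names(fr) <- paste0("frac_", names(fr))
  truth2 <- cbind(data.frame(sample_id = c("A", "B"), true_age = c(60, 60),
                             true_acceleration = c(10, 0)),
                  as.data.frame(fr))
  b2 <- betaValues(simulateBetas(truth2, truth2, sig2, cfg2))
  cp <- clockProbeIds(sig2)
  shift <- qlogis(b2[cp, "A"]) - qlogis(b2[cp, "B"])
  expect_equal(unname(shift), unname(clockProbeSlopes(sig2)) * 10,
               tolerance = 1e-9)

  # dimension mismatch between signatures and configured probe set
  expect_error(simulateBetas(truth2, truth2, sig2, cfg), "shape")
})

test_that("event times follow the planted proportional-hazards model", {
  zeroCov <- c(age = 0, former = 0, current = 0, pack_years = 0, chd = 0)

  sub <- simulateSubjects(tiny_config(nSubjects = 200, baselineRate = 0))
  ev <- simulateEvents(sub$phenotypes, sub$truth,
                       tiny_config(nSubjects = 200, baselineRate = 0))
  expect_true(all(ev$phenotypes$event == 0))
  expect_true(all(ev$phenotypes$time == 20))

  # closed-form exponential CDF for a zero-covariate subject
  cfg <- tiny_config(nSubjects = 50000, baselineRate = 0.02,
                     trueLogHrPerSd = 0, covariateLogHr = zeroCov, seed = 2)
  sub <- simulateSubjects(cfg)
  ev <- simulateEvents(sub$phenotypes, sub$truth, cfg)
  expect_lt(abs(mean(ev$truth$true_event_time <= 5) - (1 - exp(-0.02 * 5))),
            0.006)

  # with no planted effect, events are independent of acceleration tercile
  terc <- cut(ev$truth$true_acceleration,
              quantile(ev$truth$true_acceleration, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  chi <- suppressWarnings(chisq.test(table(ev$phenotypes$event, terc)))
  expect_gt(chi$p.value, 0.001)

  expect_error(simConfig(baselineRate = -1), "rates")
})

test_that("cohorts are seed-deterministic and hit a ~2% incidence", {
  cfg <- tiny_config(seed = 12)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(betaValues(c1$betas), betaValues(c2$betas))
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth, c2$truth)

  # cumulative event fraction under default conditions brackets 2.1%
  dflt <- simConfig(seed = 31)
  sub <- simulateSubjects(dflt)
  ev <- simulateEvents(sub$phenotypes, sub$truth, dflt)
  expect_gte(mean(ev$phenotypes$event), 0.01)
  expect_lte(mean(ev$phenotypes$event), 0.05)
})
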