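test_that("person-days convert to 4-decimal person-years", {
  expect_identical(personYearsFromDays(0), 0)
  expect_identical(personYearsFromDays(365), 0.9993)
  expect_identical(personYearsFromDays(7305), 20)
  expect_identical(personYearsFromDays(c(1, 36525)), c(0.0027, 100))
  expect_error(personYearsFromDays(-1), "days")
})

test_that("Kruskal-Wallis H matches the hand-computed toy and permutations", {
  kw <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7 = 3.857 (3 dp)
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(round(kw$statistic, 3), 3.857)
  expect_identical(kw$group_sizes, c(3L, 3L))

  # label invariance: same partition, relabeled
  kw2 <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("z", "q"), each = 3))
  expect_equal(kw2$statistic, kw$statistic)

  # chi-square p agrees with a 10,000-shuffle permutation oracle
  set.seed(9)
  x <- rnorm(24)
  g <- rep(c("a", "b"), each = 12)
  obs <- kruskalWallis(x, g)
  r <- rank(x)
  expect_equal(obs$statistic, kw_H_from_ranks(r, g), tolerance = 1e-10)
  hp <- replicate(10000, kw_H_from_ranks(r, sample(g)))
  pPerm <- mean(hp >= obs$statistic - 1e-12)
  expect_lt(abs(pPerm - obs$p_value), 0.03)

  expect_error(kruskalWallis(rep(1, 6), rep(c("a", "b"), each = 3)),
               "identical")
  expect_error(kruskalWallis(1:5, rep("a", 5)), "groups")
})

test_that("biweight midcorrelation is exact on linear maps, near Pearson on
          clean data", {
  set.seed(10)
  x <- rnorm(50)
  expect_equal(bicor(x, x)$estimate, 1.0)
  expect_equal(bicor(x, -2 * x + 3)$estimate, -1.0)
  expect_identical(bicor(x, x)$p_value, 0)

  n <- 10000
  z <- matrix(rnorm(2 * n), ncol = 2)
  y <- 0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
  b <- bicor(z[, 1], y)
  expect_lt(abs(b$estimate - cor(z[, 1], y)), 0.03)
  expect_lt(b$p_value, 1e-10)

  const <- c(rep(0, 48), 1, 2)
  expect_warning(fb <- bicor(const, rnorm(50)), "MAD")
  expect_match(fb$method, "pearson")
  expect_error(bicor(const, rnorm(50), fallbackPearson = FALSE), "deviation")
})

test_that("Cox log HR matches a dense grid search of the partial likelihood", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1,
                  x = c(1, 0, 1, 1, 0, 0))
  fit <- coxFit(d, "x")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- cox_loglik_grid(d$time, d$event, d$x, grid)
  expect_lt(abs(coxTable(fit)$logHR[1] - grid[which.max(ll)]), 1e-3)
  # the reported optimum is at least as good as every grid point
  expect_gte(fit@fit$loglik[2], max(ll) - 1e-8)

  dc <- d
  dc$x <- 0
  expect_error(coxFit(dc, "x"), "rank")
  expect_error(coxFit(d[d$event == 0, ], "x"), "events")
})

test_that("Breslow baseline hazard steps exactly at distinct event times", {
  cfg <- tiny_config(nSubjects = 150, baselineRate = 0.004, seed = 16)
  sub <- simulateSubjects(cfg)
  ph <- simulateEvents(sub$phenotypes, sub$truth, cfg)$phenotypes
  fit <- coxFit(ph, c("age", "pack_years"))
  bh <- baselineCumhaz(fit)
  expect_true(all(diff(bh$hazard) >= 0))
  jumps <- sum(c(bh$hazard[1] > 0, diff(bh$hazard) > 0))
  expect_identical(jumps, length(unique(ph$time[ph$event == 1])))

  expect_gt(fit@nEvents, 0)
  expect_equal(fit@personYears, sum(ph$time))
  expect_true(all(hazardRatios(fit) > 0))
  expect_true(fit@rSquared >= 0 && fit@rSquared < 1)
})

test_that("monotone likelihood is flagged with the offending covariate", {
  set.seed(17)
  d <- data.frame(time = runif(40, 1, 10), event = rep(0:1, 20))
  d$sep <- d$event
  expect_warning(fit <- coxFit(d, "sep"), "monotone")
  expect_false(fit@converged)
})

test_that("age strata use left-closed decades and conserve events", {
  set.seed(18)
  n <- 90
  ph <- data.frame(sample_id = sprintf("S%05d", 1:n),
                   age = c(55, 59.99, 60, 69.99, 70, 79,
                           runif(n - 6, 50, 79)),
                   race = "white", smoking = "never", pack_years = 0,
                   chd = 0, event = rbinom(n, 1, 0.4),
                   time = runif(n, 1, 20), stringsAsFactors = FALSE)
  z <- setNames(rnorm(n), ph$sample_id)
  fits <- stratifiedAnalysis(ph, z, strata = "age")
  expect_named(fits, c("50-59", "60-69", "70+"))
  grp <- cut(ph$age, c(-Inf, 60, 70, Inf), right = FALSE)
  expect_identical(sapply(fits, function(f) f@n), setNames(
    as.integer(table(grp)), names(fits)))
  expect_identical(sum(sapply(fits, function(f) f@nEvents)),
                   sum(ph$event))
  # 59.99 belongs to 50-59; 60 and 69.99 to 60-69; 70 to 70+
  expect_identical(as.character(grp[2:5]),
                   c("[-Inf,60)", "[60,70)", "[60,70)", "[70, Inf)"))
})

test_that("smoking strata drop pack-years for never smokers", {
  set.seed(19)
  n <- 120
  smoking <- rep(c("never", "former", "current"), each = n / 3)
  ph <- data.frame(sample_id = sprintf("S%05d", 1:n),
                   age = runif(n, 50, 79), race = "white",
                   smoking = smoking,
                   pack_years = ifelse(smoking == "never", 0,
                                       rgamma(n, 2, 0.1)),
                   chd = rbinom(n, 1, 0.3), event = rbinom(n, 1, 0.35),
                   time = runif(n, 1, 20), stringsAsFactors = FALSE)
  z <- setNames(rnorm(n), ph$sample_id)
  fits <- stratifiedAnalysis(ph, z, strata = "smoking")
  expect_false("pack_years" %in% coxTable(fits$never)$term)
  expect_true("pack_years" %in% coxTable(fits$former)$term)
  expect_true("pack_years" %in% coxTable(fits$current)$term)

  # an event-free stratum is reported as unestimable, not dropped
  ph2 <- ph
  ph2$event[ph2$smoking == "never"] <- 0
  fits2 <- stratifiedAnalysis(ph2, z, strata = "smoking")
  expect_false(fits2$never@converged)
  expect_match(fits2$never@label, "unestimable")
})

test_that("planted stratum-specific effects keep their ordering", {
  hit <- 0
  for (s in 1:50) {
    cfg <- tiny_config(nSubjects = 4000, baselineRate = 3.5e-4,
                       strataLogHrPerSd = c(0, 0, log(2.5)), seed = 700 + s)
    sub <- simulateSubjects(cfg)
    ph <- simulateEvents(sub$phenotypes, sub$truth, cfg)$phenotypes
    z <- setNames(sub$truth$true_acceleration / 5, ph$sample_id)
    fits <- suppressWarnings(stratifiedAnalysis(ph, z, strata = "age"))
    hrs <- sapply(fits, function(f) hazardRatios(f)[["ieaa"]])
    if (which.max(hrs) == 3) hit <- hit + 1
  }
  expect_gte(hit, 45)
})

test_that("incidence curves follow the Breslow baseline and the profile", {
  cfg <- tiny_config(nSubjects = 2000, baselineRate = 1e-3,
                     trueLogHrPerSd = log(2), seed = 20)
  sub <- simulateSubjects(cfg)
  ph <- simulateEvents(sub$phenotypes, sub$truth, cfg)$phenotypes
  ph$ieaa <- sub$truth$true_acceleration / 5
  fit <- coxFit(ph, c("ieaa", "age", "pack_years"))

  prof0 <- c(ieaa = 0, age = 0, pack_years = 0)
  bh <- baselineCumhaz(fit)
  ci <- predictIncidence(fit, prof0, c(0, bh$time))
  expect_identical(ci$incidence[1], 0)
  expect_equal(ci$incidence[-1], 1 - exp(-bh$hazard), tolerance = 1e-12)
  expect_true(all(diff(ci$incidence) >= 0))

  tgrid <- seq(0, 20, by = 0.5)
  hi <- predictIncidence(fit, c(ieaa = 1, age = 65, pack_years = 10), tgrid)
  lo <- predictIncidence(fit, c(ieaa = 0, age = 65, pack_years = 10), tgrid)
  expect_gt(coxTable(fit)$logHR[1], 0)
  expect_true(all(hi$incidence >= lo$incidence))

  expect_warning(predictIncidence(fit, prof0, max(bh$time) + 5), "flat")
  expect_error(predictIncidence(fit, c(ieaa = 1), tgrid), "cover")
})

test_that("landmark exclusion removes only early cases", {
  ph <- data.frame(sample_id = paste0("S", 1:5),
                   event = c(1, 1, 1, 0, 0),
                   time = c(0.5, 2, 4, 0.3, 10))
  e0 <- landmarkExclusion(ph, 0)
  expect_identical(nrow(e0), 5L)
  expect_identical(attr(e0, "nExcluded"), 0L)
  e1 <- landmarkExclusion(ph, 1)
  expect_identical(attr(e1, "nExcluded"), 1L)
  expect_false("S1" %in% e1$sample_id)
  expect_true("S4" %in% e1$sample_id)  # early censoring is retained
  e5 <- landmarkExclusion(ph, 5)
  expect_identical(attr(e5, "nExcluded"), 3L)
  expect_error(landmarkExclusion(ph, -1), ">= 0")
})

test_that("logistic sensitivity: duplication invariance and null consistency", {
  cfg <- tiny_config(nSubjects = 500, baselineRate = 1.5e-3, seed = 21)
  sub <- simulateSubjects(cfg)
  ph <- simulateEvents(sub$phenotypes, sub$truth, cfg)$phenotypes
  ph$z <- sub$truth$true_acceleration / 5
  covs <- c("z", "age", "smoking", "pack_years", "chd")
  t1 <- logisticSensitivity(ph, covs)
  t2 <- logisticSensitivity(rbind(ph, ph), covs)
  expect_equal(t1$logOR, t2$logOR, tolerance = 1e-6)

  # zero planted effect at n = 50,000: log OR pinned near 0
  cfg0 <- tiny_config(nSubjects = 50000, baselineRate = 1e-3,
                      trueLogHrPerSd = 0, seed = 22)
  sub0 <- simulateSubjects(cfg0)
  ph0 <- simulateEvents(sub0$phenotypes, sub0$truth, cfg0)$phenotypes
  ph0$z <- sub0$truth$true_acceleration / 5
  t0 <- logisticSensitivity(ph0, covs)
  expect_lte(abs(t0$logOR[t0$term == "z"]), 0.05)

  sep <- data.frame(event = rep(0:1, each = 25), x = rep(0:1, each = 25),
                    age = runif(50, 50, 79))
  expect_error(logisticSensitivity(sep, c("x", "age")), "separation")
  expect_error(logisticSensitivity(data.frame(event = rep(1, 10),
                                              x = rnorm(10)), "x"),
               "outcome classes")
})

test_that("with a rare outcome the logistic OR approximates the Cox HR", {
  cfg <- tiny_config(nSubjects = 20000, seed = 23)  # ~2% incidence
  sub <- simulateSubjects(cfg)
  ph <- simulateEvents(sub$phenotypes, sub$truth, cfg)$phenotypes
  ph$z <- sub$truth$true_acceleration / 5
  covs <- c("z", "age", "race", "chd", "smoking", "pack_years")
  hr <- hazardRatios(coxFit(ph, covs))[["z"]]
  lt <- logisticSensitivity(ph, covs)
  or <- lt$OR[lt$term == "z"]
  expect_lte(abs(or - hr), 0.1)
})
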