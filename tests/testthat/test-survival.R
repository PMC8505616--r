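test_that("univariate Cox estimate maximizes the Efron partial likelihood", {
  clin <- toyClinical(times = c(2, 4, 6, 8, 10, 12),
                      events = c(1, 1, 0, 1, 1, 0))
  x <- setNames(c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9), clin$sample_id)
  fit <- fitCoxUnivariate(x, clin)
  expect_equal(fit$beta, gridCoxBeta(clin$os_time, clin$os_event, x[clin$sample_id]),
               tolerance = 1e-3)
  expect_equal(fit$events, 4)
  expect_true(fit$ci_lo < fit$hr && fit$hr < fit$ci_hi)

  # a few random small datasets against the grid oracle
  for (s in 1:3) {
    set.seed(s)
    cl <- toyClinical(times = rexp(20, 0.1), events = rbinom(20, 1, 0.6))
    xv <- setNames(rnorm(20), cl$sample_id)
    if (sum(cl$os_event) < 2) next
    f <- fitCoxUnivariate(xv, cl)
    expect_equal(f$beta, gridCoxBeta(cl$os_time, cl$os_event, xv[cl$sample_id]),
                 tolerance = 1e-3)
  }
})

test_that("doubling the covariate halves beta and preserves the Wald test", {
  set.seed(8)
  clin <- toyClinical(times = rexp(40, 0.1), events = rbinom(40, 1, 0.7))
  x <- setNames(rnorm(40), clin$sample_id)
  f1 <- fitCoxUnivariate(x, clin)
  f2 <- fitCoxUnivariate(2 * x, clin)
  expect_equal(f2$beta, f1$beta / 2, tolerance = 1e-8)
  expect_equal(f2$p, f1$p, tolerance = 1e-8)
})

test_that("Cox preconditions are enforced and divergence is flagged", {
  clin <- toyClinical(times = c(1, 2, 3, 4), events = c(1, 1, 1, 1))
  expect_error(fitCoxUnivariate(setNames(rep(1, 4), clin$sample_id), clin),
               "constant")
  clin1 <- toyClinical(times = c(1, 2, 3, 4), events = c(1, 0, 0, 0))
  expect_error(fitCoxUnivariate(setNames(rnorm(4), clin1$sample_id), clin1),
               "2 events")
  # perfectly ordered covariate vs event times: monotone likelihood
  clinD <- toyClinical(times = 8:1, events = rep(1, 8))
  xD <- setNames(as.numeric(1:8), clinD$sample_id)
  expect_warning(fD <- fitCoxUnivariate(xD, clinD), "divergence")
  expect_true(fD$flagged)
})

test_that("Kaplan-Meier product-limit matches hand computation", {
  clin <- toyClinical(times = c(1, 2, 3), events = c(1, 0, 1))
  km <- kmEstimate(clin)$all
  expect_equal(km$surv[km$time == 1], 2/3)
  expect_equal(km$surv[km$time == 3], 0)

  cens <- toyClinical(times = c(1, 2, 3), events = c(0, 0, 0))
  expect_true(all(kmEstimate(cens)$all$surv == 1))

  onetime <- toyClinical(times = rep(5, 4), events = rep(1, 4))
  expect_equal(kmEstimate(onetime)$all$surv, 0)

  # no censoring: KM equals the empirical survival function
  set.seed(3)
  t <- sort(rexp(30, 0.1))
  noC <- toyClinical(times = t, events = rep(1, 30))
  km2 <- kmEstimate(noC)$all
  expect_equal(km2$surv, 1 - seq_len(30) / 30, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hypergeometric hand computation", {
  clin <- toyClinical(times = c(1, 5, 5, 5), events = c(1, 0, 0, 0))
  g <- setNames(c("a", "a", "b", "b"), clin$sample_id)
  lr <- logrankTest(clin, g)
  # one event, 2/4 at risk in group a: (1 - 0.5)^2 / 0.25 = 1
  expect_equal(lr$statistic, 1, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(1, 1, lower.tail = FALSE))

  # identical copies give statistic 0, p 1
  clin2 <- toyClinical(times = rep(c(1, 3, 7), 2),
                       events = rep(c(1, 0, 1), 2))
  g2 <- setNames(rep(c("a", "b"), each = 3), clin2$sample_id)
  lr2 <- logrankTest(clin2, g2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)

  allc <- toyClinical(times = 1:4, events = rep(0, 4))
  expect_error(logrankTest(allc, setNames(c("a", "a", "b", "b"),
                                          allc$sample_id)), "no events")
  expect_error(logrankTest(clin, setNames(rep("a", 4), clin$sample_id)),
               "two groups")
})

test_that("log-rank null rejection rate is calibrated", {
  set.seed(42)
  n <- 100
  rej <- vapply(1:400, function(i) {
    clin <- toyClinical(times = rexp(2 * n, 0.05),
                        events = rbinom(2 * n, 1, 0.8))
    g <- setNames(rep(c("a", "b"), each = n), clin$sample_id)
    logrankTest(clin, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("restricted mean survival integrates the KM curve over a common horizon", {
  clin <- toyClinical(times = c(1, 2, 3, 4), events = c(1, 1, 1, 1))
  g <- setNames(rep("all", 4), clin$sample_id)
  # S = 1 on [0,1), .75 on [1,2), .5 on [2,3), .25 on [3,4)
  expect_equal(unname(restrictedMeanSurvival(clin, g, tau = 4)),
               1 + 0.75 + 0.5 + 0.25)
})

test_that("the per-cohort screen returns one row per signature and cohort", {
  cfg <- simConfig(nCohorts = 2, samplesPerCohort = 40, nGenes = 200,
                   nSignatures = 6, genesPerSignature = 10,
                   nProtective = 1, nRisk = 1, seed = 99)
  sim <- simulateCohorts(cfg)
  nes <- lapply(sim$cohorts, function(co)
    normalizeNES(ssgseaScore(co$expression, simSignatureCollection(cfg))))
  tab <- coxScreen(nes, lapply(sim$cohorts, `[[`, "clinical"))
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$hr > 0))
  expect_true(all(tab$events <= tab$n))
})
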