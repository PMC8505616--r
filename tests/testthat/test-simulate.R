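cfgSmall <- simConfig(nCohorts = 2, samplesPerCohort = 40, nGenes = 300,
                      nSignatures = 8, genesPerSignature = 10,
                      nProtective = 2, nRisk = 1, seed = 55)

test_that("the generator is a pure function of config and seed", {
  s1 <- simulateCohorts(cfgSmall, seed = 5)
  s2 <- simulateCohorts(cfgSmall, seed = 5)
  expect_identical(exprValues(s1$cohorts[[1]]$expression),
                   exprValues(s2$cohorts[[1]]$expression))
  expect_identical(s1$cohorts[[2]]$clinical, s2$cohorts[[2]]$clinical)
  expect_identical(s1$truth$activity, s2$truth$activity)

  s3 <- simulateCohorts(cfgSmall, seed = 6)
  expect_false(identical(s1$cohorts[[1]]$clinical, s3$cohorts[[1]]$clinical))
})

test_that("simulated clinical tables satisfy the survival invariants", {
  sim <- simulateCohorts(cfgSmall, seed = 9)
  for (co in sim$cohorts) {
    clin <- co$clinical
    expect_true(all(clin$os_time > 0))
    expect_true(all(clin$os_event %in% c(0, 1)))
    # administrative censoring close to the configured fraction
    expect_equal(mean(clin$os_event == 0), cfgSmall$censoringFraction,
                 tolerance = 0.05)
  }
})

test_that("cohort baseline shifts preserve ranks and hence enrichment scores", {
  sim <- simulateCohorts(cfgSmall, seed = 11)
  sets <- simSignatureCollection(cfgSmall)
  m <- sim$cohorts[[1]]$expression
  shifted <- ExpressionMatrix(exprValues(m) + 5, scale = "log2",
                              unit = "intensity")
  expect_equal(enrichES(ssgseaScore(shifted, sets)),
               enrichES(ssgseaScore(m, sets)), tolerance = 1e-12)
})

test_that("planted survival effects point the hazard the right way", {
  cfg <- simConfig(nCohorts = 1, samplesPerCohort = 400, nGenes = 300,
                   nSignatures = 8, genesPerSignature = 10,
                   nProtective = 2, nRisk = 1, seed = 2)
  sim <- simulateCohorts(cfg)
  clin <- sim$cohorts[[1]]$clinical
  A <- sim$truth$activity[[1]]
  # high protective activity -> longer observed survival on average
  protAct <- rowSums(A[, sim$truth$protective, drop = FALSE])
  f <- fitCoxUnivariate(setNames(protAct, clin$sample_id), clin)
  expect_lt(f$hr, 1)
  riskAct <- A[, sim$truth$risk[1]]
  f2 <- fitCoxUnivariate(setNames(riskAct, clin$sample_id), clin)
  expect_gt(f2$hr, 1)
})

test_that("null-signature Cox p-values are uniform", {
  cfg <- simConfig(nCohorts = 1, samplesPerCohort = 60, nGenes = 400,
                   nSignatures = 20, genesPerSignature = 10,
                   nProtective = 0, nRisk = 0, seed = 1)
  sets <- simSignatureCollection(cfg)
  ps <- unlist(lapply(1:25, function(r) {
    sim <- simulateCohorts(cfg, seed = 1000 + r)
    nes <- normalizeNES(ssgseaScore(sim$cohorts[[1]]$expression, sets))
    coxScreen(list(cohort1 = nes),
              list(cohort1 = sim$cohorts[[1]]$clinical))$p
  }))
  expect_gte(length(ps), 500)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("response labels carry the configured separation", {
  cfg <- simConfig(nCohorts = 1, samplesPerCohort = 500, nGenes = 120,
                   nSignatures = 6, genesPerSignature = 10,
                   nProtective = 2, nRisk = 1, seed = 3)
  sim <- simulateCohorts(cfg)
  huge <- simulateResponse(sim$truth, separation = 50, seed = 4)
  expect_gte(rocAuc(huge$true_score, huge$response)$auc, 0.99)
  expect_error(simulateResponse(sim$truth, separation = -1), ">= 0")
})

test_that("segment construction plants altered fractions exactly", {
  tg <- data.frame(sample_id = c("a", "b", "c"),
                   fgg = c(0.25, 0, 0.1), fgl = c(0.25, 0, 0.4))
  sim <- simulateSegments(targets = tg)
  gf <- genomeAlteredFractions(sim$segments)
  expect_equal(gf$fgg, sim$targets$fgg, tolerance = 1e-12)
  expect_equal(gf$fgl, sim$targets$fgl, tolerance = 1e-12)
  expect_equal(gf$fga[gf$sample_id == "a"], 0.5, tolerance = 1e-12)
  expect_equal(gf$fga[gf$sample_id == "b"], 0)

  rnd <- simulateSegments(nSamples = 50, seed = 8)
  gr <- genomeAlteredFractions(rnd$segments)
  gr <- gr[match(rnd$targets$sample_id, gr$sample_id), ]
  expect_equal(gr$fgg, rnd$targets$fgg, tolerance = 1e-12)
  expect_equal(gr$fgl, rnd$targets$fgl, tolerance = 1e-12)

  expect_error(simulateSegments(targets = data.frame(
    sample_id = "x", fgg = 0.7, fgl = 0.5)), "<= 1")
})

test_that("recovery evaluation counts hits, nulls and sign agreement", {
  sim <- simulateCohorts(cfgSmall, seed = 12)
  perfect <- SignatureSelection(protective = sim$truth$protective,
                                risk = sim$truth$risk)
  r <- evaluateRecovery(perfect, sim$truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$false_selection_rate, 0)
  expect_equal(r$sign_accuracy, 1)

  empty <- SignatureSelection()
  r0 <- evaluateRecovery(empty, sim$truth)
  expect_equal(r0$sensitivity, 0)
  expect_true(is.na(r0$sign_accuracy))

  flipped <- SignatureSelection(protective = sim$truth$risk,
                                risk = sim$truth$protective)
  expect_equal(evaluateRecovery(flipped, sim$truth)$sign_accuracy, 0)
})
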