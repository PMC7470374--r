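test_that("cohort generation is bit-identical under a fixed seed and config", {
  c1 <- generateCohort(simulationConfig(nSamples = 40, seed = 3))
  c2 <- generateCohort(simulationConfig(nSamples = 40, seed = 3))
  expect_identical(panelMatrix(c1), panelMatrix(c2))
  expect_identical(trueScores(c1, "ROR_PT"), trueScores(c2, "ROR_PT"))
  expect_identical(trueScores(c1, "mammaprint"), trueScores(c2, "mammaprint"))
  c3 <- generateCohort(simulationConfig(nSamples = 40, seed = 4))
  expect_false(identical(panelMatrix(c1), panelMatrix(c3)))
})

test_that("generated cohorts satisfy the container invariants", {
  coh <- refCohort()
  m <- panelMatrix(coh)
  expect_true(all(m > 0))
  expect_true(all(apply(m, 2, sd) > 0))
  for (k in c("ROR", "ROR_P", "ROR_PT", "RS")) {
    v <- trueScores(coh, k)
    expect_true(all(v >= 0 & v <= 100))
  }
  sz <- tumourSize(coh)
  expect_true(all(sz > 0))
  expect_true(any(sz > 2) && any(sz <= 2))   # both indicator classes occur
  expect_setequal(unique(trueScores(coh, "mammaprint")), c("low", "high"))
})

test_that("factor perturbation is seeded, positive, and identity at zero", {
  base <- baseScalingFactors()
  cfg0 <- simulationConfig(centeringShiftSd = 0, scalingMultRange = c(1, 1))
  expect_equal(perturbFactors(base, cfg0), base)
  cfg <- simulationConfig(seed = 9)
  p1 <- perturbFactors(base, cfg)
  p2 <- perturbFactors(base, cfg)
  expect_identical(p1, p2)
  expect_true(all(scaling(p1) > 0))
  expect_false(identical(centering(p1), centering(base)))
})

test_that("config validation rejects invalid study conditions", {
  expect_error(simulationConfig(nSamples = 5), "nSamples")
  expect_error(simulationConfig(subtypeProportions = c(a = 1, b = 1, c = 0, d = 0)),
               "sum")
  expect_error(simulationConfig(expressionNoiseSd = -1), "noise")
  expect_error(simulationConfig(scalingMultRange = c(-0.1, 1)), "positive|ordered")
})

test_that("closed loop: with no perturbation or score noise the untrained fit matches truth", {
  coh <- cleanCohort()
  lg <- prosignaLogMatrix(coh)
  res <- alternatingOptimization(
    lg, unname(tumourSize(coh)),
    unname(trueScores(coh, "ROR_P")), unname(trueScores(coh, "ROR_PT")),
    init = untrainedInit(lg), nIterations = 0)
  pred <- scores(applyTrained(res, coh))
  truth <- trueScores(coh, "ROR_PT")
  expect_gt(cor(pred, truth), 0.995)
  expect_lt(mean((pred - truth)^2), 1)
})

test_that("GSTM1 is bimodal with roughly half the cohort below background", {
  lg <- normalizeHousekeeping(panelMatrix(refCohort()), loadPanel("oncotype"))
  frac_low <- mean(lg[, "GSTM1"] < loadMetageneModel()@gstm1Background)
  expect_gt(frac_low, 0.3)
  expect_lt(frac_low, 0.7)
})

test_that("score noise degrades the achievable training-set fit", {
  fit_r <- function(noise) {
    coh <- generateCohort(simulationConfig(seed = 21, scoreNoiseSd = noise))
    lg <- prosignaLogMatrix(coh)
    res <- alternatingOptimization(
      lg, unname(tumourSize(coh)),
      unname(trueScores(coh, "ROR_P")), unname(trueScores(coh, "ROR_PT")),
      init = untrainedInit(lg), nIterations = 1,
      control = list(maxit = 400))
    pred <- scores(applyTrained(res, coh))
    cor(pred, trueScores(coh, "ROR_PT"))
  }
  expect_gt(fit_r(0), fit_r(8))
})
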