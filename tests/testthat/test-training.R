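test_that("cohort splitting is a seeded 50:50 partition", {
  ids <- sprintf("P%03d", 1:274)
  sp <- splitCohort(ids, seed = 7)
  expect_length(trainIds(sp), 137)
  expect_length(validationIds(sp), 137)
  expect_setequal(c(trainIds(sp), validationIds(sp)), ids)
  expect_identical(splitCohort(ids, seed = 7), sp)
  sp11 <- splitCohort(ids[1:11], seed = 1)
  expect_true(abs(length(trainIds(sp11)) - length(validationIds(sp11))) <= 1)
  expect_error(splitCohort("one"), "2 samples")
})

test_that("the untrained initialization is the per-gene mean and SD", {
  genes <- reporterGenes(loadPanel("prosigna"))
  x <- matrix(0, 2, 46, dimnames = list(NULL, genes))
  x[, 1] <- c(1, 3)
  f <- untrainedInit(x)
  expect_equal(unname(centering(f)[genes[1]]), 2)
  expect_equal(unname(scaling(f)[genes[1]]), sd(c(1, 3)))
  # constant genes get the floored scaling, not an error
  expect_equal(unname(scaling(f)[genes[2]]), 1e-8)
  expect_error(untrainedInit(x[1, , drop = FALSE]), "2 training samples")
})

test_that("rescale fitting is exact least squares", {
  expect_equal(fitRescale(c(0, 1, 2), c(5, 7, 9)), c(offset = 5, slope = 2))
  expect_equal(fitRescale(c(0, 1, 2), c(1, 3, 5)), c(offset = 1, slope = 2))
  expect_equal(fitRescale(c(3, 7, 11), c(3, 7, 11)), c(offset = 0, slope = 1))
  expect_error(fitRescale(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(fitRescale(c(1, 2), c(1, 2)), "3 samples")
})

test_that("the training objective trace is non-increasing", {
  coh <- recoveryCohort()
  sp <- splitCohort(sampleIds(coh), seed = 2)
  lg <- prosignaLogMatrix(coh)
  tr <- sampleIds(coh) %in% trainIds(sp)
  res <- alternatingOptimization(
    lg[tr, ], unname(tumourSize(coh))[tr],
    unname(trueScores(coh, "ROR_P"))[tr], unname(trueScores(coh, "ROR_PT"))[tr],
    init = untrainedInit(lg[tr, ]), nIterations = 4,
    control = list(maxit = 800))
  mse <- iterationTrace(res)$train_mse
  expect_true(all(diff(mse) <= 1e-6))
  assign("recoveryShortFit", res, envir = .fixtures)
  assign("recoveryShortSplit", sp, envir = .fixtures)
})

test_that("iteration 0 equals the untrained factors plus a fitted rescale", {
  coh <- cleanCohort()
  lg <- prosignaLogMatrix(coh)
  sz <- unname(tumourSize(coh))
  init <- untrainedInit(lg)
  res <- alternatingOptimization(lg, sz,
    unname(trueScores(coh, "ROR_P")), unname(trueScores(coh, "ROR_PT")),
    init = init, nIterations = 0)
  expect_equal(res@model$factors, init)
  ctx <- surrosig:::prosignaContext(lg, sz)
  raw <- surrosig:::prosignaRaw(ctx, unname(centering(init)),
                                unname(scaling(init)))$ROR_PT
  rc <- fitRescale(raw, unname(trueScores(coh, "ROR_PT")))
  expect_equal(res@rescale$ROR_PT, rc)
  # the modelling pipeline coincides with iteration-0 scoring when the same
  # normalization, factors and rescale are used
  x <- panelMatrix(coh)
  lgG <- globalNormalize(x)
  fG <- surrosig:::cohortFactors(lgG, reporterGenes(loadPanel("prosigna")))
  ctxG <- surrosig:::prosignaContext(lgG, sz)
  rawG <- surrosig:::prosignaRaw(ctxG, unname(centering(fG)),
                                 unname(scaling(fG)))$ROR_PT
  rcG <- surrosig:::minmaxRescale(rawG)
  expect_equal(unname(scores(signatureLike(coh, "prosigna", kind = "ROR_PT"))),
               unname(rescaleTruncate(rawG, rcG$offset, rcG$slope)),
               tolerance = 1e-12)
})

test_that("cross-validation partitions the training set and caps the iteration", {
  coh <- generateCohort(simulationConfig(nSamples = 60, seed = 13,
                                         scoreNoiseSd = 8))
  lg <- prosignaLogMatrix(coh)
  sz <- unname(tumourSize(coh))
  cv <- selectIterationsCV(lg, sz,
    unname(trueScores(coh, "ROR_P")), unname(trueScores(coh, "ROR_PT")),
    k = 5, maxIterations = 3, seed = 17, control = list(maxit = 300))
  expect_true(cv$chosenIteration >= 0 && cv$chosenIteration <= 3)
  expect_identical(dim(cv$foldTraces), c(4L, 5L))
  expect_false(anyNA(cv$foldTraces))
  # the chosen iteration is never worse than the untrained iteration 0
  expect_lte(cv$meanTestMse[cv$chosenIteration + 1], cv$meanTestMse[1])
  assign("noisyCv", cv, envir = .fixtures)
})

test_that("no validation sample influences any fitted parameter", {
  coh <- refCohort()
  sp <- splitCohort(sampleIds(coh), seed = 2)
  va <- validationIds(sp)
  # permute the validation samples' data among themselves
  cohPerm <- coh
  set.seed(99)
  perm <- sample(va)
  m <- SummarizedExperiment::assay(cohPerm, "counts")
  m[, va] <- m[, perm]
  SummarizedExperiment::assay(cohPerm, "counts") <- m
  cd <- SummarizedExperiment::colData(cohPerm)
  cd[va, ] <- cd[perm, ]
  SummarizedExperiment::colData(cohPerm) <- cd

  f1 <- trainOncotype(coh, sp)
  f2 <- trainOncotype(cohPerm, sp)
  expect_equal(f1@model$weights, f2@model$weights, tolerance = 1e-12)

  m1 <- trainMammaprint(coh, sp, seed = 4)
  m2 <- trainMammaprint(cohPerm, sp, seed = 4)
  expect_equal(m1@model$beta, m2@model$beta, tolerance = 1e-12)
  expect_identical(m1@model$penalty, m2@model$penalty)

  lg1 <- prosignaLogMatrix(coh)[trainIds(sp), ]
  lg2 <- prosignaLogMatrix(cohPerm)[trainIds(sp), ]
  expect_identical(lg1, lg2)   # housekeeping normalization is per-sample
})

test_that("oncotype refit recovers the generative weights exactly without noise", {
  coh <- generateCohort(simulationConfig(nSamples = 150, seed = 7,
                                         scoreNoiseSd = 0))
  fit <- trainOncotype(coh)
  m0 <- loadMetageneModel("cohort")
  slope <- surrosig:::truthRescale("oncotype")$slope
  recovered <- fit@model$weights[names(m0@weights)] / slope
  expect_equal(unname(recovered), unname(m0@weights), tolerance = 1e-6)
  # and reproduces the true scores themselves
  pred <- scores(applyTrained(fit, coh))
  expect_equal(unname(pred), unname(trueScores(coh, "RS")), tolerance = 1e-6)
  # a duplicated metagene column is flagged as collinear
  lg <- normalizeHousekeeping(panelMatrix(coh), loadPanel("oncotype"))
  m2 <- m0
  m2@definitions$her2 <- m2@definitions$proliferation
  m2@weights["her2"] <- m2@weights["proliferation"]
  expect_error(trainOncotype(panelMatrix(coh),
                             trueRs = unname(trueScores(coh, "RS")),
                             model0 = m2), "collinear")
})

test_that("ridge training is deterministic and shrinks with the penalty", {
  coh <- generateCohort(simulationConfig(nSamples = 120, seed = 19))
  f1 <- trainMammaprint(coh, seed = 4)
  f2 <- trainMammaprint(coh, seed = 4)
  expect_identical(f1@model$penalty, f2@model$penalty)
  expect_identical(f1@model$beta, f2@model$beta)
  tr <- iterationTrace(f1)
  # coefficient norm grows monotonically as the penalty decreases
  expect_true(all(diff(tr$coef_norm) > 0))
  expect_lt(tr$coef_norm[1], 0.1)   # heavy penalty shrinks towards zero
  expect_error(trainMammaprint(coh, labels = rep("high", 120)), "both risk classes")
})

test_that("frozen models are pure and reproduce their fitted training scores", {
  coh <- recoveryCohort()
  res <- .fixtures$recoveryShortFit
  sp <- .fixtures$recoveryShortSplit
  skip_if(is.null(res))
  p1 <- applyTrained(res, coh)
  p2 <- applyTrained(res, coh)
  expect_identical(scores(p1), scores(p2))
  expect_true(all(scores(p1) >= 0 & scores(p1) <= 100))
  # applying to the training split reproduces the final trace MSE
  tr <- trainIds(sp)
  mseApply <- mean((scores(p1)[tr] - trueScores(coh, "ROR_PT")[tr])^2)
  res2 <- alternatingOptimization(
    prosignaLogMatrix(coh)[tr, ], unname(tumourSize(coh)[tr]),
    unname(trueScores(coh, "ROR_P")[tr]), unname(trueScores(coh, "ROR_PT")[tr]),
    init = untrainedInit(prosignaLogMatrix(coh)[tr, ]), nIterations = 0,
    objectiveMode = "ror_pt")
  expect_lt(mseApply, iterationTrace(res2)$train_mse[1])   # trained beats untrained
})
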