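test_that("regression metrics match hand-computed least squares", {
  expect_equal(regressionMetrics(1:5, 1:5),
               list(pearson_r = 1, slope = 1, intercept = 0, n = 5L))
  # a constructed exact linear relationship is recovered to printed precision
  true <- c(5, 12, 20, 28, 40, 55)
  est <- 1.26 + 1.95 * true
  rm <- regressionMetrics(est, true)
  expect_equal(rm$slope, 1.95, tolerance = 1e-12)
  expect_equal(rm$intercept, 1.26, tolerance = 1e-12)
  expect_equal(rm$pearson_r, 1)
  # 4-point dataset against the normal equations
  x <- c(0, 1, 2, 4); y <- c(1, 2, 2, 5)
  rm2 <- regressionMetrics(y, x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(rm2$intercept, beta[1], tolerance = 1e-12)
  expect_equal(rm2$slope, beta[2], tolerance = 1e-12)
  expect_error(regressionMetrics(c(1, 1, 1), 1:3), "zero variance")
  expect_error(regressionMetrics(1:2, 1:2), "3 samples")
})

test_that("r^2 equals the product of the two regression slopes", {
  set.seed(8)
  a <- rnorm(30); b <- 0.6 * a + rnorm(30, sd = 0.5)
  sab <- regressionMetrics(a, b)$slope
  sba <- regressionMetrics(b, a)$slope
  expect_equal(sab * sba, cor(a, b)^2, tolerance = 1e-12)
})

test_that("concordance tables count diagonal agreement and direction", {
  a <- c(rep("low", 45), rep("high", 55))
  b <- c(rep("low", 40), rep("high", 5), rep("low", 10), rep("high", 45))
  ct <- concordanceTable(a, b, "binary")
  expect_equal(unname(ct$crosstab), rbind(c(40, 5), c(10, 45)), ignore_attr = TRUE)
  expect_equal(ct$concordance, 0.85)
  expect_equal(ct$frac_lower + ct$frac_higher + ct$concordance, 1)
  # single low-vs-high disagreement in ten
  a3 <- c(rep("low", 5), rep("high", 5))
  b3 <- a3; b3[1] <- "high"
  ct3 <- concordanceTable(a3, b3, "ternary")
  expect_equal(ct3$frac_lower, 0.1)
  expect_equal(ct3$frac_higher, 0)
  # identical labels are fully concordant
  ct4 <- concordanceTable(a3, a3, "ternary")
  expect_equal(ct4$concordance, 1)
  expect_true(all(ct4$crosstab[upper.tri(ct4$crosstab) |
                               lower.tri(ct4$crosstab)] == 0))
  # symmetry of the diagonal statistic
  expect_equal(concordanceTable(b, a, "binary")$concordance, ct$concordance)
  expect_error(concordanceTable(c("low", "mid"), c("low", "low"), "binary"),
               "outside scheme")
  expect_error(concordanceTable("low", c("low", "low"), "binary"), "mismatch")
})

test_that("study reports follow the all-samples / validation-only convention", {
  coh <- refCohort()
  sp <- splitCohort(sampleIds(coh), seed = 2)
  like <- list(prosigna = signatureLike(coh, "prosigna", kind = "ROR_P"),
               mammaprint = signatureLike(coh, "mammaprint"))
  onc <- trainOncotype(coh, sp)
  trained <- list(oncotype = applyTrained(onc, coh))
  reps <- buildReport(coh, sp, like = like, trained = trained)
  expect_equal(reps$prosigna_like@n, length(sampleIds(coh)))
  expect_equal(reps$oncotype_trained@n, length(validationIds(sp)))
  # trained cross-tabs still use every sample
  expect_equal(sum(reps$oncotype_trained@crosstabTernary),
               length(sampleIds(coh)))
  # MammaPrint reports concordance only
  expect_true(is.na(reps$mammaprint_like@pearsonR))
  expect_true(is.na(reps$mammaprint_like@slope))
  expect_false(is.na(reps$mammaprint_like@concordanceBinary))
  tab <- reportTable(reps)
  expect_identical(nrow(tab), 3L)
  r <- reps$oncotype_trained
  expect_equal(r@fracLower + r@fracHigher + r@concordanceTernary, 1)
})
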