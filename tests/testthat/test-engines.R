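panel46 <- loadPanel("prosigna")

test_that("housekeeping normalization is the log2 ratio to the geometric mean", {
  hk <- housekeepingGenes(panel46)
  genes <- c(reporterGenes(panel46), hk)
  x <- matrix(1, 2, length(genes), dimnames = list(c("a", "b"), genes))
  # sample a: housekeepers 2 and 8 alternating (geo-mean 4), one reporter 16
  x["a", hk] <- rep(c(2, 8), 4)
  x["a", "ESR1"] <- 16
  lg <- normalizeHousekeeping(x, panel46)
  expect_equal(lg["a", "ESR1"], log2(16 / 4))
  # reporters equal to the housekeeping geo-mean normalize to zero
  x["b", ] <- 6
  expect_equal(unname(normalizeHousekeeping(x, panel46)["b", "ESR1"]), 0)
  # scale invariance: doubling a sample's intensities changes nothing
  x2 <- x; x2["a", ] <- 2 * x2["a", ]
  expect_equal(normalizeHousekeeping(x2, panel46)["a", ],
               normalizeHousekeeping(x, panel46)["a", ])
  expect_error(normalizeHousekeeping(x * 0, panel46), "positive")
  expect_error(normalizeHousekeeping(x[, reporterGenes(panel46)], panel46),
               "missing")
})

test_that("row-scaling applies (value - centering) / scaling per gene", {
  genes <- reporterGenes(panel46)
  x <- matrix(5, 1, 46, dimnames = list("s", genes))
  f <- new("ScalingFactors", geneIds = genes,
           centering = rep(1, 46), scaling = rep(2, 46))
  expect_equal(unname(rowScale(x, f)[1, 1]), (5 - 1) / 2)
  # a gene at its centering value scales to 0
  f0 <- new("ScalingFactors", geneIds = genes,
            centering = rep(5, 46), scaling = rep(2, 46))
  expect_true(all(rowScale(x, f0) == 0))
  # data-derived factors standardize each gene
  set.seed(1)
  xm <- matrix(rnorm(20 * 46, 3, 2), 20, dimnames = list(NULL, genes))
  fd <- untrainedInit(xm)
  z <- rowScale(xm, fd)
  expect_equal(unname(colMeans(z)), rep(0, 46), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 46), tolerance = 1e-12)
  expect_error(new("ScalingFactors", geneIds = genes,
                   centering = rep(0, 46), scaling = rep(-1, 46)))
})

test_that("subtype correlations match the textbook Pearson formula", {
  cen <- loadCentroids()
  # a sample equal to a centroid correlates 1 with it, -1 when negated
  x <- matrix(cen@values[, "LumA"], 1, 46,
              dimnames = list("s", rownames(cen@values)))
  expect_equal(unname(subtypeCorrelations(x, cen)[1, "LumA"]), 1)
  xb <- matrix(-cen@values[, "Basal"], 1, 46,
               dimnames = list("s", rownames(cen@values)))
  expect_equal(unname(subtypeCorrelations(xb, cen)[1, "Basal"]), -1)
  set.seed(2)
  xr <- matrix(rnorm(3 * 46), 3, dimnames = list(NULL, rownames(cen@values)))
  co <- subtypeCorrelations(xr, cen)
  for (i in 1:3) for (j in 1:4) {
    a <- xr[i, ]; b <- cen@values[, j]
    brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(unname(co[i, j]), brute, tolerance = 1e-12)
  }
  expect_error(subtypeCorrelations(x * 0 + 1, cen), "zero-variance")
})

test_that("proliferation score is the mean of the 18 proliferation genes", {
  genes <- reporterGenes(panel46)
  pg <- names(roleMap(panel46))[roleMap(panel46) == "proliferation"]
  x <- matrix(0, 1, 46, dimnames = list("s", genes))
  expect_equal(unname(proliferationScore(x, panel46)), 0)
  x[1, ] <- 1.7
  expect_equal(unname(proliferationScore(x, panel46)), 1.7)
  set.seed(3)
  x[1, ] <- rnorm(46)
  expect_equal(unname(proliferationScore(x, panel46)), mean(x[1, pg]))
})

test_that("ROR variants add proliferation then the strict >2cm size indicator", {
  w <- loadRorWeights()
  co <- matrix(0, 2, 4, dimnames = list(NULL, names(w@subtypeWeights)))
  pr <- c(0.5, -1)
  expect_equal(rorScores(co, pr, w = w, variant = "ROR"), c(0, 0))
  expect_equal(rorScores(co, pr, w = w, variant = "ROR_P"),
               w@proliferationWeight * pr)
  expect_equal(rorScores(co, pr, c(2.5, 1.5), w, variant = "ROR_PT"),
               w@proliferationWeight * pr + w@sizeWeight * c(1, 0))
  # size exactly 2 cm does not trigger the indicator
  expect_equal(rorScores(co, pr, c(2, 2), w, variant = "ROR_PT"),
               w@proliferationWeight * pr)
  expect_error(rorScores(co, pr, NULL, w, variant = "ROR_PT"), "size")
})

test_that("rescaling truncates to [0, 100]", {
  expect_equal(rescaleTruncate(c(105, -3, 55), 0, 1), c(100, 0, 55))
  expect_equal(rescaleTruncate(2, 10, 20), 50)
  expect_error(rescaleTruncate(1, 0, -1), "slope")
})

test_that("metagene scores honour weights, GSTM1 background and CTSV exclusion", {
  m <- loadMetageneModel()
  genes <- reporterGenes(loadPanel("oncotype"))
  x <- matrix(0, 1, length(genes), dimnames = list("s", genes))
  # ER group members all at v give v (weights normalized by their sum)
  x[1, c("ESR1", "PGR", "BCL2", "SCUBE2")] <- 3
  mg <- metageneScores(x, m)
  expect_equal(unname(mg[1, "er"]), 3)
  # GSTM1 below background contributes the background level
  xg <- x; xg[1, "GSTM1"] <- -1
  expect_equal(unname(metageneScores(xg, m, background = c(GSTM1 = 0))[1, "gstm1"]), 0)
  expect_equal(unname(metageneScores(xg, m, background = c(GSTM1 = -2))[1, "gstm1"]), -1)
  # invasion reduces to MMP11 alone when CTSV is excluded
  xi <- x; xi[1, "MMP11"] <- 2; xi[1, "CTSV"] <- 9
  expect_equal(unname(metageneScores(xi, m)[1, "invasion"]), 2)
  m2 <- m; m2@ctsl2Excluded <- FALSE
  expect_equal(unname(metageneScores(xi, m2)[1, "invasion"]), (2 + 9) / 2)
})

test_that("the recurrence score is the rescaled weighted metagene sum", {
  m <- loadMetageneModel()
  mg <- matrix(0, 1, length(m@weights), dimnames = list("s", names(m@weights)))
  expect_equal(recurrenceScore(mg, m),
               min(max(m@rescaleOffset, 0), 100))
  set.seed(4)
  mg[1, ] <- rnorm(length(m@weights))
  hand <- m@rescaleOffset + m@rescaleSlope * sum(m@weights * mg[1, names(m@weights)])
  expect_equal(recurrenceScore(mg, m), min(max(hand, 0), 100))
  expect_error(recurrenceScore(mg[, -1, drop = FALSE], m), "missing")
})

test_that("gene70 index is the template correlation with the packaged cutoff", {
  t70 <- loadGene70Template()
  x <- matrix(t70@values, 1, 70, dimnames = list("s", t70@genes))
  r <- gene70Index(x, t70)
  expect_equal(unname(scores(r)), 1)
  expect_equal(unname(categories(r)), "low")
  rn <- gene70Index(-x, t70)
  expect_equal(unname(scores(rn)), -1)
  expect_equal(unname(categories(rn)), "high")
  set.seed(5)
  xr <- matrix(rnorm(70), 1, dimnames = list("s", t70@genes))
  expect_equal(unname(scores(gene70Index(xr, t70))),
               cor(xr[1, ], t70@values), tolerance = 1e-12)
})

test_that("engines are pure and ROR increases with proliferation", {
  coh <- refCohort()
  lg <- prosignaLogMatrix(coh)
  f <- untrainedInit(lg)
  expect_identical(rowScale(lg, f), rowScale(lg, f))
  w <- loadRorWeights()
  co <- matrix(0.1, 1, 4, dimnames = list(NULL, names(w@subtypeWeights)))
  p1 <- rorScores(co, 1, 3, w, "ROR_PT")
  p2 <- rorScores(co, 2, 3, w, "ROR_PT")
  expect_gt(p2, p1)   # proliferationWeight > 0
})
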