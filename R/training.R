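#' @include AllClasses.R AllGenerics.R panels.R engines.R modelling.R
NULL

#' Split a cohort 50:50 into training and validation sets
#'
#' Uniform random partition, seeded; set sizes differ by at most one.
#'
#' @param ids sample identifiers.
#' @param seed integer seed.
#' @return a \linkS4class{SplitSpec}.
#' @export
splitCohort <- function(ids, seed = 1L) {
  if (length(ids) < 2L) stop("at least 2 samples required to split")
  set.seed(as.integer(seed))
  tr <- sort(sample(length(ids), ceiling(length(ids) / 2)))
  methods::new("SplitSpec", trainIds = ids[tr], validationIds = ids[-tr],
               seed = as.integer(seed))
}

#' Untrained row-scaling factors
#'
#' The untrained initialization of the Prosigna-trained algorithm: each
#' gene's centering factor is its mean and its scaling factor its SD in the
#' training data (SD floored at 1e-8 so degenerate genes stay usable).
#'
#' @param xTrain samples x genes log2 matrix (training split).
#' @param genes genes to produce factors for; defaults to the Prosigna
#'   reporters.
#' @return a \linkS4class{ScalingFactors}.
#' @export
untrainedInit <- function(xTrain, genes = reporterGenes(loadPanel("prosigna"))) {
  if (nrow(xTrain) < 2L) stop("at least 2 training samples required (SD undefined)")
  cohortFactors(xTrain, genes)
}

#' Fit the 0-100 linear rescale
#'
#' Ordinary least squares of the true scores on the raw surrogate scores;
#' returns the intercept (offset) and slope that minimize squared error.
#'
#' @param rawScores raw per-sample surrogate scores.
#' @param trueScores corresponding true assay scores.
#' @return named numeric \code{c(offset, slope)}.
#' @export
fitRescale <- function(rawScores, trueScores) {
  if (length(rawScores) < 3L) stop("at least 3 samples required")
  v <- stats::var(rawScores)
  if (!is.finite(v) || v <= 0) stop("raw scores have zero variance")
  slope <- stats::cov(rawScores, trueScores) / v
  c(offset = mean(trueScores) - slope * mean(rawScores), slope = slope)
}

predictRescale <- function(raw, rc) {
  pmin(pmax(rc[["offset"]] + rc[["slope"]] * raw, 0), 100)
}

# Precomputed structures for fast objective evaluations. The expression is
# stored genes x samples so candidate factor vectors recycle down columns
# without allocation; the centroid columns are pre-centered, which lets the
# correlation numerator skip per-sample centering entirely (a centered
# centroid is orthogonal to the constant gene vector).
prosignaContext <- function(lg, tumourSizeCm) {
  panel <- loadPanel("prosigna")
  centroids <- loadCentroids()
  genes <- reporterGenes(panel)
  checkGenesPresent(lg, genes, "Prosigna reporter")
  w <- loadRorWeights()
  list(Xt = t(lg[, genes, drop = FALSE]),
       genes = genes,
       G = length(genes),
       Cstd = standardizeCentroids(centroids),
       subtypeNames = colnames(centroids@values),
       prolifIdx = which(roleMap(panel)[genes] == "proliferation"),
       sizeInd = as.numeric(tumourSizeCm > 2),
       sw = unname(w@subtypeWeights[colnames(centroids@values)]),
       wp = w@proliferationWeight,
       wt = w@sizeWeight,
       n = nrow(lg))
}

# Raw ROR / ROR-P / ROR-PT given candidate factors; the optimizer's inner loop.
prosignaRaw <- function(ctx, centering, scaling) {
  Yt <- (ctx$Xt - centering) / scaling             # genes x samples
  cm <- colMeans(Yt)
  den2 <- colSums(Yt * Yt) - ctx$G * cm * cm
  bad <- den2 <= 0
  den <- sqrt(ifelse(bad, 1, den2))
  co <- crossprod(Yt, ctx$Cstd) / den              # Pearson across genes
  if (any(bad)) co[bad, ] <- 0
  pr <- colMeans(Yt[ctx$prolifIdx, , drop = FALSE])
  ror <- as.numeric(co %*% ctx$sw)
  rorP <- ror + ctx$wp * pr
  list(ROR = ror, ROR_P = rorP, ROR_PT = rorP + ctx$wt * ctx$sizeInd,
       correlations = co)
}

# Objective: refit the 0-100 rescale for ROR-P and ROR-PT separately at every
# evaluation, truncate, and return the mean of the two MSEs ("both", the
# figure convention) or the ROR-PT MSE alone ("ror_pt").
prosignaObjective <- function(ctx, centering, scaling, trueP, truePT,
                              mode = "both", returnFits = FALSE) {
  raw <- prosignaRaw(ctx, centering, scaling)
  msePT <- NULL
  rcPT <- fitRescale(raw$ROR_PT, truePT)
  msePT <- mean((predictRescale(raw$ROR_PT, rcPT) - truePT)^2)
  if (mode == "ror_pt") {
    out <- msePT
    rcP <- NULL
    mseP <- NA_real_
  } else {
    rcP <- fitRescale(raw$ROR_P, trueP)
    mseP <- mean((predictRescale(raw$ROR_P, rcP) - trueP)^2)
    out <- (mseP + msePT) / 2
  }
  if (!returnFits) return(out)
  list(mse = out, mseP = mseP, msePT = msePT, rcP = rcP, rcPT = rcPT, raw = raw)
}

#' Alternating optimization of centering and scaling factors
#'
#' Starting from the untrained initialization, iterates between optimizing
#' the 46 scaling factors (holding centering fixed; optimized on the log
#' scale to enforce positivity) and the 46 centering factors (holding
#' scaling fixed), using derivative-free simplex search. Every objective
#' evaluation recomputes the subtype correlations and proliferation score,
#' refits the 0-100 linear rescale for ROR-P and ROR-PT separately, and
#' scores the mean of the two truncated-prediction MSEs against the true
#' scores (\code{objectiveMode = "both"}, the default) or the ROR-PT MSE
#' alone (\code{"ror_pt"}). Iteration 0 is the initialization with fitted
#' rescale only.
#'
#' @param lg samples x genes log2 (housekeeping-normalized) training matrix.
#' @param tumourSizeCm per-sample tumour sizes (cm).
#' @param trueRorP,trueRorPT true scores to calibrate against.
#' @param init \linkS4class{ScalingFactors} initialization.
#' @param nIterations number of full iterations (>= 0).
#' @param objectiveMode \code{"both"} or \code{"ror_pt"}.
#' @param trueRor optional true ROR scores; when given, a rescale for the
#'   subtype-only ROR is also fitted at the final factors.
#' @param evalFun optional function(centering, scaling) evaluated after
#'   iteration 0 and after each full iteration (used by cross-validation to
#'   record held-out performance); its value is stored in the trace.
#' @param control passed to \code{\link[stats]{optim}} (Nelder-Mead);
#'   defaults to relative tolerance 1e-8 and a budget of 2000 objective
#'   evaluations per half-iteration.
#' @return a \linkS4class{TrainingResult} with the fitted factors, fitted
#'   rescales, and the per-iteration objective trace.
#' @export
alternatingOptimization <- function(lg, tumourSizeCm, trueRorP, trueRorPT,
                                    init, nIterations = 20L,
                                    objectiveMode = c("both", "ror_pt"),
                                    trueRor = NULL, evalFun = NULL,
                                    control = list()) {
  objectiveMode <- match.arg(objectiveMode)
  if (nIterations < 0L) stop("nIterations must be >= 0")
  ctx <- prosignaContext(lg, tumourSizeCm)
  if (length(trueRorPT) != ctx$n || length(trueRorP) != ctx$n)
    stop("true scores must align with the training samples")
  ctrl <- utils::modifyList(list(reltol = 1e-8, maxit = 2000L), control)
  cen <- unname(centering(init)[ctx$genes])
  sca <- unname(scaling(init)[ctx$genes])
  if (anyNA(cen) || anyNA(sca)) stop("init factors must cover the Prosigna genes")

  obj <- function(cn, sc) prosignaObjective(ctx, cn, sc, trueRorP, trueRorPT,
                                            mode = objectiveMode)
  mse <- obj(cen, sca)
  if (!is.finite(mse)) stop("non-finite objective at initialization")
  trace <- data.frame(iteration = 0L, train_mse = mse)
  if (!is.null(evalFun)) trace$test_mse <- evalFun(cen, sca)

  it <- 0L
  while (it < nIterations) {
    it <- it + 1L
    # scaling half-step (log scale), centering held
    fitS <- stats::optim(log(sca), function(ls) obj(cen, exp(ls)),
                         method = "Nelder-Mead", control = ctrl)
    if (fitS$value <= mse) {
      sca <- exp(fitS$par); mse <- fitS$value
    }
    # centering half-step, scaling held
    fitC <- stats::optim(cen, function(cn) obj(cn, sca),
                         method = "Nelder-Mead", control = ctrl)
    if (fitC$value <= mse) {
      cen <- fitC$par; mse <- fitC$value
    }
    row <- data.frame(iteration = it, train_mse = mse)
    if (!is.null(evalFun)) row$test_mse <- evalFun(cen, sca)
    trace <- rbind(trace, row)
  }

  fits <- prosignaObjective(ctx, cen, sca, trueRorP, trueRorPT,
                            mode = "both", returnFits = TRUE)
  rescale <- list(ROR_P = fits$rcP, ROR_PT = fits$rcPT)
  if (!is.null(trueRor)) {
    raw <- prosignaRaw(ctx, cen, sca)
    rescale$ROR <- fitRescale(raw$ROR, trueRor)
  }
  factors <- methods::new("ScalingFactors", geneIds = ctx$genes,
                          centering = cen, scaling = sca)
  methods::new("TrainingResult", assayName = "prosigna",
    model = list(factors = factors, objectiveMode = objectiveMode),
    rescale = rescale, iterationTrace = trace,
    chosenIteration = as.integer(nIterations), seeds = list())
}

#' Choose the number of optimization iterations by k-fold cross-validation
#'
#' Splits the training set into k seeded folds; for each fold, runs the
#' alternating optimization on the 4/5 complement (initialized from that
#' complement's own means/SDs) and records held-out MSE after iteration 0
#' and after each of \code{maxIterations} iterations, applying the
#' complement-fitted rescale to the held-out samples. The chosen iteration
#' minimizes the mean held-out MSE (ties broken toward fewer iterations).
#'
#' @inheritParams alternatingOptimization
#' @param k number of folds.
#' @param maxIterations iterations to explore (default 20).
#' @param seed fold-assignment seed.
#' @return list with \code{chosenIteration}, the per-fold held-out traces
#'   (\code{foldTraces}, iterations x folds) and their mean
#'   (\code{meanTestMse}).
#' @export
selectIterationsCV <- function(lg, tumourSizeCm, trueRorP, trueRorPT,
                               k = 5L, maxIterations = 20L, seed = 1L,
                               objectiveMode = c("both", "ror_pt"),
                               control = list()) {
  objectiveMode <- match.arg(objectiveMode)
  n <- nrow(lg)
  if (k > n) stop("more folds than training samples")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  foldTraces <- matrix(NA_real_, maxIterations + 1L, k,
                       dimnames = list(0:maxIterations, paste0("fold", 1:k)))
  for (j in seq_len(k)) {
    tr <- fold != j
    if (sum(tr) < 3L || sum(!tr) < 1L) stop("degenerate fold")
    ctxTe <- prosignaContext(lg[!tr, , drop = FALSE], tumourSizeCm[!tr])
    ctxTr <- prosignaContext(lg[tr, , drop = FALSE], tumourSizeCm[tr])
    tP <- trueRorP[tr]; tPT <- trueRorPT[tr]
    evalFun <- function(cn, sc) {
      trainFit <- prosignaObjective(ctxTr, cn, sc, tP, tPT,
                                    mode = "both", returnFits = TRUE)
      rawTe <- prosignaRaw(ctxTe, cn, sc)
      msePT <- mean((predictRescale(rawTe$ROR_PT, trainFit$rcPT) -
                       trueRorPT[!tr])^2)
      if (objectiveMode == "ror_pt") return(msePT)
      mseP <- mean((predictRescale(rawTe$ROR_P, trainFit$rcP) -
                      trueRorP[!tr])^2)
      (mseP + msePT) / 2
    }
    res <- alternatingOptimization(lg[tr, , drop = FALSE], tumourSizeCm[tr],
      tP, tPT, init = untrainedInit(lg[tr, , drop = FALSE]),
      nIterations = maxIterations, objectiveMode = objectiveMode,
      evalFun = evalFun, control = control)
    foldTraces[, j] <- iterationTrace(res)$test_mse
  }
  meanTest <- rowMeans(foldTraces)
  list(chosenIteration = as.integer(which.min(meanTest) - 1L),
       foldTraces = foldTraces, meanTestMse = meanTest)
}

#' Train the Prosigna-trained scoring model
#'
#' Full training procedure: cross-validated choice of the iteration count on
#' the training split, then the alternating optimization re-run on the
#' complete training set, stopped at the chosen iteration; factors and
#' rescales are then frozen.
#'
#' @param cohort a \linkS4class{SurrogateCohort}.
#' @param split a \linkS4class{SplitSpec}.
#' @param maxIterations iterations explored by cross-validation.
#' @param cvFolds number of CV folds.
#' @param cvSeed fold-assignment seed.
#' @param objectiveMode \code{"both"} (mean of ROR-P and ROR-PT MSEs) or
#'   \code{"ror_pt"}.
#' @param control optimizer control overrides.
#' @return a frozen \linkS4class{TrainingResult}.
#' @export
trainProsigna <- function(cohort, split, maxIterations = 20L, cvFolds = 5L,
                          cvSeed = 1L, objectiveMode = c("both", "ror_pt"),
                          control = list()) {
  objectiveMode <- match.arg(objectiveMode)
  tr <- trainIds(split)
  lg <- normalizeHousekeeping(panelMatrix(cohort), loadPanel("prosigna"))
  lgTr <- lg[tr, , drop = FALSE]
  sz <- unname(tumourSize(cohort)[tr])
  tP <- unname(trueScores(cohort, "ROR_P")[tr])
  tPT <- unname(trueScores(cohort, "ROR_PT")[tr])
  tR <- unname(trueScores(cohort, "ROR")[tr])
  cv <- selectIterationsCV(lgTr, sz, tP, tPT, k = cvFolds,
                           maxIterations = maxIterations, seed = cvSeed,
                           objectiveMode = objectiveMode, control = control)
  res <- alternatingOptimization(lgTr, sz, tP, tPT,
    init = untrainedInit(lgTr), nIterations = cv$chosenIteration,
    objectiveMode = objectiveMode, trueRor = tR, control = control)
  res@chosenIteration <- cv$chosenIteration
  res@model$cv <- cv
  res@seeds <- list(cvSeed = as.integer(cvSeed), splitSeed = split@seed)
  methods::validObject(res)
  res
}

#' Apply a frozen trained model
#'
#' Deterministic scoring with frozen parameters; nothing is re-estimated
#' from the new data. For Prosigna: housekeeping normalization, row-scaling
#' with the frozen factors, the ROR combination, the frozen rescale,
#' truncation. For Oncotype: metagene scores with the frozen handling rules
#' and the refitted weights. For MammaPrint: the frozen gene standardization
#' and ridge coefficients with a 0.5 probability threshold.
#'
#' @param model a \linkS4class{TrainingResult}.
#' @param x a \linkS4class{SurrogateCohort} or samples x genes positive
#'   intensity matrix.
#' @param tumourSizeCm per-sample tumour sizes (taken from the cohort when
#'   \code{x} is one); required for ROR-PT.
#' @param kind Prosigna score variant to emit (default \code{"ROR_PT"}).
#' @return a \linkS4class{RiskScoreSet}.
#' @export
applyTrained <- function(model, x, tumourSizeCm = NULL, kind = "ROR_PT") {
  if (methods::is(x, "SurrogateCohort")) {
    tumourSizeCm <- unname(tumourSize(x))
    x <- panelMatrix(x)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  switch(assayLabel(model),
    prosigna = {
      kind <- match.arg(kind, c("ROR_PT", "ROR_P", "ROR"))
      rc <- model@rescale[[kind]]
      if (is.null(rc)) stop("no fitted rescale for kind ", kind)
      lg <- normalizeHousekeeping(x, loadPanel("prosigna"))
      ctx <- prosignaContext(lg, if (is.null(tumourSizeCm))
        rep(NA_real_, nrow(lg)) else tumourSizeCm)
      if (kind == "ROR_PT" && anyNA(ctx$sizeInd))
        stop("tumour size required for ROR_PT")
      f <- model@model$factors
      raw <- prosignaRaw(ctx, unname(centering(f)[ctx$genes]),
                         unname(scaling(f)[ctx$genes]))[[kind]]
      newScoreSet(ids, "prosigna", kind, predictRescale(raw, rc))
    },
    oncotype = applyTrainedOncotype(model, x, ids),
    mammaprint = applyTrainedMammaprint(model, x, ids),
    stop("unknown trained model assay"))
}
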