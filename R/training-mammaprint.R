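#' @include training.R
NULL

#' Train the MammaPrint-trained ridge classifier
#'
#' Predicts the binary MammaPrint risk category from the 70 panel genes with
#' L2-penalized logistic regression. Genes are standardized on the training
#' split (means/SDs frozen into the model); the penalty is chosen by k-fold
#' cross-validation minimizing held-out misclassification, with ties broken
#' toward the larger (more regularized) penalty. The decision threshold is
#' 0.5 on the probability scale.
#'
#' @param cohort a \linkS4class{SurrogateCohort} (or samples x genes positive
#'   intensity matrix with \code{labels} supplied).
#' @param split optional \linkS4class{SplitSpec} restricting to the training
#'   split.
#' @param labels per-sample "low"/"high" labels (from the cohort when
#'   omitted).
#' @param k number of CV folds.
#' @param penaltyGrid decreasing log-spaced ridge penalty grid.
#' @param seed fold-assignment seed.
#' @return a frozen \linkS4class{TrainingResult}; the trace records per-
#'   penalty CV misclassification and coefficient norm.
#' @export
trainMammaprint <- function(cohort, split = NULL, labels = NULL, k = 5L,
                            penaltyGrid = 10^seq(2, -4, length.out = 40),
                            seed = 1L) {
  if (methods::is(cohort, "SurrogateCohort")) {
    if (is.null(labels)) labels <- unname(trueScores(cohort, "mammaprint"))
    x <- panelMatrix(cohort)
  } else {
    x <- cohort
    if (is.null(labels)) stop("labels required when not passing a cohort")
  }
  if (!is.null(split)) {
    keep <- rownames(x) %in% trainIds(split)
    labels <- labels[keep]
    x <- x[keep, , drop = FALSE]
  }
  if (length(unique(labels)) < 2L)
    stop("both risk classes must be present in the training labels")
  genes <- reporterGenes(loadPanel("mammaprint"))
  lg <- if (identical(scaleTag(x), "log2")) x else globalNormalize(x)
  checkGenesPresent(lg, genes, "MammaPrint")
  lg <- lg[, genes, drop = FALSE]
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  sd[sd < SD_FLOOR] <- SD_FLOOR
  Z <- sweep(sweep(lg, 2, mu), 2, sd, "/")
  y <- as.integer(labels == "high")

  grid <- sort(penaltyGrid, decreasing = TRUE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = nrow(Z)))
  err <- matrix(NA_real_, length(grid), k)
  for (j in seq_len(k)) {
    tr <- fold != j
    if (length(unique(y[tr])) < 2L) stop("degenerate fold: one class only")
    fit <- glmnet::glmnet(Z[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = grid, standardize = FALSE)
    p <- stats::predict(fit, Z[!tr, , drop = FALSE], type = "response",
                        s = grid, exact = FALSE)
    err[, j] <- colMeans((p > 0.5) != y[!tr])
  }
  cvErr <- rowMeans(err)
  best <- which(cvErr == min(cvErr))[1]   # grid is decreasing: first = largest
  lambda <- grid[best]

  fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0, lambda = grid,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta[, best])
  norms <- sqrt(colSums(as.matrix(fit$beta)^2))
  trace <- data.frame(penalty = grid, cv_misclass = cvErr, coef_norm = norms)
  methods::new("TrainingResult", assayName = "mammaprint",
    model = list(beta = stats::setNames(beta, genes),
                 intercept = fit$a0[[best]], penalty = lambda,
                 geneMeans = mu, geneSds = sd, threshold = 0.5),
    rescale = list(), iterationTrace = trace,
    chosenIteration = NA_integer_,
    seeds = list(cvSeed = as.integer(seed)))
}

applyTrainedMammaprint <- function(model, x, ids) {
  genes <- names(model@model$beta)
  lg <- if (identical(scaleTag(x), "log2")) x else globalNormalize(x)
  checkGenesPresent(lg, genes, "MammaPrint")
  Z <- sweep(sweep(lg[, genes, drop = FALSE], 2, model@model$geneMeans),
             2, model@model$geneSds, "/")
  eta <- model@model$intercept + as.numeric(Z %*% model@model$beta)
  p <- stats::plogis(eta)
  methods::new("RiskScoreSet", sampleIds = ids, assayName = "mammaprint",
    scoreKind = "GENE70_INDEX", score = rep(NA_real_, length(ids)),
    category = ifelse(p > model@model$threshold, "high", "low"),
    scheme = "binary")
}
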