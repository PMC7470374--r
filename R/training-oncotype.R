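#' @include training.R
NULL

oncotypeDesign <- function(lg, model) {
  metageneScores(lg, model)
}

#' Train the Oncotype-trained Recurrence Score model
#'
#' Computes the metagene scores of the training split (with the GSTM1
#' background thresholding and Cathepsin-L2 exclusion rules) from
#' housekeeping-normalized data and refits the Recurrence Score as an
#' ordinary least-squares fit of the true RS on the metagene design with an
#' intercept. The published-vs-refitted weight comparison is stored
#' alongside the frozen coefficients.
#'
#' @param cohort a \linkS4class{SurrogateCohort} (or samples x genes positive
#'   intensity matrix, in which case \code{trueRs} must be supplied).
#' @param split optional \linkS4class{SplitSpec}; when given, only the
#'   training split is used for the fit.
#' @param trueRs true Recurrence Scores (taken from the cohort when omitted).
#' @param model0 the \linkS4class{MetageneModel} providing metagene
#'   definitions, handling rules and the published weights.
#' @return a frozen \linkS4class{TrainingResult}.
#' @export
trainOncotype <- function(cohort, split = NULL, trueRs = NULL,
                          model0 = loadMetageneModel("cohort")) {
  if (methods::is(cohort, "SurrogateCohort")) {
    if (is.null(trueRs)) trueRs <- unname(trueScores(cohort, "RS"))
    x <- panelMatrix(cohort)
  } else {
    x <- cohort
    if (is.null(trueRs)) stop("trueRs required when not passing a cohort")
  }
  if (!is.null(split)) {
    keep <- rownames(x) %in% trainIds(split)
    trueRs <- trueRs[keep]
    x <- x[keep, , drop = FALSE]
  }
  lg <- normalizeHousekeeping(x, loadPanel("oncotype"))
  D <- oncotypeDesign(lg, model0)
  if (nrow(D) < ncol(D) + 2L)
    stop("insufficient samples: need at least #metagenes + 2")
  X <- cbind(`(Intercept)` = 1, D)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear metagene design: rank ", qrX$rank, " < ", ncol(X))
  beta <- qr.coef(qrX, trueRs)
  fitted <- as.numeric(X %*% beta)
  # Fig 3B-style comparison: the fitted coefficient of each metagene,
  # expressed on the published-weight scale by dividing out the fitted
  # magnitude of the linear map.
  pub <- model0@weights
  comp <- data.frame(role = names(pub), published = unname(pub),
                     fitted = unname(beta[names(pub)]), row.names = NULL)
  methods::new("TrainingResult", assayName = "oncotype",
    model = list(weights = beta[-1], intercept = unname(beta[1]),
                 weightComparison = comp, metageneModel = model0),
    rescale = list(), iterationTrace = data.frame(),
    chosenIteration = NA_integer_, seeds = list())
}

applyTrainedOncotype <- function(model, x, ids) {
  m0 <- model@model$metageneModel
  lg <- normalizeHousekeeping(x, loadPanel("oncotype"))
  D <- oncotypeDesign(lg, m0)
  pred <- model@model$intercept +
    as.numeric(D[, names(model@model$weights), drop = FALSE] %*%
                 model@model$weights)
  newScoreSet(ids, "oncotype", "RS", pmin(pmax(pred, 0), 100))
}
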