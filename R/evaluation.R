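#' @include AllClasses.R AllGenerics.R engines.R
NULL

#' Regression agreement metrics
#'
#' Pearson correlation and the OLS fit of the estimated scores on the true
#' scores, i.e. \code{estimated = intercept + slope * true}, matching the
#' direction of the reported regression equations.
#'
#' @param estimated surrogate scores.
#' @param true true assay scores.
#' @return list with \code{pearson_r}, \code{slope}, \code{intercept}, \code{n}.
#' @export
regressionMetrics <- function(estimated, true) {
  if (length(estimated) != length(true)) stop("length mismatch")
  if (length(true) < 3L) stop("at least 3 samples required")
  if (stats::var(true) <= 0 || stats::var(estimated) <= 0)
    stop("zero variance input")
  slope <- stats::cov(estimated, true) / stats::var(true)
  list(pearson_r = stats::cor(estimated, true),
       slope = slope,
       intercept = mean(estimated) - slope * mean(true),
       n = length(true))
}

schemeLevels <- function(scheme) {
  if (scheme == "ternary") c("low", "intermediate", "high") else c("low", "high")
}

#' Risk-category concordance cross-tab
#'
#' Cross-tabulates two label vectors; concordance is the diagonal fraction,
#' and the discordance-direction fractions count samples the first labelling
#' puts in a lower (resp. higher) ordinal category than the second
#' (low < intermediate < high).
#'
#' @param labelsA,labelsB category labels from the scheme's set.
#' @param scheme \code{"ternary"} or \code{"binary"}.
#' @return list with \code{crosstab}, \code{concordance}, \code{frac_lower},
#'   \code{frac_higher}.
#' @export
concordanceTable <- function(labelsA, labelsB, scheme = c("ternary", "binary")) {
  scheme <- match.arg(scheme)
  if (length(labelsA) != length(labelsB)) stop("length mismatch")
  lev <- schemeLevels(scheme)
  bad <- setdiff(unique(c(labelsA, labelsB)), lev)
  if (length(bad)) stop("labels outside scheme: ", paste(bad, collapse = ", "))
  a <- factor(labelsA, levels = lev)
  b <- factor(labelsB, levels = lev)
  tab <- table(a, b, dnn = c("a", "b"))
  n <- length(a)
  list(crosstab = unclass(tab),
       concordance = sum(diag(tab)) / n,
       frac_lower = mean(as.integer(a) < as.integer(b)),
       frac_higher = mean(as.integer(a) > as.integer(b)))
}

# One report comparing an estimated score set against the truth. For assays
# with continuous 0-100 scores the regression can be restricted to a subset
# (the validation samples) while the cross-tabs use all samples.
evaluateScores <- function(estimated, truthScores, comparison,
                           regressionIds = NULL) {
  assayName <- assayLabel(estimated)
  ids <- sampleIds(estimated)
  est <- scores(estimated)
  if (assayName == "mammaprint") {
    ct <- concordanceTable(unname(categories(estimated)[ids]),
                           unname(truthScores[ids]), "binary")
    return(methods::new("EvaluationReport", assayName = assayName,
      comparison = comparison, n = length(ids),
      pearsonR = NA_real_, slope = NA_real_, intercept = NA_real_,
      crosstabTernary = matrix(NA_integer_, 0, 0),
      crosstabBinary = ct$crosstab,
      concordanceTernary = NA_real_, concordanceBinary = ct$concordance,
      fracLower = ct$frac_lower, fracHigher = ct$frac_higher))
  }
  truth <- unname(truthScores[ids])
  rids <- if (is.null(regressionIds)) ids else intersect(ids, regressionIds)
  rm <- regressionMetrics(unname(est[rids]), unname(truthScores[rids]))
  kind <- estimated@scoreKind
  truthSet <- newScoreSet(ids, assayName, kind, pmin(pmax(truth, 0), 100))
  ctT <- concordanceTable(categories(classifyRisk(estimated, "ternary")),
                          categories(classifyRisk(truthSet, "ternary")),
                          "ternary")
  ctB <- concordanceTable(categories(classifyRisk(estimated, "binary")),
                          categories(classifyRisk(truthSet, "binary")),
                          "binary")
  methods::new("EvaluationReport", assayName = assayName,
    comparison = comparison, n = rm$n,
    pearsonR = rm$pearson_r, slope = rm$slope, intercept = rm$intercept,
    crosstabTernary = ctT$crosstab, crosstabBinary = ctB$crosstab,
    concordanceTernary = ctT$concordance, concordanceBinary = ctB$concordance,
    fracLower = ctT$frac_lower, fracHigher = ctT$frac_higher)
}

#' Build the evaluation reports of a study
#'
#' Signature-like scores are compared with the truth over all samples;
#' signature-trained regressions use the validation samples only, while the
#' trained cross-tabs use all samples.
#'
#' @param cohort a \linkS4class{SurrogateCohort} carrying the true scores.
#' @param split the \linkS4class{SplitSpec} used for training.
#' @param like named list of signature-like \linkS4class{RiskScoreSet}s
#'   (names \code{prosigna}, \code{oncotype}, \code{mammaprint}).
#' @param trained named list of applied signature-trained score sets.
#' @return named list of \linkS4class{EvaluationReport}s.
#' @export
buildReport <- function(cohort, split, like = list(), trained = list()) {
  truthOf <- function(assayName, kind) {
    if (assayName == "mammaprint") return(trueScores(cohort, "mammaprint"))
    if (assayName == "oncotype") return(trueScores(cohort, "RS"))
    trueScores(cohort, kind)
  }
  out <- list()
  for (a in names(like)) {
    s <- like[[a]]
    out[[paste0(a, "_like")]] <-
      evaluateScores(s, truthOf(a, s@scoreKind), "like-vs-true")
  }
  for (a in names(trained)) {
    s <- trained[[a]]
    out[[paste0(a, "_trained")]] <-
      evaluateScores(s, truthOf(a, s@scoreKind), "trained-vs-true",
                     regressionIds = validationIds(split))
  }
  out
}

#' Flatten evaluation reports to a data.frame
#'
#' @param reports list of \linkS4class{EvaluationReport}s.
#' @return data.frame with one row per report.
#' @export
reportTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(assay = r@assayName, comparison = r@comparison, n = r@n,
               pearson_r = r@pearsonR, slope = r@slope,
               intercept = r@intercept,
               concordance_ternary = r@concordanceTernary,
               concordance_binary = r@concordanceBinary,
               frac_lower = r@fracLower, frac_higher = r@fracHigher,
               row.names = NULL)
  }))
}
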