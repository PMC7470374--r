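#' @include AllClasses.R AllGenerics.R simulate.R modelling.R training.R evaluation.R
NULL

#' Read an expression matrix
#'
#' TSV with a \code{sample_id} first column and gene symbols as the
#' remaining column headers. Validates strict positivity and uniqueness of
#' sample and gene identifiers; reports which panel genes are missing.
#'
#' @param path TSV file path.
#' @return samples x genes matrix of positive intensities.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tab))
    stop("expression TSV must have a sample_id first column")
  ids <- as.character(tab$sample_id)
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- colnames(tab)[colnames(tab) != "sample_id"]
  cg <- canonicalizeGenes(genes)
  if (anyDuplicated(cg))
    stop("duplicated gene column(s): ",
         paste(unique(cg[duplicated(cg)]), collapse = ", "))
  m <- as.matrix(tab[, genes, drop = FALSE])
  colnames(m) <- cg
  rownames(m) <- ids
  if (any(!is.finite(m)) || any(m <= 0))
    stop("intensities must be finite and strictly positive")
  for (a in c("prosigna", "oncotype", "mammaprint")) {
    p <- loadPanel(a)
    miss <- setdiff(c(reporterGenes(p), housekeepingGenes(p)), cg)
    if (length(miss))
      message(sprintf("panel '%s': %d gene(s) missing (%s)", a, length(miss),
                      paste(utils::head(miss, 5), collapse = ", ")))
  }
  withTag(m, "raw_positive")
}

#' Write an expression matrix
#'
#' @param x samples x genes matrix.
#' @param path output TSV path.
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write risk score sets as CSV
#'
#' @param scoreSets a \linkS4class{RiskScoreSet} or list of them.
#' @param path output CSV path.
#' @export
writeScores <- function(scoreSets, path) {
  if (methods::is(scoreSets, "RiskScoreSet")) scoreSets <- list(scoreSets)
  rows <- lapply(scoreSets, function(s) {
    df <- data.frame(sample_id = s@sampleIds, assay = s@assayName,
                     score_kind = s@scoreKind, score = s@score)
    if (s@assayName == "mammaprint") {
      df$category_ternary <- NA_character_
      df$category_binary <- if (length(s@category)) s@category else NA_character_
    } else if (all(!is.na(s@score))) {
      df$category_ternary <- categories(classifyRisk(s, "ternary"))
      df$category_binary <- categories(classifyRisk(s, "binary"))
    } else {
      df$category_ternary <- NA_character_
      df$category_binary <- NA_character_
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' CSV with columns \code{sample_id} and \code{tumour_size_cm}.
#' @param path CSV path.
#' @export
readCovariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tumour_size_cm") %in% colnames(tab)))
    stop("covariates CSV needs sample_id and tumour_size_cm columns")
  tab
}

reportJson <- function(reports) {
  lapply(reports, function(r) list(
    assay = r@assayName, comparison = r@comparison, n = r@n,
    pearson_r = r@pearsonR, slope = r@slope, intercept = r@intercept,
    concordance_ternary = r@concordanceTernary,
    concordance_binary = r@concordanceBinary,
    frac_lower = r@fracLower, frac_higher = r@fracHigher,
    crosstab_ternary = if (nrow(r@crosstabTernary)) r@crosstabTernary else NULL,
    crosstab_binary = r@crosstabBinary))
}

#' Run a complete simulate / score / train / apply / evaluate study
#'
#' Generates a synthetic cohort, computes the three signature-like score
#' sets, splits 50:50, trains the three signature-trained models on the
#' training split, applies them to the whole cohort, evaluates everything,
#' and (optionally) writes all artifacts — expression TSV, covariates and
#' score CSVs, trained-model and report JSON, iteration-trace CSV, and the
#' exact configuration that produced them — into an output directory.
#' Identical configuration and seeds produce byte-identical artifacts.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir optional output directory for artifacts.
#' @param splitSeed,cvSeed seeds for the 50:50 split and the CV folds.
#' @param maxIterations iteration budget explored by the Prosigna CV.
#' @param cvFolds number of CV folds.
#' @param optimControl optimizer control overrides for the alternating
#'   optimization.
#' @return (invisibly) list with the cohort, split, like and trained score
#'   sets, training results and evaluation reports.
#' @export
runStudy <- function(config = simulationConfig(), outDir = NULL,
                     splitSeed = 2L, cvSeed = 3L, maxIterations = 20L,
                     cvFolds = 5L, optimControl = list()) {
  cohort <- generateCohort(config)
  like <- list(
    prosigna = signatureLike(cohort, "prosigna", kind = "ROR_P"),
    oncotype = signatureLike(cohort, "oncotype"),
    mammaprint = signatureLike(cohort, "mammaprint"))
  split <- splitCohort(sampleIds(cohort), seed = splitSeed)
  fits <- list(
    prosigna = trainProsigna(cohort, split, maxIterations = maxIterations,
                             cvFolds = cvFolds, cvSeed = cvSeed,
                             control = optimControl),
    oncotype = trainOncotype(cohort, split),
    mammaprint = trainMammaprint(cohort, split, k = cvFolds, seed = cvSeed))
  trained <- list(
    prosigna = applyTrained(fits$prosigna, cohort, kind = "ROR_PT"),
    oncotype = applyTrained(fits$oncotype, cohort),
    mammaprint = applyTrained(fits$mammaprint, cohort))
  reports <- buildReport(cohort, split, like = like, trained = trained)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionMatrix(panelMatrix(cohort),
                          file.path(outDir, "expression.tsv"))
    utils::write.csv(
      data.frame(sample_id = sampleIds(cohort),
                 tumour_size_cm = unname(tumourSize(cohort)),
                 subtype = unname(SummarizedExperiment::colData(cohort)$subtype)),
      file.path(outDir, "covariates.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(sample_id = sampleIds(cohort),
                 ROR = unname(trueScores(cohort, "ROR")),
                 ROR_P = unname(trueScores(cohort, "ROR_P")),
                 ROR_PT = unname(trueScores(cohort, "ROR_PT")),
                 RS = unname(trueScores(cohort, "RS")),
                 mammaprint = unname(trueScores(cohort, "mammaprint"))),
      file.path(outDir, "true_scores.csv"), row.names = FALSE)
    writeScores(like, file.path(outDir, "scores_like.csv"))
    writeScores(trained, file.path(outDir, "scores_trained.csv"))
    utils::write.csv(iterationTrace(fits$prosigna),
                     file.path(outDir, "prosigna_trace.csv"), row.names = FALSE)
    f <- fits$prosigna@model$factors
    modelOut <- list(
      prosigna = list(chosen_iteration = chosenIteration(fits$prosigna),
                      centering = as.list(centering(f)),
                      scaling = as.list(scaling(f)),
                      rescale = fits$prosigna@rescale),
      oncotype = list(weights = as.list(fits$oncotype@model$weights),
                      intercept = fits$oncotype@model$intercept),
      mammaprint = list(penalty = fits$mammaprint@model$penalty,
                        intercept = fits$mammaprint@model$intercept,
                        beta = as.list(fits$mammaprint@model$beta)))
    jsonlite::write_json(modelOut, file.path(outDir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(reportJson(reports), file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- list(nSamples = config@nSamples,
                subtypeProportions = as.list(config@subtypeProportions),
                expressionNoiseSd = config@expressionNoiseSd,
                centeringShiftSd = config@centeringShiftSd,
                scalingMultRange = config@scalingMultRange,
                scoreNoiseSd = config@scoreNoiseSd,
                labelFlipProb = config@labelFlipProb,
                hkNoiseSd = config@hkNoiseSd,
                seed = config@seed, splitSeed = splitSeed, cvSeed = cvSeed,
                maxIterations = maxIterations, cvFolds = cvFolds)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  }
  invisible(list(cohort = cohort, split = split, like = like, fits = fits,
                 trained = trained, reports = reports))
}
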