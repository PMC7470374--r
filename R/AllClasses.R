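#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Gene panel of a multigene assay
#'
#' Holds the gene roster of one assay: the ordered reporter genes, the
#' reference (housekeeping) genes, a role tag per gene (e.g. proliferation,
#' er, her2, invasion, housekeeping) and, where the assay defines them,
#' within-metagene averaging weights.
#'
#' @slot assayName one of \code{"prosigna"}, \code{"oncotype"},
#'   \code{"mammaprint"}.
#' @slot reporterGenes ordered character vector of reporter gene symbols.
#' @slot housekeepingGenes character vector of reference gene symbols.
#' @slot roleMap named character vector mapping every panel gene to its role.
#' @slot avgWeights named numeric vector of within-metagene averaging weights
#'   (reporter genes only; 1 where the assay uses a plain mean).
#'
#' @exportClass GenePanel
setClass("GenePanel",
  representation(assayName = "character",
                 reporterGenes = "character",
                 housekeepingGenes = "character",
                 roleMap = "character",
                 avgWeights = "numeric"))

setValidity("GenePanel", function(object) {
  msg <- character()
  if (length(object@assayName) != 1L ||
      !object@assayName %in% c("prosigna", "oncotype", "mammaprint"))
    msg <- c(msg, "assayName must be one of prosigna/oncotype/mammaprint")
  if (length(intersect(object@reporterGenes, object@housekeepingGenes)) > 0L)
    msg <- c(msg, "reporter and housekeeping gene sets must be disjoint")
  if (anyDuplicated(object@reporterGenes))
    msg <- c(msg, "duplicated reporter genes")
  all_genes <- c(object@reporterGenes, object@housekeepingGenes)
  if (!setequal(names(object@roleMap), all_genes))
    msg <- c(msg, "roleMap must cover exactly the panel genes")
  if (object@assayName == "prosigna") {
    if (length(object@reporterGenes) != 46L)
      msg <- c(msg, "prosigna panel must have 46 reporter genes")
    if (length(object@housekeepingGenes) != 8L)
      msg <- c(msg, "prosigna panel must have 8 housekeeping genes")
    if (sum(object@roleMap == "proliferation") != 18L)
      msg <- c(msg, "prosigna panel must mark exactly 18 proliferation genes")
  }
  if (object@assayName == "oncotype") {
    counts <- table(object@roleMap[object@reporterGenes])
    want <- c(proliferation = 5, her2 = 2, er = 4, invasion = 2,
              cd68 = 1, gstm1 = 1, bag1 = 1)
    for (r in names(want))
      if (is.na(counts[r]) || counts[r] != want[r])
        msg <- c(msg, sprintf("oncotype role '%s' must have %d gene(s)", r, want[r]))
  }
  if (object@assayName == "mammaprint" &&
      length(object@reporterGenes) != 70L)
    msg <- c(msg, "mammaprint panel must have 70 reporter genes")
  if (length(msg)) msg else TRUE
})

#' Reference subtype centroids
#'
#' Row-scaled reference expression of the 46 Prosigna reporter genes for the
#' four intrinsic subtypes (LumA, LumB, HER2-enriched, Basal). Gene order is
#' identical to the Prosigna panel reporter order.
#'
#' @slot values 46 x 4 numeric matrix, rownames = genes, colnames = subtypes.
#' @exportClass SubtypeCentroids
setClass("SubtypeCentroids", representation(values = "matrix"))

setValidity("SubtypeCentroids", function(object) {
  v <- object@values
  if (ncol(v) != 4L) return("centroids must have 4 subtype columns")
  if (anyNA(v)) return("centroids must have no missing values")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("centroids must carry gene rownames and subtype colnames")
  TRUE
})

#' Risk-of-recurrence score weights
#'
#' Coefficients of the ROR linear combination: one weight per subtype
#' correlation, a proliferation weight, a weight for the tumour-size (> 2 cm)
#' indicator, and the affine constants mapping the raw combination onto the
#' reported 0-100 scale.
#'
#' @exportClass RorWeights
setClass("RorWeights",
  representation(subtypeWeights = "numeric",
                 proliferationWeight = "numeric",
                 sizeWeight = "numeric",
                 rescaleOffset = "numeric",
                 rescaleSlope = "numeric"))

setValidity("RorWeights", function(object) {
  if (length(object@subtypeWeights) != 4L ||
      is.null(names(object@subtypeWeights)))
    return("exactly 4 named subtype weights required")
  if (!all(is.finite(c(object@subtypeWeights, object@proliferationWeight,
                       object@sizeWeight))))
    return("weights must be finite")
  if (object@rescaleSlope <= 0) return("rescaleSlope must be > 0")
  TRUE
})

#' Oncotype metagene model
#'
#' Metagene membership with within-group averaging weights, the between-group
#' coefficients of the Recurrence Score, the affine constants mapping the
#' unscaled RS onto 0-100, and the two data-driven handling rules: GSTM1
#' thresholding at background and Cathepsin-L2 (CTSV) exclusion from the
#' invasion group.
#'
#' @exportClass MetageneModel
setClass("MetageneModel",
  representation(definitions = "list",
                 weights = "numeric",
                 rescaleOffset = "numeric",
                 rescaleSlope = "numeric",
                 gstm1Threshold = "logical",
                 ctsl2Excluded = "logical",
                 gstm1Background = "numeric"))

setValidity("MetageneModel", function(object) {
  if (!setequal(names(object@definitions), names(object@weights)))
    return("metagene definitions and weights must cover the same roles")
  if (object@rescaleSlope <= 0) return("rescaleSlope must be > 0")
  TRUE
})

#' gene70 good-prognosis template
#'
#' The 70-gene average good-prognosis profile and the correlation cutoff that
#' separates low from high risk (index >= cutoff is low risk).
#'
#' @exportClass Gene70Template
setClass("Gene70Template",
  representation(genes = "character", values = "numeric", cutoff = "numeric"))

setValidity("Gene70Template", function(object) {
  if (length(object@genes) != length(object@values))
    return("template genes and values must have equal length")
  if (object@cutoff <= -1 || object@cutoff >= 1)
    return("correlation cutoff must lie in (-1, 1)")
  TRUE
})

#' Per-gene centering and scaling factors
#'
#' The row-scaling parameters of the Prosigna algorithm:
#' \code{(value - centering) / scaling} per gene. These are the quantities
#' the training pipeline estimates.
#'
#' @exportClass ScalingFactors
setClass("ScalingFactors",
  representation(geneIds = "character",
                 centering = "numeric",
                 scaling = "numeric"))

setValidity("ScalingFactors", function(object) {
  n <- length(object@geneIds)
  if (length(object@centering) != n || length(object@scaling) != n)
    return("centering and scaling must match geneIds in length")
  if (any(!is.finite(object@centering)) || any(!is.finite(object@scaling)))
    return("factors must be finite")
  if (any(object@scaling <= 0)) return("scaling factors must be > 0")
  TRUE
})

#' Per-sample risk scores of one assay
#'
#' Continuous scores (0-100 for the ROR family and RS, [-1, 1] for the gene70
#' index) and/or categorical risk labels.
#'
#' @slot sampleIds sample identifiers.
#' @slot assayName assay the scores belong to.
#' @slot scoreKind one of ROR, ROR_P, ROR_PT, RS, GENE70_INDEX.
#' @slot score per-sample continuous score (may be all NA for binary-only
#'   MammaPrint labels).
#' @slot category per-sample risk label, or character(0) when not assigned.
#' @slot scheme "ternary", "binary" or "none".
#' @exportClass RiskScoreSet
setClass("RiskScoreSet",
  representation(sampleIds = "character",
                 assayName = "character",
                 scoreKind = "character",
                 score = "numeric",
                 category = "character",
                 scheme = "character"))

setValidity("RiskScoreSet", function(object) {
  n <- length(object@sampleIds)
  if (length(object@score) != n)
    return("score must have one value per sample (NA allowed)")
  if (length(object@category) != 0L && length(object@category) != n)
    return("category must be empty or one label per sample")
  k <- object@scoreKind
  s <- object@score[!is.na(object@score)]
  if (k %in% c("ROR", "ROR_P", "ROR_PT", "RS") && length(s) &&
      (min(s) < 0 || max(s) > 100))
    return(sprintf("%s scores must lie in [0, 100]", k))
  if (k == "GENE70_INDEX" && length(s) && (min(s) < -1 || max(s) > 1))
    return("gene70 index must lie in [-1, 1]")
  TRUE
})

#' Simulation configuration
#'
#' Study conditions for the synthetic cohort generator. Defaults emulate a
#' NanoString-profiled high-risk ER+ cohort: luminal-heavy subtype mix,
#' moderate biological/technical log-scale noise, hidden per-gene distortions
#' of the stated magnitude, and vendor-score measurement noise.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSamples = "integer",
                 subtypeProportions = "numeric",
                 expressionNoiseSd = "numeric",
                 gradeNoiseSd = "numeric",
                 centeringShiftSd = "numeric",
                 scalingMultRange = "numeric",
                 scoreNoiseSd = "numeric",
                 labelFlipProb = "numeric",
                 hkNoiseSd = "numeric",
                 tumourSizeMeanlog = "numeric",
                 tumourSizeSdlog = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 20L) msg <- c(msg, "nSamples must be >= 20")
  p <- object@subtypeProportions
  if (length(p) != 4L || abs(sum(p) - 1) > 1e-8 || any(p < 0))
    msg <- c(msg, "subtypeProportions must be 4 non-negative values summing to 1")
  if (object@expressionNoiseSd < 0 || object@scoreNoiseSd < 0 ||
      object@hkNoiseSd < 0 || object@centeringShiftSd < 0 ||
      object@gradeNoiseSd < 0)
    msg <- c(msg, "noise scales must be >= 0")
  r <- object@scalingMultRange
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0)
    msg <- c(msg, "scalingMultRange must be positive and ordered")
  if (object@labelFlipProb < 0 || object@labelFlipProb > 1)
    msg <- c(msg, "labelFlipProb must be a probability")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort container
#'
#' A \linkS4class{SummarizedExperiment} (genes x samples, assay
#' \code{"counts"} of strictly positive NanoString-style intensities) whose
#' \code{colData} carries the tumour size, the generative subtype and the
#' vendor-style true scores, and whose \code{metadata} records every hidden
#' generative parameter (perturbed factors, noise levels, seed).
#'
#' @exportClass SurrogateCohort
setClass("SurrogateCohort", contains = "SummarizedExperiment")

setValidity("SurrogateCohort", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m <= 0)) return("expression intensities must be strictly positive")
  cd <- SummarizedExperiment::colData(object)
  need <- c("tumour_size_cm", "subtype", "true_ROR", "true_ROR_P",
            "true_ROR_PT", "true_RS", "true_mammaprint")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  for (k in c("true_ROR", "true_ROR_P", "true_ROR_PT", "true_RS")) {
    v <- cd[[k]]
    if (any(v < 0 | v > 100)) return(sprintf("%s must lie in [0, 100]", k))
  }
  TRUE
})

#' Train/validation split
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(trainIds = "character",
                 validationIds = "character",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  if (length(intersect(object@trainIds, object@validationIds)) > 0L)
    return("train and validation ids must be disjoint")
  if (abs(length(object@trainIds) - length(object@validationIds)) > 1L)
    return("split must be 50:50 up to one sample")
  TRUE
})

#' Frozen result of one trained surrogate
#'
#' Fitted parameters (centering/scaling factors for Prosigna, metagene
#' weights for Oncotype, ridge coefficients for MammaPrint), the fitted
#' 0-100 rescales, the optimization/CV trace and the chosen iteration.
#' Frozen after fitting: applying the model never re-estimates anything.
#'
#' @exportClass TrainingResult
setClass("TrainingResult",
  representation(assayName = "character",
                 model = "list",
                 rescale = "list",
                 iterationTrace = "data.frame",
                 chosenIteration = "integer",
                 seeds = "list"))

setValidity("TrainingResult", function(object) {
  if (length(object@chosenIteration) &&
      !is.na(object@chosenIteration) && object@chosenIteration < 0L)
    return("chosenIteration must be >= 0")
  if (nrow(object@iterationTrace) &&
      "train_mse" %in% colnames(object@iterationTrace) &&
      any(!is.finite(object@iterationTrace$train_mse)))
    return("iteration trace train MSE must be finite")
  TRUE
})

#' Agreement report between two score sets
#'
#' Pearson correlation, OLS slope/intercept of estimated-on-true, ternary and
#' binary concordance cross-tabs with the discordance-direction fractions.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(assayName = "character",
                 comparison = "character",
                 n = "integer",
                 pearsonR = "numeric",
                 slope = "numeric",
                 intercept = "numeric",
                 crosstabTernary = "matrix",
                 crosstabBinary = "matrix",
                 concordanceTernary = "numeric",
                 concordanceBinary = "numeric",
                 fracLower = "numeric",
                 fracHigher = "numeric"))
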