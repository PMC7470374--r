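#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 objects; user code should use
#' these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("assayLabel", function(x) standardGeneric("assayLabel"))
#' @rdname accessors
#' @export
setGeneric("reporterGenes", function(x) standardGeneric("reporterGenes"))
#' @rdname accessors
#' @export
setGeneric("housekeepingGenes", function(x) standardGeneric("housekeepingGenes"))
#' @rdname accessors
#' @export
setGeneric("roleMap", function(x) standardGeneric("roleMap"))
#' @rdname accessors
#' @export
setGeneric("centering", function(x) standardGeneric("centering"))
#' @rdname accessors
#' @export
setGeneric("scaling", function(x) standardGeneric("scaling"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("chosenIteration", function(x) standardGeneric("chosenIteration"))
#' @rdname accessors
#' @export
setGeneric("iterationTrace", function(x) standardGeneric("iterationTrace"))
#' @rdname accessors
#' @export
setGeneric("hiddenParams", function(x) standardGeneric("hiddenParams"))
#' @rdname accessors
#' @export
setGeneric("tumourSize", function(x) standardGeneric("tumourSize"))
#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))

#' True vendor-style scores stored in a cohort
#'
#' @param x a \linkS4class{SurrogateCohort}.
#' @param kind one of \code{"ROR"}, \code{"ROR_P"}, \code{"ROR_PT"},
#'   \code{"RS"}, \code{"mammaprint"}.
#' @return numeric scores (character labels for \code{"mammaprint"}).
#' @export
setGeneric("trueScores", function(x, kind) standardGeneric("trueScores"))

setMethod("assayLabel", "GenePanel", function(x) x@assayName)
setMethod("assayLabel", "RiskScoreSet", function(x) x@assayName)
setMethod("assayLabel", "TrainingResult", function(x) x@assayName)
setMethod("assayLabel", "EvaluationReport", function(x) x@assayName)
setMethod("reporterGenes", "GenePanel", function(x) x@reporterGenes)
setMethod("reporterGenes", "Gene70Template", function(x) x@genes)
setMethod("housekeepingGenes", "GenePanel", function(x) x@housekeepingGenes)
setMethod("roleMap", "GenePanel", function(x) x@roleMap)
setMethod("centering", "ScalingFactors", function(x) {
  stats::setNames(x@centering, x@geneIds)
})
setMethod("scaling", "ScalingFactors", function(x) {
  stats::setNames(x@scaling, x@geneIds)
})
setMethod("scores", "RiskScoreSet", function(x) {
  stats::setNames(x@score, x@sampleIds)
})
setMethod("categories", "RiskScoreSet", function(x) {
  if (!length(x@category)) return(NULL)
  stats::setNames(x@category, x@sampleIds)
})
setMethod("sampleIds", "RiskScoreSet", function(x) x@sampleIds)
setMethod("sampleIds", "SurrogateCohort", function(x) colnames(x))
setMethod("chosenIteration", "TrainingResult", function(x) x@chosenIteration)
setMethod("iterationTrace", "TrainingResult", function(x) x@iterationTrace)
setMethod("hiddenParams", "SurrogateCohort", function(x) {
  S4Vectors::metadata(x)$hidden
})
setMethod("tumourSize", "SurrogateCohort", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$tumour_size_cm, colnames(x))
})
setMethod("trainIds", "SplitSpec", function(x) x@trainIds)
setMethod("validationIds", "SplitSpec", function(x) x@validationIds)

setMethod("trueScores", "SurrogateCohort", function(x, kind) {
  kind <- match.arg(kind, c("ROR", "ROR_P", "ROR_PT", "RS", "mammaprint"))
  col <- paste0("true_", kind)
  stats::setNames(SummarizedExperiment::colData(x)[[col]], colnames(x))
})

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel '%s': %d reporter + %d housekeeping genes\n",
              object@assayName, length(object@reporterGenes),
              length(object@housekeepingGenes)))
  cat("roles:", paste(sprintf("%s(%d)", names(table(object@roleMap)),
                              table(object@roleMap)), collapse = " "), "\n")
})

setMethod("show", "ScalingFactors", function(object) {
  cat(sprintf("ScalingFactors over %d genes\n", length(object@geneIds)))
  cat(sprintf("  centering: [%.3f, %.3f]  scaling: [%.3f, %.3f]\n",
              min(object@centering), max(object@centering),
              min(object@scaling), max(object@scaling)))
})

setMethod("show", "RiskScoreSet", function(object) {
  cat(sprintf("RiskScoreSet '%s' (%s), %d samples",
              object@assayName, object@scoreKind, length(object@sampleIds)))
  if (length(object@category))
    cat(sprintf(", %s categories", object@scheme))
  cat("\n")
  if (any(!is.na(object@score)))
    cat(sprintf("  score range: [%.2f, %.2f]\n",
                min(object@score, na.rm = TRUE), max(object@score, na.rm = TRUE)))
})

setMethod("show", "TrainingResult", function(object) {
  cat(sprintf("TrainingResult '%s'", object@assayName))
  if (length(object@chosenIteration) && !is.na(object@chosenIteration))
    cat(sprintf(", chosen iteration %d", object@chosenIteration))
  cat(sprintf(", trace of %d rows\n", nrow(object@iterationTrace)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport '%s' [%s], n = %d\n",
              object@assayName, object@comparison, object@n))
  if (!is.na(object@pearsonR))
    cat(sprintf("  r = %.3f, slope = %.3f, intercept = %.3f\n",
                object@pearsonR, object@slope, object@intercept))
  if (!is.na(object@concordanceTernary))
    cat(sprintf("  concordance: ternary %.3f, binary %.3f\n",
                object@concordanceTernary, object@concordanceBinary))
})

#' Coerce a risk score set to a data.frame
#'
#' @param x a \linkS4class{RiskScoreSet}.
#' @param ... unused.
#' @export
#' @method as.data.frame RiskScoreSet
as.data.frame.RiskScoreSet <- function(x, ...) {
  df <- data.frame(sample_id = x@sampleIds, assay = x@assayName,
                   score_kind = x@scoreKind, score = x@score,
                   stringsAsFactors = FALSE)
  if (length(x@category)) {
    df$category <- x@category
    df$scheme <- x@scheme
  }
  df
}
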