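#' @include AllClasses.R AllGenerics.R panels.R
NULL

# All engines are pure functions of their inputs: no RNG, no package state.
# Expression matrices are oriented samples x genes with gene symbols as
# column names; a "scaleTag" attribute tracks raw_positive / log2 /
# row_scaled provenance.

scaleTag <- function(x) attr(x, "scaleTag")

withTag <- function(x, tag) {
  attr(x, "scaleTag") <- tag
  x
}

checkGenesPresent <- function(x, genes, what) {
  miss <- setdiff(genes, colnames(x))
  if (length(miss))
    stop("missing ", what, " gene(s): ", paste(miss, collapse = ", "))
}

#' Housekeeping normalization
#'
#' Per sample, each gene's value becomes the log2 ratio of its intensity to
#' the geometric mean of the assay's housekeeping-gene intensities (NanoString
#' convention). Housekeeping columns are retained, normalized like the rest.
#'
#' @param x samples x genes matrix of strictly positive intensities.
#' @param panel \linkS4class{GenePanel} providing the housekeeping genes.
#' @return samples x genes matrix of log2 ratios.
#' @export
normalizeHousekeeping <- function(x, panel) {
  hk <- housekeepingGenes(panel)
  if (!length(hk)) stop("panel '", assayLabel(panel), "' has no housekeeping genes")
  checkGenesPresent(x, hk, "housekeeping")
  if (any(x <= 0)) stop("intensities must be strictly positive")
  lx <- log2(x)
  geo <- rowMeans(lx[, hk, drop = FALSE])
  withTag(lx - geo, "log2")
}

#' Row-scaling
#'
#' Applies per-gene centering and scaling, \code{(value - centering) /
#' scaling}, restricted (and ordered) to the factor genes.
#'
#' @param x samples x genes log2 matrix.
#' @param f \linkS4class{ScalingFactors}.
#' @return samples x genes row-scaled matrix over the factor genes.
#' @export
rowScale <- function(x, f) {
  checkGenesPresent(x, f@geneIds, "row-scaling")
  m <- x[, f@geneIds, drop = FALSE]
  n <- nrow(m)
  out <- (m - rep(f@centering, each = n)) / rep(f@scaling, each = n)
  withTag(out, "row_scaled")
}

# Centroid columns centered and L2-normalized once, for the fast Pearson
# correlation used inside the optimizer's objective.
standardizeCentroids <- function(centroids) {
  C <- centroids@values
  Cc <- sweep(C, 2, colMeans(C))
  sweep(Cc, 2, sqrt(colSums(Cc^2)), "/")
}

corAcrossGenes <- function(m, Cstd) {
  mc <- m - rowMeans(m)
  den <- sqrt(rowSums(mc^2))
  if (any(den == 0)) stop("zero-variance sample profile: correlation undefined")
  (mc %*% Cstd) / den
}

#' Subtype correlations
#'
#' Pearson correlation, across the 46 Prosigna reporter genes, between each
#' sample's row-scaled profile and each of the four subtype centroids.
#'
#' @param x samples x genes row-scaled matrix containing the 46 reporters.
#' @param centroids \linkS4class{SubtypeCentroids}.
#' @return samples x 4 matrix of correlations in [-1, 1].
#' @export
subtypeCorrelations <- function(x, centroids) {
  genes <- rownames(centroids@values)
  checkGenesPresent(x, genes, "centroid")
  corAcrossGenes(x[, genes, drop = FALSE], standardizeCentroids(centroids))
}

#' Proliferation score
#'
#' Unweighted mean of the 18 proliferation genes' row-scaled expression.
#'
#' @param x samples x genes row-scaled matrix.
#' @param panel the Prosigna \linkS4class{GenePanel}.
#' @export
proliferationScore <- function(x, panel) {
  pg <- names(roleMap(panel))[roleMap(panel) == "proliferation"]
  checkGenesPresent(x, pg, "proliferation")
  rowMeans(x[, pg, drop = FALSE])
}

#' Raw risk-of-recurrence scores
#'
#' The ROR linear combination: subtype-correlation weights alone
#' (\code{ROR}), plus proliferation weighting (\code{ROR_P}), plus the
#' tumour-size indicator, 1 when size strictly exceeds 2 cm (\code{ROR_PT}).
#' Returns the raw (unrescaled) combination.
#'
#' @param correlations samples x 4 subtype correlation matrix.
#' @param proliferation per-sample proliferation score.
#' @param tumourSizeCm per-sample tumour size in cm (required for ROR_PT).
#' @param w \linkS4class{RorWeights}.
#' @param variant \code{"ROR"}, \code{"ROR_P"} or \code{"ROR_PT"}.
#' @export
rorScores <- function(correlations, proliferation, tumourSizeCm = NULL, w,
                      variant = c("ROR_PT", "ROR_P", "ROR")) {
  variant <- match.arg(variant)
  sw <- w@subtypeWeights
  cols <- match(names(sw), colnames(correlations))
  if (anyNA(cols)) stop("correlation columns must be named by subtype")
  raw <- as.numeric(correlations[, cols, drop = FALSE] %*% sw)
  if (variant %in% c("ROR_P", "ROR_PT"))
    raw <- raw + w@proliferationWeight * proliferation
  if (variant == "ROR_PT") {
    if (is.null(tumourSizeCm)) stop("tumour size required for ROR_PT")
    raw <- raw + w@sizeWeight * as.numeric(tumourSizeCm > 2)
  }
  raw
}

#' Affine rescale with truncation to [0, 100]
#'
#' \code{clamp(offset + slope * raw, 0, 100)}.
#'
#' @param raw numeric scores.
#' @param offset,slope affine constants; slope must be positive.
#' @export
rescaleTruncate <- function(raw, offset, slope) {
  if (slope <= 0) stop("rescale slope must be > 0")
  pmin(pmax(offset + slope * raw, 0), 100)
}

#' Oncotype metagene scores
#'
#' Weighted within-group averages of the normalized member genes. When the
#' model's GSTM1 rule is on, GSTM1 values below its background level are set
#' to background before use; when Cathepsin-L2 (CTSV) is excluded, the
#' invasion group averages only its remaining member.
#'
#' @param x samples x genes log2 matrix.
#' @param m \linkS4class{MetageneModel}.
#' @param background optional named per-gene background levels; defaults to
#'   the model's packaged GSTM1 background.
#' @return samples x metagene matrix (columns named by role).
#' @export
metageneScores <- function(x, m, background = NULL) {
  if (is.null(background))
    background <- c(GSTM1 = m@gstm1Background)
  out <- matrix(NA_real_, nrow(x), length(m@definitions),
                dimnames = list(rownames(x), names(m@definitions)))
  for (role in names(m@definitions)) {
    def <- m@definitions[[role]]
    if (m@ctsl2Excluded && role == "invasion")
      def <- def[def$gene != "CTSV", , drop = FALSE]
    miss <- setdiff(def$gene, colnames(x))
    if (length(miss))
      stop("missing metagene member gene(s): ", paste(miss, collapse = ", "))
    vals <- x[, def$gene, drop = FALSE]
    if (m@gstm1Threshold && "GSTM1" %in% def$gene) {
      if (!"GSTM1" %in% names(background))
        stop("GSTM1 background level required when thresholding is enabled")
      b <- background[["GSTM1"]]
      vals[, "GSTM1"] <- pmax(vals[, "GSTM1"], b)
    }
    out[, role] <- as.numeric(vals %*% def$weight) / sum(def$weight)
  }
  out
}

#' Recurrence Score from metagene scores
#'
#' Weighted sum of the metagene scores, affinely rescaled and truncated to
#' the reported 0-100 range.
#'
#' @param metagenes samples x metagene matrix from \code{\link{metageneScores}}.
#' @param m \linkS4class{MetageneModel}.
#' @export
recurrenceScore <- function(metagenes, m) {
  miss <- setdiff(names(m@weights), colnames(metagenes))
  if (length(miss))
    stop("missing metagene role(s): ", paste(miss, collapse = ", "))
  raw <- as.numeric(metagenes[, names(m@weights), drop = FALSE] %*% m@weights)
  rescaleTruncate(raw, m@rescaleOffset, m@rescaleSlope)
}

#' gene70 index
#'
#' Pearson correlation between each sample's 70-gene profile and the
#' good-prognosis template; samples at or above the correlation cutoff are
#' low risk, the rest high risk.
#'
#' @param x samples x genes log2 (cohort-standardized) matrix.
#' @param t \linkS4class{Gene70Template}.
#' @return a \linkS4class{RiskScoreSet} with kind \code{GENE70_INDEX} and
#'   binary categories.
#' @export
gene70Index <- function(x, t) {
  checkGenesPresent(x, t@genes, "gene70")
  tm <- t@values - mean(t@values)
  tm <- tm / sqrt(sum(tm^2))
  idx <- as.numeric(corAcrossGenes(x[, t@genes, drop = FALSE],
                                   matrix(tm, ncol = 1)))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_along(idx))
  methods::new("RiskScoreSet", sampleIds = ids, assayName = "mammaprint",
    scoreKind = "GENE70_INDEX", score = idx,
    category = ifelse(idx >= t@cutoff, "low", "high"), scheme = "binary")
}

# Single source of truth for the category boundaries.
#   ROR-PT: low [0,40), intermediate [40,60], high (60,100]
#   RS:     low [0,18), intermediate [18,25], high (25,100]
# Binary collapses {low, intermediate} vs high.
riskCutoffs <- function(assayName) {
  switch(assayName,
    prosigna = c(low = 40, high = 60),
    oncotype = c(low = 18, high = 25),
    stop("no category scheme for assay '", assayName, "'"))
}

#' Risk categorization
#'
#' Assigns ternary (low/intermediate/high) or binary (low/high) risk
#' categories from continuous 0-100 scores using the assay cutoffs: 40/60
#' for the ROR family, 18/25 for the Recurrence Score. The binary scheme
#' collapses low and intermediate.
#'
#' @param x a \linkS4class{RiskScoreSet} with continuous scores.
#' @param scheme \code{"ternary"} or \code{"binary"}.
#' @return the score set with categories filled in.
#' @export
classifyRisk <- function(x, scheme = c("ternary", "binary")) {
  scheme <- match.arg(scheme)
  if (x@assayName == "mammaprint")
    stop("MammaPrint categories come from the gene70 cutoff, not classifyRisk")
  v <- x@score
  if (any(is.na(v))) stop("continuous scores required for classification")
  if (any(v < 0 | v > 100)) stop("scores must lie in [0, 100]")
  cut <- riskCutoffs(x@assayName)
  tern <- ifelse(v < cut["low"], "low",
          ifelse(v <= cut["high"], "intermediate", "high"))
  lab <- if (scheme == "ternary") tern else ifelse(tern == "high", "high", "low")
  methods::initialize(x, category = lab, scheme = scheme)
}
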