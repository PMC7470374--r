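#' @include AllClasses.R AllGenerics.R panels.R engines.R simulate.R
NULL

SD_FLOOR <- 1e-8

#' Global normalization
#'
#' The single cohort-level normalization of the modelling approach: each
#' sample's intensities are scaled so its total matches the cohort median
#' total, then log2-transformed. Optionally an affine "measurement range"
#' transform maps the cohort's 2.5th-97.5th log2 percentiles onto a
#' configured target range (used for the Oncotype-like pipeline, whose
#' published rescale presumes the vendor's 0-15 measurement scale).
#'
#' @param x samples x genes matrix of strictly positive intensities.
#' @param targetRange optional length-2 numeric target range.
#' @return samples x genes log2 matrix.
#' @export
globalNormalize <- function(x, targetRange = NULL) {
  if (!nrow(x) || !ncol(x)) stop("empty expression matrix")
  if (any(x <= 0)) stop("intensities must be strictly positive")
  tot <- rowSums(x)
  lx <- log2(x * (stats::median(tot) / tot))
  if (!is.null(targetRange)) {
    q <- stats::quantile(lx, c(0.025, 0.975), names = FALSE)
    if (diff(q) > 0) {
      slope <- diff(targetRange) / diff(q)
      lx <- targetRange[1] + (lx - q[1]) * slope
    }
  }
  withTag(lx, "log2")
}

# Per-gene cohort mean/SD factors with the degenerate-cohort guard.
cohortFactors <- function(x, genes) {
  m <- x[, genes, drop = FALSE]
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[!is.finite(sd) | sd < SD_FLOOR] <- SD_FLOOR
  methods::new("ScalingFactors", geneIds = genes, centering = unname(mu),
               scaling = unname(sd))
}

# Min-max map of a raw score vector onto [0, 100]; collapses to the
# midpoint when the cohort has no spread.
minmaxRescale <- function(raw) {
  rng <- range(raw)
  if (diff(rng) < 1e-12) return(list(offset = 50 - rng[1], slope = 1))
  list(offset = -100 * rng[1] / diff(rng), slope = 100 / diff(rng))
}

# Correlations tolerating degenerate (zero-spread) profiles, which arise in
# single-sample cohorts where the SD guard floors all row-scaled values.
corAllowDegenerate <- function(m, Cstd) {
  mc <- m - rowMeans(m)
  den <- sqrt(rowSums(mc^2))
  bad <- den == 0
  den[bad] <- 1
  out <- (mc %*% Cstd) / den
  out[bad, ] <- 0
  out
}

prosignaLikeRaw <- function(lg, tumourSizeCm, kind) {
  panel <- loadPanel("prosigna")
  centroids <- loadCentroids()
  f <- cohortFactors(lg, reporterGenes(panel))
  rsc <- rowScale(lg, f)
  co <- corAllowDegenerate(rsc[, rownames(centroids@values), drop = FALSE],
                           standardizeCentroids(centroids))
  colnames(co) <- colnames(centroids@values)
  pr <- proliferationScore(rsc, panel)
  rorScores(co, pr, tumourSizeCm, loadRorWeights(), variant = kind)
}

newScoreSet <- function(ids, assayName, kind, score) {
  methods::new("RiskScoreSet", sampleIds = ids, assayName = assayName,
               scoreKind = kind, score = score, category = character(),
               scheme = "none")
}

#' Signature-like risk scores (modelling approach)
#'
#' Applies the published algorithms after a single global normalization,
#' with no calibration against true assay results (which are deliberately
#' not parameters of this function). Prosigna-like: global normalization,
#' row-scaling with cohort per-gene means/SDs, subtype correlations,
#' proliferation score, ROR linear combination, min-max rescale to 0-100.
#' Oncotype-like: global normalization with the measurement-range transform,
#' metagene scores, published weights and published rescale. MammaPrint-like:
#' global normalization, cohort gene standardization, gene70 correlation
#' index and cutoff.
#'
#' @param x a \linkS4class{SurrogateCohort} or samples x genes matrix of
#'   positive intensities.
#' @param assayName which assay to emulate.
#' @param kind Prosigna score variant (\code{"ROR_PT"}, \code{"ROR_P"},
#'   \code{"ROR"}); ignored for the other assays.
#' @param tumourSizeCm per-sample tumour sizes (taken from the cohort when
#'   \code{x} is a \linkS4class{SurrogateCohort}).
#' @return a \linkS4class{RiskScoreSet}.
#' @export
signatureLike <- function(x, assayName = c("prosigna", "oncotype", "mammaprint"),
                          kind = "ROR_PT", tumourSizeCm = NULL) {
  assayName <- match.arg(assayName)
  if (methods::is(x, "SurrogateCohort")) {
    tumourSizeCm <- unname(tumourSize(x))
    x <- panelMatrix(x)
  }
  if (any(x <= 0)) stop("intensities must be strictly positive")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))

  if (assayName == "prosigna") {
    kind <- match.arg(kind, c("ROR_PT", "ROR_P", "ROR"))
    if (kind == "ROR_PT" && is.null(tumourSizeCm))
      stop("tumour size required for ROR_PT")
    lg <- globalNormalize(x)
    raw <- prosignaLikeRaw(lg, tumourSizeCm, kind)
    rc <- minmaxRescale(raw)
    return(newScoreSet(ids, "prosigna", kind,
                       rescaleTruncate(raw, rc$offset, rc$slope)))
  }
  if (assayName == "oncotype") {
    model <- loadMetageneModel("published")
    rng <- as.numeric(panelConfig()$oncotype$measurement_range)
    lg <- globalNormalize(x, targetRange = rng)
    # background on the transformed scale: cohort median of GSTM1
    bg <- c(GSTM1 = stats::median(lg[, "GSTM1"]))
    mg <- metageneScores(lg, model, background = bg)
    return(newScoreSet(ids, "oncotype", "RS", recurrenceScore(mg, model)))
  }
  # mammaprint
  tmpl <- loadGene70Template()
  lg <- globalNormalize(x)[, tmpl@genes, drop = FALSE]
  f <- cohortFactors(lg, tmpl@genes)
  std <- rowScale(lg, f)
  tm <- tmpl@values - mean(tmpl@values)
  tm <- tm / sqrt(sum(tm^2))
  idx <- as.numeric(corAllowDegenerate(std, matrix(tm, ncol = 1)))
  methods::new("RiskScoreSet", sampleIds = ids, assayName = "mammaprint",
    scoreKind = "GENE70_INDEX", score = idx,
    category = ifelse(idx >= tmpl@cutoff, "low", "high"), scheme = "binary")
}
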