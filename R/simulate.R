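#' @include AllClasses.R AllGenerics.R panels.R engines.R
NULL

# Deterministic sub-stream seeds so each generator component draws from its
# own seeded stream, in a fixed order. Kept below 2^31.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6 * 1013 + k * 104729) %% 2147483647)
}

#' Simulation configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults define the
#' generator's study conditions: a luminal-heavy subtype mix as in a
#' high-risk ER+ cohort, log-scale expression noise of 0.35, hidden per-gene
#' centering shifts of sd 0.5 and scaling multipliers in [0.8, 1.25],
#' vendor-score measurement noise of sd 2 (0-100 scale), a 2% MammaPrint
#' label-flip rate, and tumour sizes log-normal around a 2 cm median so the
#' size indicator splits both ways.
#'
#' @param nSamples number of samples (>= 20).
#' @param subtypeProportions named probabilities over LumA/LumB/Her2E/Basal.
#' @param expressionNoiseSd within-subtype log-scale expression noise.
#' @param gradeNoiseSd sd of the per-sample continuous proliferation/grade
#'   axis (each sample slides along the LumB-minus-LumA direction), giving
#'   the risk-score continuum real cohorts show instead of discrete subtype
#'   clusters.
#' @param centeringShiftSd sd of the hidden additive centering perturbation.
#' @param scalingMultRange range of the hidden multiplicative scaling
#'   perturbation.
#' @param scoreNoiseSd sd of the measurement noise added to true scores.
#' @param labelFlipProb probability a true MammaPrint label is flipped.
#' @param hkNoiseSd between-sample sd of housekeeping log2 levels.
#' @param tumourSizeMeanlog,tumourSizeSdlog log-normal tumour size parameters.
#' @param seed integer seed controlling every draw.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 200,
                             subtypeProportions = c(LumA = 0.45, LumB = 0.35,
                                                    Her2E = 0.12, Basal = 0.08),
                             expressionNoiseSd = 0.35,
                             gradeNoiseSd = 0.6,
                             centeringShiftSd = 0.5,
                             scalingMultRange = c(0.8, 1.25),
                             scoreNoiseSd = 2,
                             labelFlipProb = 0.02,
                             hkNoiseSd = 0.08,
                             tumourSizeMeanlog = log(2),
                             tumourSizeSdlog = 0.4,
                             seed = 1L) {
  methods::new("SimulationConfig",
    nSamples = as.integer(nSamples),
    subtypeProportions = subtypeProportions,
    expressionNoiseSd = expressionNoiseSd,
    gradeNoiseSd = gradeNoiseSd,
    centeringShiftSd = centeringShiftSd,
    scalingMultRange = as.numeric(scalingMultRange),
    scoreNoiseSd = scoreNoiseSd,
    labelFlipProb = labelFlipProb,
    hkNoiseSd = hkNoiseSd,
    tumourSizeMeanlog = tumourSizeMeanlog,
    tumourSizeSdlog = tumourSizeSdlog,
    seed = as.integer(seed))
}

#' Perturb centering/scaling factors
#'
#' Creates the hidden "vendor" factors the training stage must recover:
#' centering shifted by Gaussian offsets of the configured sd, scaling
#' multiplied by uniform factors within the configured range. Seeded and
#' reproducible.
#'
#' @param base \linkS4class{ScalingFactors} to perturb.
#' @param config \linkS4class{SimulationConfig}.
#' @return perturbed \linkS4class{ScalingFactors}.
#' @export
perturbFactors <- function(base, config) {
  methods::validObject(config)
  if (config@scalingMultRange[1] <= 0)
    stop("scaling perturbation range must keep scaling positive")
  p <- length(base@geneIds)
  set.seed(deriveSeed(config@seed, 1L))
  shift <- if (config@centeringShiftSd > 0)
    stats::rnorm(p, 0, config@centeringShiftSd) else numeric(p)
  mult <- stats::runif(p, config@scalingMultRange[1], config@scalingMultRange[2])
  methods::new("ScalingFactors", geneIds = base@geneIds,
               centering = base@centering + shift,
               scaling = base@scaling * mult)
}

# Latent subtype mean profiles, base location/gain and bimodal mixture
# parameters for every reporter gene in the union of the three panels.
unionGeneTable <- function(centroids) {
  pros <- readConstantTsv(panelConfig()$prosigna$panel_file)
  pros$gene <- canonicalizeGenes(pros$gene)
  pros <- pros[pros$role != "housekeeping", ]
  ptab <- data.frame(gene = pros$gene,
                     centroids@values[pros$gene, , drop = FALSE],
                     base_center = as.numeric(pros$base_center),
                     base_scale = as.numeric(pros$base_scale),
                     bimodal_prob = 0, bimodal_shift = 0,
                     row.names = NULL, check.names = FALSE)
  extra <- loadGeneParams()
  extra$gene <- canonicalizeGenes(extra$gene)
  rbind(ptab, extra[, colnames(ptab)])
}

#' Generate synthetic panel expression
#'
#' Draws each sample's latent profile from its subtype's centroid-anchored
#' mean with Gaussian log-scale noise, standardizes it per gene by the
#' analytic population moments implied by the configuration, maps it through
#' the packaged per-gene location/gain onto log2-ratio scale, and adds a
#' housekeeping baseline to produce strictly positive NanoString-style
#' intensities. Housekeeping genes get low between-sample variance.
#'
#' @param config \linkS4class{SimulationConfig}.
#' @param centroids \linkS4class{SubtypeCentroids} anchoring the Prosigna
#'   genes; other panels' genes use the packaged synthetic profiles.
#' @return list with \code{counts} (samples x genes positive intensities),
#'   \code{subtype} assignments, and \code{latent} (the standardized latent
#'   profiles the true scores are computed from).
#' @export
generateExpression <- function(config, centroids = loadCentroids()) {
  methods::validObject(config)
  tab <- unionGeneTable(centroids)
  hk <- loadHousekeepingParams()
  n <- config@nSamples
  pi <- config@subtypeProportions
  subtypes <- colnames(centroids@values)

  set.seed(deriveSeed(config@seed, 2L))
  subtype <- sample(subtypes, n, replace = TRUE, prob = pi)

  mu <- as.matrix(tab[, subtypes])            # genes x 4 subtype means
  rownames(mu) <- tab$gene
  sigma <- config@expressionNoiseSd
  # analytic population moments of the latent (subtype mixture + optional
  # bimodal component + expression noise)
  mbar <- as.numeric(mu %*% pi)
  vsub <- as.numeric(((mu - mbar)^2) %*% pi)
  p_b <- tab$bimodal_prob; s_b <- tab$bimodal_shift
  grade_dir <- (mu[, "LumB"] - mu[, "LumA"]) / 2   # proliferation/grade axis
  m_pop <- mbar + p_b * s_b
  v_pop <- vsub + p_b * (1 - p_b) * s_b^2 +
    config@gradeNoiseSd^2 * grade_dir^2 + sigma^2

  G <- nrow(tab)
  u <- stats::rnorm(n, 0, config@gradeNoiseSd)
  z <- mu[, subtype, drop = FALSE] + outer(grade_dir, u) +
    matrix(stats::rnorm(G * n, 0, sigma), G, n)
  if (any(p_b > 0)) {
    bi <- which(p_b > 0)
    for (g in bi) {
      on <- stats::runif(n) < p_b[g]
      z[g, on] <- z[g, on] + s_b[g]
    }
  }
  latent <- (z - m_pop) / sqrt(v_pop)         # standardized latent profiles
  l <- tab$base_center + tab$base_scale * latent

  hk_l <- matrix(stats::rnorm(nrow(hk) * n, 0, config@hkNoiseSd), nrow(hk), n) +
    hk$log2_level
  rownames(hk_l) <- hk$gene
  geo <- colMeans(hk_l)                        # per-sample log2 geometric mean
  counts <- rbind(2^(sweep(l, 2, geo, "+")), 2^hk_l)
  rownames(counts) <- c(tab$gene, hk$gene)
  colnames(counts) <- sprintf("S%03d", seq_len(n))
  colnames(latent) <- colnames(counts)
  rownames(latent) <- tab$gene
  list(counts = t(counts), subtype = stats::setNames(subtype, colnames(counts)),
       latent = latent)
}

#' Generate a complete synthetic cohort
#'
#' Runs \code{\link{generateExpression}}, draws tumour sizes, perturbs the
#' baseline Prosigna factors into the hidden "vendor" factors, computes the
#' vendor-style true scores by running the packaged reference algorithms
#' (Prosigna steps with the hidden factors; Oncotype with the published
#' metagene weights; MammaPrint as the gene70 correlation against the
#' template), adds measurement noise, truncates to the valid ranges, and
#' packs everything into a \linkS4class{SurrogateCohort} whose metadata
#' records all hidden parameters.
#'
#' @param config \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SurrogateCohort}.
#' @examples
#' coh <- generateCohort(simulationConfig(nSamples = 40, seed = 7))
#' head(trueScores(coh, "ROR_PT"))
#' @export
generateCohort <- function(config = simulationConfig()) {
  methods::validObject(config)
  centroids <- loadCentroids()
  prosPanel <- loadPanel("prosigna")
  oncPanel <- loadPanel("oncotype")
  hidden <- perturbFactors(baseScalingFactors(), config)
  ex <- generateExpression(config, centroids)
  n <- config@nSamples

  set.seed(deriveSeed(config@seed, 3L))
  size <- stats::rlnorm(n, config@tumourSizeMeanlog, config@tumourSizeSdlog)

  # Prosigna truth: housekeeping normalization, row-scaling with the HIDDEN
  # factors, correlation/proliferation, linear combination, vendor rescale.
  lg <- normalizeHousekeeping(ex$counts, prosPanel)
  rs <- rowScale(lg, hidden)
  co <- subtypeCorrelations(rs, centroids)
  pr <- proliferationScore(rs, prosPanel)
  w <- loadRorWeights()
  set.seed(deriveSeed(config@seed, 4L))
  truth <- list()
  for (kind in c("ROR", "ROR_P", "ROR_PT")) {
    rc <- truthRescale("prosigna", kind)
    raw <- rorScores(co, pr, size, w, variant = kind)
    val <- rescaleTruncate(raw, rc$offset, rc$slope) +
      stats::rnorm(n, 0, config@scoreNoiseSd)
    truth[[kind]] <- pmin(pmax(val, 0), 100)
  }

  # Oncotype truth: its own reference-gene normalization, metagene scores
  # with the GSTM1/CTSV rules, published weights, packaged rescale.
  lg_onc <- normalizeHousekeeping(ex$counts, oncPanel)
  mg <- metageneScores(lg_onc, loadMetageneModel("cohort"))
  rs_true <- recurrenceScore(mg, loadMetageneModel("cohort")) +
    stats::rnorm(n, 0, config@scoreNoiseSd)
  truth$RS <- pmin(pmax(rs_true, 0), 100)

  # MammaPrint truth: gene70 correlation of the standardized latent profile
  # with the template, thresholded, then flipped with small probability.
  tmpl <- loadGene70Template()
  set.seed(deriveSeed(config@seed, 5L))
  lat <- t(ex$latent[tmpl@genes, , drop = FALSE])
  g70 <- gene70Index(withTag(lat, "log2"), tmpl)
  lab <- categories(g70)
  flip <- stats::runif(n) < config@labelFlipProb
  lab[flip] <- ifelse(lab[flip] == "low", "high", "low")

  cd <- S4Vectors::DataFrame(
    tumour_size_cm = size, subtype = ex$subtype,
    true_ROR = truth$ROR, true_ROR_P = truth$ROR_P,
    true_ROR_PT = truth$ROR_PT, true_RS = truth$RS,
    true_mammaprint = unname(lab), row.names = rownames(ex$counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(ex$counts)), colData = cd)
  S4Vectors::metadata(se) <- list(hidden = list(
    factors = hidden, config = config, seed = config@seed,
    gene70_index = stats::setNames(scores(g70), rownames(ex$counts)),
    flipped = flip))
  methods::new("SurrogateCohort", se)
}

#' Extract the samples x genes intensity matrix of a cohort
#'
#' @param cohort a \linkS4class{SurrogateCohort}.
#' @return samples x genes matrix of positive intensities.
#' @export
panelMatrix <- function(cohort) {
  withTag(t(SummarizedExperiment::assay(cohort, "counts")), "raw_positive")
}
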