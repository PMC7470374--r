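#' @include AllClasses.R AllGenerics.R
NULL

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "surrosig", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p))
    stop("packaged constant file not found: ", file)
  p
}

readConstantTsv <- function(file) {
  utils::read.delim(extdataPath(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

panelConfig <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- yaml::read_yaml(extdataPath("panels.yaml"))
    cache
  }
})

#' Canonicalize gene symbols
#'
#' Trims whitespace, upper-cases, and resolves aliases through the packaged
#' explicit alias table. No fuzzy matching is performed: a symbol either
#' matches the table or is returned as-is.
#'
#' @param symbols character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonicalizeGenes <- function(symbols) {
  s <- toupper(trimws(symbols))
  al <- readConstantTsv(panelConfig()$aliases_file)
  hit <- match(s, toupper(al$alias))
  s[!is.na(hit)] <- al$canonical[hit[!is.na(hit)]]
  s
}

#' Load an assay gene panel
#'
#' Reads the packaged panel definition for one assay and returns a validated
#' \linkS4class{GenePanel}. The Prosigna panel carries 46 reporter genes
#' (18 of them proliferation) and 8 housekeeping genes; the Oncotype panel
#' partitions its 16 reporters into proliferation(5)/HER2(2)/ER(4)/
#' invasion(2) metagenes plus the CD68, GSTM1 and BAG1 singletons; the
#' MammaPrint panel has 70 reporters and no reference genes.
#'
#' @param assayName \code{"prosigna"}, \code{"oncotype"} or
#'   \code{"mammaprint"}.
#' @return a \linkS4class{GenePanel}.
#' @examples
#' p <- loadPanel("prosigna")
#' length(reporterGenes(p))
#' @export
loadPanel <- function(assayName) {
  assayName <- match.arg(assayName, c("prosigna", "oncotype", "mammaprint"))
  cfg <- panelConfig()[[assayName]]
  tab <- readConstantTsv(cfg$panel_file)
  if (assayName == "mammaprint") {
    genes <- canonicalizeGenes(tab$gene)
    return(methods::new("GenePanel", assayName = assayName,
      reporterGenes = genes, housekeepingGenes = character(),
      roleMap = stats::setNames(rep("reporter", length(genes)), genes),
      avgWeights = stats::setNames(rep(1, length(genes)), genes)))
  }
  if (!all(c("gene", "role") %in% colnames(tab)))
    stop("malformed panel file for ", assayName, ": need gene and role columns")
  tab$gene <- canonicalizeGenes(tab$gene)
  hk <- tab$gene[tab$role == "housekeeping"]
  rep_tab <- tab[tab$role != "housekeeping", ]
  w <- if ("avg_weight" %in% colnames(rep_tab)) {
    as.numeric(rep_tab$avg_weight)
  } else rep(1, nrow(rep_tab))
  methods::new("GenePanel", assayName = assayName,
    reporterGenes = rep_tab$gene, housekeepingGenes = hk,
    roleMap = stats::setNames(tab$role, tab$gene),
    avgWeights = stats::setNames(w, rep_tab$gene))
}

#' Load the packaged subtype centroids
#'
#' 46 genes x 4 subtypes (LumA, LumB, HER2-enriched, Basal), gene order
#' identical to the Prosigna panel reporter order. The packaged values are a
#' synthetic stand-in for the published centroids (see the file header).
#'
#' @return a \linkS4class{SubtypeCentroids}.
#' @export
loadCentroids <- function() {
  tab <- readConstantTsv(panelConfig()$prosigna$centroids_file)
  genes <- canonicalizeGenes(tab$gene)
  m <- as.matrix(tab[, setdiff(colnames(tab), "gene")])
  rownames(m) <- genes
  panel <- loadPanel("prosigna")
  if (!identical(genes, reporterGenes(panel)))
    stop("centroid gene order does not match the Prosigna panel")
  methods::new("SubtypeCentroids", values = m)
}

truthRescale <- function(assayName, kind = NULL) {
  cfg <- panelConfig()[[assayName]]$truth_rescale
  if (!is.null(kind)) cfg <- cfg[[kind]]
  list(offset = cfg$offset, slope = cfg$slope)
}

#' Load the ROR linear-combination weights
#'
#' Four subtype-correlation weights, the proliferation weight, the
#' tumour-size indicator weight and the packaged 0-100 rescale constants for
#' ROR-PT. Packaged values are synthetic stand-ins (the vendor constants are
#' not public); the structure matches the published algorithm.
#'
#' @return a \linkS4class{RorWeights}.
#' @export
loadRorWeights <- function() {
  cfg <- panelConfig()$prosigna
  sw <- unlist(cfg$ror_weights$subtype)
  rs <- truthRescale("prosigna", "ROR_PT")
  methods::new("RorWeights",
    subtypeWeights = sw,
    proliferationWeight = cfg$ror_weights$proliferation,
    sizeWeight = cfg$ror_weights$size,
    rescaleOffset = rs$offset, rescaleSlope = rs$slope)
}

#' Load the Oncotype metagene model
#'
#' Metagene membership and within-group averaging weights come from the
#' packaged panel file; the between-group coefficients are the published
#' Recurrence Score weights. \code{rescale = "cohort"} (default) uses the
#' packaged constants calibrated for this package's log2-ratio scale;
#' \code{rescale = "published"} uses the published 20 x (RSu - 6.7) form,
#' which presumes data mapped onto the vendor's 0-15 reference-normalized
#' measurement range.
#'
#' @param rescale \code{"cohort"} or \code{"published"}.
#' @return a \linkS4class{MetageneModel}.
#' @export
loadMetageneModel <- function(rescale = c("cohort", "published")) {
  rescale <- match.arg(rescale)
  cfg <- panelConfig()$oncotype
  panel <- loadPanel("oncotype")
  roles <- roleMap(panel)[reporterGenes(panel)]
  defs <- lapply(split(reporterGenes(panel), roles), function(g) {
    data.frame(gene = g, weight = panel@avgWeights[g], row.names = NULL)
  })
  rs <- if (rescale == "cohort") cfg$truth_rescale else cfg$published_rescale
  methods::new("MetageneModel",
    definitions = defs,
    weights = unlist(cfg$metagene_weights)[names(defs)],
    rescaleOffset = rs$offset, rescaleSlope = rs$slope,
    gstm1Threshold = isTRUE(cfg$gstm1_threshold),
    ctsl2Excluded = isTRUE(cfg$ctsl2_excluded),
    gstm1Background = cfg$gstm1_background)
}

#' Load the gene70 good-prognosis template
#'
#' The packaged 70-gene template profile (synthetic stand-in) and the
#' correlation cutoff separating low from high risk.
#'
#' @return a \linkS4class{Gene70Template}.
#' @export
loadGene70Template <- function() {
  cfg <- panelConfig()$mammaprint
  tab <- readConstantTsv(cfg$template_file)
  genes <- canonicalizeGenes(tab$gene)
  panel <- loadPanel("mammaprint")
  if (!identical(genes, reporterGenes(panel)))
    stop("gene70 template gene order does not match the MammaPrint panel")
  methods::new("Gene70Template", genes = genes,
               values = as.numeric(tab$value),
               cutoff = cfg$correlation_cutoff)
}

#' Load the published/packaged constants of one assay
#'
#' Convenience dispatcher over the specific loaders: for Prosigna a list with
#' the centroids and ROR weights, for Oncotype the metagene model, for
#' MammaPrint the gene70 template.
#'
#' @param assayName assay identifier.
#' @export
loadConstants <- function(assayName) {
  assayName <- match.arg(assayName, c("prosigna", "oncotype", "mammaprint"))
  switch(assayName,
    prosigna = list(centroids = loadCentroids(), rorWeights = loadRorWeights()),
    oncotype = loadMetageneModel(),
    mammaprint = loadGene70Template())
}

#' Baseline centering/scaling factors of the Prosigna panel
#'
#' The packaged per-gene log2 location and gain constants used by the cohort
#' generator as the unperturbed ("vendor nominal") row-scaling factors.
#'
#' @return a \linkS4class{ScalingFactors} over the 46 reporter genes.
#' @export
baseScalingFactors <- function() {
  tab <- readConstantTsv(panelConfig()$prosigna$panel_file)
  tab$gene <- canonicalizeGenes(tab$gene)
  rep_tab <- tab[tab$role != "housekeeping", ]
  methods::new("ScalingFactors", geneIds = rep_tab$gene,
               centering = as.numeric(rep_tab$base_center),
               scaling = as.numeric(rep_tab$base_scale))
}

# Generative constants for reporter genes outside the Prosigna panel.
loadGeneParams <- function() {
  readConstantTsv("gene_params_synthetic.tsv")
}

loadHousekeepingParams <- function() {
  readConstantTsv("housekeeping_params_synthetic.tsv")
}
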