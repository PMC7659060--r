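#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom BiocGenerics start end width strand strand<- sort
#' @importFrom GenomicRanges GRanges GRangesList seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats setNames
NULL

## as.character() drops names from plain character vectors; XStringSet
## inputs keep them. Normalise to a named character vector either way.
.asNamedChar <- function(x) {
  n <- names(x)
  x <- as.character(x)
  names(x) <- n
  x
}

## Closed vocabulary of conserved-domain labels recognised by the census.
DOMAIN_LEVELS <- c("inhibitor_I29", "peptidase_C1", "GRAN",
                   "propeptide_C1", "peptidase_C1A_cathepsinB")

## Temporal expression pattern classes (nodule time course).
PATTERN_LEVELS <- c("senescence_up", "development_down", "mid_peak",
                    "down_then_up", "up_then_down", "bimodal", "flat")

#' Gene models for one genome
#'
#' Holds one representative transcript structure per gene: the gene span, and
#' exon/CDS/UTR segments as \code{GRangesList}s parallel to the genes. All
#' coordinates are 1-based inclusive, exactly as in GFF3; no half-open
#' conversion happens anywhere in the package.
#'
#' @slot genes \code{GRanges} of gene spans, named by gene id.
#' @slot exons,cds,utr5,utr3 \code{GRangesList}s named by gene id, each list
#'   element sorted by start coordinate.
#' @export
setClass("GeneModelSet",
         representation(genes = "GRanges", exons = "GRangesList",
                        cds = "GRangesList", utr5 = "GRangesList",
                        utr3 = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msgs <- character(0)
  ids <- names(object@genes)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "gene ranges must be uniquely named by gene id")
  for (slotnm in c("exons", "cds", "utr5", "utr3")) {
    grl <- slot(object, slotnm)
    if (!identical(names(grl), ids))
      msgs <- c(msgs, sprintf("names of '%s' must match gene ids", slotnm))
  }
  if (!all(as.character(strand(object@genes)) %in% c("+", "-")))
    msgs <- c(msgs, "gene strand must be '+' or '-'")
  ex <- object@exons
  st <- as.list(start(ex)); en <- as.list(end(ex))
  cst <- as.list(start(object@cds)); cen <- as.list(end(object@cds))
  gs <- start(object@genes); ge <- end(object@genes)
  hasCds <- lengths(object@cds) > 0L
  for (i in seq_along(st)) {
    s <- st[[i]]; e <- en[[i]]
    if (length(s) == 0L) { msgs <- c(msgs, sprintf("gene '%s' has no exons", ids[i])); next }
    if (is.unsorted(s) || any(s[-1] <= e[-length(e)]))
      msgs <- c(msgs, sprintf("exons of gene '%s' are unsorted or overlap", ids[i]))
    if (s[1] < gs[i] || e[length(e)] > ge[i])
      msgs <- c(msgs, sprintf("gene span of '%s' does not cover its exons", ids[i]))
    if (!hasCds[i]) next
    cs <- cst[[i]]; ce <- cen[[i]]
    for (j in seq_along(cs)) {
      if (!any(s <= cs[j] & e >= ce[j]))
        msgs <- c(msgs, sprintf("CDS interval [%d,%d] of gene '%s' lies outside exons",
                                cs[j], ce[j], ids[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Run configuration for the survey pipeline
#'
#' Tunable parameters shared by the pipeline stages. The synonymous clock rate
#' defaults to 6.1e-9 substitutions per synonymous site per year, the rate
#' used to date the recent Glycine whole-genome duplication.
#'
#' @slot clockRate substitutions/synonymous site/year.
#' @slot tandemMaxIntervening maximum number of non-family genes allowed
#'   between consecutive members of a tandem cluster.
#' @slot collinearityWindow gene-count half-window around a focal pair within
#'   which collinearity anchors are sought.
#' @slot collinearityMinAnchors minimum chained anchors (focal pair included)
#'   for a segment pair to count as collinear.
#' @slot bootstrapReplicates bootstrap replicates for tree support.
#' @slot randomSeed seed for every stochastic operation in a run.
#' @slot foldChangeThreshold ratio that makes a consecutive-timepoint change
#'   "significant" in pattern classification.
#' @slot expressionHighQuantile per-sample quantile above which a gene counts
#'   as highly expressed for RNS candidacy.
#' @slot wgdKsWindow numeric(2), Ks interval for WGD-derived candidate pairs.
#' @slot truncationCoverageMin minimum peptidase_C1 hit coverage (fraction of
#'   the reference domain length) below which a locus is called a pseudogene.
#' @slot ksSummary "min" or "mean": reduction of member-pair Ks values to one
#'   representative Ks per segment pair.
#' @export
setClass("SurveyConfig",
         representation(clockRate = "numeric", tandemMaxIntervening = "integer",
                        collinearityWindow = "integer",
                        collinearityMinAnchors = "integer",
                        bootstrapReplicates = "integer", randomSeed = "integer",
                        foldChangeThreshold = "numeric",
                        expressionHighQuantile = "numeric",
                        wgdKsWindow = "numeric",
                        truncationCoverageMin = "numeric",
                        ksSummary = "character"))

setValidity("SurveyConfig", function(object) {
  msgs <- character(0)
  if (object@clockRate <= 0) msgs <- c(msgs, "clockRate must be > 0")
  for (nm in c("tandemMaxIntervening", "collinearityWindow",
               "collinearityMinAnchors", "bootstrapReplicates"))
    if (slot(object, nm) < 1L && nm != "tandemMaxIntervening")
      msgs <- c(msgs, sprintf("%s must be positive", nm))
  if (object@tandemMaxIntervening < 0L)
    msgs <- c(msgs, "tandemMaxIntervening must be >= 0")
  if (object@expressionHighQuantile <= 0 || object@expressionHighQuantile >= 1)
    msgs <- c(msgs, "expressionHighQuantile must lie in (0, 1)")
  if (object@foldChangeThreshold <= 1)
    msgs <- c(msgs, "foldChangeThreshold must exceed 1")
  if (length(object@wgdKsWindow) != 2L || diff(object@wgdKsWindow) <= 0)
    msgs <- c(msgs, "wgdKsWindow must be an increasing numeric(2)")
  if (object@truncationCoverageMin <= 0 || object@truncationCoverageMin > 1)
    msgs <- c(msgs, "truncationCoverageMin must lie in (0, 1]")
  if (!object@ksSummary %in% c("min", "mean"))
    msgs <- c(msgs, "ksSummary must be 'min' or 'mean'")
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration for the synthetic genome
#'
#' The stated world of the simulator: an ancestral gene set duplicated once
#' genome-wide (WGD), plus tandem clusters, pseudogenised members and a
#' nodule expression time course with known temporal classes.
#'
#' @slot nAncestralGenes ancestral family size (each yields one WGD pair).
#' @slot wgdTargetKs expected synonymous substitutions/site separating the
#'   two WGD copies (the recent Glycine WGD cohort spans roughly 0.10-0.34).
#' @slot kaKsRatio nonsynonymous rate as a fraction of the synonymous rate.
#' @slot tandemClusterSizes cluster sizes (>= 2) of tandem arrays grafted onto
#'   the first families; mirrors the chromosome-6 style clusters of 3 and 2.
#' @slot tandemTargetKs expected Ks separating tandem siblings.
#' @slot pseudogeneFraction fraction of emitted family loci pseudogenised.
#' @slot codonLength codons per ancestral gene.
#' @slot nChromosomes even number of chromosomes; the second half carries the
#'   WGD copies of the first half, in the same gene order.
#' @slot backgroundPerGap non-family genes between consecutive family genes.
#' @slot intergenicSpacer bp between consecutive gene starts.
#' @slot qpcrNoiseSd Gaussian noise on simulated Ct values, in cycles.
#' @slot efficiency qPCR amplification factor per cycle, in (1, 2].
#' @slot seed integer seed; identical configs give byte-identical bundles.
#' @slot shuffleOrder permute gene order per chromosome (negative control for
#'   collinearity).
#' @export
setClass("SimConfig",
         representation(nAncestralGenes = "integer", wgdTargetKs = "numeric",
                        kaKsRatio = "numeric", tandemClusterSizes = "integer",
                        tandemTargetKs = "numeric",
                        pseudogeneFraction = "numeric", codonLength = "integer",
                        nChromosomes = "integer", backgroundPerGap = "integer",
                        intergenicSpacer = "integer", qpcrNoiseSd = "numeric",
                        efficiency = "numeric", seed = "integer",
                        shuffleOrder = "logical"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@wgdTargetKs < 0) msgs <- c(msgs, "wgdTargetKs must be >= 0")
  if (object@pseudogeneFraction < 0 || object@pseudogeneFraction >= 1)
    msgs <- c(msgs, "pseudogeneFraction must lie in [0, 1)")
  if (object@efficiency <= 1 || object@efficiency > 2)
    msgs <- c(msgs, "efficiency must lie in (1, 2]")
  if (object@nChromosomes < 2L || object@nChromosomes %% 2L != 0L)
    msgs <- c(msgs, "nChromosomes must be even and >= 2")
  if (any(object@tandemClusterSizes < 2L))
    msgs <- c(msgs, "tandem cluster sizes must be >= 2")
  if (object@codonLength < 10L)
    msgs <- c(msgs, "codonLength must be >= 10")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a synthetic bundle
#'
#' @slot duplicatePairs data.frame(gene_a, gene_b, true_ks, origin) with
#'   origin "WGD" or "tandem".
#' @slot pseudogenes data.frame(gene_id, reason), reason "truncation" or
#'   "domain_deletion".
#' @slot groupAssignment named character, gene id -> clade label.
#' @slot expressionClass named character, gene id -> temporal class.
#' @slot rnsCandidates gene ids designed to be highly expressed in both
#'   symbiosis-related tissues and nodule stages.
#' @slot referenceGenes the two designed flat qPCR reference genes.
#' @slot unstableReferences designed unstable reference candidates.
#' @export
setClass("GroundTruth",
         representation(duplicatePairs = "data.frame",
                        pseudogenes = "data.frame",
                        groupAssignment = "character",
                        expressionClass = "character",
                        rnsCandidates = "character",
                        referenceGenes = "character",
                        unstableReferences = "character"))

#' A simulated survey bundle
#'
#' Everything one survey run consumes, plus the generating truth.
#'
#' @slot cds \code{DNAStringSet} of family coding sequences.
#' @slot proteins \code{AAStringSet} of family protein sequences.
#' @slot models \code{GeneModelSet} covering family and background genes.
#' @slot domainHits data.frame(protein_id, domain, start, end,
#'   reference_length).
#' @slot familyIds ids of the family loci (members + pseudogenes).
#' @slot paralogy data.frame(gene_a, gene_b): supplied paralogy between
#'   background genes (the detectable WGD duplicates outside the family),
#'   used as collinearity anchors.
#' @slot truth \code{GroundTruth}.
#' @export
setClass("SurveyBundle",
         representation(cds = "DNAStringSet", proteins = "AAStringSet",
                        models = "GeneModelSet", domainHits = "data.frame",
                        familyIds = "character", paralogy = "data.frame",
                        truth = "GroundTruth"))

#' Report of one pipeline run
#'
#' @slot stages data.frame(stage, status, records, output) in execution order.
#' @slot seed seed the run used.
#' @slot outDir output directory.
#' @export
setClass("PipelineReport",
         representation(stages = "data.frame", seed = "integer",
                        outDir = "character"))

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet with %d genes on %d sequences\n",
              length(object@genes),
              length(unique(as.character(seqnames(object@genes))))))
})

setMethod("show", "SurveyBundle", function(object) {
  cat(sprintf(
    "SurveyBundle: %d family loci (%d pseudogenes), %d gene models, %d WGD pairs\n",
    length(object@familyIds), nrow(object@truth@pseudogenes),
    length(object@models@genes),
    sum(object@truth@duplicatePairs$origin == "WGD")))
})

setMethod("show", "PipelineReport", function(object) {
  cat("Pipeline run (seed", object@seed, ") ->", object@outDir, "\n")
  print(object@stages, row.names = FALSE)
})
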