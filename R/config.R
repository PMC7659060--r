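#' Create a survey run configuration
#'
#' Defaults reflect the survey's stated world: a synonymous clock of
#' 6.1e-9 substitutions/site/year for dating, a WGD Ks window of
#' [0.06, 0.45] bracketing the recent-duplication cohort (observed
#' 0.1028-0.3374) with margin, strictly adjacent tandem clusters allowing one
#' intervening gene, a 25-gene collinearity window with at least 3 chained
#' anchors, 1000 bootstrap replicates, a 2-fold significance threshold for
#' temporal changes and an upper-quartile cutoff for "highly expressed".
#'
#' @param clockRate synonymous substitution rate per site per year.
#' @param tandemMaxIntervening max non-family genes between tandem members.
#' @param collinearityWindow half-window (genes) for collinearity anchors.
#' @param collinearityMinAnchors min chained anchors incl. the focal pair.
#' @param bootstrapReplicates bootstrap replicates.
#' @param randomSeed integer seed used by all stochastic stages.
#' @param foldChangeThreshold significant consecutive-timepoint ratio.
#' @param expressionHighQuantile per-sample quantile for RNS candidacy.
#' @param wgdKsWindow numeric(2) Ks interval for WGD candidates.
#' @param truncationCoverageMin peptidase_C1 coverage below which a locus is
#'   a pseudogene (the "large fragment deletion" rule).
#' @param ksSummary "min" (default) or "mean" member-pair Ks reduction.
#' @return A [SurveyConfig-class] object.
#' @export
#' @examples
#' cfg <- surveyConfig(bootstrapReplicates = 100)
#' divergenceTime(0.3374, cfg@clockRate)
surveyConfig <- function(clockRate = 6.1e-9,
                         tandemMaxIntervening = 1L,
                         collinearityWindow = 25L,
                         collinearityMinAnchors = 3L,
                         bootstrapReplicates = 1000L,
                         randomSeed = 1L,
                         foldChangeThreshold = 2,
                         expressionHighQuantile = 0.75,
                         wgdKsWindow = c(0.06, 0.45),
                         truncationCoverageMin = 0.6,
                         ksSummary = "min") {
  new("SurveyConfig", clockRate = clockRate,
      tandemMaxIntervening = as.integer(tandemMaxIntervening),
      collinearityWindow = as.integer(collinearityWindow),
      collinearityMinAnchors = as.integer(collinearityMinAnchors),
      bootstrapReplicates = as.integer(bootstrapReplicates),
      randomSeed = as.integer(randomSeed),
      foldChangeThreshold = foldChangeThreshold,
      expressionHighQuantile = expressionHighQuantile,
      wgdKsWindow = as.numeric(wgdKsWindow),
      truncationCoverageMin = truncationCoverageMin,
      ksSummary = ksSummary)
}

#' Create a simulation configuration
#'
#' The defaults emulate the inferred family history: every ancestral gene
#' duplicated once by a recent WGD with an expected synonymous divergence of
#' 0.2 (the middle of the observed 0.10-0.34 cohort), nonsynonymous changes
#' at one fifth of the synonymous rate (omega ~ 0.2, typical of the
#' purifying-selection regime the segment pairs show), tandem arrays of 3 and
#' 2 genes as on chromosome 6, and a pseudogene fraction of 0.085 (9 of 106
#' loci). Family genes sit among background genes at a density of one family
#' locus per 100 genes: still denser than a real genome (soybean carries
#' roughly one PLCP per 580 annotated genes) but sparse enough that
#' chance collinearity chains are rare, as they are in real data.
#'
#' @param nAncestralGenes ancestral family size.
#' @param wgdTargetKs expected Ks separating WGD copies.
#' @param kaKsRatio nonsynonymous/synonymous rate ratio.
#' @param tandemClusterSizes integer vector of tandem array sizes (>= 2).
#' @param tandemTargetKs expected Ks separating tandem siblings.
#' @param pseudogeneFraction fraction of family loci pseudogenised.
#' @param codonLength codons per gene.
#' @param nChromosomes even chromosome count (second half = WGD copies).
#' @param backgroundPerGap non-family genes between consecutive family genes.
#' @param intergenicSpacer bp between consecutive gene starts.
#' @param qpcrNoiseSd Ct noise (cycles).
#' @param efficiency qPCR amplification efficiency, in (1, 2].
#' @param seed integer seed.
#' @param shuffleOrder permute per-chromosome gene order (breaks
#'   collinearity; negative-control mode).
#' @return A [SimConfig-class] object.
#' @export
#' @examples
#' bundle <- simulateFamily(simConfig(nAncestralGenes = 6, seed = 7))
#' bundle
simConfig <- function(nAncestralGenes = 25L,
                      wgdTargetKs = 0.2,
                      kaKsRatio = 0.2,
                      tandemClusterSizes = c(3L, 2L),
                      tandemTargetKs = 0.03,
                      pseudogeneFraction = 0.085,
                      codonLength = 320L,
                      nChromosomes = 4L,
                      backgroundPerGap = 99L,
                      intergenicSpacer = 3000L,
                      qpcrNoiseSd = 0.2,
                      efficiency = 2,
                      seed = 1L,
                      shuffleOrder = FALSE) {
  new("SimConfig", nAncestralGenes = as.integer(nAncestralGenes),
      wgdTargetKs = wgdTargetKs, kaKsRatio = kaKsRatio,
      tandemClusterSizes = as.integer(tandemClusterSizes),
      tandemTargetKs = tandemTargetKs,
      pseudogeneFraction = pseudogeneFraction,
      codonLength = as.integer(codonLength),
      nChromosomes = as.integer(nChromosomes),
      backgroundPerGap = as.integer(backgroundPerGap),
      intergenicSpacer = as.integer(intergenicSpacer),
      qpcrNoiseSd = qpcrNoiseSd, efficiency = efficiency,
      seed = as.integer(seed), shuffleOrder = shuffleOrder)
}
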