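## Designed temporal mean profiles, as log2 fold change relative to the
## first nodule timepoint. Margins between "significant" (>= 1 log2) and
## non-significant (< 1 log2) steps are wide relative to realistic qPCR
## noise, so class recovery degrades gracefully with noise.
.CLASS_PROFILES <- list(
  senescence_up    = c(0,  1.3,  2.6,  3.9,  5.2),
  development_down = c(0, -1.4, -2.6, -3.4, -3.6),
  mid_peak         = c(0,  1.2,  2.6,  0.3, -0.6),
  down_then_up     = c(0, -1.8, -2.3, -0.8,  1.4),
  up_then_down     = c(0,  1.1,  2.2,  3.0,  1.0),
  bimodal          = c(0,  2.8,  0.3,  0.3,  3.4),
  flat             = c(0,  0.0,  0.0,  0.0,  0.0))

.SYMBIOSIS_SAMPLES <- c("nodules", "root_hairs", "roots",
                        "nodules_symbiotic", "roots_symbiotic")

.classProfile <- function(class, nT) {
  p <- .CLASS_PROFILES[[class]]
  if (is.null(p)) stop("unknown temporal class label '", class, "'")
  if (nT == length(p)) p else stats::approx(seq_along(p), p, n = nT)$y
}

#' Simulate tissue expression and a nodule qPCR time course
#'
#' Builds (1) a tissue-screening matrix over five symbiosis-related tissues
#' and the nodule timepoints, in which the designed RNS candidates are highly
#' expressed in both tissue classes (plus symbiosis-only and nodule-only
#' decoys, each gene topping the per-sample upper quartile in a designated
#' sample), and (2) a replicated qPCR Ct table for all classed genes plus
#' four candidate reference genes: two designed flat references (REF1, REF2)
#' and two unstable ones (REF3 drifts up, REF4 drifts down). Ct values are
#' baseline - log_E(relative quantity) plus Gaussian noise of sd
#' \code{qpcrNoiseSd}, three replicates per sample.
#'
#' @param truth a [GroundTruth-class] carrying expression classes.
#' @param timepoints ordered nodule sample names (default the canonical
#'   12/30/42/64/84 days-after-inoculation series).
#' @param cfg a [SimConfig-class] (noise sd, efficiency, seed).
#' @return list(se = \code{SummarizedExperiment}, ct = Ct data.frame).
#' @export
simulateExpression <- function(truth,
                               timepoints = c("12dN", "30dN", "42dN",
                                              "64dN", "84dN"),
                               cfg = simConfig()) {
  set.seed(cfg@seed + 1L)
  classes <- truth@expressionClass
  genes <- names(classes)
  bad <- setdiff(unique(classes), names(.CLASS_PROFILES))
  if (length(bad)) stop("unknown temporal class label '", bad[1], "'")
  nT <- length(timepoints)
  if (nT < 3L) stop("need at least 3 timepoints")

  ## ---- tissue-screening matrix -------------------------------------
  rns <- truth@rnsCandidates
  symOnly <- attr(rns, "symbiosis_only")
  nodOnly <- attr(rns, "nodule_only")
  samples <- c(.SYMBIOSIS_SAMPLES, timepoints)
  sclass <- c(rep("symbiosis", length(.SYMBIOSIS_SAMPLES)),
              rep("nodule", nT))
  base <- 5 + 10 * ((seq_along(genes) * 7L) %% 11L) / 11L
  names(base) <- genes
  mat <- matrix(rep(base, length(samples)), nrow = length(genes),
                dimnames = list(genes, samples))
  boost <- function(ids, cols) {
    if (!length(ids)) return()
    for (k in seq_along(ids)) {
      designated <- cols[(k - 1L) %% length(cols) + 1L]
      mat[ids[k], cols] <<- mat[ids[k], cols] * 10
      mat[ids[k], designated] <<- mat[ids[k], designated] * 10
    }
  }
  symCols <- which(sclass == "symbiosis")
  nodCols <- which(sclass == "nodule")
  boost(as.character(rns), symCols)
  boost(as.character(rns), nodCols)
  boost(symOnly, symCols)
  boost(nodOnly, nodCols)
  mat <- mat * exp(matrix(stats::rnorm(length(mat), 0, 0.05), nrow(mat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    colData = S4Vectors::DataFrame(tissue_class = sclass,
                                   row.names = samples))

  ## ---- qPCR Ct table ------------------------------------------------
  E <- cfg@efficiency
  log2fc <- rbind(
    do.call(rbind, lapply(genes, function(g)
      .classProfile(classes[[g]], nT))),
    REF1 = rep(0, nT), REF2 = rep(0, nT),
    REF3 = seq(0, 3.2, length.out = nT),
    REF4 = seq(0, -3.2, length.out = nT))
  allGenes <- c(genes, "REF1", "REF2", "REF3", "REF4")
  rownames(log2fc) <- allGenes
  ct0 <- 18 + (seq_along(allGenes) %% 8L)
  rows <- expand.grid(replicate = 1:3, sample_id = timepoints,
                      gene_id = allGenes, stringsAsFactors = FALSE)
  rows <- rows[, c("gene_id", "sample_id", "replicate")]
  idx <- cbind(match(rows$gene_id, allGenes),
               match(rows$sample_id, timepoints))
  rows$ct <- ct0[idx[, 1]] - log2fc[idx] * log(2) / log(E) +
    stats::rnorm(nrow(rows), 0, cfg@qpcrNoiseSd)
  rows$efficiency <- E
  list(se = se, ct = rows)
}
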