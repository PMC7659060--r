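## replicate-averaged Ct matrix (genes x samples) plus replicate SDs
.ctSummaries <- function(ct) {
  genes <- unique(ct$gene_id); samples <- unique(ct$sample_id)
  mean_ct <- tapply(ct$ct, list(ct$gene_id, ct$sample_id), mean)
  sd_ct <- tapply(ct$ct, list(ct$gene_id, ct$sample_id), stats::sd)
  eff <- tapply(ct$efficiency, ct$gene_id, mean)
  eff <- stats::setNames(as.numeric(eff), dimnames(eff)[[1]])
  list(mean = mean_ct[genes, samples, drop = FALSE],
       sd = sd_ct[genes, samples, drop = FALSE],
       eff = eff[genes], genes = genes, samples = samples)
}

#' geNorm expression stability of candidate reference genes
#'
#' For each gene the relative quantity per sample is Q = E^(minCt - Ct)
#' (replicate-mean Ct, per-gene minimum across samples). The geNorm
#' stability of candidate j is M_j = the mean, over the other candidates k,
#' of the standard deviation across samples of log2(Q_j / Q_k). Lower M is
#' more stable; the classic screen ranks four candidates and keeps the best
#' two as references.
#'
#' @param ct Ct table (see [readCtTable()]).
#' @param candidates ids of >= 2 candidate reference genes.
#' @return data.frame(gene_id, M, rank), ranked ascending in M.
#' @export
genormStability <- function(ct, candidates) {
  if (length(candidates) < 2L) stop("need >= 2 candidate references")
  cs <- .ctSummaries(ct)
  if (length(cs$samples) < 2L) stop("need >= 2 samples")
  miss <- candidates[!candidates %in% cs$genes]
  if (length(miss))
    stop("candidate(s) missing from the Ct table: ",
         paste(miss, collapse = ", "))
  sub <- cs$mean[candidates, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- candidates[apply(is.na(sub), 1, any)]
    stop("candidate(s) missing in some sample: ", paste(bad, collapse = ", "))
  }
  logQ <- log2(cs$eff[candidates]) * (apply(sub, 1, min) - sub)
  M <- vapply(seq_along(candidates), function(j) {
    others <- setdiff(seq_along(candidates), j)
    mean(vapply(others, function(k)
      stats::sd(logQ[j, ] - logQ[k, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene_id = candidates, M = M, stringsAsFactors = FALSE)
  out <- out[order(out$M, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Efficiency-corrected relative expression of a target gene
#'
#' Replicate Cts are averaged per (gene, sample); the per-sample
#' normalisation factor is the geometric mean of the reference quantities
#' E^(-Ct); the normalised target quantity is divided by its value in the
#' baseline sample, so the baseline fold change is exactly 1. With E = 2 and
#' a single reference this reduces to the classic 2^-ddCt. Replicate SDs are
#' propagated to the fold changes by first-order (delta-method) error
#' propagation.
#'
#' @param ct Ct table.
#' @param target target gene id.
#' @param references reference gene ids (validated by [genormStability()]).
#' @param baselineSample sample id used as the calibrator.
#' @param samples optional explicit sample order (default: order of
#'   appearance in the table).
#' @return data.frame(sample_id, fold_change, sd).
#' @export
relativeExpression <- function(ct, target, references, baselineSample,
                               samples = NULL) {
  cs <- .ctSummaries(ct)
  if (is.null(samples)) samples <- cs$samples
  if (!baselineSample %in% samples) stop("baseline sample not present")
  need <- c(target, references)
  miss <- need[!need %in% cs$genes]
  if (length(miss)) stop("gene(s) missing from the Ct table: ",
                         paste(miss, collapse = ", "))
  sub <- cs$mean[need, samples, drop = FALSE]
  if (anyNA(sub))
    stop("zero reference or target quantity (missing Ct) in some sample")
  lnE <- log(cs$eff[need])
  ## log quantities: ln Q = -Ct * ln E
  lnQ <- -sub * lnE
  lnNF <- colMeans(lnQ[references, , drop = FALSE])
  lnNorm <- lnQ[target, ] - lnNF
  fold <- exp(lnNorm - lnNorm[baselineSample])
  sdm <- cs$sd[need, samples, drop = FALSE]
  sdm[is.na(sdm)] <- 0
  varLn <- lnE[target]^2 * sdm[target, ]^2 +
    colSums((lnE[references]^2 * sdm[references, , drop = FALSE]^2)) /
    length(references)^2
  varTot <- varLn + varLn[baselineSample]
  sdFold <- fold * sqrt(varTot)
  sdFold[baselineSample] <- 0
  data.frame(sample_id = samples, fold_change = unname(fold),
             sd = unname(sdFold), stringsAsFactors = FALSE)
}

#' Classify a temporal expression pattern
#'
#' Consecutive-timepoint changes are significant when the ratio is at least
#' \code{fcThreshold} (rise) or at most 1/\code{fcThreshold} (fall). The
#' classes, tried in priority order, are: senescence_up (a rise, no fall,
#' maximum at the last timepoint), development_down (a fall, no rise),
#' mid_peak (global maximum at an early-to-middle interior timepoint with a
#' significant fall after it), down_then_up (first significant move a fall,
#' later a rise), up_then_down (first a rise, later a fall, peak at the
#' penultimate timepoint), bimodal (two local maxima, each within
#' \code{fcThreshold} of the global maximum, with both a rise and a fall),
#' flat (no significant moves). Classification is scale-invariant.
#'
#' @param foldChanges fold changes relative to the first timepoint, ordered
#'   and named by timepoint; >= 3 timepoints.
#' @param fcThreshold significance ratio, default 2.
#' @return data.frame(class, peak_timepoint).
#' @export
classifyPattern <- function(foldChanges, fcThreshold = 2) {
  fc <- foldChanges
  nT <- length(fc)
  if (nT < 3L) stop("need at least 3 timepoints")
  if (is.null(names(fc))) names(fc) <- seq_along(fc)
  ratio <- fc[-1] / fc[-nT]
  rise <- ratio >= fcThreshold
  fall <- ratio <= 1 / fcThreshold
  peak <- which.max(fc)
  moves <- which(rise | fall)
  firstMove <- if (length(moves)) moves[1] else NA_integer_
  localMax <- which(vapply(seq_len(nT), function(i) {
    left <- if (i > 1L) fc[i] >= fc[i - 1L] else TRUE
    right <- if (i < nT) fc[i] >= fc[i + 1L] else TRUE
    left && right
  }, logical(1)))
  nearGlobal <- localMax[fc[peak] / fc[localMax] <= fcThreshold]
  cls <- if (any(rise) && !any(fall) && peak == nT) {
    "senescence_up"
  } else if (any(fall) && !any(rise)) {
    "development_down"
  } else if (peak >= 2L && peak <= nT - 2L && any(fall & seq_len(nT - 1L) >= peak)) {
    "mid_peak"
  } else if (!is.na(firstMove) && fall[firstMove] &&
             any(rise & seq_len(nT - 1L) > firstMove)) {
    "down_then_up"
  } else if (!is.na(firstMove) && rise[firstMove] && peak < nT &&
             any(fall & seq_len(nT - 1L) >= peak)) {
    "up_then_down"
  } else if (length(nearGlobal) >= 2L && any(rise) && any(fall)) {
    "bimodal"
  } else if (!length(moves)) {
    "flat"
  } else if (peak >= 2L && peak < nT) {
    "mid_peak"   # residual interior-peak shapes
  } else {
    "flat"
  }
  data.frame(class = cls, peak_timepoint = names(fc)[peak],
             stringsAsFactors = FALSE)
}

#' Select root-nodule-symbiosis candidate genes
#'
#' Genes whose abundance strictly exceeds the per-sample
#' \code{highQuantile} quantile in at least one symbiosis-related tissue AND
#' at least one nodule-stage sample.
#'
#' @param se \code{SummarizedExperiment} with colData \code{tissue_class}
#'   in {"symbiosis", "nodule"}.
#' @param highQuantile quantile defining "highly expressed" (default 0.75).
#' @return Character vector of selected gene ids.
#' @export
selectRnsCandidates <- function(se, highQuantile = 0.75) {
  mat <- SummarizedExperiment::assay(se)
  classes <- SummarizedExperiment::colData(se)$tissue_class
  for (cl in c("symbiosis", "nodule"))
    if (!cl %in% classes) stop("tissue class '", cl, "' absent")
  thr <- apply(mat, 2, stats::quantile, probs = highQuantile)
  high <- sweep(mat, 2, thr, ">")
  sel <- rowSums(high[, classes == "symbiosis", drop = FALSE]) > 0 &
         rowSums(high[, classes == "nodule", drop = FALSE]) > 0
  rownames(mat)[sel]
}

#' Heatmap-ready transformation of an expression matrix
#'
#' log2(value + 1) followed by per-gene (row) centering; the transformation
#' is recorded in the object metadata.
#'
#' @param se \code{SummarizedExperiment} with non-negative assay values.
#' @return A \code{SummarizedExperiment} with assay "transformed".
#' @export
heatmapMatrix <- function(se) {
  mat <- SummarizedExperiment::assay(se)
  if (any(mat < 0)) stop("expression values must be non-negative")
  lg <- log2(mat + 1)
  centered <- lg - rowMeans(lg)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(transformed = centered),
    colData = SummarizedExperiment::colData(se))
  S4Vectors::metadata(out)$transformation <- "log2(x + 1), row-centered"
  out
}
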