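#' Exon/intron/UTR structure summaries
#'
#' One row per gene (representative isoform): exon and intron counts, intron
#' lengths in transcription order, and strand-aware UTR presence. UTR
#' classification is recomputed from geometry: an untranslated interval on
#' the 5' side of the CDS in transcription orientation counts as 5' UTR, so
#' for a minus-strand gene the 5' UTR is the highest-coordinate one.
#'
#' @param models a [GeneModelSet-class].
#' @return data.frame(gene_id, chromosome, strand, exon_count, intron_count,
#'   has_utr5, has_utr3, intron_lengths, span_bp).
#' @export
summarizeStructure <- function(models) {
  ids <- names(models@genes)
  rows <- lapply(seq_along(ids), function(i) {
    ex <- models@exons[[i]]
    s <- start(ex); e <- end(ex)
    if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
      stop("overlapping exons in gene '", ids[i], "'")
    introns <- if (length(s) > 1L) s[-1] - e[-length(e)] - 1L else integer(0)
    str <- as.character(strand(models@genes))[i]
    if (str == "-") introns <- rev(introns)
    utrs <- c(models@utr5[[i]], models@utr3[[i]])
    cds <- models@cds[[i]]
    has5 <- FALSE; has3 <- FALSE
    if (length(utrs) && length(cds)) {
      cdsLo <- min(start(cds)); cdsHi <- max(end(cds))
      up <- end(utrs) < cdsLo     # low-coordinate side
      down <- start(utrs) > cdsHi
      if (str == "+") { has5 <- any(up); has3 <- any(down) }
      else { has5 <- any(down); has3 <- any(up) }
    }
    data.frame(gene_id = ids[i],
               chromosome = as.character(seqnames(models@genes))[i],
               strand = str, exon_count = length(ex),
               intron_count = length(introns),
               has_utr5 = has5, has_utr3 = has3,
               intron_lengths = paste(introns, collapse = ","),
               span_bp = width(models@genes)[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group gene structure statistics
#'
#' @param summaries output of [summarizeStructure()].
#' @param cladeAssignment named character, gene id -> group; every
#'   summarised gene must be assigned.
#' @return data.frame(group, n, frac_zero_intron, frac_one_intron,
#'   frac_multi_intron, mean_exon_count); groups with no summarised genes
#'   are omitted with a warning.
#' @export
groupStructureStats <- function(summaries, cladeAssignment) {
  missing <- setdiff(summaries$gene_id, names(cladeAssignment))
  if (length(missing))
    stop("gene(s) without group assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  grp <- cladeAssignment[summaries$gene_id]
  empty <- setdiff(unique(cladeAssignment), grp)
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  rows <- lapply(sort(unique(grp)), function(g) {
    s <- summaries[grp == g, ]
    data.frame(group = g, n = nrow(s),
               frac_zero_intron = mean(s$intron_count == 0L),
               frac_one_intron = mean(s$intron_count == 1L),
               frac_multi_intron = mean(s$intron_count >= 2L),
               mean_exon_count = mean(s$exon_count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
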