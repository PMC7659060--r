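#' Read a domain-hit table
#'
#' Expects the tab-separated columns protein_id, domain, start, end,
#' reference_length (the format of a flattened conserved-domain search
#' report). Domains must come from the closed vocabulary used by the census:
#' inhibitor_I29, peptidase_C1, GRAN, propeptide_C1, peptidase_C1A_cathepsinB.
#'
#' @param path path to the TSV.
#' @return data.frame of domain hits.
#' @export
readDomainHits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end", "reference_length")
  if (!all(need %in% names(df)))
    stop("domain-hit table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$domain), DOMAIN_LEVELS)
  if (length(bad))
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  if (any(df$start < 1L | df$end < df$start))
    stop("domain hits must satisfy 1 <= start <= end")
  df
}

#' @rdname readDomainHits
#' @param hits data.frame of domain hits.
#' @export
writeDomainHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix with sample annotations
#'
#' The TSV carries one annotation line \code{#tissue_class} ahead of the
#' header, assigning each sample to "symbiosis" (symbiosis-related tissue) or
#' "nodule" (nodule developmental stage). Returned as a
#' \code{SummarizedExperiment} with assay "abundance" and colData
#' \code{tissue_class}.
#'
#' @param path path to the TSV.
#' @return A \code{SummarizedExperiment}.
#' @export
readExpressionMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#tissue_class"))
    stop("expression TSV must start with a '#tissue_class' annotation line")
  classes <- strsplit(first, "\t")[[1]][-1]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (length(classes) != ncol(mat))
    stop("annotation line length does not match sample count")
  if (any(mat < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    colData = S4Vectors::DataFrame(tissue_class = classes,
                                   row.names = colnames(mat)))
}

#' @rdname readExpressionMatrix
#' @param se \code{SummarizedExperiment} with colData \code{tissue_class}.
#' @export
writeExpressionMatrix <- function(se, path) {
  mat <- SummarizedExperiment::assay(se)
  classes <- SummarizedExperiment::colData(se)$tissue_class
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#tissue_class", classes), collapse = "\t"), con)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Columns: gene_id, sample_id, replicate, ct, efficiency. Ct must be
#' positive; efficiency (amplification factor per cycle) must lie in (1, 2].
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "replicate", "ct", "efficiency")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  if (any(df$efficiency <= 1 | df$efficiency > 2))
    stop("efficiency must lie in (1, 2]")
  df
}

#' @rdname readCtTable
#' @param ct data.frame Ct table.
#' @export
writeCtTable <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a segment-pair divergence table
#'
#' Emits the survey's central table: one row per duplicated segment pair with
#' the member gene ids, Ka, Ks, omega = Ka/Ks (2 decimals) and the estimated
#' divergence time in Mya (2 decimals, T = Ks/(2 lambda) x 1e-6). Ka and
#' omega cells are left blank when Ka is unavailable. Gene ids are emitted
#' verbatim as supplied.
#'
#' @param pairs data.frame with columns pair, members_a, members_b, ka
#'   (NA allowed), ks.
#' @param path output path.
#' @param clockRate synonymous substitutions/site/year used for dating.
#' @return The formatted data.frame, invisibly.
#' @export
writeSegmentPairTable <- function(pairs, path, clockRate = 6.1e-9) {
  cols <- c("pair", "members_a", "members_b", "ka", "ks")
  if (nrow(pairs) && !all(cols %in% names(pairs)))
    stop("segment-pair table needs columns: ", paste(cols, collapse = ", "))
  fmt <- function(x, digits) ifelse(is.na(x), "", formatC(x, digits = digits,
                                                          format = "f"))
  if (nrow(pairs)) {
    out <- data.frame(
      pair = pairs$pair,
      members_a = pairs$members_a,
      members_b = pairs$members_b,
      ka = fmt(pairs$ka, 4),
      ks = fmt(pairs$ks, 4),
      omega = fmt(round(pairs$ka / pairs$ks, 2), 2),
      time_mya = fmt(divergenceTime(pairs$ks, clockRate), 2),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pair = integer(0), members_a = character(0),
                      members_b = character(0), ka = character(0),
                      ks = character(0), omega = character(0),
                      time_mya = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write and read Newick trees
#'
#' Trees are \pkg{ape} \code{phylo} objects; bootstrap supports travel as
#' internal node labels and survive a round trip.
#'
#' @param tree a \code{phylo} with labelled tips and non-negative edge
#'   lengths.
#' @param path output path; if \code{NULL}, the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labelled")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}

#' The printed divergence table of the reference survey
#'
#' The 19 duplicated segment pairs with their printed Ka, Ks, omega and
#' estimated divergence times (Mya), shipped as a plain-text fixture. Pairs
#' 10 and 11 print Ks and time but no Ka; their ka/omega are NA.
#'
#' @return data.frame(pair, gene_a, gene_b, ka, ks, omega, time_mya).
#' @export
#' @examples
#' t1 <- table1SegmentPairs()
#' range(divergenceTime(t1$ks))
table1SegmentPairs <- function() {
  path <- system.file("extdata", "segment_pairs_table1.tsv",
                      package = "famsurvey", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
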