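#' Construct a GeneModelSet
#'
#' @param genes named \code{GRanges} of gene spans (strand "+"/"-").
#' @param exons,cds,utr5,utr3 \code{GRangesList}s named like \code{genes};
#'   missing lists default to empty ranges (exons defaults to the gene span).
#' @return A validated [GeneModelSet-class].
#' @export
geneModelSet <- function(genes, exons = NULL, cds = NULL,
                         utr5 = NULL, utr3 = NULL) {
  ids <- names(genes)
  if (is.null(ids)) stop("'genes' must be named by gene id")
  emptyList <- function() {
    grl <- GRangesList(lapply(ids, function(i) GRanges()))
    names(grl) <- ids
    grl
  }
  fill <- function(grl, default) {
    if (is.null(grl)) return(default)
    grl <- grl[ids]
    names(grl) <- ids
    GRangesList(lapply(grl, function(g) sort(g)))
  }
  if (is.null(exons)) {
    exons <- GRangesList(lapply(seq_along(genes), function(i) genes[i]))
    names(exons) <- ids
  } else exons <- fill(exons, NULL)
  obj <- new("GeneModelSet", genes = genes, exons = exons,
             cds = fill(cds, emptyList()), utr5 = fill(utr5, emptyList()),
             utr3 = fill(utr3, emptyList()))
  validObject(obj)
  obj
}

#' Read gene models from GFF3
#'
#' Builds one [GeneModelSet-class] entry per gene, taking the longest mRNA
#' (by summed exon length) as the representative isoform. Coordinates stay
#' 1-based inclusive as in the file.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon/CDS/UTR features
#'   linked by Parent attributes.
#' @return A [GeneModelSet-class].
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent1 <- function(x) {
    p <- x$Parent
    vapply(p, function(v) if (length(v)) as.character(v)[1] else NA_character_,
           character(1))
  }
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  names(genes) <- genes$ID
  mrna <- gr[type == "mRNA"]
  mrnaParent <- parent1(mrna)
  if (anyNA(mrnaParent)) stop("mRNA feature without Parent in ", path)
  subTypes <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  subs <- lapply(subTypes, function(tt) {
    g <- gr[type == tt]
    p <- parent1(g)
    if (length(g) && anyNA(p))
      stop("unparented ", tt, " feature in ", path)
    if (length(g) && !all(p %in% mrna$ID))
      stop(tt, " feature with unknown Parent '",
           p[which(!p %in% mrna$ID)[1]], "' in ", path)
    S4Vectors::split(g, factor(p, levels = mrna$ID))
  })
  ## representative isoform: longest summed exon length, span as fallback
  exlen <- sum(width(subs$exon))
  exlen[lengths(subs$exon) == 0L] <- width(mrna)[lengths(subs$exon) == 0L]
  ids <- names(genes)
  rep_tx <- vapply(ids, function(g) {
    k <- which(mrnaParent == g)
    if (!length(k)) return(NA_integer_)
    k[which.max(exlen[k])]
  }, integer(1))
  if (anyNA(rep_tx))
    stop("gene(s) without mRNA in ", path, ": ",
         paste(ids[is.na(rep_tx)], collapse = ", "))
  repTxId <- mrna$ID[rep_tx]
  pick <- function(part) {
    flat <- unlist(part, use.names = FALSE)
    owner <- rep(names(part), lengths(part))
    keep <- owner %in% repTxId
    flat <- flat[keep]; owner <- owner[keep]
    gene <- ids[match(owner, repTxId)]
    o <- order(match(gene, ids), start(flat))
    flat <- flat[o]
    mcols(flat) <- NULL
    grl <- S4Vectors::split(flat, factor(gene[o], levels = ids))
    names(grl) <- ids
    grl
  }
  gclean <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                    strand = strand(genes))
  names(gclean) <- ids
  obj <- new("GeneModelSet", genes = gclean, exons = pick(subs$exon),
             cds = pick(subs$cds), utr5 = pick(subs$utr5),
             utr3 = pick(subs$utr3))
  validObject(obj)
  obj
}

#' Write gene models to GFF3
#'
#' Emits one gene + one mRNA per entry with exon/CDS/UTR children, so the
#' file round-trips through [readGff3()].
#'
#' @param models a [GeneModelSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(models, path) {
  ids <- names(models@genes)
  g <- models@genes
  chromOf <- stats::setNames(as.character(seqnames(g)), ids)
  strandOf <- stats::setNames(as.character(strand(g)), ids)
  partDf <- function(grl, type) {
    lens <- lengths(grl)
    if (!sum(lens)) return(NULL)
    owner <- rep(names(grl), lens)
    flat <- unlist(grl, use.names = FALSE)
    data.frame(seqnames = chromOf[owner], start = start(flat),
               end = end(flat), strand = strandOf[owner], type = type,
               ID = NA_character_, parent = paste0(owner, ".t1"),
               phase = NA_integer_, owner = owner,
               stringsAsFactors = FALSE)
  }
  base <- data.frame(seqnames = chromOf[ids], start = start(g),
                     end = end(g), strand = strandOf[ids],
                     stringsAsFactors = FALSE)
  df <- rbind(
    cbind(base, type = "gene", ID = ids, parent = NA_character_,
          phase = NA_integer_, owner = ids),
    cbind(base, type = "mRNA", ID = paste0(ids, ".t1"), parent = ids,
          phase = NA_integer_, owner = ids),
    partDf(models@exons, "exon"), partDf(models@cds, "CDS"),
    partDf(models@utr5, "five_prime_UTR"),
    partDf(models@utr3, "three_prime_UTR"))
  ## CDS phase: bases to skip before the first complete codon, accumulated
  ## in transcription order within each gene
  isCds <- df$type == "CDS"
  if (any(isCds)) {
    cdsDf <- df[isCds, ]
    txPos <- ifelse(cdsDf$strand == "+", cdsDf$start, -cdsDf$start)
    o <- order(cdsDf$owner, txPos)
    w <- cdsDf$end - cdsDf$start + 1L
    before <- stats::ave(w[o], cdsDf$owner[o],
                         FUN = function(x) cumsum(c(0L, utils::head(x, -1))))
    ph <- integer(nrow(cdsDf))
    ph[o] <- (3L - before %% 3L) %% 3L
    df$phase[isCds] <- ph
  }
  ## stable order: by gene (genomic), then feature hierarchy, then start
  typeRank <- c(gene = 1L, mRNA = 2L, exon = 3L, five_prime_UTR = 4L,
                CDS = 5L, three_prime_UTR = 6L)
  df <- df[order(match(df$owner, ids), typeRank[df$type], df$start), ]
  par <- as.list(df$parent)
  par[is.na(df$parent)] <- list(character(0))
  gr <- GRanges(df$seqnames, IRanges(df$start, df$end), strand = df$strand,
                source = "famsurvey", type = df$type, ID = df$ID,
                Parent = as(par, "CharacterList"), phase = df$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Gene order along chromosomes
#'
#' @param models a [GeneModelSet-class].
#' @return data.frame(gene_id, chromosome, strand, start, end, order) where
#'   \code{order} is the 1-based rank of the gene on its chromosome by start
#'   coordinate.
#' @export
geneOrder <- function(models) {
  g <- models@genes
  df <- data.frame(gene_id = names(g),
                   chromosome = as.character(seqnames(g)),
                   strand = as.character(strand(g)),
                   start = start(g), end = end(g),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start, df$gene_id), ]
  df$order <- as.integer(stats::ave(df$start, df$chromosome, FUN = seq_along))
  rownames(df) <- NULL
  df
}
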