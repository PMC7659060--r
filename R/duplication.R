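#' Tandem duplication clusters
#'
#' Maximal runs of family genes on one chromosome in which consecutive
#' members are separated by at most \code{tandemMaxIntervening} non-family
#' genes. Clusters are disjoint and need at least two members.
#'
#' @param models a [GeneModelSet-class].
#' @param familyIds family gene ids (must all be present in the models).
#' @param tandemMaxIntervening max intervening non-family genes.
#' @return data.frame(cluster, chromosome, members, n, start, end).
#' @export
findTandemClusters <- function(models, familyIds, tandemMaxIntervening = 1L) {
  ord <- geneOrder(models)
  missing <- setdiff(familyIds, ord$gene_id)
  if (length(missing))
    stop("family id(s) absent from gene models: ",
         paste(utils::head(missing, 5), collapse = ", "))
  fam <- ord[ord$gene_id %in% familyIds, ]
  out <- list()
  for (chrom in unique(fam$chromosome)) {
    fc <- fam[fam$chromosome == chrom, ]
    fc <- fc[order(fc$order), ]
    run <- 1L
    grp <- cumsum(c(0L, diff(fc$order) - 1L > tandemMaxIntervening))
    for (g in unique(grp)) {
      members <- fc[grp == g, ]
      if (nrow(members) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        members = paste(members$gene_id, collapse = ","),
        n = nrow(members), start = min(members$start),
        end = max(members$end), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster = integer(0), chromosome = character(0),
                      members = character(0), n = integer(0),
                      start = integer(0), end = integer(0)))
  res <- do.call(rbind, out)
  res <- cbind(cluster = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

## longest chain of anchors strictly increasing in both coordinates
.longestChain <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(0L)
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a[j] < a[i] && b[j] < b[i] && best[j] + 1L > best[i])
        best[i] <- best[j] + 1L
    }
  }
  max(best)
}

#' Collinearity support around a focal homolog pair
#'
#' Counts the anchors in the longest chain of homolog pairs whose positions
#' increase strictly on both segments, restricted to +/- \code{window} genes
#' around the focal pair. Orientation-aware: the better of the forward and
#' reversed order of the second segment is used, so inverted segments score
#' identically.
#'
#' @param orderA,orderB named integer vectors: gene id -> position in the
#'   chromosome/segment gene order (background genes included in the
#'   numbering).
#' @param homologPairs data.frame(gene_a, gene_b) relating genes of segment
#'   A to genes of segment B.
#' @param focal length-2 character: the focal (gene_a, gene_b) pair; must be
#'   one of \code{homologPairs}.
#' @param window half-window in genes.
#' @return Integer anchor count (the focal pair counts).
#' @export
collinearitySupport <- function(orderA, orderB, homologPairs, focal,
                                window = 25L) {
  hit <- homologPairs$gene_a == focal[1] & homologPairs$gene_b == focal[2]
  if (!any(hit)) stop("focal pair not present in homologPairs")
  pa <- orderA[homologPairs$gene_a]
  pb <- orderB[homologPairs$gene_b]
  ok <- !is.na(pa) & !is.na(pb)
  fa <- orderA[[focal[1]]]; fb <- orderB[[focal[2]]]
  ok <- ok & abs(pa - fa) <= window & abs(pb - fb) <= window
  pa <- pa[ok]; pb <- pb[ok]
  max(.longestChain(pa, pb), .longestChain(pa, -pb))
}

.segmentPhyloGrouped <- function(sides, geneA, geneB, allowed) {
  sizes <- lengths(sides)
  cand <- which(vapply(sides, function(s) geneA %in% s && geneB %in% s,
                       logical(1)))
  if (!length(cand)) return(FALSE)
  smallest <- sides[[cand[which.min(sizes[cand])]]]
  all(smallest %in% allowed)
}

#' Identify WGD-derived duplicated segment pairs
#'
#' Implements the three-step candidate procedure followed by two validation
#' criteria: (1) candidate member pairs are family gene pairs on different
#' chromosomes whose Ks falls in the configured WGD window, reduced to
#' mutual-best matches and clustered into segment pairs by gene-order
#' proximity; (2) criterion 1 (phylogeny) requires each member pair to sit in
#' a tree clade containing only this segment pair's family genes, and
#' criterion 2 (collinearity) requires at least
#' \code{collinearityMinAnchors} chained anchors around the lowest-Ks focal
#' pair. Validated pairs carry a representative Ks (minimum member-pair Ks
#' by default), omega where Ka is available, and the estimated divergence
#' time.
#'
#' @param models a [GeneModelSet-class].
#' @param familyIds family gene ids.
#' @param ksLookup data.frame(gene_a, gene_b, ks) with optional ka column
#'   (e.g. from [pairKaKs()]).
#' @param tree \code{phylo} over the family genes (criterion 1).
#' @param config a [SurveyConfig-class].
#' @param paralogy optional data.frame(gene_a, gene_b) of supplied homolog
#'   pairs outside the family (e.g. a precomputed synteny/paralogy list);
#'   these contribute collinearity anchors alongside the family pairs.
#' @return data.frame, one row per candidate segment pair, with columns
#'   pair, chromosome_a, chromosome_b, members_a, members_b, member_pairs,
#'   ka, ks, omega, time_mya, selection, phylo_grouped, collinear_anchors,
#'   validated.
#' @export
identifySegmentPairs <- function(models, familyIds, ksLookup, tree,
                                 config = surveyConfig(), paralogy = NULL) {
  if (!length(familyIds)) stop("empty family")
  ord <- geneOrder(models)
  pos <- stats::setNames(ord$order, ord$gene_id)
  chrom <- stats::setNames(ord$chromosome, ord$gene_id)
  if (is.null(ksLookup$ka)) ksLookup$ka <- NA_real_

  cand <- ksLookup[ksLookup$gene_a %in% familyIds &
                   ksLookup$gene_b %in% familyIds &
                   !is.na(ksLookup$ks) &
                   ksLookup$ks >= config@wgdKsWindow[1] &
                   ksLookup$ks <= config@wgdKsWindow[2], , drop = FALSE]
  cand <- cand[chrom[cand$gene_a] != chrom[cand$gene_b], , drop = FALSE]
  if (nrow(cand)) {
    ## orient: chromosome_a < chromosome_b
    swap <- chrom[cand$gene_a] > chrom[cand$gene_b]
    tmp <- cand$gene_a[swap]
    cand$gene_a[swap] <- cand$gene_b[swap]
    cand$gene_b[swap] <- tmp
    ## mutual best by Ks
    bestOf <- function(ids, partners, ks) {
      b <- tapply(seq_along(ids), ids, function(i) partners[i][which.min(ks[i])])
      stats::setNames(as.character(b), names(b))
    }
    bestA <- bestOf(cand$gene_a, cand$gene_b, cand$ks)
    bestB <- bestOf(cand$gene_b, cand$gene_a, cand$ks)
    cand <- cand[bestA[cand$gene_a] == cand$gene_b &
                 bestB[cand$gene_b] == cand$gene_a, , drop = FALSE]
  }
  if (!nrow(cand))
    return(data.frame(pair = integer(0), chromosome_a = character(0),
                      chromosome_b = character(0), members_a = character(0),
                      members_b = character(0), member_pairs = character(0),
                      ka = numeric(0), ks = numeric(0), omega = numeric(0),
                      time_mya = numeric(0), selection = character(0),
                      phylo_grouped = logical(0),
                      collinear_anchors = integer(0),
                      validated = logical(0)))

  cand$chrom_a <- chrom[cand$gene_a]
  cand$chrom_b <- chrom[cand$gene_b]
  cand$pos_a <- pos[cand$gene_a]
  cand$pos_b <- pos[cand$gene_b]

  ## cluster member pairs into segments: only tandem-adjacent pairs merge
  ## (at most tandemMaxIntervening intervening genes on both chromosomes),
  ## so multi-gene segments arise exactly where tandem arrays duplicate
  win <- config@tandemMaxIntervening + 1L
  cand <- cand[order(cand$chrom_a, cand$chrom_b, cand$pos_a), ]
  keyPrev <- c(NA, utils::head(paste(cand$chrom_a, cand$chrom_b), -1))
  gapA <- c(Inf, diff(cand$pos_a))
  gapB <- c(Inf, abs(diff(cand$pos_b)))
  newSeg <- paste(cand$chrom_a, cand$chrom_b) != keyPrev | gapA > win |
    gapB > win
  newSeg[is.na(newSeg)] <- TRUE
  cand$segment <- cumsum(newSeg)

  famPos <- pos[intersect(names(pos), familyIds)]
  sides <- .treeSplits(tree)
  rows <- list()
  for (s in unique(cand$segment)) {
    mp <- cand[cand$segment == s, ]
    chA <- mp$chrom_a[1]; chB <- mp$chrom_b[1]
    spanGenes <- function(ch, lo, hi)
      names(famPos)[chrom[names(famPos)] == ch & famPos >= lo &
                    famPos <= hi]
    ## tandem siblings adjacent to the members belong to the segment
    segA <- spanGenes(chA, min(mp$pos_a) - win, max(mp$pos_a) + win)
    segB <- spanGenes(chB, min(mp$pos_b) - win, max(mp$pos_b) + win)
    segA <- segA[order(pos[segA])]
    segB <- segB[order(pos[segB])]
    allowed <- union(segA, segB)
    grouped <- all(vapply(seq_len(nrow(mp)), function(i)
      .segmentPhyloGrouped(sides, mp$gene_a[i], mp$gene_b[i], allowed),
      logical(1)))
    focalRow <- which.min(mp$ks)
    anchorPairs <- cand[cand$chrom_a == chA & cand$chrom_b == chB,
                        c("gene_a", "gene_b")]
    if (!is.null(paralogy) && nrow(paralogy)) {
      pp <- paralogy
      swapP <- !is.na(chrom[pp$gene_a]) & !is.na(chrom[pp$gene_b]) &
        chrom[pp$gene_a] > chrom[pp$gene_b]
      tmpP <- pp$gene_a[swapP]
      pp$gene_a[swapP] <- pp$gene_b[swapP]
      pp$gene_b[swapP] <- tmpP
      pp <- pp[!is.na(chrom[pp$gene_a]) & !is.na(chrom[pp$gene_b]) &
               chrom[pp$gene_a] == chA & chrom[pp$gene_b] == chB, ,
               drop = FALSE]
      anchorPairs <- rbind(anchorPairs, pp)
    }
    anchors <- collinearitySupport(
      pos[chrom == chA], pos[chrom == chB], anchorPairs,
      c(mp$gene_a[focalRow], mp$gene_b[focalRow]),
      config@collinearityWindow)
    if (config@ksSummary == "min") {
      ks <- mp$ks[focalRow]; ka <- mp$ka[focalRow]
    } else {
      ks <- mean(mp$ks); ka <- mean(mp$ka, na.rm = TRUE)
      if (is.nan(ka)) ka <- NA_real_
    }
    omega <- if (!is.na(ka) && ks > 0) ka / ks else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome_a = chA, chromosome_b = chB,
      members_a = paste(segA, collapse = ","),
      members_b = paste(segB, collapse = ","),
      member_pairs = paste(paste(mp$gene_a, mp$gene_b, sep = "|"),
                           collapse = ","),
      ka = ka, ks = ks, omega = omega,
      time_mya = divergenceTime(ks, config@clockRate),
      selection = if (is.na(omega)) NA_character_ else selectionClass(omega),
      phylo_grouped = grouped, collinear_anchors = anchors,
      validated = grouped && anchors >= config@collinearityMinAnchors,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- cbind(pair = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
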