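## Synthetic genome with a known duplication history. Ancestral genes are
## built from fourfold-degenerate codon families (third position free) so
## that each codon carries exactly one synonymous site: the simulator's
## "true Ks" (expected synonymous substitutions per synonymous site) is then
## directly the quantity NG86 estimates, without site-counting bias.

.NTS <- c("A", "C", "G", "T")
.FOURFOLD_PREFIX <- c("GC", "GT", "GG", "AC", "CC", "TC")

.randomOrf <- function(nCodons) {
  pre <- sample(.FOURFOLD_PREFIX, nCodons - 1L, replace = TRUE)
  third <- sample(.NTS, nCodons - 1L, replace = TRUE)
  c("ATG", paste0(pre, third))
}

.isStop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

## Jukes-Cantor style evolution restricted to synonymous (third) positions:
## per site, a Poisson(d) number of events, each replacing the base with one
## of the three alternatives uniformly.
.evolveSyn <- function(codons, d) {
  if (d <= 0 || length(codons) < 2L) return(codons)
  idx <- which(substr(codons, 1, 2) %in% .FOURFOLD_PREFIX)
  idx <- idx[idx >= 2L]
  if (!length(idx)) return(codons)
  events <- stats::rpois(length(idx), d)
  for (k in which(events > 0L)) {
    i <- idx[k]
    third <- substr(codons[i], 3, 3)
    for (e in seq_len(events[k])) third <- sample(setdiff(.NTS, third), 1L)
    substr(codons[i], 3, 3) <- third
  }
  codons
}

## nonsynonymous events at codon positions 1-2; stop codons are rejected.
.evolveNonsyn <- function(codons, d) {
  if (d <= 0 || length(codons) < 2L) return(codons)
  sites <- expand.grid(codon = 2:length(codons), pos = 1:2)
  events <- stats::rpois(nrow(sites), d)
  for (k in which(events > 0L)) {
    i <- sites$codon[k]; p <- sites$pos[k]
    for (e in seq_len(events[k])) {
      cur <- substr(codons[i], p, p)
      repeat {
        alt <- sample(setdiff(.NTS, cur), 1L)
        cand <- codons[i]
        substr(cand, p, p) <- alt
        if (!.isStop(cand)) { codons[i] <- cand; break }
      }
    }
  }
  codons
}

## One gene model laid out from a transcription-ordered segment plan,
## returned as plain coordinate matrices (GRanges construction is deferred
## and done in bulk for speed). For minus-strand genes the 5' UTR sits at
## the high-coordinate end.
.buildGeneModel <- function(chrom, strand, startPos, cdsLen, nExons,
                            utr5Len = 60L, utr3Len = 60L, intronLen = 120L) {
  hasCds <- cdsLen > 0L
  if (hasCds) {
    chunk <- rep(cdsLen %/% nExons, nExons)
    chunk[nExons] <- chunk[nExons] + cdsLen %% nExons
  } else {
    chunk <- rep(0L, nExons)
  }
  exLen <- chunk
  exLen[1] <- exLen[1] + if (hasCds) utr5Len else 300L
  if (hasCds) exLen[nExons] <- exLen[nExons] + utr3Len
  ## transcription-order sub-intervals per exon: (type, offset, length)
  parts <- list()
  for (i in seq_len(nExons)) {
    off <- 0L
    if (i == 1L && hasCds && utr5Len > 0L) {
      parts[[length(parts) + 1L]] <- list("utr5", i, 0L, utr5Len)
      off <- utr5Len
    } else if (i == 1L && !hasCds) {
      off <- 0L
    }
    if (chunk[i] > 0L)
      parts[[length(parts) + 1L]] <- list("cds", i, off, chunk[i])
    if (i == nExons && hasCds && utr3Len > 0L)
      parts[[length(parts) + 1L]] <- list("utr3", i, off + chunk[i], utr3Len)
  }
  span <- sum(exLen) + intronLen * (nExons - 1L)
  ## genomic exon starts; for '-' the transcription order is reversed
  if (strand == "+") {
    exStart <- startPos + cumsum(c(0L, utils::head(exLen, -1) + intronLen))
    names(exStart) <- seq_len(nExons)
  } else {
    rev_len <- rev(exLen)
    st <- startPos + cumsum(c(0L, utils::head(rev_len, -1) + intronLen))
    exStart <- st[match(seq_len(nExons), rev(seq_len(nExons)))]
    names(exStart) <- seq_len(nExons)
  }
  mk <- function(type) {
    sel <- Filter(function(p) p[[1]] == type, parts)
    if (!length(sel)) return(cbind(start = integer(0), end = integer(0)))
    s <- vapply(sel, function(p) {
      i <- p[[2]]; off <- p[[3]]; len <- p[[4]]
      if (strand == "+") exStart[[i]] + off
      else exStart[[i]] + (exLen[i] - off - len)
    }, numeric(1))
    len <- vapply(sel, function(p) p[[4]], integer(1))
    o <- order(s)
    cbind(start = as.integer(s[o]), end = as.integer(s[o] + len[o] - 1L))
  }
  exo <- order(exStart)
  list(gene = c(start = startPos, end = startPos + span - 1L),
       exons = cbind(start = as.integer(exStart[exo]),
                     end = as.integer(exStart[exo] + exLen[exo] - 1L)),
       cds = mk("cds"), utr5 = mk("utr5"), utr3 = mk("utr3"),
       span = span)
}

#' Simulate a gene family with known duplication history
#'
#' Generates a toy genome: ancestral open reading frames are duplicated once
#' genome-wide (chromosome i and i + n/2 carry the two WGD copies in the same
#' gene order), tandem arrays are grafted next to the first families of the
#' first chromosome, every duplicate pair accumulates synonymous changes with
#' expectation \code{wgdTargetKs} (nonsynonymous at \code{kaKsRatio} times
#' that rate), and a fraction of loci are pseudogenised by truncation to
#' fewer than 150 codons or by an internal deletion removing half of the
#' peptidase_C1 domain. Family genes are interleaved with background genes so
#' collinearity statistics see realistic family sparsity. Domain-hit rows
#' describe what remains of each protein. Deterministic under a fixed seed.
#'
#' @param cfg a [SimConfig-class].
#' @return A [SurveyBundle-class] with ground truth attached.
#' @export
simulateFamily <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nAncestralGenes
  half <- cfg@nChromosomes %/% 2L
  perChrom <- ceiling(n / half)
  chromOf <- rep(seq_len(half), each = perChrom)[seq_len(n)]
  if (length(cfg@tandemClusterSizes) > sum(chromOf == 1L))
    stop("tandem cluster sizes exceed the capacity of chromosome 1")

  L <- cfg@codonLength
  ## sequences
  anc <- lapply(seq_len(n), function(i) .randomOrf(L))
  bA <- cfg@wgdTargetKs / 2
  bN <- cfg@wgdTargetKs * cfg@kaKsRatio / 2
  copyA <- lapply(anc, function(s) .evolveNonsyn(.evolveSyn(s, bA), bN))
  copyB <- lapply(anc, function(s) .evolveNonsyn(.evolveSyn(s, bA), bN))

  ## tandem arrays on the A copies of the first families of chromosome 1
  tandem <- list()   # per family: list of codon vectors
  tandemFam <- integer(0)
  for (ci in seq_along(cfg@tandemClusterSizes)) {
    f <- ci                      # family index on chromosome 1
    k <- cfg@tandemClusterSizes[ci] - 1L
    tandem[[as.character(f)]] <- lapply(seq_len(k), function(j)
      .evolveNonsyn(.evolveSyn(copyA[[f]], cfg@tandemTargetKs),
                    cfg@tandemTargetKs * cfg@kaKsRatio))
    tandemFam <- c(tandemFam, f)
  }

  ## locus registry: one row per family locus
  loci <- data.frame(gene_id = character(0), family = integer(0),
                     copy = character(0), stringsAsFactors = FALSE)
  seqs <- list()
  for (f in seq_len(n)) {
    idA <- sprintf("Fam%03dA", f); idB <- sprintf("Fam%03dB", f)
    loci <- rbind(loci, data.frame(gene_id = c(idA, idB), family = f,
                                   copy = c("A", "B")))
    seqs[[idA]] <- copyA[[f]]; seqs[[idB]] <- copyB[[f]]
    tg <- tandem[[as.character(f)]]
    for (j in seq_along(tg)) {
      idT <- sprintf("Fam%03dA.t%d", f, j)
      loci <- rbind(loci, data.frame(gene_id = idT, family = f,
                                     copy = paste0("T", j)))
      seqs[[idT]] <- tg[[j]]
    }
  }
  nLoci <- nrow(loci)

  ## pseudogenisation: alternate truncation / domain deletion
  nPseudo <- round(cfg@pseudogeneFraction * nLoci)
  pseudoIds <- if (nPseudo > 0L) sample(loci$gene_id, nPseudo) else character(0)
  pseudoReason <- rep(c("truncation", "domain_deletion"),
                      length.out = nPseudo)
  names(pseudoReason) <- pseudoIds

  c1s <- round(0.31 * L); c1e <- L - 5L
  refC1 <- c1e - c1s + 1L
  i29 <- c(round(0.09 * L), round(0.28 * L))
  delFrom <- c1s + ceiling(0.45 * refC1)
  delTo <- c1s + ceiling(0.95 * refC1) - 1L

  domainRows <- list()
  truthPairs <- list()
  for (id in loci$gene_id) {
    reason <- pseudoReason[id]
    if (!is.na(reason) && reason == "truncation") {
      seqs[[id]] <- seqs[[id]][1:100]
    } else if (!is.na(reason) && reason == "domain_deletion") {
      seqs[[id]] <- seqs[[id]][-(delFrom:delTo)]
    }
    plen <- length(seqs[[id]])
    f <- loci$family[loci$gene_id == id]
    hit <- function(domain, s, e, ref) {
      if (s > plen) return(NULL)
      data.frame(protein_id = id, domain = domain, start = s,
                 end = min(e, plen), reference_length = ref,
                 stringsAsFactors = FALSE)
    }
    rows <- list(hit("inhibitor_I29", i29[1], i29[2], i29[2] - i29[1] + 1L))
    if (!is.na(reason) && reason == "domain_deletion") {
      rows <- c(rows, list(hit("peptidase_C1", c1s, delFrom - 1L, refC1)))
    } else {
      rows <- c(rows, list(hit("peptidase_C1", c1s, c1e, refC1)))
    }
    if (f %% 7L == 3L && is.na(reason))
      rows <- c(rows, list(hit("GRAN", plen - 40L, plen - 10L, 31L)))
    if (f %% 11L == 5L && is.na(reason))
      rows <- c(rows, list(hit("propeptide_C1", 5L, i29[1] - 1L,
                               i29[1] - 5L),
                           hit("peptidase_C1A_cathepsinB", c1s, c1e, refC1)))
    domainRows <- c(domainRows, rows)
  }
  domainHits <- do.call(rbind, Filter(Negate(is.null), domainRows))

  ## true duplicate pairs
  for (f in seq_len(n)) {
    idA <- sprintf("Fam%03dA", f); idB <- sprintf("Fam%03dB", f)
    truthPairs[[length(truthPairs) + 1L]] <-
      data.frame(gene_a = idA, gene_b = idB, true_ks = cfg@wgdTargetKs,
                 origin = "WGD", stringsAsFactors = FALSE)
    for (j in seq_along(tandem[[as.character(f)]]))
      truthPairs[[length(truthPairs) + 1L]] <-
        data.frame(gene_a = idA, gene_b = sprintf("Fam%03dA.t%d", f, j),
                   true_ks = cfg@tandemTargetKs, origin = "tandem",
                   stringsAsFactors = FALSE)
  }
  duplicatePairs <- do.call(rbind, truthPairs)
  duplicatePairs$intact <- !(duplicatePairs$gene_a %in% pseudoIds |
                             duplicatePairs$gene_b %in% pseudoIds)

  ## chromosome layouts: slots of background and family genes; the B side
  ## mirrors the A side gene-for-gene (minus tandem extras), which defines
  ## the background paralogy
  layout <- list()
  bgBySide <- list()
  bgCount <- 0L
  for (side in c("A", "B")) {
    for (ch in seq_len(half)) {
      chromName <- sprintf("Chr%02d", ch + if (side == "B") half else 0L)
      slots <- character(0)
      fams <- which(chromOf == ch)
      for (f in fams) {
        bg <- sprintf("Bg%s%02d.%03d", side, ch,
                      bgCount + seq_len(cfg@backgroundPerGap))
        bgCount <- bgCount + cfg@backgroundPerGap
        slots <- c(slots, bg, sprintf("Fam%03d%s", f, side))
        if (side == "A") {
          tg <- tandem[[as.character(f)]]
          if (!is.null(tg))
            slots <- c(slots, sprintf("Fam%03dA.t%d", f, seq_along(tg)))
        }
      }
      bg <- sprintf("Bg%s%02d.%03d", side, ch,
                    bgCount + seq_len(cfg@backgroundPerGap))
      bgCount <- bgCount + cfg@backgroundPerGap
      slots <- c(slots, bg)
      bgBySide[[side]][[ch]] <- slots[startsWith(slots, "Bg")]
      if (cfg@shuffleOrder) slots <- sample(slots)
      layout[[chromName]] <- slots
    }
  }
  ## supplied paralogy: every 12th background pair is a detectable WGD
  ## duplicate (anchor); the rest count as diverged beyond detection
  paralogy <- do.call(rbind, lapply(seq_len(half), function(ch) {
    a <- bgBySide[["A"]][[ch]]; b <- bgBySide[["B"]][[ch]]
    k <- seq_along(a)[seq_along(a) %% 12L == 0L]
    data.frame(gene_a = a[k], gene_b = b[k], stringsAsFactors = FALSE)
  }))

  ## gene models: background rows vectorised, family genes laid out fully
  famRows <- list()
  partRows <- list(exons = list(), cds = list(), utr5 = list(),
                   utr3 = list())
  bgChunks <- list()
  for (chromName in names(layout)) {
    slots <- layout[[chromName]]
    isFam <- startsWith(slots, "Fam")
    spans <- rep(300L, length(slots))
    if (any(isFam)) {
      famIdx <- as.integer(substr(slots[isFam], 4, 6))
      nExV <- 1L + (famIdx - 1L) %% 3L
      cdsLenV <- vapply(slots[isFam], function(g) 3L * length(seqs[[g]]),
                        integer(1))
      spans[isFam] <- 120L + cdsLenV + 120L * (nExV - 1L)
    }
    starts <- 1L + c(0L, cumsum(utils::head(spans + cfg@intergenicSpacer,
                                            -1L)))
    strands <- ifelse((starts %/% 1000L) %% 2L == 0L, "+", "-")
    bgChunks[[chromName]] <- data.frame(
      gene_id = slots[!isFam], chrom = chromName,
      strand = strands[!isFam], start = starts[!isFam],
      end = starts[!isFam] + 299L, stringsAsFactors = FALSE)
    for (k in which(isFam)) {
      gid <- slots[k]
      f <- as.integer(substr(gid, 4, 6))
      gm <- .buildGeneModel(chromName, strands[k], starts[k],
                            3L * length(seqs[[gid]]), 1L + (f - 1L) %% 3L)
      famRows[[gid]] <- data.frame(gene_id = gid, chrom = chromName,
                                   strand = strands[k],
                                   start = gm$gene[["start"]],
                                   end = gm$gene[["end"]],
                                   stringsAsFactors = FALSE)
      for (part in names(partRows)) {
        m <- gm[[part]]
        if (nrow(m))
          partRows[[part]][[gid]] <- data.frame(
            gene_id = gid, chrom = chromName, strand = strands[k],
            start = m[, "start"], end = m[, "end"],
            stringsAsFactors = FALSE)
      }
    }
  }
  bgDf <- do.call(rbind, bgChunks)
  gdf <- rbind(do.call(rbind, famRows), bgDf)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand)
  names(genes) <- gdf$gene_id
  asList <- function(rows, extra = NULL) {
    df <- rbind(if (length(rows)) do.call(rbind, rows), extra)
    if (is.null(df))
      df <- data.frame(gene_id = character(0), chrom = character(0),
                       strand = character(0), start = integer(0),
                       end = integer(0))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    grl <- S4Vectors::split(gr, factor(df$gene_id, levels = gdf$gene_id))
    names(grl) <- gdf$gene_id
    grl
  }
  models <- new("GeneModelSet", genes = genes,
                exons = asList(partRows$exons, bgDf),
                cds = asList(partRows$cds),
                utr5 = asList(partRows$utr5), utr3 = asList(partRows$utr3))
  validObject(models)

  cds <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                         collapse = ""))
  proteins <- Biostrings::translate(cds)

  members <- setdiff(loci$gene_id, pseudoIds)
  groups <- stats::setNames(sprintf("G%03d", loci$family), loci$gene_id)

  ## temporal classes cycle over the member loci; RNS candidacy and
  ## symbiosis-only / nodule-only decoys are fixed deterministic slices
  classes <- stats::setNames(PATTERN_LEVELS[(seq_along(members) - 1L) %%
                                            length(PATTERN_LEVELS) + 1L],
                             members)
  m <- length(members)
  rns <- members[seq_len(max(1L, round(0.3 * m)))]
  rest <- setdiff(members, rns)
  nDecoy <- max(1L, round(0.1 * m))
  symOnly <- rest[seq_len(min(nDecoy, length(rest)))]
  nodOnly <- setdiff(rest, symOnly)[seq_len(min(nDecoy, length(rest) -
                                                  length(symOnly)))]
  attr(rns, "symbiosis_only") <- symOnly
  attr(rns, "nodule_only") <- nodOnly

  truth <- new("GroundTruth", duplicatePairs = duplicatePairs,
               pseudogenes = data.frame(gene_id = pseudoIds,
                                        reason = unname(pseudoReason),
                                        stringsAsFactors = FALSE),
               groupAssignment = groups, expressionClass = classes,
               rnsCandidates = rns,
               referenceGenes = c("REF1", "REF2"),
               unstableReferences = c("REF3", "REF4"))

  new("SurveyBundle", cds = cds, proteins = proteins, models = models,
      domainHits = domainHits, familyIds = loci$gene_id,
      paralogy = paralogy, truth = truth)
}
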