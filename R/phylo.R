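.msaMatrix <- function(msa) {
  if (is.matrix(msa)) {
    m <- msa
  } else {
    seqs <- .asNamedChar(msa)
    if (is.null(names(seqs))) stop("alignment sequences must be named")
    if (length(unique(nchar(seqs))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named")
  m
}

#' Pairwise p-distances from a peptide alignment
#'
#' d(i, j) = mismatches / compared columns, where columns holding a gap
#' ("-" or ".") in either sequence are excluded pairwise.
#'
#' @param msa named character vector / \code{AAStringSet} of aligned
#'   sequences, or a character matrix.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sequence
#'   name.
#' @export
pDistance <- function(msa) {
  m <- .msaMatrix(msa)
  n <- nrow(m)
  gaps <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !gaps[i, ] & !gaps[j, ]
      if (!any(ok))
        stop("no comparable columns between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising
#' Q(i, j) = (r - 2) d(i, j) - R(i) - R(j) is joined, with the usual
#' branch-length formulas. Negative branch lengths are clamped to zero with
#' the deficit moved to the sibling edge, so the joined distance is
#' preserved. Q ties are broken towards the lexicographically smallest pair
#' of subtree labels (the smallest tip label each subtree contains). The
#' result is an unrooted \code{phylo}.
#'
#' @param d symmetric distance matrix with labelled rows, >= 3 taxa.
#' @return An \pkg{ape} \code{phylo} object.
#' @export
njTree <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("'d' must be a symmetric matrix")
  if (any(!is.finite(d))) stop("distances must be finite")
  labels <- rownames(d)
  if (is.null(labels) || length(labels) < 3L)
    stop("need >= 3 labelled taxa")
  frag <- labels                 # Newick fragment per active node
  key <- labels                  # smallest tip label per active node
  D <- unname(d)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1L) {
      pk <- apply(best, 1, function(ij) {
        p <- sort(c(key[ij[1]], key[ij[2]]))
        paste(p, collapse = "\r")
      })
      best <- best[order(pk), , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- D[i, j]; vi <- 0 }
    if (vj < 0) { vi <- D[i, j]; vj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newKey <- min(key[i], key[j])
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    key <- c(key[keep], newKey)
  }
  ## final trifurcation: three-point formulas
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(va), frag[2], fmt(vb),
                 frag[3], fmt(vc))
  ape::read.tree(text = txt)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance NJ
#' tree per replicate, and attaches to each internal node of the original
#' tree the fraction of replicate trees containing its bipartition.
#'
#' @param msa alignment as in [pDistance()].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; identical seeds give identical supports.
#' @return The original NJ tree with supports in \code{node.label}.
#' @export
bootstrapSupport <- function(msa, replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("'replicates' must be >= 1")
  m <- .msaMatrix(msa)
  tree <- njTree(pDistance(m))
  set.seed(seed)
  boot <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot[[b]] <- njTree(pDistance(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- formatC(counts / replicates, digits = 3, format = "g")
  tree
}

.treeSplits <- function(tree) {
  ## all bipartition sides of an unrooted tree, as tip-label sets
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    side <- tips[p]
    sides[[length(sides) + 1L]] <- side
    comp <- setdiff(tips, side)
    if (length(comp)) sides[[length(sides) + 1L]] <- comp
  }
  unique(sides)
}

#' Assign leaves to reference groups by smallest enclosing clade
#'
#' Each unlabelled leaf takes the group of the smallest clade (bipartition
#' side) that contains it together with at least one group exemplar. Leaves
#' whose smallest exemplar-containing clade mixes exemplars of several
#' groups are labelled "unassigned" (the fate of lineages independent of
#' every group).
#'
#' @param tree a \code{phylo}.
#' @param referenceMembers named character vector (exemplar id -> group) or
#'   data.frame(gene_id, group).
#' @return Named character vector: every tip -> group label or "unassigned".
#' @export
assignGroups <- function(tree, referenceMembers) {
  if (is.data.frame(referenceMembers)) {
    ref <- stats::setNames(referenceMembers$group, referenceMembers$gene_id)
  } else ref <- referenceMembers
  missing <- setdiff(names(ref), tree$tip.label)
  if (length(missing))
    stop("exemplar(s) absent from tree: ", paste(missing, collapse = ", "))
  sides <- .treeSplits(tree)
  sizes <- lengths(sides)
  out <- stats::setNames(rep(NA_character_, length(tree$tip.label)),
                         tree$tip.label)
  out[names(ref)] <- ref
  for (tip in setdiff(tree$tip.label, names(ref))) {
    cand <- which(vapply(sides, function(s)
      tip %in% s && any(names(ref) %in% s), logical(1)))
    if (!length(cand)) { out[tip] <- "unassigned"; next }
    ## all minimal-size candidate clades count; ties spanning several
    ## groups leave the leaf unassigned (the fate of basal outliers)
    minimal <- cand[sizes[cand] == min(sizes[cand])]
    groups <- unique(unlist(lapply(minimal, function(k)
      ref[intersect(names(ref), sides[[k]])])))
    out[tip] <- if (length(groups) == 1L) groups else "unassigned"
  }
  out
}

#' Star-progressive alignment of a protein family
#'
#' Fallback aligner for synthetic data: all sequences are globally aligned
#' (match 1, mismatch -1, gap -2) against the longest sequence and merged on
#' its coordinates. Equal-length inputs pass through unchanged. Pre-computed
#' alignments should be preferred for real data.
#'
#' @param seqs named \code{AAStringSet} or character vector.
#' @return Named character vector of aligned, equal-length sequences.
#' @export
alignFamily <- function(seqs) {
  seqs <- .asNamedChar(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  center <- names(seqs)[which.max(nchar(seqs))]
  L <- nchar(seqs[[center]])
  alpha <- unique(c(strsplit(paste(seqs, collapse = ""), "")[[1]]))
  sub <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(sub) <- 1
  resAt <- list(); insAt <- list()
  for (id in names(seqs)) {
    if (id == center) {
      resAt[[id]] <- strsplit(seqs[[center]], "")[[1]]
      insAt[[id]] <- rep("", L + 1L)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs[[id]], subject = seqs[[center]], type = "global",
      substitutionMatrix = sub, gapOpening = 0, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    res <- character(L); ins <- rep("", L + 1L)
    cpos <- 0L
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        ins[cpos + 1L] <- paste0(ins[cpos + 1L], p[k])
      } else {
        cpos <- cpos + 1L
        res[cpos] <- p[k]
      }
    }
    resAt[[id]] <- res; insAt[[id]] <- ins
  }
  pad <- Reduce(pmax, lapply(insAt, nchar))
  build <- function(id) {
    out <- character(0)
    for (pos in 0:L) {
      ins <- insAt[[id]][pos + 1L]
      out <- c(out, paste0(ins, strrep("-", pad[pos + 1L] - nchar(ins))),
               if (pos < L) resAt[[id]][pos + 1L])
    }
    paste(out, collapse = "")
  }
  stats::setNames(vapply(names(seqs), build, character(1)), names(seqs))
}
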