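# Independent oracles, written against the definitions rather than the
# package internals, so implementation and check cannot share a bug.

# ---- NG86: exhaustive pathway enumeration ---------------------------------

oracleNg86 <- function(sa, sb) {
  GC <- Biostrings::GENETIC_CODE
  splitCod <- function(s) substring(s, seq(1, nchar(s), 3),
                                    seq(3, nchar(s), 3))
  ca <- splitCod(sa); cb <- splitCod(sb)
  stopifnot(length(ca) == length(cb))
  siteFrac <- function(codon) {
    s <- 0
    for (p in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (substr(codon, p, p) == nt) next
        mut <- codon
        substr(mut, p, p) <- nt
        if (GC[[mut]] == GC[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  pathCounts <- function(c1, c2) {
    dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dif)) return(c(0, 0))
    recur <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0, 0)))
      out <- list()
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- GC[[cur]] == GC[[nxt]]
        blocked <- GC[[nxt]] == "*" && nxt != c2
        for (tail in recur(nxt, setdiff(remaining, p)))
          out[[length(out) + 1]] <- c(tail[1] + syn, tail[2] + !syn,
                                      max(tail[3], blocked))
      }
      out
    }
    paths <- do.call(rbind, recur(c1, dif))
    use <- paths[, 3] == 0
    if (!any(use)) use <- rep(TRUE, nrow(paths))
    colMeans(paths[use, 1:2, drop = FALSE])
  }
  S <- (sum(vapply(ca, siteFrac, 0)) + sum(vapply(cb, siteFrac, 0))) / 2
  d <- vapply(seq_along(ca), function(i) pathCounts(ca[i], cb[i]),
              numeric(2))
  list(S = S, N = 3 * length(ca) - S, Sd = sum(d[1, ]), Nd = sum(d[2, ]))
}

# random codon sequence without stops, plus a mutated partner
randomCodonPair <- function(nCodons, nMut) {
  nts <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    a <- paste(sample(nts, 3 * nCodons, replace = TRUE), collapse = "")
    if (!any(substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3)) %in%
             stops)) break
  }
  b <- a
  for (m in seq_len(nMut)) {
    repeat {
      p <- sample.int(nchar(b), 1)
      cand <- b
      substr(cand, p, p) <- sample(setdiff(nts, substr(b, p, p)), 1)
      cods <- substring(cand, seq(1, nchar(cand), 3), seq(3, nchar(cand), 3))
      if (!any(cods %in% stops)) { b <- cand; break }
    }
  }
  c(a, b)
}

# ---- longest chain: brute force over all anchor subsets -------------------

bruteChain <- function(a, b) {
  n <- length(a)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    o <- order(a[idx])
    aa <- a[idx][o]; bb <- b[idx][o]
    okF <- all(diff(aa) > 0) && all(diff(bb) > 0)
    okR <- all(diff(aa) > 0) && all(diff(-bb) > 0)
    if (okF || okR) best <- length(idx)
  }
  best
}

# ---- isoelectric point: grid search with a separate charge function -------

oraclePi <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  pkaPos <- c(H = 5.98, K = 10.0, R = 12.0)
  pkaNeg <- c(C = 9.0, D = 4.05, E = 4.45, Y = 10.0)
  nTermTab <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.7, G = 7.5)
  cTermTab <- c(D = 4.55, E = 4.75)
  nT <- ifelse(res[1] %in% names(nTermTab), nTermTab[res[1]], 7.5)
  cT <- ifelse(res[length(res)] %in% names(cTermTab),
               cTermTab[res[length(res)]], 3.55)
  charge <- function(pH) {
    q <- 1 / (1 + 10^(pH - nT)) - 1 / (1 + 10^(cT - pH))
    for (r in res) {
      if (r %in% names(pkaPos)) q <- q + 1 / (1 + 10^(pH - pkaPos[[r]]))
      if (r %in% names(pkaNeg)) q <- q - 1 / (1 + 10^(pkaNeg[[r]] - pH))
    }
    q
  }
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(vapply(grid, charge, 0)))]
}

# ---- geNorm M: spreadsheet-style step-by-step computation -----------------

oracleGenorm <- function(ctMatrix, E) {
  # ctMatrix: candidates x samples of replicate-mean Ct
  Q <- t(apply(ctMatrix, 1, function(ct) E^(min(ct) - ct)))
  M <- numeric(nrow(Q))
  for (j in seq_len(nrow(Q))) {
    sds <- c()
    for (k in seq_len(nrow(Q))) {
      if (k == j) next
      sds <- c(sds, stats::sd(log2(Q[j, ] / Q[k, ])))
    }
    M[j] <- mean(sds)
  }
  stats::setNames(M, rownames(ctMatrix))
}

# ---- additive distance matrices and exhaustive LS topology search ---------

randomAdditiveMatrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}

# least-squares fit of branch lengths for a fixed topology
lsFit <- function(topo, d) {
  tips <- topo$tip.label
  nE <- nrow(topo$edge)
  pairs <- utils::combn(length(tips), 2)
  X <- matrix(0, ncol(pairs), nE)
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    np <- ape::nodepath(topo, i, j)
    for (s in seq_len(length(np) - 1)) {
      e <- which((topo$edge[, 1] == np[s] & topo$edge[, 2] == np[s + 1]) |
                 (topo$edge[, 2] == np[s] & topo$edge[, 1] == np[s + 1]))
      X[k, e] <- 1
    }
    y[k] <- d[tips[i], tips[j]]
  }
  b <- qr.coef(qr(X), y)
  b[is.na(b)] <- 0
  sum((y - X %*% b)^2)
}

bestLsTopology <- function(d) {
  n <- nrow(d)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(d))
  ss <- vapply(topos, lsFit, numeric(1), d = d)
  topos[[which.min(ss)]]
}

# ---- small synthetic worlds ----------------------------------------------

smallSimConfig <- function(...) {
  args <- list(nAncestralGenes = 12L, codonLength = 240L,
               backgroundPerGap = 9L, seed = 5L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}
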