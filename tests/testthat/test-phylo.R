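test_that("p-distance counts mismatches over comparable columns", {
  msa <- c(a = "AAAA", b = "AAAT", c = "AAAA")
  d <- pDistance(msa)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(unname(d)))
  # a gapped column is excluded only for the pairs it affects
  msa2 <- c(a = "AAAA", b = "AA-A", c = "TAAA")
  d2 <- pDistance(msa2)
  expect_equal(d2["a", "b"], 0)        # 3 comparable columns, all equal
  expect_equal(d2["a", "c"], 0.25)     # full 4 columns compared
  expect_error(pDistance(c(a = "--", b = "A-")), "comparable")
})

test_that("neighbor-joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  # three-point formulas: va = (dab + dac - dbc)/2 etc.
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), 1)
  expect_equal(unname(el["b"]), 2)
  expect_equal(unname(el["c"]), 3)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("neighbor-joining recovers additive matrices exactly", {
  # 4-taxon additive matrix with known unique topology ((a,b),(c,d))
  tr0 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  d <- stats::cophenetic(tr0)
  tr <- njTree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  # 8-taxon random additive matrices: path-length matrix reproduces input
  for (seed in 1:20) {
    am <- randomAdditiveMatrix(8, seed)
    out <- njTree(am$d)
    expect_equal(stats::cophenetic(out)[rownames(am$d), colnames(am$d)],
                 am$d, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(am$tree, out)), 0)
  }
})

test_that("neighbor-joining matches ape::nj on random noisy matrices", {
  set.seed(33)
  for (i in 1:5) {
    am <- randomAdditiveMatrix(7, i + 100)
    d <- am$d + matrix(stats::runif(49, 0, 0.01), 7)  # mild non-additivity
    d <- (d + t(d)) / 2; diag(d) <- 0
    expect_equal(as.numeric(ape::dist.topo(njTree(d),
                                           ape::unroot(ape::nj(d)))), 0)
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  b <- simulateFamily(smallSimConfig(nAncestralGenes = 5L))
  msa <- as.character(b@proteins)
  names(msa) <- names(b@proteins)
  msa <- msa[nchar(msa) == max(nchar(msa))]
  t1 <- bootstrapSupport(msa, replicates = 25, seed = 4)
  t2 <- bootstrapSupport(msa, replicates = 25, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s <- suppressWarnings(as.numeric(t1$node.label))
  s <- s[!is.na(s)]
  expect_true(all(s >= 0 & s <= 1))
  # one replicate: supports are 0 or 1
  t3 <- bootstrapSupport(msa, replicates = 1, seed = 4)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 1)))
  expect_error(bootstrapSupport(msa, replicates = 0), ">= 1")
})

test_that("well-separated clades get high bootstrap support", {
  # two clades of near-identical sequences, far apart from each other
  set.seed(12)
  base1 <- paste(sample(c("A", "V", "G", "T"), 120, replace = TRUE),
                 collapse = "")
  base2 <- paste(sample(c("K", "R", "D", "E"), 120, replace = TRUE),
                 collapse = "")
  mut <- function(s, k) {
    for (i in sample.int(nchar(s), k)) substr(s, i, i) <- "S"
    s
  }
  msa <- c(a1 = mut(base1, 2), a2 = mut(base1, 3), a3 = mut(base1, 4),
           b1 = mut(base2, 2), b2 = mut(base2, 3), b3 = mut(base2, 4))
  tr <- bootstrapSupport(msa, replicates = 100, seed = 1)
  part <- ape::prop.part(tr)
  labs <- suppressWarnings(as.numeric(tr$node.label))
  # the bipartition separating the clades has support >= 0.95
  sides <- lapply(part, function(p) sort(tr$tip.label[p]))
  sep <- which(vapply(sides, function(s)
    identical(s, c("a1", "a2", "a3")) || identical(s, c("b1", "b2", "b3")),
    logical(1)))
  expect_true(any(labs[sep] >= 0.95))
})

test_that("group assignment follows the smallest exemplar clade", {
  tr <- ape::read.tree(text = "(((x1:1,exA:1):1,exA2:1):2,((y1:1,exB:1):1,z1:5):2);")
  ref <- c(exA = "A", exA2 = "A", exB = "B")
  g <- assignGroups(tr, ref)
  expect_identical(unname(g["x1"]), "A")
  expect_identical(unname(g["y1"]), "B")
  # z1's smallest exemplar clade contains only B exemplars here; use a
  # deeper outlier tree to exercise "unassigned"
  tr2 <- ape::read.tree(text = "((a:1,exA:1):1,(b:1,exB:1):1,lone:9);")
  g2 <- assignGroups(tr2, c(exA = "A", exB = "B"))
  expect_identical(unname(g2["lone"]), "unassigned")
  expect_error(assignGroups(tr2, c(ghost = "A")), "absent")
})

test_that("clade ground truth is recovered from simulated families", {
  b <- simulateFamily(smallSimConfig(nAncestralGenes = 8L,
                                     pseudogeneFraction = 0))
  msa <- as.character(b@proteins)
  names(msa) <- names(b@proteins)
  tr <- njTree(pDistance(msa))
  truth <- b@truth@groupAssignment
  exemplars <- truth[sprintf("Fam%03dA", 1:8)]   # one exemplar per family
  g <- assignGroups(tr, exemplars)
  expect_identical(g[names(truth)], truth)
  # both members of every WGD pair share a group (criterion-1 feeder)
  wgd <- b@truth@duplicatePairs[b@truth@duplicatePairs$origin == "WGD", ]
  expect_identical(unname(g[wgd$gene_a]), unname(g[wgd$gene_b]))
})

test_that("the fallback star alignment handles unequal lengths", {
  seqs <- c(long = "MKVAWGG", mid = "MKVAGG", shorter = "MKAG")
  aln <- alignFamily(seqs)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln[["long"]]), "MKVAWGG")
  expect_identical(gsub("-", "", aln[["shorter"]]), "MKAG")
  # equal-length input passes through unchanged
  eq <- c(a = "MKV", b = "MKL")
  expect_identical(alignFamily(eq), eq)
})
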