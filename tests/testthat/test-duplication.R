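makeOrderedModels <- function(famAt, n = 30L, chrom = "Chr01") {
  # n genes in a row; family genes at positions famAt
  starts <- seq(1L, by = 1000L, length.out = n)
  ids <- sprintf("g%02d", seq_len(n))
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(starts, starts + 500L),
                              strand = "+")
  names(g) <- ids
  list(models = geneModelSet(g), family = ids[famAt], ids = ids)
}

test_that("tandem clusters are maximal runs bounded by intervening genes", {
  w <- makeOrderedModels(c(5, 6, 7, 15, 20))
  tc <- findTandemClusters(w$models, w$family, tandemMaxIntervening = 1L)
  expect_equal(nrow(tc), 1L)
  expect_identical(tc$members, "g05,g06,g07")
  # two family genes separated by more than the allowance: no cluster
  tc2 <- findTandemClusters(w$models, c("g05", "g08"),
                            tandemMaxIntervening = 1L)
  expect_equal(nrow(tc2), 0L)
  # allowance 2 bridges one 2-gene gap
  tc3 <- findTandemClusters(w$models, c("g05", "g08"),
                            tandemMaxIntervening = 2L)
  expect_equal(nrow(tc3), 1L)
  expect_error(findTandemClusters(w$models, "nope", 1L), "absent")
})

test_that("tandem clusters match a brute-force scan over permuted orders", {
  bruteClusters <- function(ord, fam, maxInt) {
    # ord: gene ids in chromosome order
    pos <- match(fam, ord)
    pos <- sort(pos)
    groups <- split(pos, cumsum(c(0, diff(pos) - 1 > maxInt)))
    Filter(function(g) length(g) >= 2, groups)
  }
  set.seed(21)
  for (rep in 1:100) {
    n <- 25L
    starts <- seq(1L, by = 1000L, length.out = n)
    ids <- sample(sprintf("g%02d", 1:n))   # random order along chromosome
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(starts, starts + 10L),
                                strand = "+")
    names(g) <- ids
    models <- geneModelSet(g)
    fam <- sample(ids, 8)
    maxInt <- sample(0:3, 1)
    got <- findTandemClusters(models, fam, maxInt)
    want <- bruteClusters(ids, fam, maxInt)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wantMembers <- sort(vapply(want, function(p)
        paste(ids[p], collapse = ","), character(1)))
      expect_setequal(got$members, wantMembers)
    }
  }
})

test_that("collinearity support counts the longest strictly-increasing chain", {
  ordA <- stats::setNames(1:10, paste0("a", 1:10))
  ordB <- stats::setNames(1:10, paste0("b", 1:10))
  hp <- data.frame(gene_a = paste0("a", c(2, 4, 6, 8, 9)),
                   gene_b = paste0("b", c(2, 4, 6, 8, 9)))
  # exact gene-order copies: all 5 pairs chain
  expect_equal(collinearitySupport(ordA, ordB, hp, c("a6", "b6"), 25L), 5L)
  # reversing segment B leaves the count unchanged (orientation-aware)
  ordBrev <- stats::setNames(10:1, paste0("b", 1:10))
  expect_equal(collinearitySupport(ordA, ordBrev, hp, c("a6", "b6"), 25L),
               5L)
  # window restriction: only anchors within +/- 2 genes of the focal pair
  expect_equal(collinearitySupport(ordA, ordB, hp, c("a6", "b6"), 2L), 3L)
  expect_error(collinearitySupport(ordA, ordB, hp, c("a1", "b1"), 25L),
               "focal")
})

test_that("chain length equals the brute-force subset oracle", {
  set.seed(77)
  for (rep in 1:50) {
    k <- sample(3:11, 1)
    a <- sample(1:30, k)
    b <- sample(1:30, k)
    ids <- sprintf("p%02d", seq_len(k))
    ordA <- stats::setNames(a, paste0("x", ids))
    ordB <- stats::setNames(b, paste0("y", ids))
    hp <- data.frame(gene_a = paste0("x", ids), gene_b = paste0("y", ids))
    focal <- c(paste0("x", ids[1]), paste0("y", ids[1]))
    got <- collinearitySupport(ordA, ordB, hp, focal, window = 100L)
    expect_equal(got, max(bruteChain(a, b), bruteChain(a, -b)))
  }
})

test_that("segment pairs recover the simulated WGD history", {
  cfg <- smallSimConfig(pseudogeneFraction = 0)
  b <- simulateFamily(cfg)
  msa <- as.character(b@proteins)
  names(msa) <- names(b@proteins)
  pd <- pDistance(msa)
  tree <- njTree(pd)
  cand <- which(pd <= 0.5 & upper.tri(pd), arr.ind = TRUE)
  pairs <- data.frame(gene_a = rownames(pd)[cand[, 1]],
                      gene_b = rownames(pd)[cand[, 2]],
                      stringsAsFactors = FALSE)
  ks <- pairKaKs(b@cds, pairs)
  seg <- identifySegmentPairs(b@models, b@familyIds, ks, tree,
                              surveyConfig(), paralogy = b@paralogy)
  expect_true(all(seg$validated))
  rec <- unlist(strsplit(seg$member_pairs, ","))
  wgd <- b@truth@duplicatePairs[b@truth@duplicatePairs$origin == "WGD", ]
  expect_setequal(rec, paste(wgd$gene_a, wgd$gene_b, sep = "|"))
  # tandem siblings are below the WGD Ks window, so they are not members,
  # but they sit inside the segment spans of their families
  expect_true(any(grepl("\\.t1", seg$members_a)))
  # representative Ks values fall in the WGD window and date to ~16 Mya
  expect_true(all(seg$ks >= 0.06 & seg$ks <= 0.45))
  expect_true(all(abs(seg$time_mya - divergenceTime(seg$ks)) < 1e-9))
  # purifying selection throughout (the simulated omega is ~0.2)
  expect_true(all(seg$selection == "purifying"))
  expect_error(identifySegmentPairs(b@models, character(0), ks, tree),
               "empty family")
})
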