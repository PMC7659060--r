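makeCt <- function(ctMatrix, E = 2, reps = 1L, noise = 0) {
  rows <- expand.grid(replicate = seq_len(reps),
                      sample_id = colnames(ctMatrix),
                      gene_id = rownames(ctMatrix),
                      stringsAsFactors = FALSE)
  rows <- rows[, c("gene_id", "sample_id", "replicate")]
  rows$ct <- ctMatrix[cbind(rows$gene_id, rows$sample_id)] +
    stats::rnorm(nrow(rows), 0, noise)
  rows$efficiency <- E
  rows
}

test_that("geNorm M is zero for perfectly parallel candidates", {
  samples <- paste0("s", 1:5)
  ctm <- rbind(r1 = c(20, 21, 19, 22, 20),
               r2 = c(25, 26, 24, 27, 25))   # parallel: constant ratio
  colnames(ctm) <- samples
  st <- genormStability(makeCt(ctm), c("r1", "r2"))
  expect_equal(st$M, c(0, 0), tolerance = 1e-12)
})

test_that("geNorm M matches the step-by-step spreadsheet oracle", {
  set.seed(14)
  samples <- paste0("s", 1:5)
  ctm <- matrix(20 + stats::rnorm(20, 0, 1.5), 4,
                dimnames = list(paste0("r", 1:4), samples))
  st <- genormStability(makeCt(ctm), rownames(ctm))
  oracle <- oracleGenorm(ctm, 2)
  expect_equal(stats::setNames(st$M, st$gene_id),
               sort(oracle), tolerance = 1e-10)
  expect_identical(st$rank, seq_len(4L))
  # invariant: adding a constant to every Ct of one sample changes nothing
  ctm2 <- ctm; ctm2[, 3] <- ctm2[, 3] + 2.5
  st2 <- genormStability(makeCt(ctm2), rownames(ctm))
  expect_equal(st2$M[order(st2$gene_id)], st$M[order(st$gene_id)],
               tolerance = 1e-10)
  expect_error(genormStability(makeCt(ctm), "r1"), ">= 2")
  expect_error(genormStability(makeCt(ctm), c("r1", "zz")), "zz")
})

test_that("relative expression is efficiency-corrected and baseline-anchored", {
  samples <- c("12dN", "30dN")
  # flat references; target one cycle lower at 30dN -> fold 2 with E = 2
  ctm <- rbind(tgt = c(24, 23), ref1 = c(20, 20), ref2 = c(22, 22))
  colnames(ctm) <- samples
  fc <- relativeExpression(makeCt(ctm), "tgt", c("ref1", "ref2"), "12dN")
  expect_equal(fc$fold_change[fc$sample_id == "12dN"], 1)
  expect_equal(fc$sd[fc$sample_id == "12dN"], 0)
  expect_equal(fc$fold_change[fc$sample_id == "30dN"], 2)
  # with one reference and E = 2 this is the classic 2^-ddCt
  set.seed(3)
  ctm2 <- rbind(tgt = c(24, 22.3, 25.1), ref = c(20, 20.8, 19.2))
  colnames(ctm2) <- paste0("s", 1:3)
  fc2 <- relativeExpression(makeCt(ctm2), "tgt", "ref", "s1")
  ddct <- (ctm2["tgt", ] - ctm2["ref", ]) -
    (ctm2["tgt", "s1"] - ctm2["ref", "s1"])
  expect_equal(fc2$fold_change, unname(2^-ddct), tolerance = 1e-12)
  expect_error(relativeExpression(makeCt(ctm2), "tgt", "ref", "zz"),
               "baseline")
})

test_that("noisy fold changes stay within 3 SD of the generator truth", {
  set.seed(8)
  truthLog2 <- c(0, 1.5, 3, 2, -1)
  samples <- paste0("t", 1:5)
  ctm <- rbind(tgt = 24 - truthLog2, ref1 = rep(20, 5), ref2 = rep(21, 5))
  colnames(ctm) <- samples
  ct <- makeCt(ctm, reps = 3L, noise = 0.2)
  fc <- relativeExpression(ct, "tgt", c("ref1", "ref2"), "t1")
  ok <- abs(log2(fc$fold_change) - truthLog2) <=
    pmax(3 * fc$sd / (fc$fold_change * log(2)), 1e-9) + 3 * 0.2
  expect_true(all(ok))
})

test_that("temporal patterns classify by the stated rules", {
  tp <- c("12dN", "30dN", "42dN", "64dN", "84dN")
  cl <- function(fc) classifyPattern(stats::setNames(fc, tp))$class
  expect_identical(cl(c(1, 1.2, 2.5, 4, 9)), "senescence_up")
  expect_identical(cl(c(1, 0.4, 0.3, 0.2, 0.2)), "development_down")
  expect_identical(cl(c(1, 2.3, 6, 1.2, 0.7)), "mid_peak")
  expect_identical(cl(c(1, 0.3, 0.2, 0.6, 2.6)), "down_then_up")
  expect_identical(cl(c(1, 2.1, 4.6, 8, 2)), "up_then_down")
  expect_identical(cl(c(1, 7, 1.4, 1.4, 10)), "bimodal")
  expect_identical(cl(c(1, 1.2, 0.9, 1.1, 1)), "flat")
  pk <- classifyPattern(stats::setNames(c(1, 2.3, 6, 1.2, 0.7), tp))
  expect_identical(pk$peak_timepoint, "42dN")
  # scale invariance
  for (fc in list(c(1, 1.2, 2.5, 4, 9), c(1, 7, 1.4, 1.4, 10))) {
    expect_identical(classifyPattern(stats::setNames(fc, tp))$class,
                     classifyPattern(stats::setNames(fc * 37, tp))$class)
  }
  expect_error(classifyPattern(c(1, 2)), "3 timepoints")
})

test_that("RNS candidates need high expression in both tissue classes", {
  mat <- matrix(1, 8, 4, dimnames = list(paste0("g", 1:8),
                                         c("sym1", "sym2", "nod1", "nod2")))
  mat["g1", ] <- 50                       # high everywhere -> selected
  mat["g2", c("sym1", "sym2")] <- 50      # symbiosis only -> not selected
  mat["g3", c("nod1", "nod2")] <- 50      # nodule only -> not selected
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    colData = S4Vectors::DataFrame(
      tissue_class = c("symbiosis", "symbiosis", "nodule", "nodule"),
      row.names = colnames(mat)))
  expect_identical(selectRnsCandidates(se), "g1")
  bad <- se[, 1:2]
  expect_error(selectRnsCandidates(bad), "nodule")
})

test_that("heatmap transform is log2(x+1) with row centering", {
  set.seed(5)
  mat <- matrix(stats::rexp(40, 0.1), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  mat[1, ] <- 0
  mat[2, ] <- 7.3
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    colData = S4Vectors::DataFrame(tissue_class = rep("nodule", 5),
                                   row.names = colnames(mat)))
  hm <- heatmapMatrix(se)
  tm <- SummarizedExperiment::assay(hm)
  expect_equal(unname(tm[1, ]), rep(0, 5))       # all-zero row stays zero
  expect_equal(unname(tm[2, ]), rep(0, 5))       # constant row centers to 0
  expect_equal(unname(rowMeans(tm)), rep(0, 8))  # algebraic identity
  expect_match(S4Vectors::metadata(hm)$transformation, "log2")
})
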