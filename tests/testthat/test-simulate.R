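test_that("the simulator conserves gene counts and is deterministic", {
  cfg <- smallSimConfig(seed = 13L)
  b <- simulateFamily(cfg)
  nTandemExtra <- sum(cfg@tandemClusterSizes - 1L)
  expect_equal(length(b@familyIds),
               2L * cfg@nAncestralGenes + nTandemExtra)
  expect_equal(nrow(b@truth@pseudogenes),
               round(cfg@pseudogeneFraction * length(b@familyIds)))
  # byte-identical bundles from identical configs
  b2 <- simulateFamily(smallSimConfig(seed = 13L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(b, d1); writeBundle(b2, d2)
  for (f in c("cds.fna", "proteins.faa", "genes.gff3", "domain_hits.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed gives different sequences
  b3 <- simulateFamily(smallSimConfig(seed = 14L))
  expect_false(identical(as.character(b@cds), as.character(b3@cds)))
})

test_that("every non-pseudogene translates without internal stops", {
  b <- simulateFamily(smallSimConfig(pseudogeneFraction = 0.2, seed = 3L))
  prot <- as.character(b@proteins)
  expect_false(any(grepl("\\*", prot)))
  expect_true(all(substr(prot, 1, 1) == "M"))
})

test_that("zero target divergence gives identical duplicate pairs", {
  b <- simulateFamily(smallSimConfig(wgdTargetKs = 0, tandemTargetKs = 0,
                                     kaKsRatio = 0, pseudogeneFraction = 0))
  cds <- as.character(b@cds)
  tp <- b@truth@duplicatePairs
  expect_true(all(cds[tp$gene_a] == cds[tp$gene_b]))
  expect_true(all(tp$true_ks == 0))
  r <- ng86KaKs(cds[[tp$gene_a[1]]], cds[[tp$gene_b[1]]])
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
})

test_that("NG86 estimates of simulated WGD pairs are calibrated", {
  # pilot-scale check of the generator/estimator pairing: n = 20 pairs
  b <- simulateFamily(simConfig(nAncestralGenes = 20L, wgdTargetKs = 0.2,
                                pseudogeneFraction = 0, seed = 31L,
                                backgroundPerGap = 9L))
  wgd <- b@truth@duplicatePairs[b@truth@duplicatePairs$origin == "WGD", ]
  ks <- pairKaKs(b@cds, wgd)
  se <- stats::sd(ks$ks) / sqrt(nrow(ks))
  expect_lte(abs(mean(ks$ks) - 0.2), 3 * se)
})

test_that("tandem arrays overflowing a chromosome are rejected", {
  expect_error(simulateFamily(simConfig(nAncestralGenes = 2L,
                                        tandemClusterSizes = c(2L, 2L, 2L),
                                        nChromosomes = 4L)),
               "capacity")
})

test_that("simulated expression honours class profiles and references", {
  b <- simulateFamily(smallSimConfig(pseudogeneFraction = 0, seed = 17L))
  cfg0 <- smallSimConfig(pseudogeneFraction = 0, seed = 17L,
                         qpcrNoiseSd = 0)
  ex <- simulateExpression(b@truth, cfg = cfg0)
  ct <- ex$ct
  # designed flat references: identical Ct at all timepoints with no noise
  for (ref in b@truth@referenceGenes) {
    cts <- ct$ct[ct$gene_id == ref]
    expect_equal(diff(range(cts)), 0)
  }
  # a senescence-up gene is monotone with its maximum at the last timepoint
  up <- names(b@truth@expressionClass)[b@truth@expressionClass ==
                                       "senescence_up"][1]
  fc <- relativeExpression(ct, up, b@truth@referenceGenes, "12dN")
  expect_true(all(diff(fc$fold_change) > 0))
  expect_equal(which.max(fc$fold_change), 5L)
  # unknown class labels are rejected
  bad <- b@truth
  bad@expressionClass[1] <- "mystery"
  expect_error(simulateExpression(bad, cfg = cfg0), "mystery")
})
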