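test_that("molecular weight matches atomic-mass summation", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecularWeight("GG"), 2 * molecularWeight("G") - 18.01524)
  expect_error(molecularWeight(""), "empty")
  expect_error(molecularWeight("GXG"), "position 2")

  # brute-force oracle: independent residue-mass table, random peptides
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  set.seed(42)
  for (i in 1:20) {
    pep <- paste(sample(names(masses), sample(5:80, 1), replace = TRUE),
                 collapse = "")
    oracle <- sum(masses[strsplit(pep, "")[[1]]]) + 18.01524
    expect_equal(molecularWeight(pep), oracle, tolerance = 1e-8)
  }
})

test_that("isoelectric point agrees with a grid-search charge oracle", {
  expect_gt(isoelectricPoint("KKKKKK"), 7)    # only basic side chains
  expect_lt(isoelectricPoint("DDDDDD"), 7)
  pep <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(isoelectricPoint(pep), oraclePi(pep), tolerance = 0.01)
  set.seed(7)
  for (i in 1:10) {
    p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(4:40, 1), replace = TRUE), collapse = "")
    expect_equal(isoelectricPoint(p), oraclePi(p), tolerance = 0.01)
  }
})

test_that("census applies the pseudogene rules and assigns architectures", {
  prot <- c(short = strrep("A", 149),      # 149 aa with a full domain
            exact = strrep("A", 150),      # boundary: 150 aa is a member
            nohit = strrep("A", 300),
            trunc = strrep("A", 300),
            gran = strrep("A", 300),
            cathb = strrep("A", 300))
  hits <- rbind(
    data.frame(protein_id = "short", domain = "peptidase_C1", start = 1,
               end = 149, reference_length = 149),
    data.frame(protein_id = "exact", domain = c("inhibitor_I29",
                                                "peptidase_C1"),
               start = c(1, 20), end = c(15, 150),
               reference_length = c(15, 131)),
    data.frame(protein_id = "trunc", domain = "peptidase_C1", start = 10,
               end = 109, reference_length = 220),  # 45% coverage
    data.frame(protein_id = "gran", domain = c("inhibitor_I29",
                                               "peptidase_C1", "GRAN"),
               start = c(1, 50, 270), end = c(40, 260, 295),
               reference_length = c(40, 211, 26)),
    data.frame(protein_id = "cathb",
               domain = c("propeptide_C1", "peptidase_C1A_cathepsinB",
                          "peptidase_C1"),
               start = c(1, 60, 60), end = c(50, 290, 290),
               reference_length = c(50, 231, 231)))
  cen <- callCensus(prot, hits)
  row <- function(id) cen[cen$protein_id == id, ]
  expect_identical(row("short")$status, "pseudogene")
  expect_identical(row("short")$reasons, "length_lt_150")
  expect_identical(row("exact")$status, "member")
  expect_identical(row("exact")$architecture, "I29+C1")
  expect_identical(row("nohit")$reasons, "missing_peptidase_C1")
  expect_identical(row("trunc")$reasons, "truncated_peptidase_C1")
  expect_identical(row("gran")$architecture, "I29+C1+GRAN")
  expect_identical(row("cathb")$architecture, "proC1+cathepsinB")
  # partition: every input gets exactly one call, counts conserve
  expect_equal(nrow(cen), length(prot))
  expect_equal(sum(cen$status == "member") + sum(cen$status == "pseudogene"),
               length(prot))
  # pseudogene status and non-empty reasons coincide
  expect_identical(cen$status == "pseudogene", nzchar(cen$reasons))
  # orphan domain hit
  orphan <- data.frame(protein_id = "ghost", domain = "peptidase_C1",
                       start = 1, end = 10, reference_length = 10)
  expect_error(callCensus(prot, orphan), "ghost")
})

test_that("census recovers simulated pseudogenes exactly", {
  b <- simulateFamily(smallSimConfig(pseudogeneFraction = 0.2, seed = 9L))
  cen <- callCensus(b@proteins, b@domainHits)
  called <- cen$protein_id[cen$status == "pseudogene"]
  expect_setequal(called, b@truth@pseudogenes$gene_id)
  # both trigger paths are exercised
  expect_setequal(unique(b@truth@pseudogenes$reason),
                  c("truncation", "domain_deletion"))
})
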