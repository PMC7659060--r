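## Average isotopic residue masses (Da), ExPASy-style, plus one water per
## peptide chain.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

## Bjellqvist pKa values as used by ExPASy Compute pI: side chains, and
## residue-specific N-/C-terminal pKa.
.PKA_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0,
               Y = 10.0)
.PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.7, G = 7.5)
.PKA_NTERM_DEFAULT <- 7.5
.PKA_CTERM <- c(D = 4.55, E = 4.75)
.PKA_CTERM_DEFAULT <- 3.55

.checkResidues <- function(sequence) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Average molecular weight of a peptide
#'
#' Sum of average isotopic residue masses plus one water (18.01524 Da).
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @return Molecular weight in Da.
#' @export
#' @examples
#' molecularWeight("G")  # glycine, 75.07 Da
molecularWeight <- function(sequence) {
  res <- .checkResidues(sequence)
  sum(.RESIDUE_MASS[res]) + .WATER_MASS
}

.netCharge <- function(res, pH) {
  ## Henderson-Hasselbalch: positive groups (N-terminus, H, K, R) carry
  ## +1/(1+10^(pH-pKa)), negative groups (C-terminus, C, D, E, Y) carry
  ## -1/(1+10^(pKa-pH)).
  n <- length(res)
  pkN <- .PKA_NTERM[res[1]]
  if (is.na(pkN)) pkN <- .PKA_NTERM_DEFAULT
  pkC <- .PKA_CTERM[res[n]]
  if (is.na(pkC)) pkC <- .PKA_CTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pkN))
  neg <- -1 / (1 + 10^(pkC - pH))
  counts <- table(res)
  for (r in c("H", "K", "R")) {
    k <- counts[r]
    if (!is.na(k)) pos <- pos + k / (1 + 10^(pH - .PKA_SIDE[[r]]))
  }
  for (r in c("C", "D", "E", "Y")) {
    k <- counts[r]
    if (!is.na(k)) neg <- neg - k / (1 + 10^(.PKA_SIDE[[r]] - pH))
  }
  unname(pos + neg)
}

#' Isoelectric point of a peptide
#'
#' The pH at which the Henderson-Hasselbalch net charge over the termini and
#' the ionisable side chains (D, E, C, Y, H, K, R; Bjellqvist/ExPASy pKa set)
#' crosses zero. The net charge is monotone decreasing in pH, so the root is
#' unique; it is found by bisection on [0, 14] to a tolerance of 1e-3.
#'
#' @param sequence amino-acid string over the 20 standard residues.
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(sequence) {
  res <- .checkResidues(sequence)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (.netCharge(res, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Census of a gene family: members, pseudogenes, architectures
#'
#' Applies the survey's pseudogene rules: a locus is a putative pseudogene
#' iff its peptide is shorter than 150 residues, or it has no peptidase_C1
#' hit, or its best peptidase_C1 hit covers less than
#' \code{truncationCoverageMin} of the reference domain length (the "large
#' fragment deletion" rule; exactly 150 residues is a member). The domain
#' architecture is read off the surviving hit set.
#'
#' @param proteins named \code{AAStringSet} (or character vector).
#' @param domainHits data.frame(protein_id, domain, start, end,
#'   reference_length); every protein_id must be present in \code{proteins}.
#' @param truncationCoverageMin coverage cutoff, default 0.6.
#' @return data.frame(protein_id, status, reasons, architecture, length,
#'   molecular_weight, isoelectric_point); reasons is a comma-separated
#'   subset of {length_lt_150, missing_peptidase_C1, truncated_peptidase_C1},
#'   empty for members.
#' @export
callCensus <- function(proteins, domainHits, truncationCoverageMin = 0.6) {
  prot <- .asNamedChar(proteins)
  if (is.null(names(prot))) stop("'proteins' must be named")
  orphan <- setdiff(unique(domainHits$protein_id), names(prot))
  if (length(orphan))
    stop("domain hits for unknown protein(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  hitsBy <- split(domainHits, domainHits$protein_id)
  rows <- lapply(names(prot), function(id) {
    seq <- prot[[id]]
    len <- nchar(seq)
    hits <- hitsBy[[id]]
    doms <- if (is.null(hits)) character(0) else unique(hits$domain)
    reasons <- character(0)
    if (len < 150L) reasons <- c(reasons, "length_lt_150")
    c1 <- if (is.null(hits)) hits else hits[hits$domain == "peptidase_C1", ]
    if (is.null(c1) || nrow(c1) == 0L) {
      reasons <- c(reasons, "missing_peptidase_C1")
    } else {
      cov <- max((c1$end - c1$start + 1) / c1$reference_length)
      if (cov < truncationCoverageMin)
        reasons <- c(reasons, "truncated_peptidase_C1")
    }
    arch <- if (all(c("propeptide_C1", "peptidase_C1A_cathepsinB") %in% doms))
      "proC1+cathepsinB"
    else if (all(c("inhibitor_I29", "peptidase_C1", "GRAN") %in% doms))
      "I29+C1+GRAN"
    else if (all(c("inhibitor_I29", "peptidase_C1") %in% doms))
      "I29+C1"
    else "other"
    data.frame(protein_id = id,
               status = if (length(reasons)) "pseudogene" else "member",
               reasons = paste(reasons, collapse = ","),
               architecture = arch, length = len,
               molecular_weight = molecularWeight(seq),
               isoelectric_point = isoelectricPoint(seq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
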