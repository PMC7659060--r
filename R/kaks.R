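## Nei-Gojobori (1986) site and difference counting with equal-weight
## pathway averaging and Jukes-Cantor correction. Per-codon-pair counts are
## memoised, so whole-family scans reduce to table lookups.

.ng86 <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (is.null(.ng86$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ng86$aa <- gc
    .ng86$stops <- names(gc)[gc == "*"]
  }
  .ng86$aa
}

.translateCodon <- function(codon) unname(.codonTable()[codon])

## synonymous site count of one codon: per position, the fraction of the 3
## possible single-nucleotide changes that preserve the amino acid. Changes
## into stop codons count as nonsynonymous.
.synSites <- function(codon) {
  aa <- .codonTable()
  key <- paste0("S_", codon)
  if (!is.null(.ng86[[key]])) return(.ng86[[key]])
  nts <- c("A", "C", "G", "T")
  s <- 0
  split <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (nt in setdiff(nts, split[pos])) {
      alt <- split
      alt[pos] <- nt
      alt <- paste(alt, collapse = "")
      if (identical(aa[[alt]], aa[[codon]])) s <- s + 1 / 3
    }
  }
  .ng86[[key]] <- s
  s
}

## pathway-averaged (Sd, Nd) between two codons. All orderings of the
## differing positions are weighted equally; orderings that pass through a
## stop codon are excluded (if every ordering is blocked, all are used).
.pathDiffs <- function(c1, c2) {
  key <- paste0("D_", c1, "_", c2)
  if (!is.null(.ng86[[key]])) return(.ng86[[key]])
  aa <- .codonTable()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff <- which(a != b)
  res <- if (length(diff) == 0L) c(0, 0) else {
    perms <- .permutations(diff)
    paths <- matrix(NA_real_, nrow = nrow(perms), ncol = 2)
    blocked <- logical(nrow(perms))
    for (p in seq_len(nrow(perms))) {
      cur <- a
      sd <- 0; nd <- 0
      for (pos in perms[p, ]) {
        prev <- paste(cur, collapse = "")
        cur[pos] <- b[pos]
        nxt <- paste(cur, collapse = "")
        if (identical(aa[[nxt]], "*") && nxt != c2) blocked[p] <- TRUE
        if (identical(aa[[prev]], aa[[nxt]])) sd <- sd + 1 else nd <- nd + 1
      }
      paths[p, ] <- c(sd, nd)
    }
    use <- if (all(blocked)) rep(TRUE, nrow(perms)) else !blocked
    colMeans(paths[use, , drop = FALSE])
  }
  .ng86[[key]] <- res
  res
}

.permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

.splitCodons <- function(seq, label) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length of '", label, "' is not divisible by 3")
  if (grepl("[^ACGT]", seq))
    stop("sequence '", label, "' contains non-ACGT characters (gaps are not allowed)")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  stops <- which(codons %in% .ng86$stops)
  internal <- stops[stops < length(codons)]
  if (length(internal))
    stop("internal stop codon at codon ", internal[1], " in '", label, "'")
  if (length(codons) && codons[length(codons)] %in% .ng86$stops)
    codons <- codons[-length(codons)]
  codons
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon as the
#' fraction of single-nucleotide changes preserving the amino acid, averaged
#' over both sequences; counts synonymous/nonsynonymous differences (Sd, Nd)
#' by equal-weight averaging over all minimal mutational pathways between
#' differing codons, excluding pathways through stop codons; and corrects the
#' proportions pS = Sd/S, pN = Nd/N for multiple hits with the Jukes-Cantor
#' formula d = -3/4 log(1 - 4 p / 3).
#'
#' @param cdsA,cdsB in-frame, gap-free coding sequences of equal length
#'   (character or \code{DNAString}); a single trailing stop codon is
#'   trimmed, internal stops are an error.
#' @return A one-row data.frame with columns S, N, Sd, Nd, pS, pN, Ka, Ks,
#'   omega (omega is NA when Ks = 0).
#' @export
#' @examples
#' ng86KaKs("TTTGCTGCAACT", "TTCGCTGCAACT")  # one silent Phe change
ng86KaKs <- function(cdsA, cdsB) {
  .codonTable()
  ca <- .splitCodons(cdsA, "cdsA")
  cb <- .splitCodons(cdsB, "cdsB")
  if (length(ca) != length(cb))
    stop("sequences have different codon counts (", length(ca), " vs ",
         length(cb), ")")
  if (length(ca) == 0L) stop("empty coding sequences")
  Sa <- sum(vapply(ca, .synSites, numeric(1)))
  Sb <- sum(vapply(cb, .synSites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) .pathDiffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p, what) {
    if (p >= 0.75)
      stop("proportion of ", what,
           " differences is >= 0.75; Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS, "synonymous")
  Ka <- jc(pN, "nonsynonymous")
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ka = Ka, Ks = Ks,
             omega = if (Ks > 0) Ka / Ks else NA_real_)
}

#' Ka/Ks over a set of gene pairs
#'
#' @param cds named \code{DNAStringSet} (or character) of coding sequences.
#' @param pairs data.frame with columns gene_a, gene_b.
#' @return \code{pairs} with columns ka, ks, omega appended.
#' @export
pairKaKs <- function(cds, pairs) {
  cds <- .asNamedChar(cds)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing))
    stop("CDS missing for: ", paste(utils::head(missing, 5), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i)
    ng86KaKs(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]]))
  pairs$ka <- vapply(res, function(r) r$Ka, numeric(1))
  pairs$ks <- vapply(res, function(r) r$Ks, numeric(1))
  pairs$omega <- vapply(res, function(r) r$omega, numeric(1))
  pairs
}

#' Date a duplication from synonymous divergence
#'
#' T = Ks / (2 lambda) x 1e-6 million years, with lambda the synonymous
#' substitution rate per site per year (default 6.1e-9, the rate used for
#' the recent Glycine WGD). Reported to 2 decimals.
#'
#' @param ks synonymous substitutions per synonymous site (vectorised).
#' @param clockRate lambda, substitutions/site/year.
#' @param digits decimals to round to (NULL for no rounding).
#' @return Estimated divergence time(s) in Mya.
#' @export
#' @examples
#' divergenceTime(0.3374)  # 27.66 Mya
divergenceTime <- function(ks, clockRate = 6.1e-9, digits = 2) {
  if (any(!is.na(ks) & ks < 0)) stop("Ks must be >= 0")
  if (clockRate <= 0) stop("clockRate must be > 0")
  t <- ks / (2 * clockRate) * 1e-6
  if (is.null(digits)) t else round(t, digits)
}

#' Classify selection from omega = Ka/Ks
#'
#' omega < 1: purifying selection on at least one copy; omega > 1:
#' directional selection; omega = 1: neutral.
#'
#' @param omega non-negative Ka/Ks ratio(s).
#' @return character vector in {"purifying", "neutral", "directional"}.
#' @export
selectionClass <- function(omega) {
  if (any(!is.na(omega) & omega < 0)) stop("omega must be >= 0")
  ifelse(is.na(omega), NA_character_,
         ifelse(omega < 1, "purifying",
                ifelse(omega > 1, "directional", "neutral")))
}
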