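#' Read a FASTA file
#'
#' Thin validating wrapper around \pkg{Biostrings}. Record order is
#' preserved, sequences are upper-cased, duplicate ids and empty records are
#' rejected with the offending line number.
#'
#' @param path path to a FASTA file.
#' @param type "AA" or "DNA"; selects the returned \code{XStringSet} class.
#' @return A named \code{AAStringSet} or \code{DNAStringSet}.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "MKV"), tf)
#' readFasta(tf, "AA")
readFasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  hdr <- startsWith(trimws(lines), ">")
  first <- which(keep)[1]
  if (is.na(first)) stop("FASTA parse error: file '", path, "' is empty")
  if (!hdr[first])
    stop("FASTA parse error at line ", first, ": expected a '>' header")
  headers <- which(hdr)
  ids <- sub("^>\\s*", "", trimws(lines[headers]))
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop("FASTA parse error at line ", headers[which(!nzchar(ids))[1]],
         ": empty header")
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1]
    stop("FASTA parse error at line ", headers[d],
         ": duplicate id '", ids[d], "'")
  }
  ## a record is empty when its header is followed by another header/EOF
  nxt <- c(headers[-1], length(lines) + 1L)
  for (i in seq_along(headers)) {
    body <- lines[seq(headers[i] + 1L, length.out = nxt[i] - headers[i] - 1L)]
    if (!any(nzchar(gsub("\\s", "", body))))
      stop("FASTA parse error at line ", headers[i],
           ": record '", ids[i], "' has an empty sequence")
  }
  set <- switch(type,
                AA = Biostrings::readAAStringSet(path),
                DNA = Biostrings::readDNAStringSet(path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  switch(type,
         AA = Biostrings::AAStringSet(seqs),
         DNA = Biostrings::DNAStringSet(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs a named \code{XStringSet} (or named character vector).
#' @param path output path.
#' @param width line width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
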