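#' Write a survey bundle to a directory
#'
#' Emits every format the pipeline reads (FASTA, GFF3, TSV tables), the
#' ground-truth tables, an optional expression/Ct pair, and a manifest.
#'
#' @param bundle a [SurveyBundle-class].
#' @param dir output directory (created if needed).
#' @param expression optional list(se, ct) from [simulateExpression()].
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir, expression = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  writeFasta(bundle@cds, p("cds.fna"))
  writeFasta(bundle@proteins, p("proteins.faa"))
  writeGff3(bundle@models, p("genes.gff3"))
  writeDomainHits(bundle@domainHits, p("domain_hits.tsv"))
  writeLines(bundle@familyIds, p("family_ids.txt"))
  if (nrow(bundle@paralogy))
    utils::write.table(bundle@paralogy, p("paralogy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tr <- bundle@truth
  utils::write.table(tr@duplicatePairs, p("truth", "duplicate_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr@pseudogenes, p("truth", "pseudogenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(tr@groupAssignment),
               group = unname(tr@groupAssignment)),
    p("truth", "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(tr@expressionClass),
               class = unname(tr@expressionClass)),
    p("truth", "expression_classes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  roles <- rbind(
    data.frame(gene_id = as.character(tr@rnsCandidates), role = "rns"),
    data.frame(gene_id = attr(tr@rnsCandidates, "symbiosis_only"),
               role = "symbiosis_only"),
    data.frame(gene_id = attr(tr@rnsCandidates, "nodule_only"),
               role = "nodule_only"),
    data.frame(gene_id = tr@referenceGenes, role = "reference"),
    data.frame(gene_id = tr@unstableReferences, role = "unstable_reference"))
  utils::write.table(roles, p("truth", "expression_roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(expression)) {
    writeExpressionMatrix(expression$se, p("expression.tsv"))
    writeCtTable(expression$ct, p("ct.tsv"))
  }
  files <- list.files(dir, recursive = TRUE)
  manifest <- data.frame(file = files,
                         bytes = file.size(file.path(dir, files)))
  manifest <- manifest[manifest$file != "manifest.tsv", ]
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

.stageInputs <- list(
  census = c("proteins.faa", "domain_hits.tsv"),
  phylo = c("proteins.faa", "domain_hits.tsv", "family_ids.txt"),
  dup = c("genes.gff3", "cds.fna", "proteins.faa", "domain_hits.tsv",
          "family_ids.txt"),
  structure = c("genes.gff3"),
  expr = c("expression.tsv", "ct.tsv"))

#' Run the survey pipeline over a bundle directory
#'
#' Stages run in dependency order (census, phylogeny, duplication,
#' structure, expression); missing inputs for any requested stage abort the
#' run before any stage executes; identical bundle + configuration gives
#' byte-identical outputs.
#'
#' @param bundleDir directory holding the bundle files (see
#'   [writeBundle()]).
#' @param config a [SurveyConfig-class].
#' @param stages subset of c("census", "phylo", "dup", "structure", "expr").
#' @param outDir output directory, default \code{bundleDir}/results.
#' @return A [PipelineReport-class].
#' @export
runPipeline <- function(bundleDir, config = surveyConfig(),
                        stages = c("census", "phylo", "dup", "structure",
                                   "expr"),
                        outDir = file.path(bundleDir, "results")) {
  stages <- match.arg(stages, names(.stageInputs), several.ok = TRUE)
  stages <- names(.stageInputs)[names(.stageInputs) %in% stages]
  for (st in stages) {
    need <- file.path(bundleDir, .stageInputs[[st]])
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("missing input for stage '", st, "': ",
           paste(basename(miss), collapse = ", "))
  }
  if ("dup" %in% stages && !all(c("census", "phylo") %in% stages))
    stop("stage 'dup' requires stages 'census' and 'phylo'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rec <- list()
  note <- function(stage, records, output) {
    rec[[length(rec) + 1L]] <<- data.frame(stage = stage, status = "ok",
                                           records = records,
                                           output = output,
                                           stringsAsFactors = FALSE)
    message("[", stage, "] ", records, " records -> ", output)
  }
  census <- NULL; tree <- NULL; members <- NULL; pd <- NULL

  if ("census" %in% stages) {
    proteins <- readFasta(file.path(bundleDir, "proteins.faa"), "AA")
    hits <- readDomainHits(file.path(bundleDir, "domain_hits.tsv"))
    census <- callCensus(proteins, hits, config@truncationCoverageMin)
    out <- file.path(outDir, "census.tsv")
    utils::write.table(census, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("census", nrow(census), out)
  }
  if ("phylo" %in% stages) {
    proteins <- readFasta(file.path(bundleDir, "proteins.faa"), "AA")
    members <- if (!is.null(census))
      census$protein_id[census$status == "member"] else names(proteins)
    msa <- alignFamily(.asNamedChar(proteins)[members])
    pd <- pDistance(msa)
    tree <- bootstrapSupport(msa, config@bootstrapReplicates,
                             config@randomSeed)
    out <- file.path(outDir, "tree.nwk")
    writeNewick(tree, out)
    note("phylo", length(tree$tip.label), out)
  }
  if ("dup" %in% stages) {
    models <- readGff3(file.path(bundleDir, "genes.gff3"))
    cds <- readFasta(file.path(bundleDir, "cds.fna"), "DNA")
    famIds <- readLines(file.path(bundleDir, "family_ids.txt"))
    tc <- findTandemClusters(models, famIds, config@tandemMaxIntervening)
    outTc <- file.path(outDir, "tandem_clusters.tsv")
    utils::write.table(tc, outTc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ## Ka/Ks only for plausibly-homologous member pairs (p-distance <= 0.5);
    ## cross-family distances sit near saturation and are skipped
    cand <- which(pd <= 0.5 & upper.tri(pd), arr.ind = TRUE)
    pairs <- data.frame(gene_a = rownames(pd)[cand[, 1]],
                        gene_b = rownames(pd)[cand[, 2]],
                        stringsAsFactors = FALSE)
    ## equal-length pairs only: NG86 needs in-frame gap-free sequences
    len <- stats::setNames(nchar(as.character(cds)), names(cds))
    pairs <- pairs[len[pairs$gene_a] == len[pairs$gene_b], , drop = FALSE]
    ks <- pairKaKs(cds, pairs)
    outKs <- file.path(outDir, "ks_pairs.tsv")
    utils::write.table(ks, outKs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paraFile <- file.path(bundleDir, "paralogy.tsv")
    paralogy <- if (file.exists(paraFile))
      utils::read.delim(paraFile, stringsAsFactors = FALSE) else NULL
    seg <- identifySegmentPairs(models, intersect(famIds, members), ks,
                                tree, config, paralogy = paralogy)
    outSeg <- file.path(outDir, "segment_pairs.tsv")
    utils::write.table(seg, outSeg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSegmentPairTable(seg[seg$validated, , drop = FALSE],
                          file.path(outDir, "segment_pairs_table.tsv"),
                          config@clockRate)
    note("dup", nrow(seg), outSeg)
  }
  if ("structure" %in% stages) {
    models <- readGff3(file.path(bundleDir, "genes.gff3"))
    famFile <- file.path(bundleDir, "family_ids.txt")
    ids <- if (file.exists(famFile)) readLines(famFile)
           else names(models@genes)
    sub <- models@genes[names(models@genes) %in% ids]
    fam <- new("GeneModelSet", genes = sub,
               exons = models@exons[names(sub)],
               cds = models@cds[names(sub)],
               utr5 = models@utr5[names(sub)],
               utr3 = models@utr3[names(sub)])
    summ <- summarizeStructure(fam)
    out <- file.path(outDir, "structure.tsv")
    utils::write.table(summ, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("structure", nrow(summ), out)
  }
  if ("expr" %in% stages) {
    se <- readExpressionMatrix(file.path(bundleDir, "expression.tsv"))
    ct <- readCtTable(file.path(bundleDir, "ct.tsv"))
    hm <- heatmapMatrix(se)
    outHm <- file.path(outDir, "heatmap_matrix.tsv")
    writeExpressionMatrix(hm, outHm)
    refCands <- grep("^REF", unique(ct$gene_id), value = TRUE)
    targets <- setdiff(unique(ct$gene_id), refCands)
    baseline <- ct$sample_id[1]
    patterns <- NULL
    if (length(refCands) >= 2L) {
      stab <- genormStability(ct, refCands)
      utils::write.table(stab, file.path(outDir, "reference_stability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      refs <- stab$gene_id[1:2]
      patterns <- do.call(rbind, lapply(targets, function(g) {
        fc <- relativeExpression(ct, g, refs, baseline)
        cl <- classifyPattern(stats::setNames(fc$fold_change, fc$sample_id),
                              config@foldChangeThreshold)
        cbind(gene_id = g, cl)
      }))
      utils::write.table(patterns, file.path(outDir, "patterns.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    rns <- selectRnsCandidates(se, config@expressionHighQuantile)
    writeLines(rns, file.path(outDir, "rns_candidates.txt"))
    note("expr", length(targets), file.path(outDir, "patterns.tsv"))
  }
  new("PipelineReport", stages = do.call(rbind, rec),
      seed = config@randomSeed, outDir = outDir)
}

#' Recompute dating and selection from a printed divergence table
#'
#' Reads a segment-pair table carrying printed Ka/Ks (and optionally printed
#' omega and time) columns, recomputes the estimated divergence time
#' T = Ks/(2 lambda) x 1e-6 and omega = Ka/Ks per row, and reports
#' printed-vs-recomputed columns with the maximum absolute deviation
#' (attributes \code{max_dev_time} and \code{max_dev_omega}).
#'
#' @param path TSV with columns pair, ks and optionally ka, omega, time_mya;
#'   default is the packaged printed table.
#' @param config a [SurveyConfig-class] (clock rate).
#' @return data.frame with recomputed columns appended.
#' @export
#' @examples
#' chk <- checkTable1()
#' attr(chk, "max_dev_time")
checkTable1 <- function(path = NULL, config = surveyConfig()) {
  df <- if (is.null(path)) table1SegmentPairs()
        else utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- df
    attr(out, "max_dev_time") <- NA_real_
    attr(out, "max_dev_omega") <- NA_real_
    return(out)
  }
  if (!all(c("pair", "ks") %in% names(df)))
    stop("table must have columns 'pair' and 'ks'")
  bad <- which(is.na(df$ks) | !is.finite(df$ks))
  if (length(bad)) stop("malformed Ks in row ", bad[1])
  df$time_recomputed <- divergenceTime(df$ks, config@clockRate)
  df$omega_recomputed <- if (is.null(df$ka)) NA_real_
                         else round(df$ka / df$ks, 3)
  df$selection <- selectionClass(df$omega_recomputed)
  attr(df, "max_dev_time") <- if (is.null(df$time_mya)) NA_real_
    else max(abs(df$time_recomputed - df$time_mya), na.rm = TRUE)
  attr(df, "max_dev_omega") <- if (is.null(df$omega)) NA_real_
    else max(abs(round(df$omega_recomputed, 2) - df$omega), na.rm = TRUE)
  df
}
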