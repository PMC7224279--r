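# Writers for the pipeline's tabular and track outputs. Sequence formats go
# through Biostrings, GTF through rtracklayer; BED-style and TSV tables are
# plain tab-separated files.

#' Write a genome package to FASTA + GTF
#'
#' @param genome a [GenomePackage-class].
#' @param fasta,gtf output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
writeGenome <- function(genome, fasta = NULL, gtf = NULL) {
  if (!is.null(fasta))
    Biostrings::writeXStringSet(contigSeqs(genome), fasta)
  if (!is.null(gtf)) {
    ann <- geneAnnotation(genome)
    gr <- ann
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "circSponge",
      type = S4Vectors::mcols(ann)$feature,
      gene_id = S4Vectors::mcols(ann)$gene_id,
      transcript_id = paste0(S4Vectors::mcols(ann)$gene_id, ".t1"),
      exon_number = S4Vectors::mcols(ann)$exon_rank,
      phase = ifelse(S4Vectors::mcols(ann)$feature == "CDS", 0L,
                     NA_integer_))
    rtracklayer::export(gr, gtf, format = "gtf")
  }
  invisible(c(fasta = fasta, gtf = gtf))
}

#' Read a GTF annotation into the internal representation
#'
#' Accepts GTF/GFF with exon, CDS and UTR feature rows carrying `gene_id`.
#'
#' @param path GTF/GFF file.
#' @return annotation GRanges as used by [GenomePackage-class].
#' @export
readAnnotation <- function(path) {
  g <- rtracklayer::import(path)
  type <- as.character(S4Vectors::mcols(g)$type)
  map <- c(exon = "exon", CDS = "CDS", five_prime_utr = "five_prime_utr",
           three_prime_utr = "three_prime_utr", `5UTR` = "five_prime_utr",
           `3UTR` = "three_prime_utr")
  keep <- type %in% names(map)
  g <- g[keep]
  rank <- S4Vectors::mcols(g)$exon_number
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                IRanges::IRanges(GenomicRanges::start(g),
                                                 GenomicRanges::end(g)),
                                strand = BiocGenerics::strand(g))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = S4Vectors::mcols(g)$gene_id,
    feature = unname(map[type[keep]]),
    exon_rank = if (is.null(rank)) NA_integer_ else as.integer(rank))
  out
}

#' Write the truth set as a BED6+ table
#'
#' Columns: contig, start (0-based, BED convention), end, circ_id, score
#' (mean expected BSJ count), strand, class, blocks, per-sample abundances
#' (comma-separated).
#'
#' @param truths a [CircTruthSet-class].
#' @param path output TSV path.
#' @export
writeTruthBed <- function(truths, path) {
  gr <- junctions(truths)
  mc <- S4Vectors::mcols(gr)
  lam <- trueAbundance(truths)
  bl <- vapply(as.list(exonBlocks(truths)), function(b)
    paste(sprintf("%d-%d", IRanges::start(b), IRanges::end(b)),
          collapse = ","), "")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = mc$circ_id,
    score = round(rowMeans(lam), 3),
    strand = as.character(BiocGenerics::strand(gr)),
    class = mc$true_class,
    blocks = bl,
    abundances = apply(round(lam, 3), 1L, paste, collapse = ","))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write per-sample BSJ candidates as a BED6+ table
#'
#' @param candidates data.frame from [callSample()].
#' @param path output path.
#' @export
writeCandidates <- function(candidates, path) {
  df <- data.frame(
    contig = candidates$contig, start = candidates$start - 1L,
    end = candidates$end,
    name = circDisplay(candidates$contig, candidates$start, candidates$end),
    score = candidates$support, strand = candidates$strand,
    unique_support = candidates$unique_support,
    junction_phred = round(candidates$junction_phred, 2),
    splice_signal = candidates$splice_signal)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write a circRNA catalogue to disk
#'
#' Emits `catalog.tsv` (one row per circRNA with display coordinates, class,
#' host gene, exon count, spliced length, mean/SD CPM and per-sample CPM
#' columns), `hotspots.tsv`, `summary.json` and `catalog.bed` (BED12 with
#' exon blocks for exonic circles).
#'
#' @param catalog a [CircCatalog-class].
#' @param dir output directory.
#' @param min_isoforms hotspot threshold.
#' @return invisibly, the output directory.
#' @export
writeCatalog <- function(catalog, dir, min_isoforms = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- SummarizedExperiment::rowRanges(catalog)
  rd <- SummarizedExperiment::rowData(catalog)
  cpm <- circCpm(catalog)
  main <- data.frame(
    circ_id = rd$circ_id,
    coordinates = circDisplay(as.character(GenomicRanges::seqnames(gr)),
                              GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    class = rd$class, host_gene = rd$host_gene,
    n_exons = rd$n_exons, spliced_length = rd$spliced_length,
    mean_cpm = round(rd$mean_cpm, 4), sd_cpm = round(rd$sd_cpm, 4))
  main <- cbind(main, round(as.data.frame(cpm), 4))
  data.table::fwrite(main, file.path(dir, "catalog.tsv"), sep = "\t")
  data.table::fwrite(detectHotspots(catalog, min_isoforms),
                     file.path(dir, "hotspots.tsv"), sep = "\t")
  s <- summarizeCatalog(catalog)
  s$exon_count_table <- as.list(s$exon_count_table)
  jsonlite::write_json(s, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  # BED12 with exon blocks
  blocks <- strsplit(rd$blocks, ",", fixed = TRUE)
  bed <- lapply(seq_along(gr), function(i) {
    b <- do.call(rbind, lapply(strsplit(blocks[[i]], "-", fixed = TRUE),
                               as.integer))
    st <- GenomicRanges::start(gr)[i] - 1L
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[i],
               chromStart = st, chromEnd = GenomicRanges::end(gr)[i],
               name = rd$circ_id[i], score = 0L,
               strand = as.character(BiocGenerics::strand(gr))[i],
               thickStart = st, thickEnd = GenomicRanges::end(gr)[i],
               itemRgb = "0", blockCount = nrow(b),
               blockSizes = paste0(paste(b[, 2L] - b[, 1L] + 1L,
                                         collapse = ","), ","),
               blockStarts = paste0(paste(b[, 1L] - 1L - st,
                                          collapse = ","), ","))
  })
  data.table::fwrite(data.table::rbindlist(bed),
                     file.path(dir, "catalog.bed"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

#' Write the sponge network outputs
#'
#' Emits `edges.tsv` (all screened pairs with evidence columns),
#' `network.graphml` (final network, Cytoscape-importable) and, when
#' `targetHits` is given, `target_hits.tsv`.
#'
#' @param net a [SpongeNetwork-class].
#' @param dir output directory.
#' @param targetHits optional data.frame from [scanTargets()].
#' @export
writeNetwork <- function(net, dir, targetHits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(spongeEdges(net), file.path(dir, "edges.tsv"),
                     sep = "\t")
  g <- asSpongeGraph(net)
  igraph::write_graph(g, file.path(dir, "network.graphml"),
                      format = "graphml")
  if (!is.null(targetHits))
    data.table::fwrite(targetHits, file.path(dir, "target_hits.tsv"),
                       sep = "\t")
  invisible(dir)
}

#' Write association and age-test results
#'
#' @param assoc data.frame from [correlateAbundance()].
#' @param corrected residual matrix from [correctPhenotypes()].
#' @param ageTest list from [ageGroupTest()] (optional).
#' @param dir output directory.
#' @export
writeAssociations <- function(assoc, corrected, ageTest = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(assoc, file.path(dir, "associations.tsv"), sep = "\t")
  cr <- data.frame(sample_id = rownames(corrected),
                   as.data.frame(unclass(corrected)))
  data.table::fwrite(cr, file.path(dir, "corrected_phenotypes.tsv"),
                     sep = "\t")
  if (!is.null(ageTest))
    jsonlite::write_json(
      ageTest[c("p_count", "p_abundance", "n_young", "n_mature")],
      file.path(dir, "age_test.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
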