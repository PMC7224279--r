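#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges CompressedIRangesList
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

setOldClass("data.table")

#' GenomePackage: reference contigs plus exon-level annotation
#'
#' Container for a reference genome and its gene annotation. Contigs are a
#' [Biostrings::DNAStringSet]; the annotation is a [GenomicRanges::GRanges]
#' holding one row per (exon x feature) with metadata columns `gene_id`,
#' `feature` (one of `exon`, `CDS`, `five_prime_utr`, `three_prime_utr`) and
#' `exon_rank` (rank in transcription order, i.e. 5'->3' on the gene strand).
#'
#' Validity enforces: all annotated intervals lie within their contig; exon
#' intervals of a gene do not overlap each other; every CDS/UTR interval is
#' contained in an exon of the same gene.
#'
#' @slot contigs DNAStringSet of contig sequences.
#' @slot annotation GRanges of gene features (may be empty).
#' @export
setClass("GenomePackage",
  representation(contigs = "DNAStringSet", annotation = "GRanges"))

setValidity("GenomePackage", function(object) {
  ann <- object@annotation
  if (length(ann) == 0L) return(TRUE)
  need <- c("gene_id", "feature", "exon_rank")
  if (!all(need %in% names(S4Vectors::mcols(ann))))
    return(paste("annotation must carry mcols:", paste(need, collapse = ", ")))
  ok <- S4Vectors::mcols(ann)$feature %in%
    c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  if (!all(ok)) return("unknown feature type in annotation")
  cl <- as.character(GenomicRanges::seqnames(ann))
  if (!all(cl %in% names(object@contigs)))
    return("annotation on a contig absent from the genome")
  lens <- Biostrings::width(object@contigs)[match(cl, names(object@contigs))]
  if (any(GenomicRanges::start(ann) < 1L) || any(GenomicRanges::end(ann) > lens))
    return("annotated interval outside contig bounds")
  ex <- ann[S4Vectors::mcols(ann)$feature == "exon"]
  for (g in unique(S4Vectors::mcols(ex)$gene_id)) {
    gex <- ex[S4Vectors::mcols(ex)$gene_id == g]
    if (length(gex) > 1L &&
        !IRanges::isDisjoint(GenomicRanges::ranges(gex)))
      return(sprintf("overlapping exons within gene %s", g))
  }
  sub <- ann[S4Vectors::mcols(ann)$feature != "exon"]
  if (length(sub)) {
    hit <- GenomicRanges::findOverlaps(sub, ex, type = "within")
    same <- S4Vectors::mcols(sub)$gene_id[S4Vectors::queryHits(hit)] ==
      S4Vectors::mcols(ex)$gene_id[S4Vectors::subjectHits(hit)]
    if (!all(seq_along(sub) %in% S4Vectors::queryHits(hit)[same]))
      return("CDS/UTR interval not contained in an exon of its gene")
  }
  TRUE
})

#' CircTruthSet: planted circRNAs with ground truth
#'
#' Planted circle junctions (a GRanges; start = acceptor/first base, end =
#' donor/last base, strand = transcription strand) with metadata columns
#' `circ_id`, `true_class`, `host_gene`, `n_exons`, `spliced_length`; the
#' genomic exon blocks composing each circle; the per-sample expected BSJ read
#' count (true abundance) matrix; planted sponge pairs and phenotype effects.
#'
#' @slot junctions GRanges of planted back-splice junction spans.
#' @slot exonBlocks CompressedIRangesList, genomic blocks per circle.
#' @slot abundance matrix (circles x samples) of expected BSJ read counts.
#' @slot spongePairs data.frame with columns circ_id, mirna_id, site_pos
#'   (1-based position of the planted site in circle spliced coordinates).
#' @slot phenoEffects data.frame with columns circ_id, trait, coef.
#' @export
setClass("CircTruthSet",
  representation(junctions = "GRanges", exonBlocks = "CompressedIRangesList",
                 abundance = "matrix", spongePairs = "data.frame",
                 phenoEffects = "data.frame"))

setValidity("CircTruthSet", function(object) {
  n <- length(object@junctions)
  if (length(object@exonBlocks) != n) return("exonBlocks length mismatch")
  if (n && nrow(object@abundance) != n) return("abundance row mismatch")
  if (any(object@abundance < 0)) return("negative true abundance")
  ids <- S4Vectors::mcols(object@junctions)$circ_id
  if (n && !identical(rownames(object@abundance), ids))
    return("abundance rownames must equal circ_id")
  TRUE
})

#' CircCatalog: merged, quantified and classified circRNA set
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. Rows are
#' back-splice junctions (rowRanges span = acceptor..donor), columns are
#' samples. Assays: `counts` (BSJ-spanning read counts; 0 where undetected)
#' and `cpm` (counts per million raw reads). `colData$raw_total` holds the raw
#' sequenced read total used as the CPM denominator. rowData carries
#' `circ_id`, `class`, `host_gene`, `n_exons`, `spliced_length`, `mean_cpm`,
#' `sd_cpm` and `blocks` (comma-separated genomic exon blocks).
#'
#' @export
setClass("CircCatalog", contains = "RangedSummarizedExperiment")

setValidity("CircCatalog", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "cpm") %in% a))
    return("assays 'counts' and 'cpm' are required")
  if (!"raw_total" %in% names(SummarizedExperiment::colData(object)))
    return("colData must carry raw_total")
  tot <- SummarizedExperiment::colData(object)$raw_total
  if (any(!is.finite(tot)) || any(tot <= 0))
    return("raw_total must be positive and finite")
  cnt <- SummarizedExperiment::assay(object, "counts")
  cpm <- SummarizedExperiment::assay(object, "cpm")
  expect <- sweep(cnt, 2L, tot, "/") * 1e6
  if (nrow(cnt) && max(abs(cpm - expect)) > 1e-6)
    return("cpm assay inconsistent with counts / raw_total * 1e6")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("circ_id", "class", "host_gene", "n_exons", "spliced_length")
  if (!all(need %in% names(rd)))
    return(paste("rowData must carry:", paste(need, collapse = ", ")))
  bad <- rd$class == "intergenic" & !is.na(rd$host_gene)
  if (any(bad)) return("intergenic circRNAs must have no host gene")
  exonic <- rd$class %in% c("CDS", "5UTR", "3UTR")
  if (any(exonic & rd$n_exons < 1L))
    return("exonic circRNAs must have n_exons >= 1")
  if (any(!exonic & rd$n_exons != 0L))
    return("non-exonic circRNAs must have n_exons == 0")
  TRUE
})

#' GenomeIndex: exact k-mer lookup structure over the plus strand
#'
#' Maps every length-k substring of every contig to its positions. Minus-strand
#' occurrences are resolved at query time by looking up the reverse complement
#' of the query. Backs the anchor-alignment step of BSJ detection.
#'
#' @slot table data.table keyed by `kmer` with columns contig, pos (1-based
#'   start of the occurrence on the plus strand).
#' @slot anchorLength integer k.
#' @slot contigs DNAStringSet the index was built from.
#' @export
setClass("GenomeIndex",
  representation(table = "data.table", anchorLength = "integer",
                 contigs = "DNAStringSet"))

#' SpongeNetwork: circRNA-miRNA edges with PCIT and target-site evidence
#'
#' @slot edges data.frame over all circRNA x miRNA pairs retained for
#'   screening: circ_id, mirna_id, pearson_r, pcit_kept, n_sites,
#'   best_target_score, in_final_network.
#' @slot degrees data.frame of node degrees in the final network.
#' @export
setClass("SpongeNetwork",
  representation(edges = "data.frame", degrees = "data.frame"))

setValidity("SpongeNetwork", function(object) {
  e <- object@edges
  need <- c("circ_id", "mirna_id", "pearson_r", "pcit_kept", "n_sites",
            "in_final_network")
  if (!all(need %in% names(e)))
    return(paste("edges must carry:", paste(need, collapse = ", ")))
  bad <- e$in_final_network &
    !(e$pcit_kept & e$pearson_r < 0 & e$n_sites > 0)
  if (any(bad))
    return("final edges must be PCIT-kept, negative and target-supported")
  TRUE
})
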