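# circRNA catalogue: CPM normalisation against raw sequenced read totals,
# genomic classification against the annotation, and the CircCatalog
# container tying junctions, counts, CPM and classification together.

#' Normalize BSJ counts to counts per million raw reads
#'
#' CPM here is the number of BSJ-spanning reads per million raw sequenced
#' reads in the sample (not per million mapped or per million BSJ reads).
#'
#' @param counts junctions x samples count matrix.
#' @param raw_totals numeric vector of raw read totals, one per column (if
#'   named, matched to `colnames(counts)`).
#' @return matrix of the same shape: `counts / raw_total * 1e6`.
#' @examples
#' normalizeCpm(matrix(10, 1, 1), 5e6)  # 2 CPM
#' @export
normalizeCpm <- function(counts, raw_totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(raw_totals)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(raw_totals)))
      stop("raw total missing for sample(s): ",
           paste(setdiff(colnames(counts), names(raw_totals)),
                 collapse = ", "))
    raw_totals <- raw_totals[colnames(counts)]
  }
  if (length(raw_totals) != ncol(counts))
    stop("raw_totals length does not match the number of samples")
  bad <- !is.finite(raw_totals) | raw_totals <= 0
  if (any(bad))
    stop("zero or missing raw total for sample(s): ",
         paste((colnames(counts) %||% seq_len(ncol(counts)))[bad],
               collapse = ", "))
  sweep(counts, 2L, raw_totals, "/") * 1e6
}

#' Classify circRNA junction spans against a gene annotation
#'
#' A circle overlapping no gene is intergenic; overlapping a gene but no exon
#' is intronic; otherwise exonic, with the sub-class (CDS, 3UTR, 5UTR) given
#' by the feature type covering the largest share of the circle's exonic
#' overlap (ties broken CDS > 3UTR > 5UTR). The host gene is the gene with
#' the largest overlap (exonic bp for exonic circles, gene-body bp
#' otherwise; ties alphabetical). For exonic circles `n_exons` counts the
#' host exons whose boundaries fall inside the span and `spliced_length` sums
#' their widths; for the others the genomic span length is used.
#'
#' @param gr GRanges of junction spans (start = acceptor, end = donor).
#' @param annotation annotation GRanges as in [GenomePackage-class] (or a
#'   GenomePackage).
#' @return S4Vectors::DataFrame with columns class, host_gene, n_exons,
#'   spliced_length, blocks (comma-separated genomic exon blocks).
#' @export
classifyCircRNAs <- function(gr, annotation) {
  if (methods::is(annotation, "GenomePackage"))
    annotation <- geneAnnotation(annotation)
  n <- length(gr)
  cls <- rep("intergenic", n)
  host <- rep(NA_character_, n)
  nEx <- integer(n)
  spl <- GenomicRanges::width(gr)
  blocks <- sprintf("%d-%d", GenomicRanges::start(gr),
                    GenomicRanges::end(gr))
  if (n == 0L)
    return(S4Vectors::DataFrame(class = character(0),
                                host_gene = character(0),
                                n_exons = integer(0),
                                spliced_length = integer(0),
                                blocks = character(0)))
  if (length(annotation)) {
    ex <- annotation[S4Vectors::mcols(annotation)$feature == "exon"]
    exg <- S4Vectors::mcols(ex)$gene_id
    bodies <- BiocGenerics::unlist(range(GenomicRanges::split(ex, exg)))
    sub <- annotation[S4Vectors::mcols(annotation)$feature != "exon"]
    subg <- S4Vectors::mcols(sub)$gene_id
    subf <- S4Vectors::mcols(sub)$feature
    featMap <- c(CDS = "CDS", three_prime_utr = "3UTR",
                 five_prime_utr = "5UTR")
    # strand-agnostic span overlap (co-location, as with interval tools)
    grU <- gr; BiocGenerics::strand(grU) <- "*"
    exU <- ex; BiocGenerics::strand(exU) <- "*"
    bodU <- bodies; BiocGenerics::strand(bodU) <- "*"
    subU <- sub; BiocGenerics::strand(subU) <- "*"
    ovB <- GenomicRanges::findOverlaps(grU, bodU)
    ovE <- GenomicRanges::findOverlaps(grU, exU)
    for (i in seq_len(n)) {
      gHit <- S4Vectors::subjectHits(ovB)[S4Vectors::queryHits(ovB) == i]
      if (!length(gHit)) next               # intergenic
      eHit <- S4Vectors::subjectHits(ovE)[S4Vectors::queryHits(ovE) == i]
      span <- grU[i]
      if (!length(eHit)) {                  # intronic
        cls[i] <- "intronic"
        w <- vapply(gHit, function(j) sum(GenomicRanges::width(
          GenomicRanges::pintersect(bodU[j], span))), 0)
        cand <- names(bodies)[gHit]
        host[i] <- sort(cand[w == max(w)])[1L]
        next
      }
      # exonic: host = gene with largest exonic overlap
      ew <- GenomicRanges::width(GenomicRanges::pintersect(
        exU[eHit], rep(span, length(eHit))))
      wByGene <- tapply(ew, exg[eHit], sum)
      hg <- sort(names(wByGene)[wByGene == max(wByGene)])[1L]
      host[i] <- hg
      # sub-class by feature share within the circle's exonic overlap
      sHit <- which(subg == hg)
      fw <- c(CDS = 0, `3UTR` = 0, `5UTR` = 0)
      if (length(sHit)) {
        iw <- GenomicRanges::width(GenomicRanges::pintersect(
          subU[sHit], rep(span, length(sHit))))
        agg <- tapply(iw, featMap[subf[sHit]], sum)
        fw[names(agg)] <- agg
      }
      cls[i] <- if (all(fw == 0)) "CDS"
        else names(fw)[which.max(fw)]       # order CDS, 3UTR, 5UTR = tie rule
      # exon structure from the host gene's annotated exons inside the span
      hostEx <- exU[intersect(which(exg == hg), eHit)]
      inside <- GenomicRanges::start(hostEx) >= GenomicRanges::start(span) &
        GenomicRanges::end(hostEx) <= GenomicRanges::end(span)
      use <- if (any(inside)) hostEx[inside] else hostEx
      o <- order(GenomicRanges::start(use))
      use <- use[o]
      nEx[i] <- length(use)
      spl[i] <- if (any(inside)) sum(GenomicRanges::width(use))
        else sum(GenomicRanges::width(GenomicRanges::pintersect(
          use, rep(span, length(use)))))
      blocks[i] <- paste(sprintf("%d-%d",
                                 pmax(GenomicRanges::start(use),
                                      GenomicRanges::start(span)),
                                 pmin(GenomicRanges::end(use),
                                      GenomicRanges::end(span))),
                         collapse = ",")
    }
  }
  S4Vectors::DataFrame(class = cls, host_gene = host, n_exons = nEx,
                       spliced_length = as.integer(spl), blocks = blocks)
}

#' Assemble a quantified, classified circRNA catalogue
#'
#' @param junctions GRanges of merged junctions (from [mergeSamples()]).
#' @param counts junctions x samples BSJ count matrix.
#' @param raw_totals per-sample raw read totals (CPM denominator).
#' @param annotation annotation GRanges or [GenomePackage-class].
#' @return a [CircCatalog-class]. Mean and SD CPM are computed over all
#'   samples, counting undetected samples as 0.
#' @export
circCatalog <- function(junctions, counts, raw_totals, annotation) {
  stopifnot(methods::is(junctions, "GRanges"),
            length(junctions) == nrow(counts))
  if (!is.null(names(raw_totals)) && !is.null(colnames(counts)))
    raw_totals <- raw_totals[colnames(counts)]
  cpm <- normalizeCpm(counts, raw_totals)
  cl <- classifyCircRNAs(junctions, annotation)
  ids <- sprintf("circ_%04d", seq_along(junctions))
  rd <- S4Vectors::DataFrame(circ_id = ids, cl,
                             mean_cpm = rowMeans(cpm),
                             sd_cpm = apply(cpm, 1L, sd))
  rr <- junctions
  S4Vectors::mcols(rr) <- rd
  names(rr) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts), cpm = cpm),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(raw_total = as.numeric(raw_totals),
                                   row.names = colnames(counts)))
  methods::new("CircCatalog", se)
}
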