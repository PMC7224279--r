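# Catalogue reporting: hotspot host genes, class/exon/length summaries and
# same-assembly catalogue overlap.

#' Detect circRNA hotspot genes
#'
#' A hotspot is a host gene producing at least `min_isoforms` distinct exonic
#' circRNAs (distinct junction pairs).
#'
#' @param catalog a [CircCatalog-class].
#' @param min_isoforms hotspot threshold (default 5).
#' @return data.frame with columns gene_id, n_isoforms, hotspot, sorted by
#'   decreasing isoform count.
#' @export
detectHotspots <- function(catalog, min_isoforms = 5L) {
  rd <- SummarizedExperiment::rowData(catalog)
  exonic <- rd$class %in% c("CDS", "5UTR", "3UTR") & !is.na(rd$host_gene)
  if (!any(exonic))
    return(data.frame(gene_id = character(0), n_isoforms = integer(0),
                      hotspot = logical(0)))
  cnt <- table(rd$host_gene[exonic])
  out <- data.frame(gene_id = names(cnt), n_isoforms = as.integer(cnt),
                    row.names = NULL)
  out <- out[order(-out$n_isoforms, out$gene_id), , drop = FALSE]
  out$hotspot <- out$n_isoforms >= min_isoforms
  rownames(out) <- NULL
  out
}

#' Summarize a circRNA catalogue
#'
#' @param catalog a [CircCatalog-class].
#' @param top_n how many top circRNAs (by mean CPM, ties broken by
#'   coordinate order) to report.
#' @param short_length length threshold for the short-circle share (the
#'   fraction of exonic circRNAs with spliced length below it).
#' @return list with `n_circ`, `class_fractions` (named over the five
#'   classes, summing to 1), `exon_count_table`, `frac_exonic_short`,
#'   `cpm_range`, and `top` (data.frame of the top-N entries).
#' @export
summarizeCatalog <- function(catalog, top_n = 15L, short_length = 400L) {
  rd <- SummarizedExperiment::rowData(catalog)
  classes <- c("CDS", "5UTR", "3UTR", "intronic", "intergenic")
  n <- nrow(catalog)
  frac <- setNames(numeric(5L), classes)
  if (n > 0L) {
    tab <- table(factor(rd$class, levels = classes))
    frac <- as.numeric(tab) / n
    names(frac) <- classes
  }
  exonic <- rd$class %in% c("CDS", "5UTR", "3UTR")
  exTab <- if (any(exonic)) table(rd$n_exons[exonic]) else table(integer(0))
  short <- if (any(exonic))
    mean(rd$spliced_length[exonic] < short_length) else NA_real_
  gr <- SummarizedExperiment::rowRanges(catalog)
  o <- order(-rd$mean_cpm, as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  top <- head(o, top_n)
  topDf <- data.frame(
    circ_id = rd$circ_id[top],
    coordinates = circDisplay(as.character(GenomicRanges::seqnames(gr))[top],
                              GenomicRanges::start(gr)[top],
                              GenomicRanges::end(gr)[top]),
    strand = as.character(BiocGenerics::strand(gr))[top],
    class = rd$class[top], host_gene = rd$host_gene[top],
    mean_cpm = rd$mean_cpm[top], sd_cpm = rd$sd_cpm[top],
    row.names = NULL)
  cpmMeans <- if (n > 0L) rd$mean_cpm else numeric(0)
  list(n_circ = n, class_fractions = frac,
       exon_count_table = exTab, frac_exonic_short = short,
       cpm_range = if (n > 0L) range(cpmMeans) else c(NA_real_, NA_real_),
       top = topDf)
}

#' Compare two circRNA catalogues on a shared assembly
#'
#' Junctions match iff contig and strand agree and both boundary coordinates
#' lie within `boundary_tolerance_nt`. Catalogues must already be on the same
#' assembly; coordinate systems from different assemblies are not detectable
#' and are the caller's responsibility.
#'
#' @param a,b [CircCatalog-class] objects or junction GRanges.
#' @param boundary_tolerance_nt maximum per-boundary shift (default 0).
#' @return list with `frac_a_in_b` (|A intersect B| / |A|), `frac_b_in_a`,
#'   and `n_matched` (matched entries of A).
#' @export
compareCatalogs <- function(a, b, boundary_tolerance_nt = 0L) {
  asGr <- function(x) if (methods::is(x, "CircCatalog"))
    SummarizedExperiment::rowRanges(x) else x
  ga <- asGr(a); gb <- asGr(b)
  if (length(ga) == 0L || length(gb) == 0L)
    return(list(frac_a_in_b = 0, frac_b_in_a = 0, n_matched = 0L))
  tol <- boundary_tolerance_nt
  da <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    s = GenomicRanges::start(ga), e = GenomicRanges::end(ga), ia = seq_along(ga))
  db <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(gb)),
    strand = as.character(BiocGenerics::strand(gb)),
    s = GenomicRanges::start(gb), e = GenomicRanges::end(gb), ib = seq_along(gb))
  m <- merge(da, db, by = c("contig", "strand"), allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  m <- m[abs(m$s_a - m$s_b) <= tol & abs(m$e_a - m$e_b) <= tol, ]
  list(frac_a_in_b = length(unique(m$ia)) / length(ga),
       frac_b_in_a = length(unique(m$ib)) / length(gb),
       n_matched = length(unique(m$ia)))
}
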