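#' @name circSponge-accessors
#' @title Accessors for circSponge classes
#' @description Slot accessors for [GenomePackage-class], [CircTruthSet-class],
#'   [CircCatalog-class] and [SpongeNetwork-class] objects.
#' @param x an object of the documented class.
#' @return the slot contents (see the individual generics).
NULL

#' @rdname circSponge-accessors
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
#' @rdname circSponge-accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @rdname circSponge-accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname circSponge-accessors
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))
#' @rdname circSponge-accessors
#' @export
setGeneric("spongePairs", function(x) standardGeneric("spongePairs"))
#' @rdname circSponge-accessors
#' @export
setGeneric("phenoEffects", function(x) standardGeneric("phenoEffects"))
#' @rdname circSponge-accessors
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))
#' @rdname circSponge-accessors
#' @export
setGeneric("circCpm", function(x) standardGeneric("circCpm"))
#' @rdname circSponge-accessors
#' @export
setGeneric("circCounts", function(x) standardGeneric("circCounts"))
#' @rdname circSponge-accessors
#' @export
setGeneric("circClass", function(x) standardGeneric("circClass"))
#' @rdname circSponge-accessors
#' @export
setGeneric("hostGene", function(x) standardGeneric("hostGene"))
#' @rdname circSponge-accessors
#' @export
setGeneric("rawTotals", function(x) standardGeneric("rawTotals"))
#' @rdname circSponge-accessors
#' @export
setGeneric("spongeEdges", function(x) standardGeneric("spongeEdges"))
#' @rdname circSponge-accessors
#' @export
setGeneric("finalNetwork", function(x) standardGeneric("finalNetwork"))
#' @rdname circSponge-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname circSponge-accessors
setMethod("contigSeqs", "GenomePackage", function(x) x@contigs)
#' @rdname circSponge-accessors
setMethod("geneAnnotation", "GenomePackage", function(x) x@annotation)
#' @rdname circSponge-accessors
setMethod("junctions", "CircTruthSet", function(x) x@junctions)
#' @rdname circSponge-accessors
setMethod("trueAbundance", "CircTruthSet", function(x) x@abundance)
#' @rdname circSponge-accessors
setMethod("spongePairs", "CircTruthSet", function(x) x@spongePairs)
#' @rdname circSponge-accessors
setMethod("phenoEffects", "CircTruthSet", function(x) x@phenoEffects)
#' @rdname circSponge-accessors
setMethod("exonBlocks", "CircTruthSet", function(x) x@exonBlocks)
#' @rdname circSponge-accessors
setMethod("junctions", "CircCatalog",
  function(x) SummarizedExperiment::rowRanges(x))
#' @rdname circSponge-accessors
setMethod("circCpm", "CircCatalog",
  function(x) SummarizedExperiment::assay(x, "cpm"))
#' @rdname circSponge-accessors
setMethod("circCounts", "CircCatalog",
  function(x) SummarizedExperiment::assay(x, "counts"))
#' @rdname circSponge-accessors
setMethod("circClass", "CircCatalog",
  function(x) SummarizedExperiment::rowData(x)$class)
#' @rdname circSponge-accessors
setMethod("hostGene", "CircCatalog",
  function(x) SummarizedExperiment::rowData(x)$host_gene)
#' @rdname circSponge-accessors
setMethod("rawTotals", "CircCatalog",
  function(x) setNames(SummarizedExperiment::colData(x)$raw_total,
                       colnames(x)))
#' @rdname circSponge-accessors
setMethod("spongeEdges", "SpongeNetwork", function(x) x@edges)
#' @rdname circSponge-accessors
setMethod("finalNetwork", "SpongeNetwork",
  function(x) x@edges[x@edges$in_final_network, , drop = FALSE])
#' @rdname circSponge-accessors
setMethod("nodeDegrees", "SpongeNetwork", function(x) x@degrees)

setMethod("show", "GenomePackage", function(object) {
  ann <- object@annotation
  ng <- if (length(ann)) length(unique(S4Vectors::mcols(ann)$gene_id)) else 0L
  cat("GenomePackage:", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp total;",
      ng, "gene(s)\n")
})

setMethod("show", "CircTruthSet", function(object) {
  cl <- table(S4Vectors::mcols(object@junctions)$true_class)
  cat("CircTruthSet:", length(object@junctions), "planted circRNA(s) over",
      ncol(object@abundance), "sample(s)\n")
  if (length(cl))
    cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  cat("  sponge pairs:", nrow(object@spongePairs),
      "| phenotype effects:", nrow(object@phenoEffects), "\n")
})

setMethod("show", "CircCatalog", function(object) {
  cat("CircCatalog:", nrow(object), "circRNA(s) x", ncol(object),
      "sample(s)\n")
  cl <- table(circClass(object))
  if (length(cl))
    cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  callNextMethod()
})

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex: k =", object@anchorLength, "over",
      length(object@contigs), "contig(s),", nrow(object@table), "k-mers\n")
})

setMethod("show", "SpongeNetwork", function(object) {
  cat("SpongeNetwork:", nrow(object@edges), "screened pair(s);",
      sum(object@edges$in_final_network), "in final network\n")
})
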