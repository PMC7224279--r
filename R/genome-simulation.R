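# Toy genome generator: random contigs carrying multi-exon gene models with
# canonical splice dinucleotides written at every intron boundary (GT..AG on
# the plus strand of '+' genes, CT..AC for '-' genes, i.e. GT..AG read on the
# transcribed strand either way).

#' Generate a toy reference genome with exon-level annotation
#'
#' Places `n_genes` gene models across random contigs, separated by intergenic
#' gaps. Each gene has 5'UTR / CDS / 3'UTR exon structure in transcription
#' order (the two outermost exons at each end are UTR, internal exons CDS) and
#' canonical splice dinucleotides at every intron boundary on its strand.
#'
#' @param config a [simConfig()] object.
#' @return a [GenomePackage-class].
#' @examples
#' gp <- generateGenome(simConfig(seed = 1, n_contigs = 2,
#'                                contig_length = 20000, n_genes = 4))
#' gp
#' @export
generateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withStageSeed(config$seed, 101L, {
    ncon <- config$n_contigs
    clen <- config$contig_length
    contigs <- vapply(seq_len(ncon), function(i) randomDna(clen), "")
    names(contigs) <- paste0("chr", seq_len(ncon))

    rows <- list()
    if (config$n_genes > 0L) {
      geneContig <- rep(seq_len(ncon), length.out = config$n_genes)
      cursor <- rep(0L, ncon)
      for (gi in seq_len(config$n_genes)) {
        ci <- geneContig[gi]
        gap <- sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L)
        nex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
        ew <- sample(config$exon_length[1]:config$exon_length[2], nex,
                     replace = TRUE)
        iw <- if (nex > 1L)
          sample(config$intron_length[1]:config$intron_length[2], nex - 1L,
                 replace = TRUE) else integer(0)
        strand <- sample(c("+", "-"), 1L)
        gstart <- cursor[ci] + gap + 1L
        glen <- sum(ew) + sum(iw)
        if (gstart + glen - 1L > clen - 100L)
          stop(sprintf(
            "contig length %d too small to place gene %d on chr%d",
            clen, gi, ci))
        starts <- gstart + cumsum(c(0L, head(ew, -1L) + iw))
        ends <- starts + ew - 1L
        cursor[ci] <- ends[nex]

        # splice dinucleotides at intron boundaries
        if (nex > 1L) {
          don <- if (strand == "+") "GT" else "CT"  # first two intron bases
          acc <- if (strand == "+") "AG" else "AC"  # last two intron bases
          for (k in seq_len(nex - 1L)) {
            is0 <- ends[k] + 1L; ie0 <- starts[k + 1L] - 1L
            substr(contigs[ci], is0, is0 + 1L) <- don
            substr(contigs[ci], ie0 - 1L, ie0) <- acc
          }
        }

        rank <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
        feat <- ifelse(rank <= 2L, "five_prime_utr",
                       ifelse(rank >= nex - 1L, "three_prime_utr", "CDS"))
        gid <- sprintf("gene%03d", gi)
        rows[[gi]] <- data.frame(
          contig = names(contigs)[ci],
          start = c(starts, starts), end = c(ends, ends),
          strand = strand, gene_id = gid,
          feature = c(rep("exon", nex), feat),
          exon_rank = c(rank, rank))
      }
    }

    ann <- if (length(rows)) {
      df <- do.call(rbind, rows)
      GenomicRanges::GRanges(df$contig,
                             IRanges::IRanges(df$start, df$end),
                             strand = df$strand,
                             gene_id = df$gene_id, feature = df$feature,
                             exon_rank = df$exon_rank)
    } else {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = character(0), feature = character(0),
        exon_rank = integer(0))
      gr
    }
    dna <- Biostrings::DNAStringSet(contigs)
    GenomeInfoDb::seqlevels(ann) <- names(contigs)
    methods::new("GenomePackage", contigs = dna, annotation = ann)
  })
}

# exon rows of the annotation as a GRanges, optionally for one gene
exonRows <- function(annotation, gene = NULL) {
  ex <- annotation[S4Vectors::mcols(annotation)$feature == "exon"]
  if (!is.null(gene)) ex <- ex[S4Vectors::mcols(ex)$gene_id == gene]
  ex
}
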