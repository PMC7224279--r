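# Planting of ground-truth circRNAs. Exonic circles reuse annotated internal
# exons (so their back-splice flanks are the canonical splice signals already
# written at the host introns); intronic and intergenic circles get synthetic
# AG..GT flanks written into the contig sequence on their strand so they stay
# detectable under the canonical-splice requirement.

#' Plant ground-truth circRNAs into a toy genome
#'
#' Plants the per-class circle counts requested in `config$n_circ`:
#' \itemize{
#'   \item CDS: 1-10 consecutive CDS exons of one gene;
#'   \item 5UTR / 3UTR: one internal UTR exon of a gene;
#'   \item intronic: an interval wholly inside one intron (synthetic flanks);
#'   \item intergenic: an interval in a gene-free gap (synthetic flanks).
#' }
#' Per-sample true abundances (expected BSJ read counts) are drawn log-normal
#' per circle with per-sample fluctuation, clamped at
#' `config$abundance_floor`. A subset of exonic circles receives phenotype
#' effects (used later by [simulatePhenotypes()]).
#'
#' @param genome a [GenomePackage-class] from [generateGenome()].
#' @param config the [simConfig()] used to generate it.
#' @return list with elements `truths` (a [CircTruthSet-class]) and `genome`
#'   (the genome, with synthetic splice flanks written for intronic and
#'   intergenic circles).
#' @export
plantCircRNAs <- function(genome, config) {
  stopifnot(methods::is(genome, "GenomePackage"),
            inherits(config, "SimConfig"))
  nc <- config$n_circ
  ann <- geneAnnotation(genome)
  if (sum(nc[c("CDS", "5UTR", "3UTR", "intronic")]) > 0L && length(ann) == 0L)
    stop("genome has no genes but exonic/intronic circles were requested")

  withStageSeed(config$seed, 202L, {
    contigs <- as.character(contigSeqs(genome))
    ex <- exonRows(ann)
    geneIds <- unique(S4Vectors::mcols(ex)$gene_id)
    geneInfo <- lapply(geneIds, function(g) {
      gex <- ex[S4Vectors::mcols(ex)$gene_id == g]
      o <- order(GenomicRanges::start(gex))
      gex <- gex[o]
      list(gene = g,
           contig = as.character(GenomicRanges::seqnames(gex))[1],
           strand = as.character(BiocGenerics::strand(gex))[1],
           starts = GenomicRanges::start(gex),
           ends = GenomicRanges::end(gex),
           ranks = S4Vectors::mcols(gex)$exon_rank)
    })
    names(geneInfo) <- geneIds

    recs <- list()   # one record per circle
    addRec <- function(contig, strand, blocksStart, blocksEnd, class, host) {
      recs[[length(recs) + 1L]] <<- list(
        contig = contig, strand = strand,
        bstart = blocksStart, bend = blocksEnd, class = class, host = host)
    }

    # --- exonic circles: enumerate candidate exon runs -----------------
    exonPool <- function(class) {
      out <- list()
      for (gi in geneInfo) {
        nex <- length(gi$ranks)
        # genomic index by transcription rank
        byRank <- order(gi$ranks)      # byRank[r] = genomic index of rank r
        if (class == "CDS") {
          cdsRanks <- which(seq_len(nex) > 2L & seq_len(nex) < nex - 1L)
          if (!length(cdsRanks)) next
          for (len in seq_len(min(10L, length(cdsRanks))))
            for (rs in cdsRanks[seq_len(length(cdsRanks) - len + 1L)])
              out[[length(out) + 1L]] <-
                list(gene = gi$gene, ranks = rs:(rs + len - 1L))
        } else {
          r <- if (class == "5UTR") 2L else nex - 1L
          out[[length(out) + 1L]] <- list(gene = gi$gene, ranks = r)
        }
      }
      out
    }
    for (class in c("CDS", "5UTR", "3UTR")) {
      want <- nc[[class]]
      if (want == 0L) next
      pool <- exonPool(class)
      if (length(pool) < want)
        stop(sprintf("not enough eligible loci to place %d circles of class %s",
                     want, class))
      pick <- sample.int(length(pool), want)
      for (p in pool[pick]) {
        gi <- geneInfo[[p$gene]]
        idx <- sort(match(p$ranks, gi$ranks))
        addRec(gi$contig, gi$strand, gi$starts[idx], gi$ends[idx],
               class, p$gene)
      }
    }

    # --- intronic circles ----------------------------------------------
    margin <- 8L
    minLen <- max(100L, config$read_length + 25L)
    if (nc[["intronic"]] > 0L) {
      pool <- list()
      for (gi in geneInfo) {
        nex <- length(gi$starts)
        if (nex < 2L) next
        for (k in seq_len(nex - 1L)) {
          is0 <- gi$ends[k] + 1L; ie0 <- gi$starts[k + 1L] - 1L
          if (ie0 - is0 + 1L >= minLen + 2L * margin + 10L)
            pool[[length(pool) + 1L]] <-
              list(contig = gi$contig, strand = gi$strand,
                   lo = is0, hi = ie0, host = gi$gene)
        }
      }
      if (length(pool) < nc[["intronic"]])
        stop(sprintf("not enough eligible loci to place %d circles of class intronic",
                     nc[["intronic"]]))
      for (p in pool[sample.int(length(pool), nc[["intronic"]])]) {
        w <- p$hi - p$lo + 1L
        len <- sample(minLen:min(400L, w - 2L * margin), 1L)
        cs <- p$lo + margin
        ce <- cs + len - 1L
        flank <- writeCircFlanks(contigs[[p$contig]], cs, ce, p$strand)
        contigs[[p$contig]] <- flank
        addRec(p$contig, p$strand, cs, ce, "intronic", p$host)
      }
    }

    # --- intergenic circles --------------------------------------------
    if (nc[["intergenic"]] > 0L) {
      gaps <- list()
      gmargin <- 60L
      for (cn in names(contigs)) {
        clen <- nchar(contigs[[cn]])
        onC <- Filter(function(gi) gi$contig == cn, geneInfo)
        occ <- if (length(onC))
          IRanges::reduce(IRanges::IRanges(
            vapply(onC, function(gi) min(gi$starts), 0L),
            vapply(onC, function(gi) max(gi$ends), 0L)))
        else IRanges::IRanges()
        free <- IRanges::gaps(occ, start = 1L, end = clen)
        for (j in seq_along(free)) {
          lo <- IRanges::start(free)[j] + gmargin
          hi <- IRanges::end(free)[j] - gmargin
          if (hi - lo + 1L >= minLen + 2L * margin + 10L)
            gaps[[length(gaps) + 1L]] <- list(contig = cn, lo = lo, hi = hi)
        }
      }
      if (length(gaps) < nc[["intergenic"]])
        stop(sprintf("not enough eligible loci to place %d circles of class intergenic",
                     nc[["intergenic"]]))
      for (p in gaps[sample.int(length(gaps), nc[["intergenic"]])]) {
        len <- sample(minLen:min(400L, p$hi - p$lo + 1L - 2L * margin), 1L)
        cs <- p$lo + margin
        ce <- cs + len - 1L
        strand <- sample(c("+", "-"), 1L)
        contigs[[p$contig]] <- writeCircFlanks(contigs[[p$contig]], cs, ce,
                                               strand)
        addRec(p$contig, strand, cs, ce, "intergenic", NA_character_)
      }
    }

    # --- assemble truth object -----------------------------------------
    n <- length(recs)
    ids <- sprintf("circ_%04d", seq_len(n))
    gr <- if (n) GenomicRanges::GRanges(
      vapply(recs, `[[`, "", "contig"),
      IRanges::IRanges(vapply(recs, function(r) min(r$bstart), 0L),
                       vapply(recs, function(r) max(r$bend), 0L)),
      strand = vapply(recs, `[[`, "", "strand"))
    else GenomicRanges::GRanges()
    blocks <- IRanges::IRangesList(lapply(recs, function(r)
      IRanges::IRanges(r$bstart, r$bend)))
    classes <- vapply(recs, `[[`, "", "class")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      circ_id = ids,
      true_class = classes,
      host_gene = vapply(recs, `[[`, "", "host"),
      n_exons = ifelse(classes %in% c("CDS", "5UTR", "3UTR"),
                       lengths(blocks), 0L),
      spliced_length = vapply(blocks, function(b) sum(IRanges::width(b)), 0L))

    # per-sample expected BSJ read counts
    ns <- config$n_samples
    base <- rnorm(n, config$circ_meanlog, config$circ_sdlog)
    lam <- exp(base + matrix(rnorm(n * ns, 0, config$sample_sdlog), n, ns))
    lam <- pmax(lam, config$abundance_floor)
    dimnames(lam) <- list(ids, sampleIds(config))
    if (n == 0L) lam <- matrix(0, 0L, ns,
                               dimnames = list(NULL, sampleIds(config)))

    # phenotype effects on a subset of exonic circles
    exonicIds <- ids[classes %in% c("CDS", "5UTR", "3UTR")]
    ncausal <- min(config$n_causal_circ, length(exonicIds))
    eff <- if (ncausal > 0L) {
      pick <- sample(exonicIds, ncausal)
      data.frame(circ_id = pick,
                 trait = rep(c("motile_pct", "vcl", "vsl", "vap"),
                             length.out = ncausal),
                 coef = rep(config$pheno_effect_size, ncausal))
    } else data.frame(circ_id = character(0), trait = character(0),
                      coef = numeric(0))

    newGenome <- methods::new("GenomePackage",
                              contigs = Biostrings::DNAStringSet(contigs),
                              annotation = ann)
    truths <- methods::new("CircTruthSet", junctions = gr,
                           exonBlocks = methods::as(blocks,
                                                    "CompressedIRangesList"),
                           abundance = lam,
                           spongePairs = data.frame(
                             circ_id = character(0), mirna_id = character(0),
                             site_pos = integer(0)),
                           phenoEffects = eff)
    list(truths = truths, genome = newGenome)
  })
}

# write synthetic back-splice flanks around [cs, ce]: on the transcribed
# strand an AG must precede the acceptor and a GT follow the donor
writeCircFlanks <- function(seq, cs, ce, strand) {
  if (strand == "+") {
    substr(seq, cs - 2L, cs - 1L) <- "AG"
    substr(seq, ce + 1L, ce + 2L) <- "GT"
  } else {
    substr(seq, cs - 2L, cs - 1L) <- "AC"
    substr(seq, ce + 1L, ce + 2L) <- "CT"
  }
  seq
}

#' Spliced circle sequences in transcript orientation
#'
#' Concatenates the genomic exon blocks of every circle and reverse
#' complements the result for minus-strand circles, yielding the circular
#' (spliced) sequence read 5'->3' on the transcribed strand, starting at the
#' back-splice acceptor.
#'
#' @param truths a [CircTruthSet-class], a [CircCatalog-class] (blocks taken
#'   from its classification), or a GRanges (blocks via `blocks`, else the
#'   whole span).
#' @param genome the matching [GenomePackage-class].
#' @param blocks optional IRangesList of genomic blocks overriding the
#'   object's own.
#' @return a named [Biostrings::DNAStringSet].
#' @export
circSequences <- function(truths, genome, blocks = NULL) {
  gr <- if (methods::is(truths, "CircTruthSet")) junctions(truths)
    else if (methods::is(truths, "CircCatalog"))
      SummarizedExperiment::rowRanges(truths)
    else truths
  if (is.null(blocks)) {
    blocks <- if (methods::is(truths, "CircTruthSet")) exonBlocks(truths)
      else if (methods::is(truths, "CircCatalog")) {
        bl <- strsplit(SummarizedExperiment::rowData(truths)$blocks, ",",
                       fixed = TRUE)
        IRanges::IRangesList(lapply(bl, function(b) {
          m <- do.call(rbind, lapply(strsplit(b, "-", fixed = TRUE),
                                     as.integer))
          IRanges::IRanges(m[, 1L], m[, 2L])
        }))
      }
      else IRanges::IRangesList(lapply(seq_along(gr), function(i)
        IRanges::IRanges(GenomicRanges::start(gr)[i],
                         GenomicRanges::end(gr)[i])))
  }
  contigs <- as.character(contigSeqs(genome))
  seqs <- vapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    cn <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- paste(substring(contigs[[cn]], IRanges::start(b), IRanges::end(b)),
               collapse = "")
    if (as.character(BiocGenerics::strand(gr))[i] == "-") revcompChr(s) else s
  }, "")
  names(seqs) <- S4Vectors::mcols(gr)$circ_id %||% as.character(seq_along(gr))
  Biostrings::DNAStringSet(seqs)
}
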