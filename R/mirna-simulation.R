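# miRNA simulator: random 20-24 nt sequences, planted sponge sites written
# into the sponging circle's exonic sequence, and per-sample profiles whose
# log2 abundance is negatively coupled to the summed log2 abundance of the
# sponging circles.

#' Simulate miRNA sequences and per-sample profiles with planted sponging
#'
#' Selects `config$n_sponge_pairs` exonic circles (each from a distinct host
#' gene) and pairs each with one miRNA. The reverse complement of miRNA
#' positions 1-12 (which contains the reverse complement of the seed,
#' positions 2-8) is written into the middle of the circle's largest exon, so
#' the planted site appears in the spliced circle sequence. Sponged miRNA
#' log2 abundance is `mu - |sponge_effect| * sum(log2 circle abundance)`
#' (mean-centred) plus Gaussian noise whose sd is derived from
#' `config$sponge_target_r`; non-sponged miRNAs vary independently. Counts
#' are Poisson draws from the expected abundances.
#'
#' @param genome a [GenomePackage-class] (after [plantCircRNAs()]).
#' @param truths the matching [CircTruthSet-class].
#' @param config the [simConfig()].
#' @return list with elements `genome` (site-edited), `truths` (with
#'   `spongePairs` filled), `mirnaSeqs` ([Biostrings::RNAStringSet]),
#'   `profiles` (expected log2 abundance, miRNA x sample) and `counts`
#'   (observed counts, miRNA x sample).
#' @export
simulateMirnas <- function(genome, truths, config) {
  stopifnot(methods::is(genome, "GenomePackage"),
            methods::is(truths, "CircTruthSet"),
            inherits(config, "SimConfig"))
  withStageSeed(config$seed, 303L, {
    nm <- config$n_mirnas
    lens <- sample(config$mirna_length_range[1]:config$mirna_length_range[2],
                   nm, replace = TRUE)
    seqs <- vapply(lens, randomDna, "")
    names(seqs) <- sprintf("miR-%02d", seq_len(nm))

    gr <- junctions(truths)
    cls <- S4Vectors::mcols(gr)$true_class
    exonic <- which(cls %in% c("CDS", "5UTR", "3UTR"))
    npair <- config$n_sponge_pairs
    pairs <- data.frame(circ_id = character(0), mirna_id = character(0),
                        site_pos = integer(0))
    contigs <- as.character(contigSeqs(genome))

    if (npair > 0L) {
      hosts <- S4Vectors::mcols(gr)$host_gene[exonic]
      firstOfGene <- exonic[!duplicated(hosts)]
      if (length(firstOfGene) < npair)
        stop("not enough exonic circles from distinct genes for the ",
             "requested sponge pairs")
      circPick <- sample(firstOfGene, npair)
      mirPick <- sample(names(seqs), npair)

      sitePos <- integer(npair)
      for (j in seq_len(npair)) {
        i <- circPick[j]
        site <- revcompChr(substr(seqs[[mirPick[j]]], 1L, 12L))
        b <- exonBlocks(truths)[[i]]
        bo <- order(IRanges::start(b))
        bs <- IRanges::start(b)[bo]; be <- IRanges::end(b)[bo]
        k <- which.max(be - bs)
        p <- bs[k] + ((be[k] - bs[k] + 1L) - 12L) %/% 2L
        cn <- as.character(GenomicRanges::seqnames(gr))[i]
        strand <- as.character(BiocGenerics::strand(gr))[i]
        written <- if (strand == "+") site else revcompChr(site)
        substr(contigs[[cn]], p, p + 11L) <- written
        # spliced coordinate of the site start in the circle sequence
        w <- be - bs + 1L
        if (strand == "+") {
          off <- if (k > 1L) sum(w[seq_len(k - 1L)]) else 0L
          sitePos[j] <- off + (p - bs[k] + 1L)
        } else {
          off <- if (k < length(w)) sum(w[(k + 1L):length(w)]) else 0L
          sitePos[j] <- off + (be[k] - (p + 11L) + 1L)
        }
      }
      pairs <- data.frame(circ_id = S4Vectors::mcols(gr)$circ_id[circPick],
                          mirna_id = mirPick, site_pos = sitePos)
    }

    # per-sample expected log2 abundance
    lam <- trueAbundance(truths)
    ns <- config$n_samples
    mu <- rnorm(nm, config$mirna_meanlog2, 1)
    prof <- matrix(rnorm(nm * ns, 0, config$mirna_sdlog2), nm, ns) + mu
    dimnames(prof) <- list(names(seqs), sampleIds(config))
    if (npair > 0L) {
      sdSig <- abs(config$sponge_effect) * config$sample_sdlog / log(2)
      r <- abs(config$sponge_target_r)
      noiseSd <- config$mirna_coupling_noise_sd %||%
        (sdSig * sqrt(1 / r^2 - 1))
      for (j in seq_len(npair)) {
        x <- log2(lam[pairs$circ_id[j], ])
        coupl <- config$sponge_effect * (x - mean(x))
        prof[pairs$mirna_id[j], ] <- mu[match(pairs$mirna_id[j],
                                              names(seqs))] +
          coupl + rnorm(ns, 0, noiseSd)
      }
    }
    counts <- matrix(rpois(length(prof), lambda = 2^prof),
                     nrow(prof), ncol(prof), dimnames = dimnames(prof))

    truths@spongePairs <- pairs
    methods::validObject(truths)
    list(genome = methods::new("GenomePackage",
                               contigs = Biostrings::DNAStringSet(contigs),
                               annotation = geneAnnotation(genome)),
         truths = truths,
         mirnaSeqs = Biostrings::RNAStringSet(Biostrings::DNAStringSet(seqs)),
         profiles = prof, counts = counts)
  })
}
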