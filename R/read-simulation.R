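# Read simulator: linear background reads drawn uniformly from spliced gene
# transcripts plus BSJ-spanning reads built from the circular sequence, with
# the junction at a uniform-random offset at least `junction_min_overhang`
# nt from both read ends. Qualities are constant Phred (per sample override
# available); substitution errors optional.

#' Build one BSJ-spanning read from a circular sequence
#'
#' The read is the last `u` bases of the circle followed by its first
#' `L - u` bases, i.e. the back-splice junction sits after read position `u`.
#'
#' @param circSeq character scalar, spliced circle sequence (transcript
#'   orientation).
#' @param u junction offset from the read start (donor-side bases).
#' @param readLength total read length `L`.
#' @return character scalar of length `readLength`.
#' @export
bsjRead <- function(circSeq, u, readLength) {
  n <- nchar(circSeq)
  stopifnot(u >= 1L, u < readLength, readLength <= n)
  paste0(substr(circSeq, n - u + 1L, n),
         substr(circSeq, 1L, readLength - u))
}

applyErrors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < rate)
    for (i in hit) {
      cur <- substr(r, i, i)
      substr(r, i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    r
  }, "", USE.NAMES = FALSE)
}

#' Simulate per-sample FASTQ files with planted BSJ-spanning reads
#'
#' Writes one FASTQ per sample (two when `config$paired`) containing linear
#' background reads sampled uniformly from the spliced gene transcripts (or
#' from raw contigs when the genome has no genes) and, for every planted
#' circle, a Poisson number of BSJ-spanning reads with mean equal to its
#' per-sample true abundance. A `manifest.tsv` records the exact number of
#' FASTQ records written per sample (the raw-read total used as the CPM
#' denominator).
#'
#' @param genome a [GenomePackage-class] (after planting/miRNA editing).
#' @param truths the matching [CircTruthSet-class].
#' @param config the [simConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the manifest data.frame with columns `sample_id`,
#'   `fastq_1`, `fastq_2` (NA if single-end) and `total_reads`.
#' @export
simulateReads <- function(genome, truths, config, outDir) {
  stopifnot(methods::is(genome, "GenomePackage"),
            methods::is(truths, "CircTruthSet"),
            inherits(config, "SimConfig"))
  L <- config$read_length
  k0 <- config$junction_min_overhang
  if (L < 2L * k0 + 1L)
    stop("read_length must be at least 2 * junction_min_overhang + 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ann <- geneAnnotation(genome)
  contigs <- as.character(contigSeqs(genome))
  # spliced sense transcripts
  tx <- character(0)
  if (length(ann)) {
    ex <- exonRows(ann)
    for (g in unique(S4Vectors::mcols(ex)$gene_id)) {
      gex <- ex[S4Vectors::mcols(ex)$gene_id == g]
      o <- order(GenomicRanges::start(gex))
      s <- paste(substring(contigs[[as.character(
        GenomicRanges::seqnames(gex))[1]]],
        GenomicRanges::start(gex)[o], GenomicRanges::end(gex)[o]),
        collapse = "")
      if (as.character(BiocGenerics::strand(gex))[1] == "-")
        s <- revcompChr(s)
      tx[g] <- s
    }
  }
  if (!length(tx)) tx <- contigs   # background-only degenerate mode
  tx <- tx[nchar(tx) >= L]
  if (!length(tx)) stop("no transcript or contig long enough for reads")

  circ <- as.character(circSequences(truths, genome))
  lam <- trueAbundance(truths)
  if (length(circ) && any(nchar(circ) < L))
    stop("planted circle shorter than the read length")

  ids <- sampleIds(config)
  manifest <- data.frame(sample_id = ids, fastq_1 = NA_character_,
                         fastq_2 = NA_character_, total_reads = 0L)
  txw <- nchar(tx) - L + 1L

  for (s in seq_along(ids)) {
    withStageSeed(config$seed, 1000L + s, {
      nBg <- config$reads_per_sample
      gi <- sample.int(length(tx), nBg, replace = TRUE, prob = txw)
      off <- floor(runif(nBg) * txw[gi]) + 1L
      bg <- substring(tx[gi], off, off + L - 1L)

      bsj <- character(0)
      bsj2 <- character(0)
      for (ci in seq_along(circ)) {
        ncirc <- rpois(1L, lam[ci, s])
        if (ncirc == 0L) next
        u <- sample(k0:(L - k0), ncirc, replace = TRUE)
        bsj <- c(bsj, vapply(u, function(uu) bsjRead(circ[ci], uu, L), ""))
        if (config$paired) {
          u2 <- sample(k0:(L - k0), ncirc, replace = TRUE)
          bsj2 <- c(bsj2, vapply(u2, function(uu)
            revcompChr(bsjRead(circ[ci], uu, L)), ""))
        }
      }

      r1 <- c(bg, bsj)
      ord <- sample.int(length(r1))
      r1 <- applyErrors(r1[ord], config$error_rate)
      nm <- sprintf("%s_%06d", ids[s], seq_along(r1))
      q <- config$quality_by_sample[s] %||% config$base_quality
      qstr <- strrep(phredChar(q), L)

      f1 <- file.path(outDir, paste0(ids[s],
                                     if (config$paired) "_1" else "",
                                     ".fastq"))
      writeFastq(r1, nm, qstr, f1)
      manifest$fastq_1[s] <- f1
      total <- length(r1)

      if (config$paired) {
        gi2 <- sample.int(length(tx), nBg, replace = TRUE, prob = txw)
        off2 <- floor(runif(nBg) * txw[gi2]) + 1L
        bg2 <- revcompChr(substring(tx[gi2], off2, off2 + L - 1L))
        r2 <- c(bg2, bsj2)[ord]
        r2 <- applyErrors(r2, config$error_rate)
        f2 <- file.path(outDir, paste0(ids[s], "_2.fastq"))
        writeFastq(r2, nm, qstr, f2)
        manifest$fastq_2[s] <- f2
        total <- total + length(r2)
      }
      manifest$total_reads[s] <- total
    })
  }
  data.table::fwrite(manifest, file.path(outDir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

writeFastq <- function(seqs, names, qual, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(qual, length(x))))
  invisible(path)
}
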