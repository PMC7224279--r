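# Exact k-mer index over the plus strand of every contig. Minus-strand
# occurrences of a query are resolved by looking up its reverse complement.
# This replaces a seed-alignment step: anchors must match exactly; mismatches
# are only allowed during anchor extension.

#' Build an exact k-mer index of a genome
#'
#' Every length-`anchorLength` substring of every contig is recorded with its
#' 1-based plus-strand start position in a keyed [data.table::data.table].
#'
#' @param genome a [GenomePackage-class] or a named
#'   [Biostrings::DNAStringSet].
#' @param anchorLength k-mer length (the detection anchor length, >= 12).
#' @return a [GenomeIndex-class].
#' @examples
#' gi <- buildGenomeIndex(Biostrings::DNAStringSet(c(chrA = "ACGTACGT")), 4)
#' lookupKmer(gi, "ACGT")
#' @export
buildGenomeIndex <- function(genome, anchorLength = 20L) {
  contigs <- if (methods::is(genome, "GenomePackage")) contigSeqs(genome)
    else genome
  stopifnot(methods::is(contigs, "DNAStringSet"), length(contigs) > 0L)
  anchorLength <- as.integer(anchorLength)
  if (anchorLength > min(Biostrings::width(contigs)))
    stop("anchor length exceeds the shortest contig")
  tabs <- lapply(seq_along(contigs), function(i) {
    s <- as.character(contigs[[i]])
    n <- nchar(s)
    pos <- seq_len(n - anchorLength + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + anchorLength - 1L),
                           contig = names(contigs)[i], pos = pos)
  })
  tab <- data.table::rbindlist(tabs)
  data.table::setkeyv(tab, "kmer")
  methods::new("GenomeIndex", table = tab,
               anchorLength = anchorLength, contigs = contigs)
}

#' Look up a k-mer's genomic occurrences on both strands
#'
#' A minus-strand hit at `(contig, pos)` means the reverse complement of the
#' query occupies plus-strand positions `pos..pos+k-1`.
#'
#' @param index a [GenomeIndex-class].
#' @param kmer character vector of queries (length `anchorLength` each).
#' @return data.frame with columns `kmer`, `contig`, `pos`, `strand`.
#' @export
lookupKmer <- function(index, kmer) {
  stopifnot(all(nchar(kmer) == index@anchorLength))
  # the query table must be built outside the join so the local `kmer`
  # argument is not shadowed by the index column of the same name
  qf <- data.table::data.table(kmer = kmer)
  fw <- index@table[qf, nomatch = NULL, on = "kmer"]
  rcq <- revcompChr(kmer)
  qr <- data.table::data.table(kmer = rcq)
  rv <- index@table[qr, nomatch = NULL, on = "kmer"]
  if (nrow(rv)) rv$kmer <- kmer[match(rv$kmer, rcq)]
  out <- rbind(data.frame(fw[, c("kmer", "contig", "pos")],
                          strand = rep("+", nrow(fw))),
               data.frame(rv[, c("kmer", "contig", "pos")],
                          strand = rep("-", nrow(rv))))
  rownames(out) <- NULL
  out
}

# internal: plus-strand hits of a character vector of anchors, as a
# data.table (qid = index into the query vector, contig, pos)
anchorHits <- function(index, anchors) {
  q <- data.table::data.table(kmer = anchors, qid = seq_along(anchors))
  h <- index@table[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  h[, c("qid", "contig", "pos")]
}
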