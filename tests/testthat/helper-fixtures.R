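# Shared fixtures. The small study is built once per test run and reused by
# several files; everything is generated in code, nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

tinyConfig <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_samples = 6L, n_contigs = 2L,
               contig_length = 25000L, n_genes = 4L,
               n_circ = c(CDS = 3L, `5UTR` = 1L, `3UTR` = 1L, intronic = 1L,
                          intergenic = 1L),
               reads_per_sample = 300L, n_mirnas = 6L, n_sponge_pairs = 2L,
               n_causal_circ = 2L)
  args <- utils::modifyList(args, list(...))
  do.call(simConfig, args)
}

# genome + planted circles + miRNAs for a compact 6-sample study
smallStudy <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- tinyConfig()
    gp <- generateGenome(cfg)
    pl <- plantCircRNAs(gp, cfg)
    mi <- simulateMirnas(pl$genome, pl$truths, cfg)
    .fixtures$small <- list(cfg = cfg, genome = mi$genome, truths = mi$truths,
                            mirnaSeqs = mi$mirnaSeqs, profiles = mi$profiles,
                            mirnaCounts = mi$counts)
  }
  .fixtures$small
}

# a hand-built annotation: one '+' gene with two exons plus feature rows
miniAnnotation <- function() {
  GenomicRanges::GRanges(
    rep("chrT", 6L),
    IRanges::IRanges(start = c(100, 300, 100, 300, 600, 600),
                     end = c(200, 400, 200, 400, 700, 700)),
    strand = "+",
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB"),
    feature = c("exon", "exon", "CDS", "CDS", "exon", "three_prime_utr"),
    exon_rank = c(1L, 2L, 1L, 2L, 1L, 1L))
}
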