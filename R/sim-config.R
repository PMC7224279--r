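#' Simulation configuration for the synthetic sperm circRNA study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate the
#' study conditions the pipeline is designed for: 40 ejaculate samples, 75 bp
#' reads, a toy genome of 3 contigs x 100 kb, 20 planted exonic circles (14
#' CDS, 3 each UTR class) plus 3 intronic and 3 intergenic, expected BSJ read
#' support of at least 5 reads per circle per sample, 20 miRNAs with 10
#' planted sponge pairs coupled at a target Pearson correlation of -0.7 on
#' log2 abundances, and motility phenotypes driven by farm/age-class/
#' season-year fixed effects plus a handful of causal circles.
#'
#' @param seed integer master seed; every generator stage derives its own
#'   stream from it, so a fixed config yields byte-identical outputs.
#' @param n_samples number of samples (boars).
#' @param n_contigs,contig_length toy genome dimensions (bp).
#' @param n_genes number of gene models placed across contigs.
#' @param exons_per_gene integer range (min, max); at least 5 so every gene has
#'   internal 5'UTR, CDS and 3'UTR exons flanked by introns.
#' @param exon_length,intron_length,intergenic_gap bp ranges (min, max).
#' @param n_circ named integer vector of planted circle counts per class;
#'   names from CDS, 5UTR, 3UTR, intronic, intergenic.
#' @param read_length read length in nt (the study's libraries are 75 bp).
#' @param paired logical; write _1/_2 mate FASTQ files per sample.
#' @param reads_per_sample number of linear background reads per sample.
#' @param junction_min_overhang minimum distance (nt) of the back-splice
#'   junction from either read end in simulated BSJ reads.
#' @param circ_meanlog,circ_sdlog natural-log mean/sd of the per-circle
#'   baseline expected BSJ read count (log-normal across circles).
#' @param sample_sdlog natural-log sd of the per-sample abundance fluctuation
#'   around the circle baseline (log-normal across samples).
#' @param abundance_floor lower clamp on the per-sample expected BSJ read
#'   count, keeping every planted circle at the well-supported level the
#'   downstream stringency filters presume.
#' @param base_quality constant Phred base quality of simulated reads.
#' @param quality_by_sample optional integer vector (length `n_samples`)
#'   overriding `base_quality` per sample, e.g. to inject low-quality samples
#'   that the Phred filter should reject.
#' @param error_rate per-base substitution error rate.
#' @param n_mirnas number of miRNAs; must be at least `n_sponge_pairs`.
#' @param mirna_length_range miRNA length range in nt.
#' @param n_sponge_pairs number of planted circRNA-miRNA sponge pairs (each
#'   sponging circle from a distinct host gene).
#' @param sponge_effect linear coefficient of the summed sponging-circle log2
#'   abundance in the sponged miRNA's log2 abundance; must be negative.
#' @param sponge_target_r target Pearson correlation between the true log2
#'   abundances of a planted pair; the coupling noise sd is derived from it.
#' @param mirna_meanlog2 mean log2 baseline abundance of miRNAs (count scale).
#' @param mirna_sdlog2 across-sample log2 sd of non-sponged miRNA abundance.
#' @param mirna_coupling_noise_sd optional override of the coupling noise sd
#'   for sponged miRNAs; when `NULL` it is derived from `sponge_target_r`.
#' @param trait_intercepts named numeric: motile_pct, vcl, vsl, vap.
#' @param fixed_effect_sd sd of the fixed-effect level deviations (same units
#'   as the traits) for farm (3 levels), age class (3) and season-year (9).
#' @param trait_noise_sd named numeric residual sd per trait.
#' @param n_causal_circ number of exonic circles given a phenotype effect.
#' @param pheno_effect_size coefficient per unit log2 abundance for causal
#'   circles (traits assigned round-robin).
#' @param age_months_range boar age range in months.
#'
#' @return an object of class `SimConfig` (a validated list).
#' @examples
#' cfg <- simConfig(seed = 1, n_samples = 4, n_contigs = 2,
#'                  contig_length = 20000, n_genes = 4,
#'                  n_circ = c(CDS = 2), reads_per_sample = 200)
#' @export
simConfig <- function(seed = 1L,
                      n_samples = 40L,
                      n_contigs = 3L,
                      contig_length = 100000L,
                      n_genes = 30L,
                      exons_per_gene = c(5L, 9L),
                      exon_length = c(80L, 400L),
                      intron_length = c(200L, 1000L),
                      intergenic_gap = c(1000L, 3000L),
                      n_circ = c(CDS = 14L, `5UTR` = 3L, `3UTR` = 3L,
                                 intronic = 3L, intergenic = 3L),
                      read_length = 75L,
                      paired = FALSE,
                      reads_per_sample = 20000L,
                      junction_min_overhang = 20L,
                      circ_meanlog = log(15),
                      circ_sdlog = 0.3,
                      sample_sdlog = 0.5,
                      abundance_floor = 5,
                      base_quality = 37L,
                      quality_by_sample = NULL,
                      error_rate = 0,
                      n_mirnas = 20L,
                      mirna_length_range = c(20L, 24L),
                      n_sponge_pairs = 10L,
                      sponge_effect = -1,
                      sponge_target_r = -0.7,
                      mirna_meanlog2 = log2(500),
                      mirna_sdlog2 = 0.5,
                      mirna_coupling_noise_sd = NULL,
                      trait_intercepts = c(motile_pct = 75.5, vcl = 43.7,
                                           vsl = 26.4, vap = 32.4),
                      fixed_effect_sd = 4,
                      trait_noise_sd = c(motile_pct = 8, vcl = 5,
                                         vsl = 3, vap = 3),
                      n_causal_circ = 5L,
                      pheno_effect_size = 2,
                      age_months_range = c(9, 54)) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  full <- c(CDS = 0L, `5UTR` = 0L, `3UTR` = 0L, intronic = 0L,
            intergenic = 0L)
  if (length(n_circ)) {
    if (is.null(names(n_circ)) ||
        !all(names(n_circ) %in% names(full)))
      stop("n_circ must be named with classes among: ",
           paste(names(full), collapse = ", "))
    full[names(n_circ)] <- as.integer(n_circ)
  }
  cfg$n_circ <- full
  if (any(full < 0L)) stop("n_circ counts must be non-negative")
  if (cfg$n_samples < 1L) stop("n_samples must be positive")
  if (cfg$read_length < 2L * cfg$junction_min_overhang + 1L)
    stop("read_length must be at least 2 * junction_min_overhang + 1")
  if (cfg$exons_per_gene[1] < 5L)
    stop("genes need at least 5 exons (UTR/CDS/UTR structure)")
  if (cfg$exon_length[1] < cfg$read_length + 5L)
    stop("minimum exon length must exceed the read length")
  if (cfg$n_sponge_pairs > 0L && cfg$n_mirnas < cfg$n_sponge_pairs)
    stop("n_mirnas must be >= n_sponge_pairs")
  if (cfg$n_sponge_pairs > 0L && cfg$sponge_effect >= 0)
    warning("non-negative sponge effect requested; ",
            "only negative circRNA-miRNA couplings are modelled downstream")
  if (cfg$abundance_floor < 0) stop("abundance_floor must be >= 0")
  if (!is.null(quality_by_sample) &&
      length(quality_by_sample) != cfg$n_samples)
    stop("quality_by_sample must have length n_samples")
  if (cfg$reads_per_sample < 0L) stop("counts must be non-negative")
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", x$n_samples, "samples |",
      x$n_contigs, "x", x$contig_length, "bp contigs |",
      sum(x$n_circ), "planted circRNAs (",
      paste(names(x$n_circ), x$n_circ, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

sampleIds <- function(config) sprintf("S%02d", seq_len(config$n_samples))
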