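# Phenotype simulator: CASA motility traits (motile %, VCL, VSL, VAP) as
# intercept + farm + age-class + season-year fixed effects + causal-circle
# contributions on log2 abundance + Gaussian noise; motile % clipped to
# [0, 100]; boar ages in months over a configurable range.

seasonYearLevels <- c("autumn14", "autumn15", "autumn16", "winter15",
                      "winter16", "winter17", "spring15", "spring16",
                      "summer15")

#' Simulate per-sample motility phenotypes and covariates
#'
#' Each trait is `intercept + farm effect + age-class effect + season-year
#' effect + sum(coef * log2 circle abundance) + noise`. Fixed-effect level
#' deviations are drawn once (first level = 0, reference) with sd
#' `config$fixed_effect_sd`. Ages are drawn so the three age classes
#' (< 12, 12-24, > 24 months) are all represented, with most boars young.
#'
#' @param truths a [CircTruthSet-class] carrying abundances and
#'   `phenoEffects`.
#' @param config the [simConfig()].
#' @return data.frame with columns sample_id, motile_pct, vcl, vsl, vap,
#'   farm, age_class, season_year, age_months.
#' @export
simulatePhenotypes <- function(truths, config) {
  stopifnot(methods::is(truths, "CircTruthSet"), inherits(config, "SimConfig"))
  if (ncol(trueAbundance(truths)) != config$n_samples)
    stop("truth abundance columns do not match config$n_samples")
  withStageSeed(config$seed, 404L, {
    ns <- config$n_samples
    ids <- sampleIds(config)
    lo <- config$age_months_range[1]; hi <- config$age_months_range[2]

    cls <- sample(1:3, ns, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    if (ns >= 3L) cls[1:3] <- 1:3   # every age class represented
    bnd <- rbind(c(lo, min(12, hi)), c(min(12, hi), min(24, hi)),
                 c(min(24, hi), hi))
    age <- bnd[cls, 1] + runif(ns) * pmax(bnd[cls, 2] - bnd[cls, 1], 0.5)
    ageClass <- ifelse(age < 12, 1L, ifelse(age <= 24, 2L, 3L))

    farm <- sample(1:3, ns, replace = TRUE)
    sy <- sample(seasonYearLevels, ns, replace = TRUE)

    traits <- names(config$trait_intercepts)
    fe <- function(nlev) {
      m <- matrix(rnorm(length(traits) * nlev, 0, config$fixed_effect_sd),
                  length(traits), nlev, dimnames = list(traits, NULL))
      m[, 1] <- 0
      m
    }
    farmEff <- fe(3L); ageEff <- fe(3L); syEff <- fe(9L)

    lam <- trueAbundance(truths)
    eff <- phenoEffects(truths)

    out <- matrix(0, ns, length(traits), dimnames = list(ids, traits))
    for (tr in traits) {
      y <- config$trait_intercepts[[tr]] +
        farmEff[tr, farm] + ageEff[tr, ageClass] +
        syEff[tr, match(sy, seasonYearLevels)]
      rows <- eff[eff$trait == tr, , drop = FALSE]
      for (j in seq_len(nrow(rows)))
        y <- y + rows$coef[j] * log2(lam[rows$circ_id[j], ])
      y <- y + rnorm(ns, 0, config$trait_noise_sd[[tr]])
      out[, tr] <- y
    }
    out[, "motile_pct"] <- pmin(pmax(out[, "motile_pct"], 0), 100)

    data.frame(sample_id = ids,
               motile_pct = out[, "motile_pct"], vcl = out[, "vcl"],
               vsl = out[, "vsl"], vap = out[, "vap"],
               farm = factor(farm, levels = 1:3),
               age_class = factor(ageClass, levels = 1:3),
               season_year = factor(sy, levels = seasonYearLevels),
               age_months = age, row.names = NULL)
  })
}

#' Observed BSJ counts and raw totals without read-level simulation
#'
#' Draws per-sample observed BSJ read counts as Poisson around the planted
#' expected counts and returns raw-read totals (background reads plus BSJ
#' reads), the fast path for exercising the quantification, network and
#' association stages without FASTQ-level simulation.
#'
#' @param truths a [CircTruthSet-class].
#' @param config the [simConfig()].
#' @return list with `counts` (circles x samples, integer) and `raw_totals`
#'   (named numeric per sample).
#' @export
observedCircCounts <- function(truths, config) {
  withStageSeed(config$seed, 505L, {
    lam <- trueAbundance(truths)
    counts <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                     dimnames = dimnames(lam))
    tot <- config$reads_per_sample * (if (config$paired) 2L else 1L) +
      colSums(counts)
    list(counts = counts, raw_totals = setNames(as.numeric(tot),
                                                colnames(counts)))
  })
}

#' Run the whole synthetic-study generator
#'
#' Convenience orchestrator: genome, planted circles, miRNA sequences and
#' profiles, phenotypes, and (when `outDir` is given) per-sample FASTQ files.
#'
#' @param config a [simConfig()].
#' @param outDir optional directory for FASTQ output; when `NULL` no reads
#'   are written.
#' @return list with `genome`, `truths`, `mirnaSeqs`, `mirnaProfiles`,
#'   `mirnaCounts`, `phenotypes` and (if reads were written) `manifest`.
#' @export
simulateSpongeStudy <- function(config, outDir = NULL) {
  gp <- generateGenome(config)
  pl <- plantCircRNAs(gp, config)
  mi <- simulateMirnas(pl$genome, pl$truths, config)
  ph <- simulatePhenotypes(mi$truths, config)
  out <- list(genome = mi$genome, truths = mi$truths,
              mirnaSeqs = mi$mirnaSeqs, mirnaProfiles = mi$profiles,
              mirnaCounts = mi$counts, phenotypes = ph)
  if (!is.null(outDir))
    out$manifest <- simulateReads(mi$genome, mi$truths, config, outDir)
  out
}
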