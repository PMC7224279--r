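# Phenotype association: OLS fixed-effect correction, Pearson abundance
# screen (two-sided p from the t transform, no multiple-testing correction
# by default) and the Wilcoxon age-group comparison.

phenoTraits <- c("motile_pct", "vcl", "vsl", "vap")

#' Correct motility phenotypes for fixed effects
#'
#' Fits, per trait, an ordinary least squares model on dummy-coded farm, age
#' class and season-year (first level as reference) and returns the
#' residuals. Unused factor levels are dropped; a rank-deficient design is
#' an error naming the aliased columns.
#'
#' @param pheno data.frame as produced by [simulatePhenotypes()]: trait
#'   columns `motile_pct`, `vcl`, `vsl`, `vap` and factors `farm`,
#'   `age_class`, `season_year`.
#' @param traits trait columns to correct.
#' @return samples x traits matrix of residuals, with the design matrix as
#'   attribute `"design"`.
#' @export
correctPhenotypes <- function(pheno, traits = phenoTraits) {
  stopifnot(all(traits %in% names(pheno)),
            all(c("farm", "age_class", "season_year") %in% names(pheno)))
  df <- data.frame(farm = droplevels(factor(pheno$farm)),
                   age_class = droplevels(factor(pheno$age_class)),
                   season_year = droplevels(factor(pheno$season_year)))
  X <- model.matrix(~ farm + age_class + season_year, df)
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    aliased <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  if (nrow(X) <= ncol(X))
    stop("more design columns than observations")
  Y <- as.matrix(pheno[, traits, drop = FALSE])
  fit <- lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- list(pheno$sample_id %||% rownames(pheno), traits)
  attr(res, "design") <- X
  res
}

#' Pearson screen of circRNA abundance against corrected traits
#'
#' Per (circRNA, trait) pair: Pearson r and the two-sided p-value from the t
#' transform with n - 2 degrees of freedom; pairs with `p < alpha` are
#' flagged significant. No multiple-testing correction is applied by default
#' (set `adjust = "BH"` for an FDR-adjusted flag). Constant circRNA rows are
#' excluded with a warning.
#'
#' @param cpm circRNAs x samples abundance matrix.
#' @param traits samples x traits matrix (e.g. from [correctPhenotypes()]).
#' @param alpha significance level (default 0.05).
#' @param log2_transform correlate log2(x + 1) of the abundances instead.
#' @param adjust "none" (default) or "BH".
#' @return data.frame: circ_id, trait, pearson_r, p_value, significant.
#' @export
correlateAbundance <- function(cpm, traits, alpha = 0.05,
                               log2_transform = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cpm <- as.matrix(cpm)
  traits <- as.matrix(traits)
  if (ncol(cpm) != nrow(traits))
    stop("samples mismatch between abundance matrix and traits")
  if (!is.null(colnames(cpm)) && !is.null(rownames(traits)) &&
      !identical(colnames(cpm), rownames(traits)))
    traits <- traits[colnames(cpm), , drop = FALSE]
  n <- ncol(cpm)
  if (n < 4L) stop("at least 4 samples are required")
  if (log2_transform) cpm <- log2(cpm + 1)
  keep <- apply(cpm, 1L, sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant circRNA(s) excluded from the screen: ",
            paste(head(rownames(cpm)[!keep], 5L), collapse = ", "))
    cpm <- cpm[keep, , drop = FALSE]
  }
  r <- cor(t(cpm), traits)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(
    circ_id = rep(rownames(cpm) %||% seq_len(nrow(cpm)), ncol(traits)),
    trait = rep(colnames(traits) %||% seq_len(ncol(traits)),
                each = nrow(cpm)),
    pearson_r = as.vector(r), p_value = as.vector(p))
  pp <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$significant <- pp < alpha
  rownames(out) <- NULL
  out
}

#' Wilcoxon age-group comparison of circRNA load and abundance
#'
#' Splits samples into young (< `cut_months`) and mature (>= `cut_months`)
#' groups, or into the `extreme_k` youngest vs oldest when `extreme_k` is
#' given, and runs two-sided Wilcoxon rank-sum tests on (a) the per-sample
#' number of detected circRNAs and (b) the per-sample mean abundance. The
#' exact distribution is used for small tie-free groups, the normal
#' approximation with tie correction otherwise (the [stats::wilcox.test()]
#' convention).
#'
#' @param circ_counts per-sample number of detected circRNAs.
#' @param mean_abundance per-sample mean CPM over the catalogue.
#' @param ages per-sample age in months.
#' @param cut_months group cut (default 24, i.e. two years).
#' @param extreme_k optional: compare only the k youngest vs k oldest.
#' @return list with `p_count`, `p_abundance`, `n_young`, `n_mature` and the
#'   group assignment.
#' @export
ageGroupTest <- function(circ_counts, mean_abundance, ages,
                         cut_months = 24, extreme_k = NULL) {
  stopifnot(length(circ_counts) == length(ages),
            length(mean_abundance) == length(ages))
  if (!is.null(extreme_k)) {
    o <- order(ages)
    young <- o[seq_len(extreme_k)]
    mature <- o[seq.int(length(ages) - extreme_k + 1L, length(ages))]
  } else {
    young <- which(ages < cut_months)
    mature <- which(ages >= cut_months)
  }
  if (!length(young) || !length(mature))
    stop("an age group is empty after the cut")
  wt <- function(v) wilcox.test(v[young], v[mature],
                                alternative = "two.sided")$p.value
  list(p_count = suppressWarnings(wt(circ_counts)),
       p_abundance = suppressWarnings(wt(mean_abundance)),
       n_young = length(young), n_mature = length(mature),
       young = young, mature = mature)
}
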