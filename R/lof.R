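#' LOF observed/expected ratio
#'
#' The observed fraction of LOF variants among all observed coding variants
#' (LOF + missense + synonymous distinct sites), divided by the
#' mutability-derived neutral expectation (see [expected_lof_fraction()]).
#' Values below 1 indicate LOF depletion.
#'
#' @param ptv_obs Observed distinct LOF (protein-truncating) sites.
#' @param total_obs Total observed distinct sites (LOF + missense +
#'   synonymous).
#' @param expected_fraction Neutral LOF fraction in `(0, 1)`.
#' @return Numeric vector of O/E ratios; `NA` when `total_obs` is zero or
#'   the expected fraction is zero/missing.
#' @export
lof_oe <- function(ptv_obs, total_obs, expected_fraction) {
  if (any(ptv_obs < 0 | total_obs < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (any(ptv_obs > total_obs, na.rm = TRUE)) {
    stop("'ptv_obs' cannot exceed 'total_obs'")
  }
  ifelse(total_obs > 0 & !is.na(expected_fraction) & expected_fraction > 0,
         (ptv_obs / total_obs) / expected_fraction,
         NA_real_)
}

#' One-sided binomial exact test for LOF depletion
#'
#' Exact lower-tail probability `P(X <= ptv_obs)` for
#' `X ~ Binomial(total, p_expected)`: a small value means the gene carries
#' fewer LOF variants than its mutability predicts, i.e. is LOF
#' intolerant. The opposite tail (`P(X >= ptv_obs)`) is available via
#' `alternative = "enrichment"`.
#'
#' @param ptv_obs Observed LOF site count(s), `0 <= ptv_obs <= total`.
#' @param total Total observed site count(s).
#' @param p_expected Neutral LOF fraction(s) in `(0, 1)`.
#' @param alternative `"depletion"` (default) or `"enrichment"`.
#' @return P-values in `(0, 1]` (vectorized).
#' @export
lof_binomial_p <- function(ptv_obs, total,
                           p_expected, alternative = c("depletion",
                                                       "enrichment")) {
  alternative <- match.arg(alternative)
  if (any(p_expected <= 0 | p_expected >= 1)) {
    stop("'p_expected' must lie strictly in (0, 1)")
  }
  if (any(ptv_obs < 0 | ptv_obs > total)) {
    stop("need 0 <= ptv_obs <= total")
  }
  if (alternative == "depletion") {
    stats::pbinom(ptv_obs, total, p_expected)
  } else {
    stats::pbinom(ptv_obs - 1, total, p_expected, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in input
#' order. Inputs outside `(0, 1]` are an error (`NA`s pass through).
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted values in `(0, 1]`.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Tally per-gene LOF observations
#'
#' Distinct sites per gene and consequence class among the variants
#' observed in the cohort.
#'
#' @inheritParams mtr_gene_scores
#' @param genes Gene universe (defaults to the genes present in
#'   `variants`).
#' @return Data frame: `gene`, `ptv_obs`, `missense_obs`, `synonymous_obs`,
#'   `total_obs`.
#' @export
lof_tally <- function(variants, cohort = NULL, genes = NULL) {
  obs <- variants[cohort_observed(variants, cohort), , drop = FALSE]
  obs <- obs[!duplicated(variant_site_key(obs)), , drop = FALSE]
  if (is.null(genes)) genes <- unique(variants$gene)
  cnt <- function(class) {
    as.integer(table(factor(obs$gene[obs$consequence_class == class],
                            levels = genes)))
  }
  ptv <- cnt("lof")
  mis <- cnt("missense")
  syn <- cnt("synonymous")
  data.frame(gene = genes, ptv_obs = ptv, missense_obs = mis,
             synonymous_obs = syn, total_obs = ptv + mis + syn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LOF O/E and LOF-FDR scores for a cohort
#'
#' Per gene: the LOF observed/expected ratio, the one-sided binomial exact
#' p-value against the mutability-derived neutral LOF fraction, and its
#' Benjamini-Hochberg adjustment (LOF-FDR). Genes with no observed
#' variants receive missing scores and do not count toward the number of
#' tests in the adjustment.
#'
#' @inheritParams rvis_scores
#' @param cohort Ancestry label, [cohort_spec()], or `NULL` for sites
#'   observed in any group.
#' @param alternative Tail of the binomial test; `"depletion"` (default)
#'   ranks LOF-intolerant genes first.
#' @return Data frame: `gene`, `ptv_obs`, `total_obs`, `expected_fraction`,
#'   `oe`, `p_raw`, `fdr`.
#' @export
lof_scores <- function(variants, mutability, cohort = NULL,
                       alternative = c("depletion", "enrichment")) {
  alternative <- match.arg(alternative)
  tally <- lof_tally(variants, cohort, genes = mutability$gene)
  exp_frac <- expected_lof_fraction(mutability$mu_mis, mutability$mu_syn,
                                    mutability$mu_lof)
  oe <- lof_oe(tally$ptv_obs, tally$total_obs, exp_frac)
  p_raw <- rep(NA_real_, nrow(tally))
  scoreable <- tally$total_obs > 0 & !is.na(exp_frac) &
    exp_frac > 0 & exp_frac < 1
  p_raw[scoreable] <- lof_binomial_p(tally$ptv_obs[scoreable],
                                     tally$total_obs[scoreable],
                                     exp_frac[scoreable], alternative)
  fdr <- rep(NA_real_, nrow(tally))
  fdr[scoreable] <- bh_adjust(p_raw[scoreable])
  data.frame(gene = tally$gene, ptv_obs = tally$ptv_obs,
             total_obs = tally$total_obs, expected_fraction = exp_frac,
             oe = oe, p_raw = p_raw, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
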