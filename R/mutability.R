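#' Frameshift mutability from the SNV LOF rate
#'
#' Trinucleotide-context mutation-rate models only cover single-nucleotide
#' variants, so the LOF mutability they provide misses frameshift indels.
#' The frameshift contribution is approximated as a fixed multiple of the
#' SNV LOF rate (default 1.25).
#'
#' @param mu_lof_snv Non-negative SNV-only LOF mutation rate(s).
#' @param multiplier Frameshift multiplier (default 1.25).
#' @return `multiplier * mu_lof_snv`.
#' @export
frameshift_mutability <- function(mu_lof_snv, multiplier = 1.25) {
  if (any(!is.finite(mu_lof_snv) | mu_lof_snv < 0)) {
    stop("'mu_lof_snv' must be finite and non-negative")
  }
  multiplier * mu_lof_snv
}

check_mutability_components <- function(mu_mis, mu_syn, mu_lof_snv) {
  for (v in list(mu_mis, mu_syn, mu_lof_snv)) {
    if (any(!is.finite(v) | v < 0)) {
      stop("mutability components must be finite and non-negative")
    }
  }
}

#' Total genic mutability
#'
#' Sums the four per-gene mutation-rate components: missense, synonymous,
#' SNV LOF, and the frameshift term (1.25 x the SNV LOF rate). This total
#' is the regression covariate for the mutability-anchored RVIS and the
#' denominator scale of the LOF expected fraction.
#'
#' @param mu_mis,mu_syn,mu_lof_snv Non-negative per-gene rates (vectorized).
#' @param frameshift_multiplier Multiplier for the frameshift term.
#' @return Numeric vector of total mutabilities.
#' @examples
#' genic_mutability(5e-5, 2e-5, 1e-6)  # 7.225e-05
#' @export
genic_mutability <- function(mu_mis, mu_syn, mu_lof_snv,
                             frameshift_multiplier = 1.25) {
  check_mutability_components(mu_mis, mu_syn, mu_lof_snv)
  mu_mis + mu_syn + mu_lof_snv +
    frameshift_mutability(mu_lof_snv, frameshift_multiplier)
}

#' Expected LOF fraction under neutrality
#'
#' The neutral probability that a coding variant is LOF: the LOF mutability
#' (SNV plus frameshift term, i.e. `(1 + multiplier) * mu_lof_snv`) divided
#' by the total genic mutability. This is the success probability of the
#' per-gene binomial depletion test.
#'
#' @inheritParams genic_mutability
#' @return Proportions in `[0, 1]`; `NA` where the total mutability is zero.
#' @examples
#' expected_lof_fraction(5e-5, 2e-5, 1e-6)  # 2.25e-6 / 7.225e-5
#' @export
expected_lof_fraction <- function(mu_mis, mu_syn, mu_lof_snv,
                                  frameshift_multiplier = 1.25) {
  total <- genic_mutability(mu_mis, mu_syn, mu_lof_snv, frameshift_multiplier)
  lof <- (1 + frameshift_multiplier) * mu_lof_snv
  ifelse(total > 0, lof / total, NA_real_)
}

#' Expected missense fraction under neutrality
#'
#' The neutral probability that a (missense or synonymous) variant is
#' missense: `mu_mis / (mu_mis + mu_syn)`. This is the expectation term of
#' the missense tolerance ratio in mutability mode.
#'
#' @inheritParams genic_mutability
#' @return Proportions in `[0, 1]`; `NA` where both components are zero.
#' @export
expected_missense_fraction <- function(mu_mis, mu_syn) {
  check_mutability_components(mu_mis, mu_syn, 0)
  total <- mu_mis + mu_syn
  ifelse(total > 0, mu_mis / total, NA_real_)
}
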