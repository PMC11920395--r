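#' Tally common functional variants per gene
#'
#' Counts, per gene, the distinct missense and LOF sites whose minor allele
#' frequency in the requested ancestry group (or pooled cohort) strictly
#' exceeds the cutoff. Synonymous and `other`-class records are excluded.
#' A variant site is counted once regardless of how many allele copies were
#' observed.
#'
#' @param variants Variant table from [read_variants()] or
#'   [simulate_catalog()].
#' @param cohort Ancestry label or [cohort_spec()]; frequencies are pooled
#'   over the cohort's groups.
#' @param maf_cutoff MAF threshold in `(0, 0.5]`; default 0.0005
#'   ("common" = MAF > 0.05\%). The inequality is strict.
#' @return Data frame with columns `gene`, `n_common_functional`, one row
#'   per gene that has at least one variant record in `variants`.
#' @export
tally_common_functional <- function(variants, cohort, maf_cutoff = 5e-4) {
  stopifnot(is.data.frame(variants))
  if (!is.numeric(maf_cutoff) || length(maf_cutoff) != 1 ||
      maf_cutoff <= 0 || maf_cutoff > 0.5) {
    stop("'maf_cutoff' must be a single value in (0, 0.5]")
  }
  if (nrow(variants) == 0) {
    return(data.frame(gene = character(0), n_common_functional = integer(0)))
  }
  maf <- cohort_maf(variants, cohort)
  keep <- variants$consequence_class %in% c("missense", "lof") &
    !is.na(maf) & maf > maf_cutoff
  hit <- variants[keep, , drop = FALSE]
  hit <- hit[!duplicated(variant_site_key(hit)), , drop = FALSE]
  counts <- table(factor(hit$gene, levels = unique(variants$gene)))
  data.frame(gene = names(counts),
             n_common_functional = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit RVIS: studentized residuals of variant counts on mutability
#'
#' Ordinary least squares of the per-gene common functional variant count
#' (`y`) on genic mutability (`x`), with intercept. RVIS is the studentized
#' residual; a negative score marks a gene with fewer common functional
#' variants than its mutational burden predicts, i.e. an intolerant gene.
#' Percentiles run from 0 (most intolerant) to 100, with ties broken by
#' gene symbol for determinism.
#'
#' @param inputs Data frame with columns `gene`, `y` (non-negative integer
#'   count) and `x` (positive mutability).
#' @param type `"external"` (leave-one-out studentization, the default) or
#'   `"internal"`.
#' @param min_genes Minimum number of genes required to fit (default 10).
#' @return Data frame: `gene`, `n_common_functional`, `mutability`, `rvis`,
#'   `percentile`.
#' @export
fit_rvis <- function(inputs, type = c("external", "internal"),
                     min_genes = 10) {
  type <- match.arg(type)
  stopifnot(is.data.frame(inputs),
            all(c("gene", "y", "x") %in% names(inputs)))
  ok <- is.finite(inputs$y) & is.finite(inputs$x)
  inputs <- inputs[ok, , drop = FALSE]
  n <- nrow(inputs)
  if (n < min_genes) {
    stop("need at least ", min_genes, " genes with finite x and y; got ", n)
  }
  if (any(inputs$y < 0)) stop("'y' must be non-negative")
  if (any(inputs$x <= 0)) stop("'x' must be positive")
  if (stats::var(inputs$x) == 0) stop("zero variance in 'x'")

  fit <- stats::lm(y ~ x, data = inputs)
  # a numerically perfect fit has no residual scale to studentize against;
  # every gene then sits exactly on its expectation
  if (sum(stats::residuals(fit)^2) <= 1e-20 * max(1, sum(inputs$y^2))) {
    res <- rep(0, n)
  } else if (type == "external") {
    res <- stats::rstudent(fit)
  } else {
    res <- stats::rstandard(fit)
  }

  o <- order(res, inputs$gene)
  pct <- numeric(n)
  pct[o] <- 100 * (seq_len(n) - 1) / (n - 1)
  data.frame(
    gene = inputs$gene,
    n_common_functional = inputs$y,
    mutability = inputs$x,
    rvis = as.numeric(res),
    percentile = pct,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compute ancestry-group-specific RVIS from a variant catalog
#'
#' Pipeline wrapper: tallies common functional variants in the requested
#' cohort, joins genes to the mutability table (genes absent from the table
#' are dropped with a warning; genes present in the table but with no
#' qualifying variants keep an informative count of zero), and fits the
#' studentized-residual regression.
#'
#' @inheritParams tally_common_functional
#' @param mutability Mutability table from [read_mutability()] or
#'   [simulate_genes()].
#' @param x_axis `"mutability"` (default) regresses on [genic_mutability()];
#'   `"observed"` regresses on the total number of distinct variant sites
#'   observed in the cohort (the original RVIS covariate).
#' @inheritParams fit_rvis
#' @return A score table as from [fit_rvis()].
#' @export
rvis_scores <- function(variants, mutability, cohort, maf_cutoff = 5e-4,
                        x_axis = c("mutability", "observed"),
                        type = c("external", "internal")) {
  x_axis <- match.arg(x_axis)
  tally <- tally_common_functional(variants, cohort, maf_cutoff)
  y <- tally$n_common_functional[match(mutability$gene, tally$gene)]
  y[is.na(y)] <- 0L

  dropped <- setdiff(unique(variants$gene), mutability$gene)
  if (length(dropped)) {
    warning(length(dropped), " gene(s) missing from the mutability table ",
            "were dropped from RVIS")
  }

  x <- if (x_axis == "mutability") {
    genic_mutability(mutability$mu_mis, mutability$mu_syn, mutability$mu_lof)
  } else {
    obs <- variants[cohort_observed(variants, cohort), , drop = FALSE]
    obs <- obs[!duplicated(variant_site_key(obs)), , drop = FALSE]
    cnt <- table(factor(obs$gene, levels = mutability$gene))
    as.numeric(cnt)
  }
  keep <- is.finite(x) & x > 0
  fit_rvis(data.frame(gene = mutability$gene[keep], y = y[keep], x = x[keep],
                      stringsAsFactors = FALSE),
           type = match.arg(type))
}
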