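#' Define a cohort as a weighted set of ancestry groups
#'
#' A cohort names the ancestry groups whose allele counts are pooled when a
#' metric is trained "on" that cohort. Allele counts and numbers are summed
#' over the member groups, which is exact for disjoint groups (the study
#' design here: each individual belongs to one ancestry group).
#'
#' @param name Cohort name, e.g. `"maximally_diverse"`.
#' @param n_individuals Named integer vector: ancestry label -> number of
#'   individuals. Labels must match the `ac_<label>`/`an_<label>` columns of
#'   the variant table the cohort is applied to.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec("mixed", c(afr = 8701, nfe = 20000))
#' @export
cohort_spec <- function(name, n_individuals) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(n_individuals) == 0 || is.null(names(n_individuals)) ||
      any(!nzchar(names(n_individuals)))) {
    stop("'n_individuals' must be a non-empty named vector")
  }
  if (any(n_individuals <= 0) || any(n_individuals != round(n_individuals))) {
    stop("individual counts must be positive integers")
  }
  structure(
    list(name = name, ancestry_labels = names(n_individuals),
         n_individuals = n_individuals),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec '", x$name, "': ", sum(x$n_individuals),
      " individuals in ", length(x$ancestry_labels), " ancestry group(s)\n",
      sep = "")
  invisible(x)
}

# Resolve a cohort argument (single label or cohort_spec) to its labels,
# checking that the variant table carries the needed ac/an columns.
cohort_labels <- function(variants, cohort) {
  labels <- if (inherits(cohort, "cohort_spec")) {
    cohort$ancestry_labels
  } else if (is.character(cohort)) {
    cohort
  } else {
    stop("'cohort' must be an ancestry label or a cohort_spec")
  }
  missing_cols <- setdiff(
    c(paste0("ac_", labels), paste0("an_", labels)), names(variants)
  )
  if (length(missing_cols)) {
    stop("unknown ancestry label(s): variant table lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  labels
}

# Pooled allele count / allele number over the cohort's groups.
cohort_ac <- function(variants, cohort) {
  labels <- cohort_labels(variants, cohort)
  ac <- as.matrix(variants[, paste0("ac_", labels), drop = FALSE])
  rowSums(ac)
}

cohort_an <- function(variants, cohort) {
  labels <- cohort_labels(variants, cohort)
  an <- as.matrix(variants[, paste0("an_", labels), drop = FALSE])
  rowSums(an)
}

#' Minor allele frequency of each variant within a cohort
#'
#' Pools allele counts over the cohort's ancestry groups and folds the
#' frequency: `maf = min(af, 1 - af)`.
#'
#' @param variants A variant table (see [read_variants()]).
#' @param cohort An ancestry label or a [cohort_spec()].
#' @return Numeric vector of MAFs in `[0, 0.5]`; `NA` where the pooled
#'   allele number is zero.
#' @export
cohort_maf <- function(variants, cohort) {
  ac <- cohort_ac(variants, cohort)
  an <- cohort_an(variants, cohort)
  af <- ifelse(an > 0, ac / an, NA_real_)
  pmin(af, 1 - af)
}

# Which variants are observed (at least one allele) in the cohort.
cohort_observed <- function(variants, cohort = NULL) {
  if (is.null(cohort)) {
    ac_cols <- grep("^ac_", names(variants), value = TRUE)
    if (!length(ac_cols)) stop("variant table has no ac_<label> columns")
    rowSums(as.matrix(variants[, ac_cols, drop = FALSE])) > 0
  } else {
    cohort_ac(variants, cohort) > 0
  }
}

# Distinct-site key within a gene/transcript context.
variant_site_key <- function(variants) {
  paste(variants$gene, variants$transcript, variants$pos,
        variants$ref, variants$alt, sep = "\r")
}
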