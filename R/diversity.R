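#' Look up window MTR scores for a set of variants
#'
#' Matches each variant to the sliding-window MTR score of its codon on
#' its transcript.
#'
#' @param window_scores Output of [sliding_window_scores()].
#' @param variants Data frame with `transcript` and `codon_index` columns
#'   (e.g. a truth set from [simulate_variant_truth_sets()]).
#' @return Numeric vector of window MTR values (`NA` where the codon has
#'   no score), named by `variants$key` when present.
#' @export
window_score_lookup <- function(window_scores, variants) {
  key_ws <- paste(window_scores$transcript, window_scores$codon_index)
  key_v <- paste(variants$transcript, variants$codon_index)
  out <- window_scores$mtr[match(key_v, key_ws)]
  if (!is.null(variants$key)) names(out) <- variants$key
  out
}

#' Ancestral diversity versus sample size experiment
#'
#' Runs the package's central synthetic experiment: with one shared gene
#' set per replicate, three cohorts are drawn from the same simulated
#' catalog -- a maximally diverse multi-ancestry cohort, a single
#' low-diversity (NFE-like) cohort matched to the same total sample size,
#' and the same low-diversity group at ten times the sample size. Each
#' cohort's gene-level MTR is benchmarked (AUC-ROC) against the planted
#' intolerant gene set.
#'
#' @param n_replicates Number of seeded replicates (default 20).
#' @param seed Master seed; replicate r uses `seed + r - 1` as its
#'   simulation seed.
#' @param n_genes Genes per replicate.
#' @param base_config Optional [sim_config()] whose selection and SFS
#'   settings to reuse; ancestry profiles are replaced by the experiment's
#'   seven groups (the five diverse-cohort groups plus the matched and
#'   10x NFE comparators).
#' @return Data frame with one row per replicate: `replicate`,
#'   `auc_diverse`, `auc_matched`, `auc_10x`.
#' @export
diversity_experiment <- function(n_replicates = 20, seed = 1, n_genes = 300,
                                 base_config = sim_config()) {
  mixed_groups <- c(afr = 8701, sas = 9217, eas = 2150, asj = 2671,
                    nfe = 20000)
  ancestry <- data.frame(
    label = c(names(mixed_groups), "nfe_matched", "nfe_10x"),
    n_individuals = c(unname(mixed_groups), sum(mixed_groups) + 1,
                      10 * (sum(mixed_groups) + 1)),
    diversity_scale = c(1.79, 1.30, 1.18, 1.02, 1.00, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
  cohorts <- list(
    diverse = cohort_spec("maximally_diverse", mixed_groups),
    matched = cohort_spec("nfe_matched",
                          c(nfe_matched = sum(mixed_groups) + 1)),
    `10x` = cohort_spec("nfe_10x",
                        c(nfe_10x = 10 * (sum(mixed_groups) + 1)))
  )

  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(
      n_genes = n_genes, ancestry = ancestry,
      intolerant_fraction = base_config$intolerant_fraction,
      selection_strength = base_config$selection_strength,
      sfs_shape = base_config$sfs_shape, maf_sel = base_config$maf_sel,
      pop_scale = base_config$pop_scale, site_rate = base_config$site_rate,
      codon_length_range = base_config$codon_length_range,
      seed = seed + r - 1
    )
    sim <- simulate_genes(cfg)
    catalog <- simulate_catalog(sim, cfg)
    positives <- sim$truth$gene[sim$truth$intolerant]
    aucs <- vapply(cohorts, function(co) {
      scores <- mtr_gene_scores(catalog, sim$mutability, co)
      gene_auc(stats::setNames(scores$mtr, scores$gene), positives)$auc
    }, numeric(1))
    out[[r]] <- data.frame(replicate = r, auc_diverse = aucs[["diverse"]],
                           auc_matched = aucs[["matched"]],
                           auc_10x = aucs[["10x"]])
  }
  do.call(rbind, out)
}
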