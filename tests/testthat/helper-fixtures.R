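# Programmatic fixtures: small variant tables and catalogs built in code.

# One-ancestry variant table. maf entries are converted to allele counts
# against an allele number of 10000.
toy_variants <- function(gene, class, maf, pos = seq_along(gene),
                         label = "afr", an = 10000,
                         codon_index = NULL) {
  consequence <- c(missense = "missense variant",
                   synonymous = "synonymous variant",
                   lof = "stop gained",
                   other = "intron variant")[class]
  n <- length(gene)
  df <- data.frame(
    gene = gene, transcript = paste0("T_", gene),
    pos = pos, ref = rep("A", n), alt = rep("C", n),
    consequence = unname(consequence),
    consequence_class = unname(class),
    codon_index = if (is.null(codon_index)) rep(NA_integer_, n)
                  else codon_index,
    stringsAsFactors = FALSE
  )
  df[[paste0("ac_", label)]] <- round(maf * an)
  df[[paste0("an_", label)]] <- rep(an, n)
  df[[paste0("af_", label)]] <- round(maf * an) / an
  df
}

# Small config for fast generator tests: few genes, small cohorts.
small_sim_config <- function(seed = 1, n_genes = 80,
                             intolerant_fraction = 0.2,
                             selection_strength = c(missense = 0.3,
                                                    lof = 0.15),
                             ancestry = data.frame(
                               label = c("hi", "lo"),
                               n_individuals = c(4000, 4000),
                               diversity_scale = c(1.8, 1.0)
                             ),
                             ...) {
  sim_config(n_genes = n_genes, ancestry = ancestry,
             intolerant_fraction = intolerant_fraction,
             selection_strength = selection_strength,
             codon_length_range = c(150, 1200), seed = seed, ...)
}
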