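test_that("the generator is fully reproducible under a fixed seed", {
  cfg <- small_sim_config(seed = 101, n_genes = 30)
  sim1 <- simulate_genes(cfg)
  sim2 <- simulate_genes(cfg)
  expect_identical(sim1$genes, sim2$genes)
  expect_identical(sim1$mutability, sim2$mutability)
  expect_identical(simulate_catalog(sim1), simulate_catalog(sim2))
})

test_that("simulated CDS are valid and mutability tracks gene length", {
  cfg <- sim_config(n_genes = 1000, seed = 13)
  sim <- simulate_genes(cfg)
  n_codons <- nchar(sim$genes$cds) / 3
  expect_true(all(nchar(sim$genes$cds) %% 3 == 0))
  expect_true(all(substr(sim$genes$cds, 1, 3) == "ATG"))
  expect_true(all(n_codons >= 150 & n_codons <= 3000))
  # no internal stop codons: zero possible synonymous sites on stops would
  # break the enumeration check, so scan directly
  has_stop <- vapply(sim$genes$cds[1:20], function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(has_stop))

  mu_total <- genic_mutability(sim$mutability$mu_mis, sim$mutability$mu_syn,
                               sim$mutability$mu_lof)
  expect_gt(stats::cor(mu_total, n_codons), 0.8)
})

test_that("an intolerant fraction of zero plants no intolerant genes", {
  cfg <- small_sim_config(seed = 3, n_genes = 25, intolerant_fraction = 0)
  sim <- simulate_genes(cfg)
  expect_false(any(sim$truth$intolerant))
})

test_that("emitted catalogs satisfy the variant-table invariants", {
  cfg <- small_sim_config(seed = 19, n_genes = 40)
  sim <- simulate_genes(cfg)
  catalog <- simulate_catalog(sim)
  for (lab in cfg$ancestry$label) {
    ac <- catalog[[paste0("ac_", lab)]]
    an <- catalog[[paste0("an_", lab)]]
    af <- catalog[[paste0("af_", lab)]]
    expect_true(all(ac >= 0 & ac <= an))
    expect_true(all(abs(af - ac / an) < 1e-12))
  }
  expect_identical(catalog$consequence_class,
                   classify_consequence(catalog$consequence))
  # distinct sites within each transcript
  key <- paste(catalog$transcript, catalog$pos, catalog$ref, catalog$alt)
  expect_equal(anyDuplicated(key), 0L)
  # every site observed somewhere
  expect_true(all(rowSums(catalog[, paste0("ac_", cfg$ancestry$label)]) > 0))
})

test_that("truth counts round-trip against the emitted catalog", {
  cfg <- small_sim_config(seed = 23, n_genes = 30)
  sim <- simulate_genes(cfg)
  catalog <- simulate_catalog(sim)
  truth <- attr(catalog, "truth_counts")
  for (i in sample(nrow(truth), 25)) {
    lab <- truth$ancestry[i]
    got <- sum(catalog[[paste0("ac_", lab)]] > 0 &
                 catalog$gene == truth$gene[i] &
                 catalog$consequence_class ==
                   c(missense = "missense", synonymous = "synonymous",
                     lof = "lof")[truth$class[i]])
    expect_equal(got, truth$n_sites[i])
  }
})

test_that("without selection, planted genes are exchangeable with the rest", {
  cfg <- small_sim_config(seed = 29, n_genes = 300,
                          intolerant_fraction = 0.5,
                          selection_strength = c(missense = 1, lof = 1),
                          ancestry = data.frame(label = "one",
                                                n_individuals = 4000,
                                                diversity_scale = 1))
  sim <- simulate_genes(cfg)
  catalog <- simulate_catalog(sim)
  tal <- tally_common_functional(catalog, "one")
  counts <- tal$n_common_functional[match(sim$truth$gene, tal$gene)]
  counts[is.na(counts)] <- 0
  # length-matched comparison: regress out mutability, test the residuals
  mu <- genic_mutability(sim$mutability$mu_mis, sim$mutability$mu_syn,
                         sim$mutability$mu_lof)
  res <- stats::residuals(stats::lm(counts ~ mu))
  p <- stats::wilcox.test(res[sim$truth$intolerant],
                          res[!sim$truth$intolerant])$p.value
  expect_gt(p, 0.01)
})

test_that("doubling the diversity scale increases common functional counts", {
  base_anc <- function(theta) data.frame(label = "one",
                                         n_individuals = 4000,
                                         diversity_scale = theta)
  for (seed in c(31, 32, 33)) {
    totals <- vapply(c(1, 2), function(theta) {
      cfg <- small_sim_config(seed = seed, n_genes = 60,
                              intolerant_fraction = 0,
                              ancestry = base_anc(theta))
      sim <- simulate_genes(cfg)
      sum(tally_common_functional(simulate_catalog(sim),
                                  "one")$n_common_functional)
    }, numeric(1))
    expect_gt(totals[2], totals[1])
  }
})

test_that("common variants saturate with n while rare variants keep growing", {
  counts_at_n <- function(n) {
    cfg <- small_sim_config(seed = 37, n_genes = 100, intolerant_fraction = 0,
                            ancestry = data.frame(label = "one",
                                                  n_individuals = n,
                                                  diversity_scale = 1))
    sim <- simulate_genes(cfg)
    catalog <- simulate_catalog(sim)
    maf <- cohort_maf(catalog, "one")
    functional <- catalog$consequence_class %in% c("missense", "lof")
    c(common = sum(functional & maf > 5e-4),
      rare = sum(functional & maf <= 5e-4))
  }
  tallies <- vapply(c(5000, 20000, 80000), counts_at_n, numeric(2))
  expect_lt(abs(tallies["common", 3] - tallies["common", 1]),
            0.25 * tallies["common", 1])
  expect_gt(tallies["rare", 2], tallies["rare", 1])
  expect_gt(tallies["rare", 3], 1.5 * tallies["rare", 1])
})

test_that("a mixed high+low diversity cohort yields more distinct functional sites
          than a low-diversity cohort of the same total size", {
  mixed_cfg <- small_sim_config(seed = 41, n_genes = 60,
                                intolerant_fraction = 0,
                                ancestry = data.frame(
                                  label = c("hi", "lo"),
                                  n_individuals = c(4000, 4000),
                                  diversity_scale = c(1.8, 1.0)
                                ))
  single_cfg <- small_sim_config(seed = 41, n_genes = 60,
                                 intolerant_fraction = 0,
                                 ancestry = data.frame(
                                   label = "lo",
                                   n_individuals = 8000,
                                   diversity_scale = 1.0
                                 ))
  n_functional <- function(cfg, cohort) {
    sim <- simulate_genes(cfg)
    catalog <- simulate_catalog(sim)
    obs <- catalog[cohort_observed(catalog, cohort), ]
    sum(obs$consequence_class %in% c("missense", "lof"))
  }
  mixed <- n_functional(mixed_cfg, cohort_spec("mix", c(hi = 4000, lo = 4000)))
  single <- n_functional(single_cfg, "lo")
  expect_gt(mixed, single)
})

test_that("variant truth sets have exact sizes and the planted signal", {
  # a deeply sampled catalog (3x the default population scale) puts enough
  # observations in each window for the limiting-case contrast to show
  cfg <- small_sim_config(seed = 43, n_genes = 60,
                          selection_strength = c(missense = 0.05, lof = 0.05),
                          pop_scale = 9e4)
  sim <- simulate_genes(cfg)
  catalog <- simulate_catalog(sim)
  sets <- simulate_variant_truth_sets(sim, n_pathogenic = 150, n_benign = 150)
  expect_equal(nrow(sets$pathogenic), 150)
  expect_equal(nrow(sets$benign), 150)
  expect_true(all(sets$pathogenic$gene %in%
                    sim$truth$gene[sim$truth$intolerant]))
  expect_true(all(sets$benign$gene %in%
                    sim$truth$gene[!sim$truth$intolerant]))

  cds <- stats::setNames(sim$genes$cds, sim$genes$transcript)
  windows <- sliding_window_scores(cds, catalog,
                                   cohort_spec("all", c(hi = 4000, lo = 4000)))
  scores <- c(window_score_lookup(windows, sets$pathogenic),
              window_score_lookup(windows, sets$benign))
  res <- variant_auc_balanced(scores, sets$pathogenic$key, sets$benign$key,
                              seed = 11)
  expect_gt(mean(res$auc), 0.75)  # strong suppression: near-separable

  # null: no planted genes, both sets drawn from the same distribution
  cfg0 <- small_sim_config(seed = 47, n_genes = 60, intolerant_fraction = 0)
  sim0 <- simulate_genes(cfg0)
  catalog0 <- simulate_catalog(sim0)
  sets0 <- simulate_variant_truth_sets(sim0, 150, 150)
  windows0 <- sliding_window_scores(
    stats::setNames(sim0$genes$cds, sim0$genes$transcript), catalog0,
    cohort_spec("all", c(hi = 4000, lo = 4000))
  )
  scores0 <- c(window_score_lookup(windows0, sets0$pathogenic),
               window_score_lookup(windows0, sets0$benign))
  res0 <- variant_auc_balanced(scores0, sets0$pathogenic$key,
                               sets0$benign$key, seed = 13)
  expect_lt(abs(mean(res0$auc) - 0.5), 0.1)
})
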