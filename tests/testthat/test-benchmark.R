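named_scores <- function(values) {
  stats::setNames(values, sprintf("G%03d", seq_along(values)))
}

test_that("gene AUC matches exhaustive pair counting on fixed cases", {
  s <- named_scores(c(0.9, 0.8, 0.2, 0.1))
  res <- gene_auc(s, positives = c("G001", "G002"))
  expect_equal(res$auc, 1.0)
  expect_equal(res$orientation, "higher_risk")

  flat <- gene_auc(named_scores(rep(1.7, 10)),
                   positives = c("G001", "G002", "G003"))
  expect_equal(flat$auc, 0.5)

  mixed <- gene_auc(named_scores(c(3, 1, 2, 0)),
                    positives = c("G001", "G002"))
  expect_equal(mixed$auc, 0.75)  # 3 of 4 pairs concordant
})

test_that("logistic-fit AUC equals the Mann-Whitney AUC on random instances", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    scores <- named_scores(stats::rnorm(n))
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties sometimes
    pos <- sample(names(scores), sample(3:(n - 3), 1))
    res <- gene_auc(scores, pos)
    y <- names(scores) %in% pos
    mw <- oracle_pair_auc(unname(scores), y)
    expect_equal(res$auc, max(mw, 1 - mw), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(73)
  scores <- named_scores(stats::rnorm(40))
  pos <- sample(names(scores), 12)
  base <- gene_auc(scores, pos)$auc
  for (f in list(function(x) exp(x), function(x) 5 * x - 2,
                 function(x) x^3 + x)) {
    expect_equal(gene_auc(f(scores), pos)$auc, base, tolerance = 1e-12)
  }
})

test_that("gene AUC enforces class and universe contracts", {
  scores <- named_scores(1:10)
  expect_error(gene_auc(scores, positives = "ABSENT"), "universe")
  scores2 <- scores
  scores2[1:3] <- NA
  expect_error(gene_auc(scores2, positives = c("G001", "G002", "G003")),
               "empty")
})

test_that("DeLong self- and monotone-transform comparisons are null", {
  set.seed(79)
  scores <- named_scores(stats::rnorm(50))
  pos <- sample(names(scores), 15)
  self <- delong_test(scores, scores, pos)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  mono <- delong_test(scores, exp(scores) + 2, pos)
  expect_equal(mono$auc_a, mono$auc_b, tolerance = 1e-12)
  expect_equal(mono$p, 1)
})

test_that("DeLong p agrees with a stratified bootstrap oracle", {
  set.seed(7)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  latent <- stats::rnorm(n, mean = ifelse(y, 0.9, 0))
  a <- latent + stats::rnorm(n, sd = 0.8)
  b <- latent + stats::rnorm(n, sd = 1.2)
  scores_a <- stats::setNames(a, sprintf("G%03d", 1:n))
  scores_b <- stats::setNames(b, sprintf("G%03d", 1:n))
  res <- delong_test(scores_a, scores_b, names(scores_a)[y], orient = "none")

  auc_of <- function(s, lab) {
    r <- rank(s)
    np <- sum(lab)
    (sum(r[lab]) - np * (np + 1) / 2) / (np * sum(!lab))
  }
  d_obs <- auc_of(a, y) - auc_of(b, y)
  pos_i <- which(y); neg_i <- which(!y)
  boots <- vapply(1:20000, function(i) {
    idx <- c(sample(pos_i, replace = TRUE), sample(neg_i, replace = TRUE))
    auc_of(a[idx], y[idx]) - auc_of(b[idx], y[idx])
  }, numeric(1))
  p_boot <- 2 * stats::pnorm(-abs(d_obs) / stats::sd(boots))
  expect_lt(abs(res$p - p_boot), 0.02)
})

test_that("DeLong p-values are near-uniform under label permutation", {
  set.seed(83)
  n <- 80
  a <- named_scores(stats::rnorm(n))
  b <- stats::setNames(stats::rnorm(n), names(a))
  pvals <- vapply(1:500, function(i) {
    pos <- sample(names(a), 30)
    delong_test(a, b, pos, orient = "none")$p
  }, numeric(1))
  # incidental duplicate p-values trigger the KS tie warning; harmless here
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("balanced variant AUC is deterministic, sound on edge cases", {
  scores <- stats::setNames(stats::runif(40), paste0("v", 1:40))
  path <- paste0("v", 1:10)
  benign <- paste0("v", 11:40)

  r1 <- variant_auc_balanced(scores, path, benign, seed = 11)
  r2 <- variant_auc_balanced(scores, path, benign, seed = 11)
  expect_identical(r1, r2)  # bit-reproducible under a fixed seed
  expect_length(r1$auc, 10)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))

  # equal class sizes: no down-sampling randomness at all
  r_eq <- variant_auc_balanced(scores, paste0("v", 1:10), paste0("v", 11:20),
                               seed = 5)
  expect_equal(length(unique(r_eq$auc)), 1L)

  # complete separation: pathogenic strictly below benign
  sep <- stats::setNames(c(stats::runif(8, 0, 0.3), stats::runif(20, 0.5, 1)),
                         paste0("v", 1:28))
  r_sep <- variant_auc_balanced(sep, paste0("v", 1:8), paste0("v", 9:28),
                                seed = 3)
  expect_true(all(r_sep$auc == 1))

  expect_error(variant_auc_balanced(scores, character(0), benign), "empty")
})

test_that("balanced AUC mean tracks the full-data rank AUC", {
  set.seed(89)
  path_scores <- stats::rnorm(60, mean = -0.8)
  benign_scores <- stats::rnorm(300, mean = 0)
  scores <- stats::setNames(c(path_scores, benign_scores),
                            paste0("v", 1:360))
  res <- variant_auc_balanced(scores, paste0("v", 1:60),
                              paste0("v", 61:360), seed = 11)
  y <- rep(c(TRUE, FALSE), c(60, 300))
  full <- oracle_pair_auc(-c(path_scores, benign_scores), y)
  expect_lt(abs(mean(res$auc) - full), 0.05)
})

test_that("control-set construction follows the stated set algebra", {
  cohort <- paste0("v", 1:10)
  ref_a <- paste0("v", 8:12)   # overlaps cohort by 3
  ref_b <- paste0("v", c(1, 11, 20, 21))
  ctrl <- build_control_sets(cohort, ref_a, ref_b)
  expect_setequal(ctrl$tier1, c("v11", "v12"))
  expect_setequal(ctrl$tier2, c("v20", "v21"))

  # reference contained in the cohort: empty tier
  expect_length(build_control_sets(cohort, paste0("v", 2:4),
                                   character(0))$tier1, 0)
  # disjoint sets: the whole reference survives
  expect_setequal(build_control_sets(paste0("a", 1:3), paste0("b", 1:5),
                                     character(0))$tier1, paste0("b", 1:5))
})
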