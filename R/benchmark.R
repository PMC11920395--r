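# Rank (Mann-Whitney) AUC with the midrank tie convention: ties count 0.5.
rank_auc <- function(score, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  stopifnot(n_pos > 0, n_neg > 0)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

benchmark_classes <- function(scores, positives, universe) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (is.null(universe)) universe <- names(scores)
  extra <- setdiff(positives, universe)
  if (length(extra)) {
    stop("positives not contained in the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  s <- scores[intersect(universe, names(scores))]
  s <- s[!is.na(s)]
  y <- names(s) %in% positives
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("a class is empty after dropping genes with missing scores")
  }
  list(score = unname(s), positive = y, genes = names(s))
}

#' Gene-level AUC via single-predictor logistic regression
#'
#' Fits a logistic regression of disease-gene status on the gene-level
#' score and reports the AUC-ROC of the fitted probabilities, which by
#' monotonicity of the logistic link equals the rank AUC of the raw score.
#' The score orientation is auto-resolved so that the reported AUC is at
#' least 0.5, and the direction treated as risk-like is recorded (RVIS and
#' O/E mark intolerance with low values; other metrics may be reversed).
#'
#' @param scores Named numeric vector, gene symbol -> score. `NA` scores
#'   are dropped from both classes.
#' @param positives Character vector of disease-associated gene symbols
#'   (must be contained in the universe).
#' @param universe Gene universe defining the negative class
#'   (universe minus positives); defaults to all scored genes.
#' @param score_name,gene_set_name Labels carried into the result.
#' @return A one-row data frame: `score_name`, `gene_set_name`, `auc`,
#'   `n_pos`, `n_neg`, `orientation` (`"higher_risk"` or `"lower_risk"`).
#' @export
gene_auc <- function(scores, positives, universe = NULL,
                     score_name = "score", gene_set_name = "gene_set") {
  cls <- benchmark_classes(scores, positives, universe)
  y <- as.integer(cls$positive)
  fitted <- if (stats::var(cls$score) == 0) {
    rep(0.5, length(y))  # uninformative predictor
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ s, family = stats::binomial(),
                 data = data.frame(y = y, s = cls$score))
    )
    # evaluate the link deterministically so tied scores stay exactly tied
    # (IRLS fitted values can differ by an ulp between tied rows)
    beta <- stats::coef(fit)
    stats::plogis(beta[1] + beta[2] * cls$score)
  }
  auc <- rank_auc(fitted, cls$positive)
  orientation <- if (rank_auc(cls$score, cls$positive) >= 0.5) {
    "higher_risk"
  } else {
    "lower_risk"
  }
  if (auc < 0.5) auc <- 1 - auc
  data.frame(score_name = score_name, gene_set_name = gene_set_name,
             auc = auc, n_pos = sum(cls$positive),
             n_neg = sum(!cls$positive), orientation = orientation,
             stringsAsFactors = FALSE)
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two gene-level scores over the
#' intersection of genes both scores cover, using DeLong's nonparametric
#' covariance estimate. Each score is first oriented so its AUC is at
#' least 0.5 (predictive ability is compared, not sign conventions).
#'
#' @param scores_a,scores_b Named numeric score vectors.
#' @inheritParams gene_auc
#' @param min_genes Minimum shared coverage required.
#' @param orient `"auto"` (default) flips each score so its AUC is at
#'   least 0.5 before comparing; `"none"` compares the scores as given
#'   (appropriate when the risk direction is fixed a priori, e.g. in
#'   permutation analyses).
#' @return A one-row data frame: `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, positives, universe = NULL,
                        min_genes = 10, orient = c("auto", "none")) {
  orient <- match.arg(orient)
  shared <- intersect(names(scores_a)[!is.na(scores_a)],
                      names(scores_b)[!is.na(scores_b)])
  if (is.null(universe)) universe <- shared
  shared <- intersect(shared, universe)
  if (length(shared) < min_genes) {
    stop("fewer than ", min_genes, " genes scored by both metrics")
  }
  positives <- intersect(positives, shared)
  a <- scores_a[shared]
  b <- scores_b[shared]
  y <- shared %in% positives
  if (sum(y) == 0 || sum(!y) == 0) stop("a class is empty")

  if (orient == "auto") {
    flip <- function(s) if (rank_auc(s, y) >= 0.5) s else -s
    a <- flip(a)
    b <- flip(b)
  }
  auc_a <- rank_auc(a, y)
  auc_b <- rank_auc(b, y)

  if (identical(rank(a), rank(b))) {
    z <- 0; p <- 1
  } else {
    roc_a <- pROC::roc(response = y, predictor = a, direction = "<",
                       quiet = TRUE)
    roc_b <- pROC::roc(response = y, predictor = b, direction = "<",
                       quiet = TRUE)
    tst <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
    z <- unname(tst$statistic)
    p <- unname(tst$p.value)
    if (!is.finite(z)) {  # zero-variance difference with equal AUCs
      z <- 0; p <- 1
    }
  }
  data.frame(auc_a = auc_a, auc_b = auc_b, z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Variant-level AUC with balanced down-sampling
#'
#' Compares sliding-window MTR values of pathogenic versus benign variant
#' sets. Because the two sets are usually imbalanced, the larger one is
#' randomly down-sampled (without replacement) to the size of the smaller,
#' and the AUC is recomputed over `iterations` independent down-samples.
#' Higher MTR is treated as evidence that a variant is benign, so the
#' reported AUC is the probability that a random pathogenic variant has a
#' lower score than a random benign one. Each iteration uses its own seed
#' derived from `seed`, so any iteration is reproducible in isolation.
#'
#' @param scores Named numeric vector, variant key -> window MTR.
#' @param pathogenic,benign Character vectors of variant keys. Variants
#'   lacking a (non-`NA`) score are dropped.
#' @param iterations Number of down-sampling iterations (default 10).
#' @param seed Master seed.
#' @return List with `auc` (length-`iterations` numeric), `n_per_class`,
#'   `iteration_seeds` and `seed`.
#' @export
variant_auc_balanced <- function(scores, pathogenic, benign,
                                 iterations = 10, seed = 1) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  scored <- names(scores)[!is.na(scores)]
  pathogenic <- intersect(pathogenic, scored)
  benign <- intersect(benign, scored)
  if (!length(pathogenic) || !length(benign)) {
    stop("a variant class is empty after dropping unscored variants")
  }
  n <- min(length(pathogenic), length(benign))
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, iterations)
  auc <- vapply(seq_len(iterations), function(k) {
    set.seed(iter_seeds[k])
    p <- if (length(pathogenic) > n) sample(pathogenic, n) else pathogenic
    b <- if (length(benign) > n) sample(benign, n) else benign
    # pathogenic is the positive class; low MTR should rank it first
    rank_auc(-scores[c(p, b)], rep(c(TRUE, FALSE), each = n))
  }, numeric(1))
  list(auc = auc, n_per_class = n, iteration_seeds = iter_seeds, seed = seed)
}

#' Construct benign control variant sets by catalog differences
#'
#' Benign controls are defined in two tiers against a study cohort:
#' tier 1 is the first reference catalog minus the cohort, and tier 2 is
#' the second reference catalog minus both the cohort and the first
#' reference. Variant identity is whatever key the caller supplies
#' (e.g. `"chrom:pos:ref:alt"` or `"transcript:codon:alt_aa"`), and must
#' be produced the same way for all three inputs.
#'
#' @param cohort_keys,reference_a_keys,reference_b_keys Character vectors
#'   of variant identity keys.
#' @return List with character vectors `tier1` and `tier2`.
#' @export
build_control_sets <- function(cohort_keys, reference_a_keys,
                               reference_b_keys) {
  for (v in list(cohort_keys, reference_a_keys, reference_b_keys)) {
    if (!is.character(v)) stop("variant keys must be character vectors")
  }
  list(
    tier1 = setdiff(reference_a_keys, cohort_keys),
    tier2 = setdiff(reference_b_keys, union(cohort_keys, reference_a_keys))
  )
}
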