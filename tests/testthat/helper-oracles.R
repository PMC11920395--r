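# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force refits, pmf summation, O(m^2)
# step-up, exhaustive pair counting.

# Leave-one-out (externally) studentized residuals by explicit refit:
# drop point i, refit, and scale the prediction error of y_i by its
# estimated standard deviation under the reduced model.
oracle_loo_studentized <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    xi <- x[-i]; yi <- y[-i]
    fit <- stats::lm(yi ~ xi)
    s2 <- sum(stats::residuals(fit)^2) / (length(xi) - 2)
    xbar <- mean(xi)
    sxx <- sum((xi - xbar)^2)
    pred_var <- s2 * (1 + 1 / length(xi) + (x[i] - xbar)^2 / sxx)
    (y[i] - stats::predict(fit, data.frame(xi = x[i]))) / sqrt(pred_var)
  }, numeric(1))
}

# Lower-tail binomial probability by direct pmf summation.
oracle_binom_lower <- function(obs, total, p) {
  k <- 0:obs
  sum(choose(total, k) * p^k * (1 - p)^(total - k))
}

# O(m^2) Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Mann-Whitney AUC by exhaustive pair comparison (ties count 0.5).
oracle_pair_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Whole-window MTR rebuilt from scratch for one codon: filter variants to
# the boundary-anchored full-width window, count classes, enumerate
# expectations codon by codon.
oracle_window_mtr <- function(cds, variants, center, window) {
  half <- (window - 1) / 2
  n_codons <- nchar(cds) / 3
  span <- min(window, n_codons)
  lo <- min(max(1, center - half), n_codons - span + 1)
  hi <- lo + span - 1
  in_win <- variants[variants$codon_index >= lo &
                       variants$codon_index <= hi, , drop = FALSE]
  key <- paste(in_win$codon_index, in_win$pos, in_win$ref, in_win$alt)
  in_win <- in_win[!duplicated(key), , drop = FALSE]
  mo <- sum(in_win$consequence_class == "missense")
  so <- sum(in_win$consequence_class == "synonymous")
  me <- 0; se <- 0
  gc <- Biostrings::GENETIC_CODE
  for (c_i in lo:hi) {
    codon <- substr(cds, 3 * c_i - 2, 3 * c_i)
    aa <- gc[[codon]]
    for (p in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- alt
        aa2 <- gc[[mut]]
        if (aa2 == aa) se <- se + 1
        else if (aa2 != "*") me <- me + 1
      }
    }
  }
  if (mo + so == 0 || me == 0) return(NA_real_)
  (mo / (mo + so)) / (me / (me + se))
}
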