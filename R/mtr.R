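# Saturation-enumeration lookup tables for the 64 codons. For each codon,
# the 9 possible single-nucleotide substitutions (3 positions x 3 alternate
# bases, alternates in A<C<G<T order) are classified against the standard
# genetic code: silent -> synonymous, stop-introducing -> nonsense,
# amino-acid-changing -> missense. Built once at load; substitution j of
# codon code k is j = (pos - 1) * 3 + alt_rank.
.codon_bases <- c("A", "C", "G", "T")

.codon_tables <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- expand.grid(b3 = .codon_bases, b2 = .codon_bases,
                        b1 = .codon_bases, stringsAsFactors = FALSE)
  codons <- paste0(codons$b1, codons$b2, codons$b3)  # code = 16(b1)+4(b2)+b3
  cls <- matrix(0L, nrow = 64, ncol = 9)  # 1 = missense, 2 = syn, 3 = nonsense
  alt_base <- matrix("", nrow = 64, ncol = 9)
  sub_pos <- matrix(0L, nrow = 64, ncol = 9)
  for (k in seq_len(64)) {
    ref_codon <- codons[k]
    ref_aa <- gc[[ref_codon]]
    j <- 0L
    for (p in 1:3) {
      ref_base <- substr(ref_codon, p, p)
      for (alt in setdiff(.codon_bases, ref_base)) {
        j <- j + 1L
        mut <- ref_codon
        substr(mut, p, p) <- alt
        aa <- gc[[mut]]
        cls[k, j] <- if (aa == ref_aa) 2L else if (aa == "*" &&
                                                   ref_aa != "*") 3L else 1L
        alt_base[k, j] <- alt
        sub_pos[k, j] <- p
      }
    }
  }
  counts <- cbind(
    missense = rowSums(cls == 1L),
    synonymous = rowSums(cls == 2L),
    nonsense = rowSums(cls == 3L)
  )
  list(codons = codons, class = cls, counts = counts,
       alt_base = alt_base, sub_pos = sub_pos)
})

# Validate a CDS and return the 1..64 codon code of each codon.
cds_codon_codes <- function(cds_sequence) {
  if (!is.character(cds_sequence) || length(cds_sequence) != 1 ||
      !nzchar(cds_sequence)) {
    stop("'cds_sequence' must be a single non-empty string")
  }
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3, got ", n)
  chars <- strsplit(cds_sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, .codon_bases)
  if (anyNA(idx)) {
    stop("CDS contains non-ACGT character '", chars[which(is.na(idx))[1]], "'")
  }
  m <- matrix(idx - 1L, nrow = 3)
  as.integer(16L * m[1, ] + 4L * m[2, ] + m[3, ] + 1L)
}

#' Enumerate possible single-nucleotide substitutions per codon
#'
#' For each codon of a CDS, counts how many of the 9 possible
#' single-nucleotide substitutions are missense, synonymous
#' (silent), or nonsense (stop-introducing) under the standard genetic
#' code. These counts are the expectation terms of the sliding-window
#' missense tolerance ratio.
#'
#' @param cds_sequence A single nucleotide string (A/C/G/T, length a
#'   multiple of 3).
#' @return Data frame with columns `codon_index`, `possible_missense`,
#'   `possible_synonymous`, `possible_nonsense`; the three counts sum to 9
#'   on every row.
#' @examples
#' enumerate_possible("ATGTAC")
#' @export
enumerate_possible <- function(cds_sequence) {
  codes <- cds_codon_codes(cds_sequence)
  cnt <- .codon_tables$counts[codes, , drop = FALSE]
  data.frame(
    codon_index = seq_along(codes),
    possible_missense = as.integer(cnt[, "missense"]),
    possible_synonymous = as.integer(cnt[, "synonymous"]),
    possible_nonsense = as.integer(cnt[, "nonsense"]),
    row.names = NULL
  )
}

#' Missense tolerance ratio
#'
#' The observed missense fraction (among observed missense + synonymous
#' variants) divided by its neutral expectation:
#' `[mo / (mo + so)] / [me / (me + se)]`. Values below 1 indicate missense
#' depletion. The score is undefined (`NA`) when nothing was observed or
#' the expected missense fraction is zero.
#'
#' @param missense_obs,synonymous_obs Observed distinct-site counts.
#' @param missense_exp,synonymous_exp Expected counts or rates (any common
#'   positive scale; the ratio is scale-invariant).
#' @return Numeric vector of ratios (vectorized over all four arguments).
#' @export
mtr_ratio <- function(missense_obs, synonymous_obs,
                      missense_exp, synonymous_exp) {
  if (any(missense_obs < 0 | synonymous_obs < 0, na.rm = TRUE) ||
      any(missense_exp < 0 | synonymous_exp < 0, na.rm = TRUE)) {
    stop("counts and expectations must be non-negative")
  }
  obs_total <- missense_obs + synonymous_obs
  exp_total <- missense_exp + synonymous_exp
  exp_frac <- ifelse(exp_total > 0, missense_exp / exp_total, NA_real_)
  ifelse(obs_total > 0 & !is.na(exp_frac) & exp_frac > 0,
         (missense_obs / obs_total) / exp_frac,
         NA_real_)
}

# Distinct (site) rows of a per-transcript variant slice.
dedupe_sites <- function(variants) {
  cols <- intersect(c("codon_index", "pos", "ref", "alt"), names(variants))
  key <- do.call(paste, c(variants[cols], sep = "\r"))
  variants[!duplicated(key), , drop = FALSE]
}

#' Sliding-window missense tolerance ratio
#'
#' Computes the MTR for every codon of a transcript over a window of
#' `window_codons` codons centred on that codon. Near the transcript ends
#' the window is anchored to the boundary but keeps its full width, so
#' every codon is scored from `min(window_codons, n_codons)` codons and a
#' transcript no longer than the window gives every codon the
#' whole-transcript score. Observed counts are distinct
#' missense/synonymous sites whose
#' `codon_index` falls in the window; expected counts are sums of the
#' per-codon possible-substitution enumeration. Windows with no observed
#' variants yield `NA`.
#'
#' @param cds_sequence CDS nucleotide string of the transcript.
#' @param variants Variant records of this transcript; must carry
#'   `codon_index` and `consequence_class`.
#' @param window_codons Odd window width in codons (default 31).
#' @return Data frame with one row per codon: `codon_index`, `mtr`,
#'   `n_mis_obs`, `n_syn_obs`, `exp_mis`, `exp_syn`, `window_start`,
#'   `window_end`.
#' @export
sliding_window_mtr <- function(cds_sequence, variants, window_codons = 31) {
  if (window_codons %% 2 != 1 || window_codons < 1) {
    stop("'window_codons' must be a positive odd integer")
  }
  possible <- enumerate_possible(cds_sequence)
  n_codons <- nrow(possible)

  stopifnot(is.data.frame(variants))
  if (nrow(variants) > 0) {
    if (!"codon_index" %in% names(variants) || anyNA(variants$codon_index)) {
      stop("all variants must carry a codon_index")
    }
    if (any(variants$codon_index < 1 | variants$codon_index > n_codons)) {
      stop("variant codon_index outside the transcript (1..", n_codons, ")")
    }
    variants <- dedupe_sites(variants)
  }

  per_codon <- function(class) {
    if (nrow(variants) == 0) return(integer(n_codons))
    tabulate(variants$codon_index[variants$consequence_class == class],
             nbins = n_codons)
  }
  obs_mis <- per_codon("missense")
  obs_syn <- per_codon("synonymous")

  half <- (window_codons - 1) / 2
  span <- min(window_codons, n_codons)
  idx <- seq_len(n_codons)
  ws <- pmin(pmax(1L, idx - half), n_codons - span + 1L)
  we <- ws + span - 1L
  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[we + 1] - cs[ws]
  }
  data.frame(
    codon_index = idx,
    mtr = mtr_ratio(wsum(obs_mis), wsum(obs_syn),
                    wsum(possible$possible_missense),
                    wsum(possible$possible_synonymous)),
    n_mis_obs = as.integer(wsum(obs_mis)),
    n_syn_obs = as.integer(wsum(obs_syn)),
    exp_mis = as.integer(wsum(possible$possible_missense)),
    exp_syn = as.integer(wsum(possible$possible_synonymous)),
    window_start = ws,
    window_end = we,
    row.names = NULL
  )
}

#' Gene-level missense tolerance ratio
#'
#' Whole-transcript MTR for one gene. The expectation comes either from the
#' gene's mutability components (`expectation = "mutability"`, the default)
#' or from saturation enumeration of the CDS
#' (`expectation = "enumeration"`).
#'
#' @param variants Variant records of the gene (distinct sites are counted
#'   once; only missense and synonymous classes enter the score).
#' @param mu_mis,mu_syn Mutability components (mutability mode).
#' @param cds_sequence CDS string (enumeration mode).
#' @param expectation Expectation source.
#' @return A single MTR value (`NA` when undefined).
#' @export
gene_mtr <- function(variants, mu_mis = NULL, mu_syn = NULL,
                     cds_sequence = NULL,
                     expectation = c("mutability", "enumeration")) {
  expectation <- match.arg(expectation)
  v <- dedupe_sites(variants)
  mo <- sum(v$consequence_class == "missense")
  so <- sum(v$consequence_class == "synonymous")
  if (expectation == "mutability") {
    if (is.null(mu_mis) || is.null(mu_syn)) {
      stop("mutability mode needs 'mu_mis' and 'mu_syn'")
    }
    mtr_ratio(mo, so, mu_mis, mu_syn)
  } else {
    if (is.null(cds_sequence)) stop("enumeration mode needs 'cds_sequence'")
    possible <- enumerate_possible(cds_sequence)
    mtr_ratio(mo, so, sum(possible$possible_missense),
              sum(possible$possible_synonymous))
  }
}

#' Gene-level MTR scores for a cohort
#'
#' Pipeline wrapper: restricts the catalog to sites observed in the cohort,
#' counts distinct missense and synonymous sites per gene, and scores each
#' gene against its mutability-derived expected missense fraction.
#' Percentiles run from 0 (most missense-depleted) to 100.
#'
#' @inheritParams rvis_scores
#' @param cohort Ancestry label or [cohort_spec()]; `NULL` uses sites
#'   observed in any group.
#' @return Data frame: `gene`, `n_mis_obs`, `n_syn_obs`,
#'   `expected_fraction`, `mtr`, `percentile`.
#' @export
mtr_gene_scores <- function(variants, mutability, cohort = NULL) {
  obs <- variants[cohort_observed(variants, cohort), , drop = FALSE]
  obs <- obs[!duplicated(variant_site_key(obs)), , drop = FALSE]
  genes <- mutability$gene
  cnt <- function(class) {
    as.integer(table(factor(obs$gene[obs$consequence_class == class],
                            levels = genes)))
  }
  n_mis <- cnt("missense")
  n_syn <- cnt("synonymous")
  exp_frac <- expected_missense_fraction(mutability$mu_mis, mutability$mu_syn)
  mtr <- mtr_ratio(n_mis, n_syn, mutability$mu_mis, mutability$mu_syn)
  pct <- rep(NA_real_, length(genes))
  ok <- which(!is.na(mtr))
  if (length(ok) > 1) {
    o <- ok[order(mtr[ok], genes[ok])]
    pct[o] <- 100 * (seq_along(ok) - 1) / (length(ok) - 1)
  }
  data.frame(gene = genes, n_mis_obs = n_mis, n_syn_obs = n_syn,
             expected_fraction = exp_frac, mtr = mtr, percentile = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sliding-window MTR across a set of transcripts
#'
#' Applies [sliding_window_mtr()] to every transcript with a CDS, using the
#' sites observed in the given cohort.
#'
#' @param cds Named character vector of CDS sequences keyed by transcript
#'   id (see [read_cds_fasta()]).
#' @inheritParams mtr_gene_scores
#' @param window_codons Odd window width in codons.
#' @return Data frame of per-codon window scores with a leading
#'   `transcript` column.
#' @export
sliding_window_scores <- function(cds, variants, cohort = NULL,
                                  window_codons = 31) {
  obs <- variants[cohort_observed(variants, cohort), , drop = FALSE]
  out <- lapply(names(cds), function(tx) {
    v <- obs[obs$transcript == tx & !is.na(obs$codon_index), , drop = FALSE]
    scores <- sliding_window_mtr(cds[[tx]], v, window_codons)
    cbind(transcript = tx, scores, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
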