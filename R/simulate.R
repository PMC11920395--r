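#' Configuration for the synthetic multi-ancestry cohort generator
#'
#' The generator emulates the statistical structure the intolerance
#' pipeline consumes: per-gene coding sequences whose mutability scales
#' with length, per-ancestry catalogs of distinct variant sites whose
#' count follows Watterson scaling (`mu * pop_scale * diversity_scale *
#' a(2n)` with `a(m) = sum(1/1..m-1)`), allele counts drawn from a
#' `1/k^sfs_shape` site-frequency spectrum, and purifying selection
#' modeled as frequency-targeted thinning: in intolerant genes, a
#' functional (missense or LOF) site whose minor allele frequency exceeds
#' `maf_sel` is retained only with probability `selection_strength[class]`.
#' Rare functional variation is untouched, which is what makes common
#' functional variants the informative signal and lets rare-variant
#' accumulation at large sample sizes dilute, rather than sharpen, the
#' contrast.
#'
#' Default ancestry profiles mirror the composition of a maximally diverse
#' biobank sub-cohort (AFR 8701, SAS 9217, EAS 2150, ASJ 2671, NFE 20000
#' individuals); the `diversity_scale` values are the common-missense
#' fold-enrichments of each group over the NFE group observed in large
#' exome catalogs (AFR 1.79, SAS 1.30, EAS 1.18, ASJ 1.02).
#'
#' @param n_genes Number of genes to simulate.
#' @param ancestry Data frame with columns `label`, `n_individuals`,
#'   `diversity_scale`.
#' @param intolerant_fraction Fraction of genes under purifying selection.
#' @param selection_strength Named numeric vector with entries `missense`
#'   and `lof`: retention probability of a common functional site in an
#'   intolerant gene (1 = no selection, 0 = full suppression).
#' @param sfs_shape Exponent of the `1/k^shape` site-frequency spectrum
#'   (1 = neutral constant-size shape).
#' @param maf_sel MAF above which selection acts (default 0.0005, the
#'   "common" threshold).
#' @param pop_scale Population-scaled mutation multiplier (of order
#'   4*Ne); with the default per-site rate this yields realistic
#'   tens-of-sites-per-gene catalogs.
#' @param site_rate Per-possible-substitution mutation rate.
#' @param codon_length_range CDS length range in codons.
#' @param seed Master seed; named sub-streams are derived from it so genes,
#'   catalogs and truth sets can be regenerated independently.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       ancestry = data.frame(
                         label = c("afr", "sas", "eas", "asj", "nfe"),
                         n_individuals = c(8701, 9217, 2150, 2671, 20000),
                         diversity_scale = c(1.79, 1.30, 1.18, 1.02, 1.00)
                       ),
                       intolerant_fraction = 0.15,
                       selection_strength = c(missense = 0.3, lof = 0.15),
                       sfs_shape = 1,
                       maf_sel = 5e-4,
                       pop_scale = 3e4,
                       site_rate = 1.2e-8,
                       codon_length_range = c(150, 3000),
                       seed = 1) {
  stopifnot(n_genes >= 1,
            is.data.frame(ancestry),
            all(c("label", "n_individuals", "diversity_scale") %in%
                  names(ancestry)),
            nrow(ancestry) >= 1,
            all(ancestry$n_individuals >= 1),
            all(ancestry$diversity_scale > 0),
            intolerant_fraction >= 0, intolerant_fraction <= 1,
            all(c("missense", "lof") %in% names(selection_strength)),
            all(selection_strength >= 0 & selection_strength <= 1),
            sfs_shape > 0, maf_sel > 0, maf_sel < 0.5,
            pop_scale > 0, site_rate > 0,
            length(codon_length_range) == 2,
            codon_length_range[1] >= 2,
            codon_length_range[2] >= codon_length_range[1])
  if (anyDuplicated(ancestry$label)) stop("duplicate ancestry labels")
  structure(
    list(n_genes = as.integer(n_genes), ancestry = ancestry,
         intolerant_fraction = intolerant_fraction,
         selection_strength = selection_strength,
         sfs_shape = sfs_shape, maf_sel = maf_sel,
         pop_scale = pop_scale, site_rate = site_rate,
         codon_length_range = codon_length_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Named RNG sub-stream of the master seed (kept below 2^31).
sub_seed <- function(seed, op) {
  offset <- c(genes = 1L, catalog = 2L, truth_sets = 3L)[[op]]
  as.integer((as.numeric(seed) %% 134217011) * 16 + offset)
}

# a(m) = sum_{i=1}^{m-1} 1/i, the Watterson normalizer for m haplotypes.
watterson_a <- function(n_haplotypes) {
  vapply(n_haplotypes, function(m) sum(1 / seq_len(m - 1)), numeric(1))
}

# Draw allele counts from the 1/k^shape spectrum, given its cumulative
# weight vector over k = 1..Kmax.
sample_sfs <- function(n, cum) {
  findInterval(stats::runif(n) * cum[length(cum)], cum) + 1L
}

.sense_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' Simulate genes, mutability table and ground truth
#'
#' Generates random coding sequences (log-uniform length, ATG start, no
#' internal stop codons, terminal stop omitted), derives each gene's
#' mutability components as `possible-substitution count x per-gene rate
#' scalar x site_rate` (so mutability and CDS length are strongly
#' correlated, as in real constraint tables), and plants the intolerant
#' gene set.
#'
#' @param config A [sim_config()].
#' @return An object of class `intol_sim`: list with `genes` (gene,
#'   transcript, n_codons, cds), `mutability` (gene, transcript, mu_mis,
#'   mu_syn, mu_lof), `truth` (gene, intolerant), plus internal
#'   substitution pools reused by [simulate_catalog()].
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "genes"))
  n <- config$n_genes
  lo <- config$codon_length_range[1]
  hi <- config$codon_length_range[2]
  n_codons <- as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))

  gene <- sprintf("G%05d", seq_len(n))
  transcript <- sprintf("T%05d", seq_len(n))

  cds <- character(n)
  codes <- vector("list", n)
  pools <- vector("list", n)
  counts <- matrix(0L, nrow = n, ncol = 3,
                   dimnames = list(NULL, c("mis", "syn", "non")))
  for (i in seq_len(n)) {
    body <- sample(.sense_codons, n_codons[i] - 1L, replace = TRUE)
    cds[i] <- paste0("ATG", paste(body, collapse = ""))
    cc <- cds_codon_codes(cds[i])
    codes[[i]] <- cc
    cls <- as.vector(t(.codon_tables$class[cc, , drop = FALSE]))
    pools[[i]] <- list(mis = which(cls == 1L), syn = which(cls == 2L),
                       non = which(cls == 3L))
    counts[i, ] <- c(length(pools[[i]]$mis), length(pools[[i]]$syn),
                     length(pools[[i]]$non))
  }

  rate_scalar <- stats::rlnorm(n, meanlog = 0, sdlog = 0.3)
  mutability <- data.frame(
    gene = gene, transcript = transcript,
    mu_mis = counts[, "mis"] * rate_scalar * config$site_rate,
    mu_syn = counts[, "syn"] * rate_scalar * config$site_rate,
    mu_lof = counts[, "non"] * rate_scalar * config$site_rate,
    stringsAsFactors = FALSE
  )

  n_intol <- round(config$intolerant_fraction * n)
  intolerant <- rep(FALSE, n)
  if (n_intol > 0) intolerant[sample.int(n, n_intol)] <- TRUE

  structure(
    list(
      genes = data.frame(gene = gene, transcript = transcript,
                         n_codons = n_codons, cds = cds,
                         stringsAsFactors = FALSE),
      mutability = mutability,
      truth = data.frame(gene = gene, intolerant = intolerant,
                         stringsAsFactors = FALSE),
      pools = pools, codes = codes, config = config
    ),
    class = "intol_sim"
  )
}

#' @export
print.intol_sim <- function(x, ...) {
  cat("intol_sim: ", nrow(x$genes), " genes (",
      sum(x$truth$intolerant), " intolerant), ",
      nrow(x$config$ancestry), " ancestry group(s)\n", sep = "")
  invisible(x)
}

# Decode integer site keys of one gene into catalog rows. SNV keys are the
# substitution index (codon - 1) * 9 + j; frameshift keys are -pos.
decode_sites <- function(sim, gidx, keys) {
  cds <- sim$genes$cds[gidx]
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  cc <- sim$codes[[gidx]]
  snv <- keys > 0
  pos <- integer(length(keys))
  ref <- alt <- consequence <- character(length(keys))
  codon <- integer(length(keys))
  if (any(snv)) {
    id <- keys[snv]
    codon_i <- (id - 1L) %/% 9L + 1L
    j <- (id - 1L) %% 9L + 1L
    code <- cc[codon_i]
    p_in <- .codon_tables$sub_pos[cbind(code, j)]
    pos[snv] <- (codon_i - 1L) * 3L + p_in
    ref[snv] <- chars[pos[snv]]
    alt[snv] <- .codon_tables$alt_base[cbind(code, j)]
    cls <- .codon_tables$class[cbind(code, j)]
    consequence[snv] <- c("missense variant", "synonymous variant",
                          "stop gained")[cls]
    codon[snv] <- codon_i
  }
  if (any(!snv)) {
    p <- -keys[!snv]
    pos[!snv] <- p
    ref[!snv] <- chars[p]
    alt[!snv] <- paste0(chars[p], c("A", "C", "G", "T")[(p %% 4L) + 1L])
    consequence[!snv] <- "frameshift variant"
    codon[!snv] <- (p - 1L) %/% 3L + 1L
  }
  data.frame(
    gene = sim$genes$gene[gidx], transcript = sim$genes$transcript[gidx],
    pos = pos, ref = ref, alt = alt, consequence = consequence,
    codon_index = codon, stringsAsFactors = FALSE
  )
}

#' Simulate a multi-ancestry variant catalog
#'
#' Draws, for every gene, ancestry group and consequence class, a Poisson
#' number of distinct variant sites with mean
#' `mu * pop_scale * diversity_scale * a(2n)` (LOF uses
#' `2.25 x mu_lof`, covering SNV stop-gains plus frameshift indels at
#' 1.25x the SNV rate), samples the sites without replacement from the
#' gene's possible-substitution pools, assigns allele counts from the
#' `1/k^sfs_shape` spectrum, and applies frequency-targeted purifying
#' selection to functional sites of intolerant genes. Sites drawn in
#' several groups are merged into a single record with per-group
#' `ac`/`an` fields.
#'
#' @param sim An `intol_sim` from [simulate_genes()].
#' @param config Optional [sim_config()] override; defaults to the one the
#'   genes were simulated under.
#' @return A variant table in the [read_variants()] column layout, with
#'   attribute `truth_counts`: a data frame of realized distinct-site
#'   counts per (gene, ancestry, class).
#' @export
simulate_catalog <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "intol_sim"), inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "catalog"))
  anc <- config$ancestry
  n_genes <- nrow(sim$genes)
  mu <- sim$mutability
  intol <- sim$truth$intolerant
  s_mis <- config$selection_strength[["missense"]]
  s_lof <- config$selection_strength[["lof"]]

  long <- vector("list", nrow(anc) * 3L)
  slot <- 0L
  for (a in seq_len(nrow(anc))) {
    an_hap <- 2L * anc$n_individuals[a]
    k_max <- an_hap - 1L
    a2n <- watterson_a(an_hap)
    cum <- cumsum(seq_len(k_max)^(-config$sfs_shape))
    scale <- config$pop_scale * anc$diversity_scale[a] * a2n

    for (class in c("missense", "synonymous", "lof")) {
      lambda <- switch(class,
        missense = mu$mu_mis, synonymous = mu$mu_syn,
        lof = 2.25 * mu$mu_lof
      ) * scale
      n_sites <- stats::rpois(n_genes, lambda)
      recs <- vector("list", n_genes)
      for (g in which(n_sites > 0L)) {
        n_g <- n_sites[g]
        if (class == "lof") {
          n_snv <- stats::rbinom(1L, n_g, 1 / 2.25)
          pool <- sim$pools[[g]]$non
          n_snv <- min(n_snv, length(pool))
          snv_keys <- if (n_snv > 0) {
            if (length(pool) == 1L) pool else sample(pool, n_snv)
          } else integer(0)
          n_fs <- min(n_g - n_snv, 3L * sim$genes$n_codons[g])
          fs_keys <- if (n_fs > 0) {
            -sample.int(3L * sim$genes$n_codons[g], n_fs)
          } else integer(0)
          keys <- c(snv_keys, fs_keys)
        } else {
          pool <- sim$pools[[g]][[if (class == "missense") "mis" else "syn"]]
          n_g <- min(n_g, length(pool))
          if (n_g == 0L) next
          keys <- if (length(pool) == 1L) pool else sample(pool, n_g)
        }
        if (!length(keys)) next
        k <- sample_sfs(length(keys), cum)
        if (intol[g] && class != "synonymous") {
          s <- if (class == "missense") s_mis else s_lof
          maf <- pmin(k, an_hap - k) / an_hap
          keep <- maf <= config$maf_sel | stats::runif(length(k)) < s
          keys <- keys[keep]
          k <- k[keep]
        }
        if (!length(keys)) next
        recs[[g]] <- data.frame(gidx = g, key = keys, anc = a,
                                k = k, class = class)
      }
      slot <- slot + 1L
      long[[slot]] <- do.call(rbind, recs)
    }
  }
  long <- do.call(rbind, long)

  labels <- anc$label
  an_vals <- 2 * anc$n_individuals
  if (is.null(long) || nrow(long) == 0) {
    out <- data.frame(gene = character(0), transcript = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), consequence = character(0),
                      consequence_class = character(0),
                      codon_index = integer(0))
    for (i in seq_along(labels)) {
      out[[paste0("ac_", labels[i])]] <- numeric(0)
      out[[paste0("an_", labels[i])]] <- numeric(0)
      out[[paste0("af_", labels[i])]] <- numeric(0)
    }
    attr(out, "truth_counts") <- data.frame(gene = character(0),
                                            ancestry = character(0),
                                            class = character(0),
                                            n_sites = integer(0))
    return(out)
  }

  site_id <- paste(long$gidx, long$key)
  first <- !duplicated(site_id)
  u_gidx <- long$gidx[first]
  u_key <- long$key[first]
  idx <- match(site_id, site_id[first])
  ac <- matrix(0, nrow = sum(first), ncol = nrow(anc))
  ac[cbind(idx, long$anc)] <- long$k

  # decode per gene, preserving the unique-site order
  ord <- order(u_gidx)
  rows <- lapply(split(seq_along(u_gidx)[ord], u_gidx[ord]), function(ii) {
    cbind(decode_sites(sim, u_gidx[ii[1]], u_key[ii]), .row = ii)
  })
  dec <- do.call(rbind, rows)
  dec <- dec[order(dec$.row), , drop = FALSE]
  out <- dec[, c("gene", "transcript", "pos", "ref", "alt", "consequence",
                 "codon_index")]
  out$consequence_class <- classify_consequence(out$consequence)
  out <- out[, c("gene", "transcript", "pos", "ref", "alt", "consequence",
                 "consequence_class", "codon_index")]
  for (i in seq_along(labels)) {
    out[[paste0("ac_", labels[i])]] <- ac[, i]
    out[[paste0("an_", labels[i])]] <- rep(an_vals[i], nrow(out))
    out[[paste0("af_", labels[i])]] <- ac[, i] / an_vals[i]
  }
  rownames(out) <- NULL

  counts <- stats::aggregate(list(n_sites = long$k > -1),
                             by = list(gene = sim$genes$gene[long$gidx],
                                       ancestry = labels[long$anc],
                                       class = long$class),
                             FUN = length)
  counts$n_sites <- as.integer(counts$n_sites)
  attr(out, "truth_counts") <- counts[order(counts$gene, counts$ancestry,
                                            counts$class), ]
  out
}

#' Simulate pathogenic and benign variant truth sets
#'
#' Pathogenic missense variants are sampled from the possible-substitution
#' pools of intolerant genes (the regions whose observed variation the
#' catalog suppresses); benign variants are sampled uniformly over
#' tolerant genes. When no genes are intolerant both sets are drawn from
#' the same (whole-exome) distribution, giving a null benchmark.
#'
#' @param sim An `intol_sim`.
#' @param n_pathogenic,n_benign Set sizes (exact).
#' @param config Optional [sim_config()] override.
#' @return List with data frames `pathogenic` and `benign` (columns
#'   `gene`, `transcript`, `pos`, `ref`, `alt`, `codon_index`, `key`).
#' @export
simulate_variant_truth_sets <- function(sim, n_pathogenic = 300,
                                        n_benign = 300,
                                        config = sim$config) {
  stopifnot(inherits(sim, "intol_sim"))
  set.seed(sub_seed(config$seed, "truth_sets"))
  intol_idx <- which(sim$truth$intolerant)
  toler_idx <- which(!sim$truth$intolerant)
  if (!length(intol_idx)) intol_idx <- seq_len(nrow(sim$genes))
  if (!length(toler_idx)) toler_idx <- seq_len(nrow(sim$genes))

  draw <- function(gene_idx, n) {
    sizes <- vapply(sim$pools[gene_idx], function(p) length(p$mis),
                    integer(1))
    total <- sum(sizes)
    if (n > total) stop("requested more variants than possible sites")
    picks <- sort(sample.int(total, n))
    cum <- cumsum(sizes)
    gi <- findInterval(picks - 1L, cum) + 1L
    local_i <- picks - c(0L, cum)[gi]
    out <- lapply(split(seq_len(n), gi), function(ii) {
      g <- gene_idx[gi[ii[1]]]
      keys <- sim$pools[[g]]$mis[local_i[ii]]
      decode_sites(sim, g, keys)
    })
    res <- do.call(rbind, out)
    res$key <- paste(res$transcript, res$pos, res$alt, sep = ":")
    rownames(res) <- NULL
    res
  }
  list(pathogenic = draw(intol_idx, n_pathogenic),
       benign = draw(toler_idx, n_benign))
}
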