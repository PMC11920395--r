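#' Read a variant table
#'
#' Reads ancestry-stratified variant catalogs from either the package's flat
#' TSV dialect or a VCF annotated with per-ancestry allele counts. Each row
#' of the result is one (variant, transcript) record with the consequence
#' class populated by [classify_consequence()] and per-ancestry allele
#' frequencies `af_<label> = ac_<label> / an_<label>`.
#'
#' The TSV dialect is tab-separated with a header and columns
#' `gene`, `transcript`, `pos`, `ref`, `alt`, `consequence`, an optional
#' `codon_index`, and `ac_<label>`/`an_<label>` pairs for each ancestry
#' group. VCF input must carry `AC_<label>`/`AN_<label>` INFO fields plus a
#' SnpEff-style `ANN` field; multi-allelic sites are decomposed to one
#' record per alternate allele.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A data frame with columns `gene`, `transcript`, `pos`, `ref`,
#'   `alt`, `consequence`, `consequence_class`, `codon_index`, then
#'   `ac_*`, `an_*`, `af_*` columns.
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "transcript", "pos", "ref", "alt", "consequence")
  if (!all(need %in% names(df))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  ac_cols <- grep("^ac_", names(df), value = TRUE)
  an_cols <- grep("^an_", names(df), value = TRUE)
  labels <- sub("^ac_", "", ac_cols)
  missing_an <- setdiff(paste0("an_", labels), an_cols)
  if (length(missing_an)) {
    stop("AC column present without matching AN column: ",
         paste(missing_an, collapse = ", "))
  }
  if (!length(ac_cols)) stop("variant TSV has no ac_<label> columns")

  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(!is.finite(pos) | pos < 1 | pos != round(pos))
  if (length(bad)) {
    stop("malformed 'pos' at line ", bad[1] + 1L, " of ", path)
  }
  for (lab in labels) {
    ac <- suppressWarnings(as.numeric(df[[paste0("ac_", lab)]]))
    an <- suppressWarnings(as.numeric(df[[paste0("an_", lab)]]))
    bad <- which(!is.finite(ac) | !is.finite(an) | ac < 0 | an < 0 | ac > an)
    if (length(bad)) {
      stop("malformed allele counts for group '", lab, "' at line ",
           bad[1] + 1L, " of ", path, " (need 0 <= ac <= an)")
    }
    df[[paste0("ac_", lab)]] <- ac
    df[[paste0("an_", lab)]] <- an
  }
  codon_index <- if ("codon_index" %in% names(df)) {
    suppressWarnings(as.integer(df$codon_index))
  } else {
    rep(NA_integer_, nrow(df))
  }
  out <- data.frame(
    gene = as.character(df$gene),
    transcript = as.character(df$transcript),
    pos = as.integer(pos),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    consequence = as.character(df$consequence),
    consequence_class = classify_consequence(df$consequence),
    codon_index = codon_index,
    stringsAsFactors = FALSE
  )
  for (lab in labels) {
    out[[paste0("ac_", lab)]] <- df[[paste0("ac_", lab)]]
    out[[paste0("an_", lab)]] <- df[[paste0("an_", lab)]]
    an <- df[[paste0("an_", lab)]]
    out[[paste0("af_", lab)]] <- ifelse(an > 0, df[[paste0("ac_", lab)]] / an,
                                        NA_real_)
  }
  out
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("empty VCF: ", path)
  info <- vcfR::getINFO(vcf)
  hits <- regmatches(info, gregexpr("(^|;)AC_[A-Za-z0-9]+=", info))
  labels <- unique(sub("=$", "", sub("^;?AC_", "", unlist(hits))))
  if (!length(labels)) stop("VCF has no AC_<label> INFO fields: ", path)

  info_field <- function(key) {
    has <- grepl(paste0("(^|;)", key, "="), info)
    val <- rep(NA_character_, length(info))
    val[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info[has])
    val
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ann_raw <- info_field("ANN")[i]
    if (is.na(ann_raw)) {
      stop("VCF record ", i, " lacks an ANN field")
    }
    ann <- strsplit(strsplit(ann_raw, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
    ac_by_lab <- lapply(labels, function(lab) {
      v <- info_field(paste0("AC_", lab))[i]
      if (is.na(v)) return(rep(0, length(alts)))
      as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
    })
    names(ac_by_lab) <- labels
    an_by_lab <- vapply(labels, function(lab) {
      v <- info_field(paste0("AN_", lab))[i]
      if (is.na(v) && any(ac_by_lab[[lab]] > 0)) {
        stop("VCF record ", i, ": AC_", lab, " present without AN_", lab)
      }
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))

    recs <- lapply(ann, function(a) {
      if (length(a) < 7) return(NULL)
      j <- match(a[1], alts)
      if (is.na(j)) return(NULL)
      codon <- NA_integer_
      if (length(a) >= 14 && nzchar(a[14])) {
        codon <- suppressWarnings(as.integer(sub("/.*$", "", a[14])))
      }
      r <- data.frame(
        gene = a[4], transcript = a[7],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = a[1],
        consequence = a[2],
        consequence_class = classify_consequence(a[2]),
        codon_index = codon,
        stringsAsFactors = FALSE
      )
      for (lab in labels) {
        ac <- ac_by_lab[[lab]][j]
        an <- an_by_lab[[lab]]
        r[[paste0("ac_", lab)]] <- ac
        r[[paste0("an_", lab)]] <- an
        r[[paste0("af_", lab)]] <- if (an > 0) ac / an else NA_real_
      }
      r
    })
    rows[[i]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a gene list
#'
#' One symbol per line; `#` comments and blank lines are skipped; duplicates
#' are dropped. An empty file is an error.
#'
#' @param path Path to the gene list.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- unique(lines[nzchar(lines)])
  if (!length(genes)) stop("empty gene list: ", path)
  genes
}

#' Write / read a score table
#'
#' Score tables are plain TSVs with a header row; undefined scores are
#' written as `NA`. Numeric columns round-trip at full double precision.
#'
#' @param table A data frame of per-gene (or per-codon) scores.
#' @param path Output path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns the data frame.
#' @export
write_score_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a per-gene mutability table
#'
#' TSV with columns `gene`, `transcript`, `mu_mis`, `mu_syn`, `mu_lof`
#' (scientific notation accepted), shaped like the per-gene mutation-rate
#' components of the gnomAD constraint-metrics file. `mu_lof` is the
#' SNV-only LOF rate; the frameshift contribution is added downstream (see
#' [genic_mutability()]).
#'
#' @param path Path to the TSV.
#' @return Data frame with the five columns, rates validated non-negative.
#' @export
read_mutability <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "mu_mis", "mu_syn", "mu_lof")
  if (!all(need %in% names(df))) {
    stop("mutability TSV must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("mu_mis", "mu_syn", "mu_lof")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]) | df[[col]] < 0)) {
      stop("mutability column '", col, "' must be finite and non-negative")
    }
  }
  df[, need]
}

#' Read CDS sequences from FASTA
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' FASTA header (the transcript identifier).
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of upper-case nucleotide sequences.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1)
  out
}

#' Write CDS sequences to FASTA
#'
#' @param cds Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(is.character(cds), !is.null(names(cds)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}
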