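#' Consequence term lists
#'
#' The annotation terms assigned to each consequence class. Synonymous,
#' missense (which includes in-frame indels), and loss-of-function (LOF;
#' stop-gain, frameshift, start-loss, canonical splice disruption, and the
#' compound terms an annotator may emit for multi-effect variants).
#'
#' @format A named list with character vectors `synonymous`, `missense`,
#'   and `lof`. Terms are stored in normalized form (lower case, single
#'   spaces).
#' @export
consequence_terms <- list(
  synonymous = "synonymous",
  missense = c(
    "missense",
    "in frame insertion",
    "in frame deletion"
  ),
  lof = c(
    "frameshift variant",
    "stop gained",
    "start lost",
    "splice acceptor variant",
    "splice donor variant",
    "stop gained and frameshift variant",
    "splice donor variant and coding sequence variant and intron variant",
    "splice donor variant and intron variant",
    "stop gained and in frame insertion",
    "frameshift variant and stop lost",
    "frameshift variant and start lost",
    "start lost and splice region variant",
    "stop gained and protein altering variant",
    "stop gained and frameshift variant and splice region variant",
    "stop gained and in frame deletion",
    "frameshift variant and stop retained variant"
  )
)

normalize_consequence <- function(x) {
  x <- tolower(x)
  x <- gsub("_", " ", x, fixed = TRUE)
  # VCF ANN fields join multi-effect annotations with "&"
  x <- gsub("\\s*&\\s*", " and ", x)
  x <- gsub("\\s*\\+\\s*", " and ", x)
  x <- gsub("inframe", "in frame", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Classify a raw consequence annotation
#'
#' Maps an annotation string to one of the four consequence classes used
#' throughout the package: `synonymous`, `missense`, `lof` or `other`.
#' Matching is case-insensitive, treats underscores, `&` and `+` as spaces /
#' "and", and tolerates a trailing "variant" on the single-effect terms
#' (so `"missense_variant"` and `"missense"` are equivalent). Unrecognized
#' strings map to `other`; they never error.
#'
#' @param consequence_raw Character vector of annotation strings.
#' @return Character vector (same length) with values in
#'   `c("synonymous", "missense", "lof", "other")`.
#' @examples
#' classify_consequence(c("stop_gained", "missense variant", "intron_variant"))
#' @export
classify_consequence <- function(consequence_raw) {
  stopifnot(is.character(consequence_raw) | length(consequence_raw) == 0)
  x <- normalize_consequence(as.character(consequence_raw))
  stripped <- sub(" variant$", "", x)
  out <- rep("other", length(x))
  for (cls in c("synonymous", "missense", "lof")) {
    terms <- consequence_terms[[cls]]
    hit <- x %in% terms | (out == "other" & stripped %in% terms)
    out[hit & out == "other"] <- cls
  }
  out
}

#' Select the canonical transcript of a gene
#'
#' Canonical means the longest isoform; among equally long isoforms, the one
#' with the greatest number of observed variants; remaining ties are broken
#' by transcript identifier for determinism.
#'
#' @param transcripts A data frame with columns `transcript_id`, `length`
#'   and `n_observed_variants` (one row per candidate isoform of one gene).
#' @return The selected `transcript_id` (length-1 character).
#' @export
select_canonical <- function(transcripts) {
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0) {
    stop("'transcripts' must be a non-empty data frame")
  }
  need <- c("transcript_id", "length", "n_observed_variants")
  if (!all(need %in% names(transcripts))) {
    stop("'transcripts' must have columns: ", paste(need, collapse = ", "))
  }
  o <- order(-transcripts$length, -transcripts$n_observed_variants,
             transcripts$transcript_id)
  as.character(transcripts$transcript_id[o[1]])
}
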