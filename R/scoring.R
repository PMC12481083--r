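#' Resolve one model variant to an effective dosage for one sample
#'
#' Resolution order: a proxy-map entry with `action = "assume_wildtype"`
#' scores 0 (wild-type fallback); a `substitute` entry uses the surrogate's
#' observed dosage, reversed to 2 - d when the LD orientation is negative;
#' otherwise the variant's own dosage is used. Any missing observation at
#' the resolved site — surrogate absent from the matrix, uncalled genotype,
#' dropped-out variant — falls back to dosage 0 and is logged as
#' `missing_as_wildtype`, never raised as an error: the score must be
#' computable for every sample.
#'
#' @param variant_id model variant to resolve
#' @param dosages samples x variants dosage matrix (entries 0/1/2/NA)
#' @param map a [proxy_map] (or NULL for all-direct)
#' @param sample_id row of `dosages` to resolve
#' @return list with `dosage` (0, 1 or 2) and `resolution` (one of
#'   "direct", "proxy", "proxy_reversed", "wildtype_fallback",
#'   "missing_as_wildtype")
#' @export
resolve_dosage <- function(variant_id, dosages, map = NULL, sample_id) {
  entry <- NULL
  if (!is.null(map) && nrow(map) > 0) {
    k <- which(map$original_id == variant_id)
    if (length(k) == 1) entry <- map[k, ]
  }
  if (!is.null(entry) && entry$action == "assume_wildtype") {
    return(list(dosage = 0L, resolution = "wildtype_fallback"))
  }
  site <- if (is.null(entry)) variant_id else entry$proxy_id
  d <- if (site %in% colnames(dosages)) dosages[sample_id, site] else NA_integer_
  if (is.na(d)) {
    return(list(dosage = 0L, resolution = "missing_as_wildtype"))
  }
  if (is.null(entry)) {
    list(dosage = as.integer(d), resolution = "direct")
  } else if (entry$orientation == "negative") {
    list(dosage = 2L - as.integer(d), resolution = "proxy_reversed")
  } else {
    list(dosage = as.integer(d), resolution = "proxy")
  }
}

#' Build the effective (resolved) dosage matrix for a model
#'
#' Vectorized application of [resolve_dosage()] across all samples and model
#' variants. The result contains no missing values: every unresolvable cell
#' has been scored as wild-type (0) and tagged in the resolution matrix.
#'
#' @param dosages samples x variants observed dosage matrix
#' @param model a [prs_model]
#' @param map a [proxy_map] or NULL
#' @return list with `dosage` (samples x model variants, integer, no NA)
#'   and `resolution` (character matrix of the same shape)
#' @export
resolve_dosage_matrix <- function(dosages, model, map = NULL) {
  stopifnot(inherits(model, "prs_model"))
  samples <- rownames(dosages)
  eff <- matrix(0L, nrow = length(samples), ncol = nrow(model),
                dimnames = list(samples, model$variant_id))
  res <- matrix("missing_as_wildtype", nrow = length(samples), ncol = nrow(model),
                dimnames = list(samples, model$variant_id))
  for (j in seq_len(nrow(model))) {
    vid <- model$variant_id[j]
    entry <- NULL
    if (!is.null(map) && nrow(map) > 0) {
      k <- which(map$original_id == vid)
      if (length(k) == 1) entry <- map[k, ]
    }
    if (!is.null(entry) && entry$action == "assume_wildtype") {
      res[, j] <- "wildtype_fallback"
      next
    }
    site <- if (is.null(entry)) vid else entry$proxy_id
    if (!site %in% colnames(dosages)) next  # stays missing_as_wildtype / 0
    d <- dosages[, site]
    ok <- !is.na(d)
    if (is.null(entry)) {
      eff[ok, j] <- as.integer(d[ok])
      res[ok, j] <- "direct"
    } else if (entry$orientation == "negative") {
      eff[ok, j] <- 2L - as.integer(d[ok])
      res[ok, j] <- "proxy_reversed"
    } else {
      eff[ok, j] <- as.integer(d[ok])
      res[ok, j] <- "proxy"
    }
  }
  list(dosage = eff, resolution = res)
}

#' Compute polygenic risk scores
#'
#' Per sample, the PRS is the weighted sum over all model variants of the
#' effective effect-allele dosage times the variant's weight. Proxy
#' substitution replaces the genotyping of a site, not its coefficient: a
#' surrogate's dosage is always multiplied by the original variant's weight.
#'
#' @param dosages samples x variants observed dosage matrix (0/1/2/NA)
#' @param model a [prs_model]
#' @param map a [proxy_map] or NULL (score all variants directly)
#' @return data.frame of class `prs_scores` with one row per sample:
#'   `sample_id`, `prs`, and resolution counts `n_direct`, `n_proxy`,
#'   `n_reversed`, `n_wildtype_fallback`, `n_missing_as_wildtype`.
#'   Attributes: `contributions` (samples x variants matrix of
#'   weight x dosage products), `resolution` (character matrix),
#'   `effective_dosage` (integer matrix).
#' @export
compute_prs <- function(dosages, model, map = NULL) {
  stopifnot(inherits(model, "prs_model"))
  if (nrow(model) == 0) stop("empty model: nothing to score")
  resolved <- resolve_dosage_matrix(dosages, model, map)
  w <- model$weight
  contrib <- sweep(resolved$dosage, 2, w, `*`)
  prs <- rowSums(contrib)
  count_of <- function(tag) rowSums(resolved$resolution == tag)
  out <- data.frame(
    sample_id = rownames(dosages),
    prs = prs,
    n_direct = count_of("direct"),
    n_proxy = count_of("proxy"),
    n_reversed = count_of("proxy_reversed"),
    n_wildtype_fallback = count_of("wildtype_fallback"),
    n_missing_as_wildtype = count_of("missing_as_wildtype"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "contributions") <- contrib
  attr(out, "resolution") <- resolved$resolution
  attr(out, "effective_dosage") <- resolved$dosage
  class(out) <- c("prs_scores", "data.frame")
  out
}

#' Write a PRS score table
#'
#' Scores are written at full floating precision; rounding (e.g. to the
#' 4 decimals conventional for reporting) is a display concern.
#'
#' @param scores a `prs_scores` data.frame from [compute_prs()]
#' @param path output TSV path
#' @param contributions optional path for a long-format per-variant
#'   contribution table (sample_id, variant_id, dosage, contribution,
#'   resolution)
#' @return `path`, invisibly
#' @export
write_scores <- function(scores, path, contributions = NULL) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(contributions)) {
    contrib <- attr(scores, "contributions")
    res <- attr(scores, "resolution")
    eff <- attr(scores, "effective_dosage")
    long <- data.frame(
      sample_id = rep(rownames(contrib), times = ncol(contrib)),
      variant_id = rep(colnames(contrib), each = nrow(contrib)),
      dosage = as.vector(eff),
      contribution = as.vector(contrib),
      resolution = as.vector(res),
      stringsAsFactors = FALSE
    )
    utils::write.table(long, contributions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
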