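#' Construct a PRS model
#'
#' A PRS model is the single source of truth for variant identity and
#' per-effect-allele weights: one row per variant with GRCh37 coordinates,
#' ref/alt alleles, the effect allele (which must be ref or alt), the
#' log-odds weight, whether the reference array typed the site directly or
#' imputed it, and a low-complexity-region flag. Indel ref/alt pairs are
#' left-aligned to their minimal representation on construction.
#'
#' @param variants data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `effect_allele`, `weight`, `array_status`
#'   ("genotyped" or "imputed"), `low_complexity` (logical)
#' @param name model name
#' @param genome_build genome build label; models are defined on GRCh37
#' @return object of class `prs_model` (a validated data.frame with
#'   attributes `model_name` and `genome_build`)
#' @export
prs_model <- function(variants, name = "prs_model", genome_build = "GRCh37") {
  required <- c("variant_id", "chromosome", "position", "ref", "alt",
                "effect_allele", "weight", "array_status", "low_complexity")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("model table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  v <- as.data.frame(variants)[, required]
  v$variant_id <- as.character(v$variant_id)
  v$chromosome <- normalize_chrom(v$chromosome)
  v$position <- as.integer(v$position)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$weight <- as.numeric(v$weight)
  v$array_status <- as.character(v$array_status)
  v$low_complexity <- as.logical(v$low_complexity)

  for (i in seq_len(nrow(v))) {
    norm <- normalize_allele_pair(v$position[i], v$ref[i], v$alt[i])
    if (v$effect_allele[i] == v$ref[i]) {
      v$effect_allele[i] <- norm$ref
    } else if (v$effect_allele[i] == v$alt[i]) {
      v$effect_allele[i] <- norm$alt
    }
    v$position[i] <- norm$pos
    v$ref[i] <- norm$ref
    v$alt[i] <- norm$alt
  }

  dup <- v$variant_id[duplicated(v$variant_id)]
  if (length(dup) > 0) {
    stop("duplicate variant_id in model: ", paste(unique(dup), collapse = ", "))
  }
  bad_pos <- which(is.na(v$position) | v$position < 1)
  if (length(bad_pos) > 0) {
    stop("invalid position for variant(s): ",
         paste(v$variant_id[bad_pos], collapse = ", "))
  }
  bad_ea <- which(v$effect_allele != v$ref & v$effect_allele != v$alt)
  if (length(bad_ea) > 0) {
    stop("effect allele not among ref/alt for variant(s): ",
         paste(v$variant_id[bad_ea], collapse = ", "))
  }
  if (any(!is.finite(v$weight))) {
    stop("non-finite weight for variant(s): ",
         paste(v$variant_id[!is.finite(v$weight)], collapse = ", "))
  }
  bad_status <- which(!v$array_status %in% c("genotyped", "imputed"))
  if (length(bad_status) > 0) {
    stop("array_status must be 'genotyped' or 'imputed' for variant(s): ",
         paste(v$variant_id[bad_status], collapse = ", "))
  }

  rownames(v) <- NULL
  structure(v, class = c("prs_model", "data.frame"),
            model_name = name, genome_build = genome_build)
}

#' @export
as.data.frame.prs_model <- function(x, ...) {
  attr(x, "model_name") <- NULL
  attr(x, "genome_build") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
as.data.frame.proxy_map <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("PRS model '%s' (%s): %d variants (%d genotyped, %d imputed on array)\n",
              attr(x, "model_name"), attr(x, "genome_build"), nrow(x),
              sum(x$array_status == "genotyped"), sum(x$array_status == "imputed")))
  invisible(x)
}

#' Load a PRS model from a tab-separated table
#'
#' Expects a header row with columns `variant_id`, `chromosome`, `position`,
#' `ref`, `alt`, `effect_allele`, `weight`, `array_status`, `low_complexity`.
#' Row order is preserved. All model invariants (unique ids, effect allele
#' among ref/alt, finite weights) are enforced on load; violations are hard
#' errors naming the offending variant.
#'
#' @param path path to the TSV model table
#' @param name model name; defaults to the file stem
#' @return a [prs_model]
#' @export
load_prs_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  prs_model(tab, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Save a PRS model as a tab-separated table
#'
#' `load_prs_model(save_prs_model(m, path))` reproduces `m` field-for-field.
#'
#' @param model a [prs_model]
#' @param path output path
#' @return `path`, invisibly
#' @export
save_prs_model <- function(model, path) {
  stopifnot(inherits(model, "prs_model"))
  utils::write.table(as.data.frame(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a proxy map
#'
#' The proxy map records, for each model variant that cannot be genotyped
#' reliably on the sequencing panel, either a surrogate variant in linkage
#' disequilibrium (`action = "substitute"`, with its r-squared, D-prime and
#' LD orientation) or the instruction to score the wild-type genotype
#' (`action = "assume_wildtype"`). Negative orientation means the proxy's
#' effect-aligned allele travels with the target's non-effect allele, so an
#' observed proxy dosage d scores as 2 - d.
#'
#' @param entries data.frame with columns `original_id`, `proxy_id`, `r2`,
#'   `d_prime`, `orientation` ("positive"/"negative"), `action`
#'   ("substitute"/"assume_wildtype")
#' @param model the [prs_model] the entries refer to
#' @return object of class `proxy_map` (a validated data.frame)
#' @export
proxy_map <- function(entries, model) {
  stopifnot(inherits(model, "prs_model"))
  required <- c("original_id", "proxy_id", "r2", "d_prime", "orientation", "action")
  if (is.null(entries) || nrow(entries) == 0) {
    e <- data.frame(original_id = character(), proxy_id = character(),
                    r2 = numeric(), d_prime = numeric(),
                    orientation = character(), action = character(),
                    stringsAsFactors = FALSE)
    return(structure(e, class = c("proxy_map", "data.frame")))
  }
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("proxy map missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  e <- as.data.frame(entries)[, required]
  e$original_id <- as.character(e$original_id)
  e$proxy_id <- as.character(e$proxy_id)
  e$proxy_id[is.na(e$proxy_id)] <- ""
  e$r2 <- as.numeric(e$r2)
  e$d_prime <- as.numeric(e$d_prime)
  e$orientation <- as.character(e$orientation)
  e$action <- as.character(e$action)

  unknown <- setdiff(e$original_id, model$variant_id)
  if (length(unknown) > 0) {
    stop("proxy map original_id not in model: ", paste(unknown, collapse = ", "))
  }
  dup <- e$original_id[duplicated(e$original_id)]
  if (length(dup) > 0) {
    stop("multiple proxy entries for original_id: ",
         paste(unique(dup), collapse = ", "))
  }
  sub <- e$action == "substitute"
  if (any(!e$action %in% c("substitute", "assume_wildtype"))) {
    stop("action must be 'substitute' or 'assume_wildtype'")
  }
  if (any(sub & (is.na(e$r2) | e$r2 < 0 | e$r2 > 1))) {
    stop("r2 out of [0,1] for: ",
         paste(e$original_id[sub & (is.na(e$r2) | e$r2 < 0 | e$r2 > 1)], collapse = ", "))
  }
  if (any(sub & (is.na(e$d_prime) | e$d_prime < 0 | e$d_prime > 1))) {
    stop("d_prime out of [0,1] for: ",
         paste(e$original_id[sub & (is.na(e$d_prime) | e$d_prime < 0 | e$d_prime > 1)], collapse = ", "))
  }
  if (any(sub & !e$orientation %in% c("positive", "negative"))) {
    stop("orientation must be 'positive' or 'negative' for substitute entries")
  }
  if (any(sub & e$proxy_id == "")) {
    stop("substitute entries need a proxy_id: ",
         paste(e$original_id[sub & e$proxy_id == ""], collapse = ", "))
  }
  if (any(!sub & e$proxy_id != "")) {
    stop("assume_wildtype entries must have empty proxy_id: ",
         paste(e$original_id[!sub & e$proxy_id != ""], collapse = ", "))
  }

  rownames(e) <- NULL
  structure(e, class = c("proxy_map", "data.frame"))
}

#' Load a proxy map from a tab-separated table
#'
#' Columns: `original_id`, `proxy_id`, `r2`, `d_prime`, `orientation`,
#' `action`. An empty file (header only) yields an empty map, meaning every
#' model variant is scored directly. Every `original_id` must resolve
#' against the model and appear at most once.
#'
#' @param path path to the TSV proxy map
#' @param model the [prs_model] to validate against
#' @return a [proxy_map]
#' @export
load_proxy_map <- function(path, model) {
  if (!file.exists(path)) stop("proxy map file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  proxy_map(tab, model)
}

#' Save a proxy map as a tab-separated table
#'
#' @param map a [proxy_map]
#' @param path output path
#' @return `path`, invisibly
#' @export
save_proxy_map <- function(map, path) {
  stopifnot(inherits(map, "proxy_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
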