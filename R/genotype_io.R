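#' Extract effect-allele dosages from a VCF
#'
#' For each model variant, the VCF is searched for a record matching on
#' (chromosome, position, ref, alt) after chromosome-name normalization and
#' indel left-alignment; multiallelic records are decomposed per ALT allele.
#' The dosage is the number of effect-allele copies in the called genotype:
#' when the effect allele is ALT this is the ALT-allele count, when it is
#' REF it is 2 minus the ALT count. Variants absent from the VCF, uncalled
#' genotypes, half-calls (./1), non-diploid calls, and genotypes involving
#' an ALT allele that does not match the model are missing (NA).
#'
#' @param path VCF file (plain or bgzipped, v4.2 with GT)
#' @param model a [prs_model]; proxy variants to be resolved later may be
#'   supplied through `extra_variants`
#' @param extra_variants optional data.frame with columns `variant_id`,
#'   `chromosome`, `position`, `ref`, `alt`, `effect_allele` for panel sites
#'   outside the model (proxy surrogates)
#' @return integer matrix, samples x variants, entries in \{0,1,2\} or NA,
#'   with attribute `unmatched` listing model variants not found in the VCF
#' @export
read_dosage_vcf <- function(path, model, extra_variants = NULL) {
  stopifnot(inherits(model, "prs_model"))
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)

  targets <- data.frame(
    variant_id = model$variant_id,
    chromosome = model$chromosome,
    position = model$position,
    ref = model$ref, alt = model$alt,
    effect_allele = model$effect_allele,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_variants) && nrow(extra_variants) > 0) {
    ev <- as.data.frame(extra_variants)
    ev$chromosome <- normalize_chrom(ev$chromosome)
    for (i in seq_len(nrow(ev))) {
      norm <- normalize_allele_pair(as.integer(ev$position[i]),
                                    ev$ref[i], ev$alt[i])
      if (toupper(ev$effect_allele[i]) == toupper(ev$ref[i])) {
        ev$effect_allele[i] <- norm$ref
      } else {
        ev$effect_allele[i] <- norm$alt
      }
      ev$position[i] <- norm$pos
      ev$ref[i] <- norm$ref
      ev$alt[i] <- norm$alt
    }
    targets <- rbind(targets,
                     ev[, c("variant_id", "chromosome", "position",
                            "ref", "alt", "effect_allele")])
  }

  fix <- vcf@fix
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) stop("VCF has no sample genotype columns: ", path)
  n_rec <- nrow(fix)

  # decomposed lookup: "chrom:pos:ref:alt" -> (record index, alt allele index)
  rec_idx <- integer(0); alt_idx <- integer(0); keys <- character(0)
  if (n_rec > 0) {
    for (r in seq_len(n_rec)) {
      alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
      for (a in seq_along(alts)) {
        if (is.na(alts[a]) || alts[a] %in% c(".", "*")) next
        norm <- normalize_allele_pair(as.integer(fix[r, "POS"]),
                                      fix[r, "REF"], alts[a])
        keys <- c(keys, variant_key(fix[r, "CHROM"], norm$pos, norm$ref, norm$alt))
        rec_idx <- c(rec_idx, r)
        alt_idx <- c(alt_idx, a)
      }
    }
  }

  gt <- vcf@gt[, -1, drop = FALSE]
  dos <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(targets),
                dimnames = list(samples, targets$variant_id))
  unmatched <- character(0)

  for (j in seq_len(nrow(targets))) {
    key <- variant_key(targets$chromosome[j], targets$position[j],
                       targets$ref[j], targets$alt[j])
    hit <- which(keys == key)
    if (length(hit) == 0) {
      unmatched <- c(unmatched, targets$variant_id[j])
      next
    }
    hit <- hit[1]  # first matching record wins
    r <- rec_idx[hit]; a <- alt_idx[hit]
    gt_strings <- if (n_rec == 1) gt[r, ] else gt[r, , drop = TRUE]
    # GT is the first colon-delimited field
    gt_only <- sub(":.*$", "", gt_strings)
    alleles <- strsplit(gt_only, "[/|]")
    dos[, j] <- vapply(alleles, function(al) {
      if (length(al) != 2) return(NA_integer_)       # non-diploid or half
      if (any(al == "." | al == "")) return(NA_integer_)
      code <- suppressWarnings(as.integer(al))
      if (any(is.na(code))) return(NA_integer_)
      if (any(code != 0L & code != a)) return(NA_integer_)  # other ALT allele
      sum(code == a)
    }, integer(1))
  }

  # orient to effect allele: effect == REF -> 2 - alt count
  flip <- targets$effect_allele == targets$ref
  if (any(flip)) dos[, flip] <- 2L - dos[, flip, drop = FALSE]

  attr(dos, "unmatched") <- unmatched
  dos
}

#' Read per-site read depths into a samples x variants table
#'
#' Input is a TSV with columns `sample`, `chrom`, `pos`, `depth` (the shape
#' of standard per-base depth exports restricted to panel positions). Model
#' variants with no row for a sample get depth 0.
#'
#' @param path depth TSV
#' @param model a [prs_model]
#' @param samples optional character vector fixing the sample universe and
#'   row order; defaults to the sorted samples present in the file
#' @return integer matrix, samples x model variants, read counts (>= 0)
#' @export
read_depth_table <- function(path, model, samples = NULL) {
  stopifnot(inherits(model, "prs_model"))
  if (!file.exists(path)) stop("depth file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "pos", "depth")
  if (!all(required %in% names(tab))) {
    stop("depth table needs columns: ", paste(required, collapse = ", "))
  }
  tab$depth <- as.numeric(tab$depth)
  if (any(is.na(tab$depth)) || any(tab$depth < 0)) {
    stop("negative or non-numeric depth values in ", path)
  }
  if (is.null(samples)) samples <- sort(unique(as.character(tab$sample)))
  dep <- matrix(0L, nrow = length(samples), ncol = nrow(model),
                dimnames = list(samples, model$variant_id))
  if (nrow(tab) > 0) {
    site_key <- paste(normalize_chrom(tab$chrom), tab$pos, sep = ":")
    model_key <- paste(model$chromosome, model$position, sep = ":")
    keep <- tab$sample %in% samples & site_key %in% model_key
    if (any(keep)) {
      i <- match(tab$sample[keep], samples)
      j <- match(site_key[keep], model_key)
      dep[cbind(i, j)] <- as.integer(round(tab$depth[keep]))
    }
  }
  dep
}

#' Write a depth table in the TSV format `read_depth_table()` consumes
#'
#' @param depths samples x variants integer matrix
#' @param model a [prs_model] supplying coordinates for each variant column
#' @param path output path
#' @return `path`, invisibly
#' @export
write_depth_table <- function(depths, model, path) {
  stopifnot(inherits(model, "prs_model"))
  j <- match(colnames(depths), model$variant_id)
  if (any(is.na(j))) stop("depth columns not in model")
  long <- data.frame(
    sample = rep(rownames(depths), times = ncol(depths)),
    chrom = rep(model$chromosome[j], each = nrow(depths)),
    pos = rep(model$position[j], each = nrow(depths)),
    depth = as.vector(depths),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
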