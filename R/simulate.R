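#' Simulate a PRS model with per-variant effect-allele frequencies
#'
#' Generates a synthetic panel mirroring the geometry of the 313-variant
#' breast-cancer score: `n_genotyped` variants typed directly on the
#' reference array and the remainder imputed, a subset flagged as lying in
#' low-complexity sequence (the sites sequencing struggles with). Weights
#' are drawn N(0, 0.06) — with allele frequencies uniform on
#' [0.05, 0.95] this reproduces a population score spread comparable to
#' published PRS distributions (sd around 0.6 for 313 variants).
#' Effect alleles are assigned to REF for roughly a third of variants so
#' the orientation-flip path is always exercised.
#'
#' @param n_variants panel size
#' @param n_genotyped number of array-genotyped (non-imputed) variants
#' @param n_low_complexity number of variants flagged low-complexity
#' @param seed RNG seed
#' @return list: `model` (a [prs_model]) and `frequencies` (named vector of
#'   effect-allele population frequencies)
#' @export
simulate_prs_model <- function(n_variants = 313, n_genotyped = 105,
                               n_low_complexity = 29, seed = 1) {
  set.seed(seed)
  stopifnot(n_genotyped <= n_variants, n_low_complexity <= n_variants)
  chrom <- as.character(sample(1:22, n_variants, replace = TRUE))
  pos <- integer(n_variants)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(2e8, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  effect_is_ref <- stats::runif(n_variants) < 1 / 3
  status <- rep("imputed", n_variants)
  status[sample.int(n_variants, n_genotyped)] <- "genotyped"
  lowc <- rep(FALSE, n_variants)
  lowc[sample.int(n_variants, n_low_complexity)] <- TRUE
  variants <- data.frame(
    variant_id = paste0("var", seq_len(n_variants), "_", chrom, ":", pos),
    chromosome = chrom, position = pos, ref = ref, alt = alt,
    effect_allele = ifelse(effect_is_ref, ref, alt),
    weight = stats::rnorm(n_variants, 0, 0.06),
    array_status = status, low_complexity = lowc,
    stringsAsFactors = FALSE
  )
  model <- prs_model(variants, name = sprintf("synthetic_prs_%d", n_variants))
  freq <- stats::runif(n_variants, 0.05, 0.95)
  names(freq) <- model$variant_id
  list(model = model, frequencies = freq)
}

#' Feasible LD range for a two-locus system
#'
#' @param pA,pB effect-allele frequencies at the two loci
#' @return list: `D_min`, `D_max`, `r_min`, `r_max`
#' @export
ld_feasible_range <- function(pA, pB) {
  qA <- 1 - pA; qB <- 1 - pB
  D_min <- max(-pA * pB, -qA * qB)
  D_max <- min(pA * qB, qA * pB)
  denom <- sqrt(pA * qA * pB * qB)
  list(D_min = D_min, D_max = D_max,
       r_min = D_min / denom, r_max = D_max / denom)
}

#' Draw phased two-locus haplotypes at a target LD
#'
#' Haplotype frequencies are set to p_AB = pA pB + D (and complements) with
#' D = r sqrt(pA qA pB qB); a negative `r` puts the two effect alleles in
#' repulsion, the configuration whose surrogate dosages must be reversed.
#'
#' @param pA,pB effect-allele frequencies, strictly in (0,1)
#' @param r target signed allelic correlation (r, not r-squared)
#' @param n number of haplotypes to draw
#' @param seed RNG seed (NULL to use the current RNG state)
#' @return list: `hapA`, `hapB` (0/1 integer vectors of length n, 1 =
#'   effect allele) and `freqs` (the four theoretical haplotype frequencies)
#' @export
simulate_two_locus_haplotypes <- function(pA, pB, r, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, n >= 1)
  qA <- 1 - pA; qB <- 1 - pB
  D <- r * sqrt(pA * qA * pB * qB)
  f <- c(AB = pA * pB + D, Ab = pA * qB - D, aB = qA * pB - D, ab = qA * qB + D)
  if (any(f < -1e-12)) {
    rng <- ld_feasible_range(pA, pB)
    stop(sprintf(
      "infeasible LD: r = %.3f outside [%.3f, %.3f] for pA = %.3f, pB = %.3f",
      r, rng$r_min, rng$r_max, pA, pB))
  }
  f <- pmax(f, 0); f <- f / sum(f)
  draw <- sample.int(4, n, replace = TRUE, prob = f)
  list(hapA = as.integer(draw %in% c(1, 2)),
       hapB = as.integer(draw %in% c(1, 3)),
       freqs = f)
}

#' Design a synthetic proxy layout over a model
#'
#' Selects `n_proxies + n_wildtype` low-complexity target variants; for each
#' proxied target, invents a nearby surrogate variant and links it at an
#' r-squared drawn from `r2_range` (defaults spanning the 0.47-1 range seen
#' in optimized panel designs), with `n_negative` of the links in repulsion
#' (negative orientation). The `n_wildtype` remaining targets get
#' `assume_wildtype` entries — sites with no usable surrogate.
#'
#' @param model a [prs_model]
#' @param frequencies named effect-allele frequency vector for the model
#' @param n_proxies number of substitute entries
#' @param n_negative how many substitute links are in negative LD
#' @param n_wildtype number of assume_wildtype entries
#' @param r2_range range to draw target r-squared values from
#' @param seed RNG seed
#' @return list: `map` (a [proxy_map]), `proxy_variants` (data.frame of the
#'   surrogate sites: variant_id, chromosome, position, ref, alt,
#'   effect_allele), `pair_spec` (data.frame original_id, proxy_id,
#'   r signed, p_original, p_proxy used by [simulate_truth_cohort()])
#' @export
simulate_proxy_layout <- function(model, frequencies, n_proxies = 27,
                                  n_negative = 2, n_wildtype = 2,
                                  r2_range = c(0.47, 1), seed = 1) {
  set.seed(seed)
  stopifnot(inherits(model, "prs_model"), n_negative <= n_proxies)
  n_targets <- n_proxies + n_wildtype
  pool <- model$variant_id[model$low_complexity]
  if (length(pool) < n_targets) {
    stop(sprintf("need %d low-complexity targets, model has %d",
                 n_targets, length(pool)))
  }
  targets <- sample(pool, n_targets)
  sub_targets <- targets[seq_len(n_proxies)]
  wt_targets <- setdiff(targets, sub_targets)
  neg <- rep(FALSE, n_proxies)
  if (n_negative > 0) neg[sample.int(n_proxies, n_negative)] <- TRUE

  r2 <- stats::runif(n_proxies, r2_range[1], r2_range[2])
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n_proxies)
  pv <- vector("list", n_proxies)
  for (i in seq_len(n_proxies)) {
    orig <- model[model$variant_id == sub_targets[i], ]
    pA <- frequencies[[orig$variant_id]]
    # |r| = sqrt(r2) is feasible at matched frequencies: pB = pA when the
    # effect alleles are coupled, pB = 1 - pA when they repel
    pB <- if (neg[i]) 1 - pA else pA
    pref <- sample(bases, 1)
    palt <- sample(setdiff(bases, pref), 1)
    pid <- sprintf("proxy%d_%s:%d", i, orig$chromosome, orig$position + 500L + i)
    pv[[i]] <- data.frame(
      variant_id = pid, chromosome = orig$chromosome,
      position = orig$position + 500L + i, ref = pref, alt = palt,
      effect_allele = palt, stringsAsFactors = FALSE
    )
    rows[[i]] <- data.frame(
      original_id = orig$variant_id, proxy_id = pid,
      r2 = r2[i], d_prime = 1,
      orientation = if (neg[i]) "negative" else "positive",
      action = "substitute",
      r = (if (neg[i]) -1 else 1) * sqrt(r2[i]),
      p_original = pA, p_proxy = pB,
      stringsAsFactors = FALSE
    )
  }
  entries <- do.call(rbind, rows)
  if (n_wildtype > 0) {
    entries <- rbind(entries, data.frame(
      original_id = wt_targets, proxy_id = "",
      r2 = NA_real_, d_prime = NA_real_,
      orientation = "positive", action = "assume_wildtype",
      r = NA_real_, p_original = NA_real_, p_proxy = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  map <- proxy_map(entries[, c("original_id", "proxy_id", "r2", "d_prime",
                               "orientation", "action")], model)
  list(map = map,
       proxy_variants = do.call(rbind, pv),
       pair_spec = entries[entries$action == "substitute",
                           c("original_id", "proxy_id", "r", "p_original", "p_proxy")])
}

#' Simulate a truth cohort of effect-allele dosages
#'
#' Unlinked variants are drawn Binomial(2, freq) per sample; each
#' original/surrogate pair in `pair_spec` is drawn jointly from two-locus
#' haplotypes at its target r, so the surrogate genuinely tags the original.
#' Dosages are counts of the effect allele.
#'
#' @param model a [prs_model]
#' @param frequencies named effect-allele frequency vector
#' @param n_samples cohort size
#' @param pair_spec optional data.frame from [simulate_proxy_layout()]
#'   (`original_id`, `proxy_id`, `r`, `p_original`, `p_proxy`)
#' @param seed RNG seed
#' @return integer matrix, samples x (model variants + surrogate variants)
#' @export
simulate_truth_cohort <- function(model, frequencies, n_samples = 154,
                                  pair_spec = NULL, seed = 1) {
  set.seed(seed)
  stopifnot(inherits(model, "prs_model"), n_samples >= 1)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  linked <- if (is.null(pair_spec)) character(0) else pair_spec$original_id
  proxy_ids <- if (is.null(pair_spec)) character(0) else pair_spec$proxy_id
  all_ids <- c(model$variant_id, proxy_ids)
  dos <- matrix(NA_integer_, n_samples, length(all_ids),
                dimnames = list(sample_ids, all_ids))
  for (j in seq_len(nrow(model))) {
    vid <- model$variant_id[j]
    if (vid %in% linked) next
    dos[, vid] <- stats::rbinom(n_samples, 2, frequencies[[vid]])
  }
  if (!is.null(pair_spec)) {
    for (k in seq_len(nrow(pair_spec))) {
      hp <- simulate_two_locus_haplotypes(
        pA = pair_spec$p_original[k], pB = pair_spec$p_proxy[k],
        r = pair_spec$r[k], n = 2 * n_samples)
      odd <- seq(1, 2 * n_samples, by = 2)
      dos[, pair_spec$original_id[k]] <- hp$hapA[odd] + hp$hapA[odd + 1]
      dos[, pair_spec$proxy_id[k]] <- hp$hapB[odd] + hp$hapB[odd + 1]
    }
  }
  dos
}

#' Simulate the array-plus-imputation observation of a truth cohort
#'
#' Each call is independently replaced by one of the two other genotype
#' classes (uniformly) with a per-variant miscall probability: a low rate
#' for directly genotyped markers and a higher one for imputed markers,
#' reflecting that imputation — not array chemistry — dominates the
#' reference method's error.
#'
#' @param truth samples x variants truth dosage matrix
#' @param model a [prs_model] (supplies `array_status` per variant;
#'   non-model columns, e.g. sequencing surrogates, are dropped — an array
#'   only reports its own content)
#' @param error_genotyped miscall probability for array-genotyped variants
#' @param error_imputed miscall probability for imputed variants
#' @param seed RNG seed
#' @return integer dosage matrix, samples x model variants
#' @export
simulate_array_observation <- function(truth, model,
                                       error_genotyped = 0.001,
                                       error_imputed = 0.03, seed = 1) {
  set.seed(seed)
  stopifnot(inherits(model, "prs_model"))
  obs <- truth[, model$variant_id, drop = FALSE]
  err <- ifelse(model$array_status == "genotyped", error_genotyped, error_imputed)
  for (j in seq_len(ncol(obs))) {
    if (err[j] <= 0) next
    hit <- which(stats::runif(nrow(obs)) < err[j])
    for (i in hit) {
      obs[i, j] <- sample(setdiff(0:2, obs[i, j]), 1)
    }
  }
  obs
}

#' Simulate the sequencing observation of a truth cohort
#'
#' Per cell, a read depth is drawn from an overdispersed negative-binomial
#' distribution around the variant's panel mean; below `dropout_depth`
#' reads the call is missing. Otherwise the genotype is called by
#' maximum likelihood from binomial read sampling of the two alleles with
#' a symmetric per-read error — accuracy therefore rises with depth.
#' `site_error` adds a per-variant pre-sequencing corruption probability
#' (uniform other genotype) modelling systematic mismapping in
#' low-complexity regions, which no amount of depth fixes.
#'
#' @param truth samples x variants truth dosage matrix
#' @param mean_depth named per-variant mean depth vector (variants of
#'   `truth` not named here default to `default_depth`)
#' @param default_depth panel-wide mean depth for unspecified variants
#' @param dropout_depth minimum reads for a call (below -> missing)
#' @param per_read_error symmetric per-read allele error
#' @param site_error named per-variant corruption probability (default 0)
#' @param dispersion negative-binomial size parameter for depth
#' @param seed RNG seed
#' @return list: `dosage` (integer matrix with NA for dropouts) and
#'   `depth` (integer matrix, same shape)
#' @export
simulate_ngs_observation <- function(truth, mean_depth = NULL,
                                     default_depth = 559,
                                     dropout_depth = 8,
                                     per_read_error = 0.001,
                                     site_error = NULL,
                                     dispersion = 10, seed = 1) {
  set.seed(seed)
  vids <- colnames(truth)
  mu <- rep(default_depth, length(vids)); names(mu) <- vids
  if (!is.null(mean_depth)) {
    common <- intersect(names(mean_depth), vids)
    mu[common] <- mean_depth[common]
  }
  serr <- rep(0, length(vids)); names(serr) <- vids
  if (!is.null(site_error)) {
    common <- intersect(names(site_error), vids)
    serr[common] <- site_error[common]
  }
  n <- nrow(truth)
  dosage <- matrix(NA_integer_, n, length(vids), dimnames = dimnames(truth))
  depth <- matrix(0L, n, length(vids), dimnames = dimnames(truth))
  e <- per_read_error
  p_read_alt <- c(e, 0.5, 1 - e)  # P(read shows effect allele | genotype 0/1/2)
  for (j in seq_along(vids)) {
    g <- truth[, j]
    if (serr[j] > 0) {
      hit <- which(stats::runif(n) < serr[j])
      for (i in hit) g[i] <- sample(setdiff(0:2, g[i]), 1)
    }
    d <- if (mu[j] <= 0) rep(0L, n) else
      stats::rnbinom(n, size = dispersion, mu = mu[j])
    depth[, j] <- d
    callable <- which(d >= dropout_depth & !is.na(g))
    if (length(callable) == 0) next
    k <- stats::rbinom(length(callable), d[callable], p_read_alt[g[callable] + 1])
    # ML genotype from k effect-allele reads out of d
    ll <- vapply(0:2, function(gg)
      stats::dbinom(k, d[callable], p_read_alt[gg + 1], log = TRUE),
      numeric(length(callable)))
    if (length(callable) == 1) ll <- matrix(ll, nrow = 1)
    dosage[callable, j] <- max.col(ll, ties.method = "first") - 1L
  }
  list(dosage = dosage, depth = depth)
}

#' Draw a per-variant panel depth profile
#'
#' Most sites get comfortable coverage (gamma-distributed around the global
#' panel mean); `low_ids` sites get a low mean below 30x and `dead_ids`
#' sites mean 0 (never sequenceable).
#'
#' @param model a [prs_model]
#' @param global_mean panel-wide mean depth target
#' @param low_ids variant ids to give low coverage (mean uniform on [10,29])
#' @param dead_ids variant ids to give zero coverage
#' @param seed RNG seed
#' @return named per-variant mean-depth vector
#' @export
simulate_depth_profile <- function(model, global_mean = 559,
                                   low_ids = character(0),
                                   dead_ids = character(0), seed = 1) {
  set.seed(seed)
  mu <- stats::rgamma(nrow(model), shape = 6, scale = global_mean / 6)
  names(mu) <- model$variant_id
  mu[low_ids] <- stats::runif(length(low_ids), 10, 29)
  mu[dead_ids] <- 0
  mu
}

#' Write a minimal genotype VCF (v4.2, GT only)
#'
#' Dosages are effect-allele counts; they are converted back to ALT-allele
#' counts per the variant's effect-allele orientation before encoding as
#' 0/0, 0/1, 1/1 (missing -> ./.). Records are sorted by chromosome and
#' position. The output reads back with any VCF v4.2 parser.
#'
#' @param dosages samples x variants effect-allele dosage matrix
#' @param variants data.frame with `variant_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `effect_allele` covering the matrix columns (a
#'   [prs_model] works, possibly rbind-ed with surrogate definitions)
#' @param path output path (".gz" suffix gzip-compresses)
#' @return `path`, invisibly
#' @export
write_dosage_vcf <- function(dosages, variants, path) {
  v <- as.data.frame(variants)
  j <- match(colnames(dosages), v$variant_id)
  if (any(is.na(j))) {
    stop("variant definitions missing for: ",
         paste(colnames(dosages)[is.na(j)], collapse = ", "))
  }
  v <- v[j, ]
  ord <- order(v$chromosome, v$position)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  )
  body <- vapply(ord, function(jj) {
    d <- dosages[, jj]
    alt_count <- if (toupper(v$effect_allele[jj]) == toupper(v$ref[jj])) 2L - d else d
    gt <- ifelse(is.na(alt_count), "./.", gt_code[alt_count + 1L])
    paste(c(normalize_chrom(v$chromosome[jj]), v$position[jj], v$variant_id[jj],
            toupper(v$ref[jj]), toupper(v$alt[jj]), ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, body), con)
  invisible(path)
}

#' Simulate a full paired-method study
#'
#' One call wiring the generator end to end under the study geometry:
#' a synthetic model (default 313 variants, 105 array-genotyped), a proxy
#' layout (27 surrogates, 2 in negative LD, 2 wild-type fallbacks), a truth
#' cohort (default 154 samples), the array-plus-imputation observation, and
#' the sequencing observation of the optimized panel with 15 low-coverage
#' sites and extra miscalls at low-complexity sites.
#'
#' @param n_samples cohort size
#' @param n_variants,n_genotyped,n_low_complexity model geometry
#' @param n_proxies,n_negative,n_wildtype proxy-layout geometry
#' @param n_low_depth number of model sites with mean depth < 30x
#' @param error_genotyped,error_imputed array miscall rates
#' @param lowc_site_error sequencing miscall rate at low-complexity sites
#' @param per_read_error symmetric per-read error for sequencing
#' @param seed RNG seed (all sub-seeds derive from it)
#' @return list: `model`, `frequencies`, `proxy_map`, `proxy_variants`,
#'   `pair_spec`, `truth`, `array`, `ngs` (list dosage/depth),
#'   `mean_depth`, `dead_ids`, `low_ids`
#' @export
simulate_study <- function(n_samples = 154, n_variants = 313,
                           n_genotyped = 105, n_low_complexity = 29,
                           n_proxies = 27, n_negative = 2, n_wildtype = 2,
                           n_low_depth = 15,
                           error_genotyped = 0.001, error_imputed = 0.03,
                           lowc_site_error = 0.4, per_read_error = 0.001,
                           seed = 1) {
  gen <- simulate_prs_model(n_variants, n_genotyped, n_low_complexity,
                            seed = seed)
  layout <- simulate_proxy_layout(gen$model, gen$frequencies,
                                  n_proxies = n_proxies,
                                  n_negative = n_negative,
                                  n_wildtype = n_wildtype, seed = seed + 1)
  truth <- simulate_truth_cohort(gen$model, gen$frequencies, n_samples,
                                 pair_spec = layout$pair_spec,
                                 seed = seed + 2)
  arr <- simulate_array_observation(truth, gen$model,
                                    error_genotyped, error_imputed,
                                    seed = seed + 3)
  # proxied + wildtype targets are the hard-to-sequence sites; the
  # wildtype targets are dead (mean depth 0), the rest of the low-depth
  # quota is drawn from the proxied targets
  targets <- layout$map$original_id
  dead_ids <- layout$map$original_id[layout$map$action == "assume_wildtype"]
  n_more_low <- max(0, n_low_depth - length(dead_ids))
  sub_ids <- setdiff(targets, dead_ids)
  set.seed(seed + 4)
  low_ids <- sample(sub_ids, min(n_more_low, length(sub_ids)))
  mean_depth <- simulate_depth_profile(gen$model, low_ids = low_ids,
                                       dead_ids = dead_ids, seed = seed + 5)
  # surrogates sequence well
  proxy_mu <- rep(559, nrow(layout$proxy_variants))
  names(proxy_mu) <- layout$proxy_variants$variant_id
  mean_depth <- c(mean_depth, proxy_mu)
  site_error <- rep(0, nrow(gen$model))
  names(site_error) <- gen$model$variant_id
  lowc_not_dead <- setdiff(gen$model$variant_id[gen$model$low_complexity], dead_ids)
  site_error[lowc_not_dead] <- lowc_site_error
  ngs <- simulate_ngs_observation(truth, mean_depth = mean_depth,
                                  per_read_error = per_read_error,
                                  site_error = site_error, seed = seed + 6)
  list(model = gen$model, frequencies = gen$frequencies,
       proxy_map = layout$map, proxy_variants = layout$proxy_variants,
       pair_spec = layout$pair_spec, truth = truth, array = arr,
       ngs = ngs, mean_depth = mean_depth,
       dead_ids = dead_ids, low_ids = low_ids)
}
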