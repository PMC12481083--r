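#' Classify one reference/test genotype pair under the carrier dichotomy
#'
#' A call is "positive" when it carries at least one effect allele
#' (dosage >= 1). With the reference method's call on the rows: both
#' positive -> TP, both negative -> TN, test-only positive -> FP,
#' reference-only positive -> FN. Heterozygous-vs-homozygous swaps are both
#' positive, hence TP here, while still counting as discordant in the
#' three-level [concordance()] metric — the two comparisons answer
#' different questions.
#'
#' @param ref_dosage reference-method dosage, 0/1/2 (vectorized)
#' @param test_dosage test-method dosage, 0/1/2 (vectorized)
#' @return character vector in \{"TP","TN","FP","FN"\}
#' @export
classify_call <- function(ref_dosage, test_dosage) {
  if (any(is.na(ref_dosage)) || any(is.na(test_dosage))) {
    stop("classify_call requires non-missing dosages; resolve missing cells first")
  }
  if (any(!ref_dosage %in% 0:2) || any(!test_dosage %in% 0:2)) {
    stop("dosages must be 0, 1 or 2")
  }
  ref_pos <- ref_dosage >= 1
  test_pos <- test_dosage >= 1
  out <- character(length(ref_pos))
  out[ref_pos & test_pos] <- "TP"
  out[!ref_pos & !test_pos] <- "TN"
  out[!ref_pos & test_pos] <- "FP"
  out[ref_pos & !test_pos] <- "FN"
  out
}

#' Tally confusion counts between two resolved dosage matrices
#'
#' @param ref reference-method samples x variants dosage matrix (no NA)
#' @param test test-method matrix, same samples and variants
#' @param variants optional subset of variant ids defining the stratum
#'   (e.g. the array-genotyped, non-imputed variants); default all shared
#' @return named list `tp`, `tn`, `fp`, `fn`, `n_calls`
#' @export
confusion_counts <- function(ref, test, variants = NULL) {
  shared_s <- intersect(rownames(ref), rownames(test))
  shared_v <- intersect(colnames(ref), colnames(test))
  if (length(shared_s) == 0) stop("no shared samples between matrices")
  if (!is.null(variants)) shared_v <- intersect(shared_v, variants)
  if (length(shared_v) == 0) stop("no shared variants in the requested stratum")
  r <- ref[shared_s, shared_v, drop = FALSE]
  t <- test[shared_s, shared_v, drop = FALSE]
  cls <- classify_call(as.vector(r), as.vector(t))
  list(tp = sum(cls == "TP"), tn = sum(cls == "TN"),
       fp = sum(cls == "FP"), fn = sum(cls == "FN"),
       n_calls = length(cls))
}

#' Sensitivity, specificity, PPV and NPV from confusion counts
#'
#' sensitivity = TP*100/(TP+FN), specificity = TN*100/(TN+FP),
#' PPV = TP*100/(TP+FP), NPV = TN*100/(TN+FN), as percentages. A zero
#' denominator yields NA (not available), never 0. Raw values are returned;
#' set `digits` to round half-up for report display.
#'
#' @param tp,tn,fp,fn non-negative counts (or a list with these names as
#'   the first argument, as returned by [confusion_counts()])
#' @param digits decimal places for half-up rounding; NULL for raw values
#' @return named numeric vector: sensitivity, specificity, ppv, npv
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL, digits = 2) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  ratio <- function(num, den) if (den == 0) NA_real_ else num * 100 / den
  out <- c(sensitivity = ratio(tp, tp + fn),
           specificity = ratio(tn, tn + fp),
           ppv = ratio(tp, tp + fp),
           npv = ratio(tn, tn + fn))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Three-level genotype concordance between two methods
#'
#' For each variant, the fraction of samples whose genotype (non-carrier,
#' heterozygous, homozygous) matches exactly between the two matrices; for
#' each sample, the analogous fraction across variants. Cells missing in
#' either matrix are excluded from numerator and denominator (evaluable
#' calls only). Variants below `threshold` are flagged for redesign.
#'
#' @param ref,test samples x variants dosage matrices sharing names
#' @param threshold flagging threshold on the per-variant fraction
#' @return list of class `concordance_report`: `per_variant` and
#'   `per_sample` named vectors (NA when nothing evaluable), `flagged`
#'   (variant ids with concordance < threshold), `n_evaluable` per variant
#' @export
concordance <- function(ref, test, threshold = 0.90) {
  shared_s <- intersect(rownames(ref), rownames(test))
  shared_v <- intersect(colnames(ref), colnames(test))
  if (length(shared_s) == 0) stop("no shared samples between matrices")
  if (length(shared_v) == 0) stop("no shared variants between matrices")
  r <- ref[shared_s, shared_v, drop = FALSE]
  t <- test[shared_s, shared_v, drop = FALSE]
  eval_cell <- !is.na(r) & !is.na(t)
  match_cell <- eval_cell & (r == t)
  match_cell[!eval_cell] <- FALSE
  per_variant <- colSums(match_cell) / colSums(eval_cell)
  per_sample <- rowSums(match_cell) / rowSums(eval_cell)
  per_variant[colSums(eval_cell) == 0] <- NA_real_
  per_sample[rowSums(eval_cell) == 0] <- NA_real_
  flagged <- names(per_variant)[!is.na(per_variant) & per_variant < threshold]
  structure(list(per_variant = per_variant, per_sample = per_sample,
                 flagged = flagged, n_evaluable = colSums(eval_cell),
                 threshold = threshold),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d variants x %d samples\n",
              length(x$per_variant), length(x$per_sample)))
  cat(sprintf("  per-variant: median %.3f, min %.3f; %d flagged below %.2f\n",
              stats::median(x$per_variant, na.rm = TRUE),
              min(x$per_variant, na.rm = TRUE),
              length(x$flagged), x$threshold))
  invisible(x)
}

#' Effect-allele frequencies from a dosage matrix
#'
#' freq = sum of dosages / (2 x number of non-missing calls), per variant.
#' All-missing variants get NA.
#'
#' @param dosages samples x variants dosage matrix
#' @return named numeric vector of frequencies in [0,1]
#' @export
allele_frequency <- function(dosages) {
  n_called <- colSums(!is.na(dosages))
  freq <- colSums(dosages, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0] <- NA_real_
  freq
}

#' Coefficient of determination between two quantitative vectors
#'
#' The squared Pearson correlation, the R-squared of the simple linear
#' regression of y on x. Used for method comparison of allele frequencies,
#' scores and risks. Note R-squared is sign-blind: y = -x also gives 1.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return R-squared in [0,1]
#' @export
coefficient_of_determination <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: R-squared undefined")
  }
  stats::cor(x, y)^2
}

#' Per-variant mean-depth QC
#'
#' Flags each variant by its mean read depth across samples: `low` below
#' `low_mean` (default 30x, the minimal target depth per site), `good`
#' above `good_mean` (default 100x, comfortable coverage), `intermediate`
#' between.
#'
#' @param depths samples x variants depth matrix
#' @param low_mean low-coverage threshold on the per-variant mean
#' @param good_mean good-coverage threshold on the per-variant mean
#' @return data.frame: `variant_id`, `mean_depth`, `flag`
#' @export
depth_qc <- function(depths, low_mean = 30, good_mean = 100) {
  if (is.null(dim(depths)) || nrow(depths) == 0 || ncol(depths) == 0) {
    stop("empty depth table")
  }
  m <- colMeans(depths)
  flag <- ifelse(m < low_mean, "low", ifelse(m > good_mean, "good", "intermediate"))
  data.frame(variant_id = colnames(depths), mean_depth = unname(m),
             flag = unname(flag), stringsAsFactors = FALSE)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts
#' against the proportions expected at the estimated allele frequency
#' p = (2 n_hom_alt + n_het) / (2 n). Used to screen array markers whose
#' genotype distribution departs from random-mating expectation.
#' A monomorphic marker fits trivially (chi2 = 0, p = 1).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return list: `chi2`, `p`, `p_alt` (estimated alt-allele frequency)
#' @export
hwe_chi2 <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chi2 = 0, p = 1, p_alt = p))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       p_alt = p)
}
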