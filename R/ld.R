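#' Two-locus linkage-disequilibrium statistics from haplotype counts
#'
#' Given counts of the four two-locus haplotypes (alleles aligned on the
#' effect alleles A and B), computes the LD coefficient D = p_AB - p_A p_B,
#' the normalized D' = |D| / D_max, and the squared allelic correlation
#' r2 = D^2 / (p_A q_A p_B q_B). D_max is min(p_A q_B, q_A p_B) when D > 0
#' and min(p_A p_B, q_A q_B) when D < 0. The sign of D gives the map
#' orientation: negative means the effect alleles repel, so a surrogate
#' dosage must be reversed (d -> 2 - d) before scoring.
#'
#' @param n_AB,n_Ab,n_aB,n_ab non-negative haplotype counts
#' @return list of class `ld_stats`: `D`, `d_prime`, `r2`, `sign`
#'   ("positive"/"negative"), plus allele frequencies `pA`, `pB`
#' @export
ld_stats <- function(n_AB, n_Ab, n_aB, n_ab) {
  counts <- c(n_AB, n_Ab, n_aB, n_ab)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("haplotype counts must be non-negative finite numbers")
  }
  n <- sum(counts)
  if (n == 0) stop("haplotype counts sum to zero")
  pAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("LD undefined: at least one locus is monomorphic in the counts")
  }
  D <- pAB - pA * pB
  qA <- 1 - pA; qB <- 1 - pB
  if (D > 0) {
    Dmax <- min(pA * qB, qA * pB)
  } else {
    Dmax <- min(pA * pB, qA * qB)
  }
  d_prime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * qA * pB * qB)
  structure(list(D = D, d_prime = d_prime, r2 = r2,
                 sign = if (D < 0) "negative" else "positive",
                 pA = pA, pB = pB),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("D = %.6f  D' = %.4f  r2 = %.4f  (%s orientation)\n",
              x$D, x$d_prime, x$r2, x$sign))
  invisible(x)
}

#' Compute ld_stats from phased two-locus haplotypes
#'
#' @param hapA,hapB 0/1 integer vectors of equal length (one entry per
#'   chromosome, 1 = effect allele present)
#' @return an [ld_stats] object
#' @export
ld_stats_from_haplotypes <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  ld_stats(sum(hapA == 1 & hapB == 1), sum(hapA == 1 & hapB == 0),
           sum(hapA == 0 & hapB == 1), sum(hapA == 0 & hapB == 0))
}

#' Rank candidate proxy variants for a target
#'
#' Mirrors the panel-design procedure: candidates within a window around the
#' target, not flagged as excluded (repeats / low-complexity context are a
#' caller-side judgement), sorted by r2 descending, then D' descending, then
#' distance ascending, truncated to `top_k`. The returned rows carry the
#' orientation implied by the sign of D, ready to become proxy-map entries.
#'
#' @param candidates data.frame with columns `variant_id`, `distance_bp`,
#'   `r2`, `d_prime`, `sign` ("positive"/"negative"), `excluded` (logical),
#'   and optionally `exclusion_reason`
#' @param window_bp window half-width in bp (candidates farther away drop out)
#' @param top_k number of ranked candidates to return
#' @return data.frame of eligible candidates in rank order with an added
#'   `orientation` column; zero rows when nothing is eligible (the caller
#'   then falls back to assume_wildtype)
#' @export
rank_proxies <- function(candidates, window_bp = 50000, top_k = 3) {
  required <- c("variant_id", "distance_bp", "r2", "d_prime", "sign", "excluded")
  if (!all(required %in% names(candidates))) {
    stop("candidates need columns: ", paste(required, collapse = ", "))
  }
  cand <- as.data.frame(candidates)
  if (any(cand$distance_bp < 0)) stop("distance_bp must be >= 0")
  keep <- !cand$excluded & cand$distance_bp <= window_bp
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    cand$orientation <- character(0)
    return(cand)
  }
  ord <- order(-cand$r2, -cand$d_prime, cand$distance_bp)
  cand <- cand[ord, , drop = FALSE]
  cand <- utils::head(cand, top_k)
  cand$orientation <- ifelse(cand$sign == "negative", "negative", "positive")
  rownames(cand) <- NULL
  cand
}
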