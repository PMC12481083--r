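#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the conventional half-up rule (88.575 -> 88.58).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half-up at `digits` decimals
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalize chromosome names
#'
#' Accepts "chr15" and "15" interchangeably; strips any leading "chr"
#' (case-insensitive) so identifiers compare on bare numerals/letters.
#'
#' @param chrom character vector of chromosome names
#' @return character vector without the "chr" prefix
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Left-align and trim a ref/alt allele pair
#'
#' Minimal representation of an indel: shared trailing bases are removed
#' first, then shared leading bases (keeping at least one base each side and
#' advancing the position for each leading base dropped). SNVs pass through
#' unchanged. Matches the usual VCF normalization convention so model rows
#' and VCF records meet on the same representation.
#'
#' @param pos 1-based position
#' @param ref reference allele string
#' @param alt alternate allele string
#' @return list with elements `pos`, `ref`, `alt`
#' @export
normalize_allele_pair <- function(pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  # trim common suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim common prefix, advancing pos
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, toupper(ref), toupper(alt), sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
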