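# Small deterministic fixtures built in code.

# A hand-written toy model: 3 variants, one with effect allele = REF,
# one indel, weights chosen for easy mental arithmetic.
toy_model <- function() {
  prs_model(data.frame(
    variant_id = c("v1", "v2", "v3"),
    chromosome = c("1", "chr2", "15"),
    position = c(100L, 200L, 100905819L),
    ref = c("A", "G", "A"),
    alt = c("C", "GT", "C"),
    effect_allele = c("C", "G", "A"),   # v2 effect = REF, v3 effect = REF
    weight = c(0.5, -0.25, 0.1),
    array_status = c("genotyped", "imputed", "imputed"),
    low_complexity = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ), name = "toy")
}

# Write VCF text for given records; gts is a list of per-record genotype
# string vectors (one entry per sample).
write_test_vcf <- function(path, samples, records, gts) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT", gts[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A small simulated study shared by several heavier tests.
small_study <- function(n_samples = 80, seed = 11) {
  simulate_study(n_samples = n_samples, n_variants = 60, n_genotyped = 20,
                 n_low_complexity = 12, n_proxies = 8, n_negative = 2,
                 n_wildtype = 2, n_low_depth = 6, seed = seed)
}
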