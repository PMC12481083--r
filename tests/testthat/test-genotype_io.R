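test_that("dosage extraction counts effect alleles with REF/ALT orientation", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(
    path, samples = c("S1", "S2", "S3"),
    records = data.frame(chrom = c("1", "2", "15"),
                         pos = c(100, 200, 100905819),
                         id = c("v1", "v2", "v3"),
                         ref = c("A", "G", "A"),
                         alt = c("C", "GT", "C")),
    gts = list(c("0/1", "1/1", "0/0"),   # v1 effect = ALT
               c("0/1", "0/0", "1|1"),   # v2 effect = REF -> 2 - alt count
               c("./.", "0/1", "./1"))   # v3: missing, het, half-call
  )
  dos <- read_dosage_vcf(path, m)
  expect_equal(dos["S1", ], c(v1 = 1L, v2 = 1L, v3 = NA_integer_))
  expect_equal(dos["S2", ], c(v1 = 2L, v2 = 2L, v3 = 1L))
  expect_equal(dos["S3", ], c(v1 = 0L, v2 = 0L, v3 = NA_integer_))
})

test_that("effect=ALT and effect=REF views of the same genotype sum to 2", {
  base <- data.frame(
    variant_id = "x", chromosome = "7", position = 1000L,
    ref = "A", alt = "G", weight = 0.1,
    array_status = "genotyped", low_complexity = FALSE,
    stringsAsFactors = FALSE
  )
  m_alt <- prs_model(transform(base, effect_allele = "G"))
  m_ref <- prs_model(transform(base, effect_allele = "A"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c("S1", "S2", "S3"),
                 data.frame(chrom = "7", pos = 1000, id = "x",
                            ref = "A", alt = "G"),
                 list(c("0/0", "0/1", "1/1")))
  d_alt <- read_dosage_vcf(path, m_alt)
  d_ref <- read_dosage_vcf(path, m_ref)
  expect_equal(d_alt[, "x"] + d_ref[, "x"], c(S1 = 2L, S2 = 2L, S3 = 2L))
})

test_that("multiallelic records decompose; foreign-allele genotypes are missing", {
  m <- prs_model(data.frame(
    variant_id = "ma", chromosome = "4", position = 50L,
    ref = "A", alt = "T", effect_allele = "T", weight = 1,
    array_status = "genotyped", low_complexity = FALSE
  ))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c("S1", "S2", "S3"),
                 data.frame(chrom = "4", pos = 50, id = "ma",
                            ref = "A", alt = "G,T"),
                 list(c("0/2", "2/2", "1/2")))  # allele 2 = T matches model
  dos <- read_dosage_vcf(path, m)
  expect_equal(dos[, "ma"],
               c(S1 = 1L, S2 = 2L, S3 = NA_integer_))  # S3 carries foreign G
})

test_that("extraction matches an independent line-by-line parse on a synthetic VCF", {
  gen <- simulate_prs_model(n_variants = 20, n_genotyped = 8,
                            n_low_complexity = 4, seed = 21)
  truth <- simulate_truth_cohort(gen$model, gen$frequencies,
                                 n_samples = 10, seed = 22)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_dosage_vcf(truth, gen$model, path)
  dos <- read_dosage_vcf(path, gen$model)

  # oracle: raw text walk, counting ALT alleles per GT string
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1]]
  samples <- hdr[-(1:9)]
  oracle <- matrix(NA_integer_, length(samples), nrow(gen$model),
                   dimnames = list(samples, gen$model$variant_id))
  for (line in body) {
    f <- strsplit(line, "\t")[[1]]
    vid <- f[3]
    row <- gen$model[gen$model$variant_id == vid, ]
    for (s in seq_along(samples)) {
      al <- strsplit(sub(":.*", "", f[9 + s]), "[/|]")[[1]]
      if (any(al == ".")) next
      alt_n <- sum(al == "1")
      oracle[s, vid] <- if (row$effect_allele == row$ref) 2L - alt_n else alt_n
    }
  }
  expect_identical(dos[samples, gen$model$variant_id], oracle)
})

test_that("dosage extraction is invariant under VCF sample-column order", {
  m <- toy_model()
  recs <- data.frame(chrom = c("1", "2"), pos = c(100, 200),
                     id = c("v1", "v2"), ref = c("A", "G"),
                     alt = c("C", "GT"))
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(p1, c("S1", "S2"), recs,
                 list(c("0/1", "1/1"), c("0/0", "0/1")))
  write_test_vcf(p2, c("S2", "S1"), recs,
                 list(c("1/1", "0/1"), c("0/1", "0/0")))
  d1 <- read_dosage_vcf(p1, m)
  d2 <- read_dosage_vcf(p2, m)
  expect_identical(d1[c("S1", "S2"), ], d2[c("S1", "S2"), ])
})

test_that("depth tables key on sample/position with zero for absent rows", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tdepth",
               "S1\t1\t100\t250",
               "S1\t15\t100905819\t0",
               "S2\tchr2\t200\t77"),  # chr prefix normalized away on match
             path)
  dep <- read_depth_table(path, m)
  expect_equal(dep["S1", ], c(v1 = 250L, v2 = 0L, v3 = 0L))
  expect_equal(dep["S2", ], c(v1 = 0L, v2 = 77L, v3 = 0L))

  # no-row file -> all zeros for declared samples
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tchrom\tpos\tdepth", empty)
  dep0 <- read_depth_table(empty, m, samples = c("A", "B"))
  expect_true(all(dep0 == 0))
  expect_equal(dim(dep0), c(2L, 3L))

  # negative depth is a hard error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tdepth", "S1\t1\t100\t-3"), bad)
  expect_error(read_depth_table(bad, m), "negative")
})

test_that("depth round-trip through write_depth_table matches hand transcription", {
  gen <- simulate_prs_model(n_variants = 5, n_genotyped = 2,
                            n_low_complexity = 1, seed = 31)
  dep <- matrix(c(0L, 10L, 30L, 559L, 12L,
                  7L, 0L, 100L, 3L, 40L,
                  1L, 2L, 3L, 4L, 5L,
                  0L, 0L, 0L, 0L, 0L,
                  9L, 8L, 7L, 6L, 5L),
                nrow = 5, byrow = TRUE,
                dimnames = list(paste0("S", 1:5), gen$model$variant_id))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(dep, gen$model, path)
  back <- read_depth_table(path, gen$model, samples = rownames(dep))
  expect_identical(back, dep)
})
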