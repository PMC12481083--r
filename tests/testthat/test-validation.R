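test_that("classify_call implements the carrier dichotomy on the full 3x3 grid", {
  # enumerated oracle: positive = dosage >= 1, reference on the first slot
  grid <- expand.grid(ref = 0:2, test = 0:2)
  expected <- with(grid, ifelse(ref >= 1 & test >= 1, "TP",
                        ifelse(ref == 0 & test == 0, "TN",
                        ifelse(test >= 1, "FP", "FN"))))
  got <- classify_call(grid$ref, grid$test)
  expect_equal(got, expected)
  expect_equal(as.list(table(got)), list(FN = 2L, FP = 2L, TN = 1L, TP = 4L))
  expect_error(classify_call(NA, 1), "non-missing")
  expect_error(classify_call(3, 1), "0, 1 or 2")
})

test_that("confusion_metrics reproduces its defining ratios and NA on 0/0", {
  perfect <- confusion_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  m <- confusion_metrics(tp = 9, tn = 8, fp = 2, fn = 1, digits = NULL)
  expect_equal(unname(m["sensitivity"]), 9 * 100 / 10)
  expect_equal(unname(m["specificity"]), 8 * 100 / 10)
  expect_equal(unname(m["ppv"]), 9 * 100 / 11)
  expect_equal(unname(m["npv"]), 8 * 100 / 9)
  degenerate <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(degenerate["sensitivity"]))  # 0/0 is NA, never 0
  expect_true(is.na(degenerate["ppv"]))
  expect_equal(unname(degenerate["specificity"]), 100)
  expect_error(confusion_metrics(tp = -1, tn = 0, fp = 0, fn = 0))
})

test_that("confusion counts sum to samples x variants per stratum", {
  study <- small_study()
  ref <- resolve_dosage_matrix(study$array, study$model)$dosage
  test <- resolve_dosage_matrix(study$ngs$dosage, study$model,
                                study$proxy_map)$dosage
  cc <- confusion_counts(ref, test)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn,
               nrow(study$truth) * nrow(study$model))
  genotyped <- study$model$variant_id[study$model$array_status == "genotyped"]
  cc_g <- confusion_counts(ref, test, variants = genotyped)
  expect_equal(cc_g$tp + cc_g$tn + cc_g$fp + cc_g$fn,
               nrow(study$truth) * length(genotyped))
})

test_that("concordance matches a brute-force cell comparison and self is 1", {
  set.seed(33)
  vids <- paste0("v", 1:30)
  sids <- paste0("S", 1:20)
  ref <- matrix(sample(0:2, 600, replace = TRUE), 20, 30,
                dimnames = list(sids, vids))
  test <- ref
  flip <- matrix(runif(600) < 0.15, 20, 30)
  test[flip] <- (test[flip] + 1L) %% 3L
  test[sample(600, 25)] <- NA  # some unevaluable cells

  rep <- concordance(ref, test, threshold = 0.9)
  for (v in sample(vids, 8)) {
    ok <- 0; n <- 0
    for (s in sids) {
      if (is.na(test[s, v])) next
      n <- n + 1
      if (ref[s, v] == test[s, v]) ok <- ok + 1
    }
    expect_equal(unname(rep$per_variant[v]), ok / n)
  }
  for (s in sample(sids, 5)) {
    ok <- sum(ref[s, ] == test[s, ], na.rm = TRUE)
    n <- sum(!is.na(test[s, ]))
    expect_equal(unname(rep$per_sample[s]), ok / n)
  }
  expect_setequal(rep$flagged,
                  names(rep$per_variant)[rep$per_variant < 0.9])

  self <- concordance(ref, ref)
  expect_true(all(self$per_variant == 1))
  expect_true(all(self$per_sample == 1))
  expect_length(self$flagged, 0)
})

test_that("a variant discordant in 80 of 154 samples is flagged at 0.90", {
  sids <- sprintf("S%03d", 1:154)
  ref <- matrix(1L, 154, 2, dimnames = list(sids, c("bad", "good")))
  test <- ref
  test[1:80, "bad"] <- 0L
  rep <- concordance(ref, test, threshold = 0.90)
  expect_equal(unname(rep$per_variant["bad"]), (154 - 80) / 154)
  expect_equal(rep$flagged, "bad")
})

test_that("allele_frequency counts alleles over non-missing calls", {
  dos <- matrix(c(0L, 1L, 1L, 2L,
                  2L, 2L, 2L, 2L,
                  0L, 0L, 0L, 0L,
                  NA, 1L, NA, 2L),
                nrow = 4,
                dimnames = list(paste0("S", 1:4), c("half", "fix", "zero", "gap")))
  f <- allele_frequency(dos)
  expect_equal(unname(f["half"]), 0.5)   # 4 of 8 alleles
  expect_equal(unname(f["fix"]), 1.0)
  expect_equal(unname(f["zero"]), 0.0)
  expect_equal(unname(f["gap"]), 3 / 4)  # 3 of 4 called alleles
  all_na <- matrix(NA_integer_, 2, 1, dimnames = list(c("a", "b"), "v"))
  expect_true(is.na(allele_frequency(all_na)))
})

test_that("allele frequencies are permutation-invariant and track simulation truth", {
  gen <- simulate_prs_model(n_variants = 10, n_genotyped = 5,
                            n_low_complexity = 0, seed = 44)
  truth <- simulate_truth_cohort(gen$model, gen$frequencies, 5000, seed = 45)
  f <- allele_frequency(truth)
  expect_equal(allele_frequency(truth[sample(nrow(truth)), ]), f)
  se <- sqrt(gen$frequencies * (1 - gen$frequencies) / (2 * 5000))
  expect_true(all(abs(f - gen$frequencies) < 3.5 * se))
})

test_that("coefficient_of_determination matches the textbook formula", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3, 2.9, 3.3, 1.1, 4.0)
  set.seed(5)
  y <- 2 * x + rnorm(10)
  # oracle: explicit covariance formula
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(coefficient_of_determination(x, y), r^2, tolerance = 1e-12)
  expect_equal(coefficient_of_determination(x, x), 1)
  expect_equal(coefficient_of_determination(x, -x), 1)  # sign-blind
  expect_error(coefficient_of_determination(x, rep(1, 10)), "variance")
  expect_error(coefficient_of_determination(1:2, 1:3), "equal length")
})

test_that("depth_qc flags means against the 30x/100x thresholds", {
  dep <- matrix(c(0, 0, 0,
                  559, 600, 520,
                  40, 50, 60,
                  29, 30, 31),
                nrow = 3,
                dimnames = list(paste0("S", 1:3), c("dead", "deep", "mid", "edge")))
  qc <- depth_qc(dep)
  expect_equal(qc$flag[qc$variant_id == "dead"], "low")
  expect_equal(qc$flag[qc$variant_id == "deep"], "good")
  expect_equal(qc$flag[qc$variant_id == "mid"], "intermediate")
  expect_equal(qc$mean_depth[qc$variant_id == "edge"], 30)
  expect_equal(qc$flag[qc$variant_id == "edge"], "intermediate")
  # means equal the arithmetic-mean oracle on a random table
  set.seed(6)
  r <- matrix(rpois(50, 80), 10, 5,
              dimnames = list(paste0("S", 1:10), paste0("v", 1:5)))
  expect_equal(depth_qc(r)$mean_depth, unname(apply(r, 2, mean)))
})

test_that("hwe_chi2 is exact at equilibrium and maximal at full het deficit", {
  eq <- hwe_chi2(25, 50, 25)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # (50, 0, 50): p = 0.5, expected (25, 50, 25), chi2 = 25 + 50 + 25 = total
  deficit <- hwe_chi2(50, 0, 50)
  expect_equal(deficit$chi2, 100)
  mono <- hwe_chi2(100, 0, 0)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
  # cross-check against stats::chisq.test goodness-of-fit on a non-trivial case
  counts <- c(30, 40, 30)
  p <- (2 * 30 + 40) / 200
  expected_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  ref <- suppressWarnings(stats::chisq.test(counts, p = expected_p))
  got <- hwe_chi2(30, 40, 30)
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, stats::pchisq(got$chi2, 1, lower.tail = FALSE))
})
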