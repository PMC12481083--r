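# prsseq

Polygenic risk scores (PRS) for breast cancer — in particular the
313-variant PRS used by BOADICEA/CanRisk — are conventionally genotyped on
SNP microarrays with imputation of untyped sites. Oncogenetics laboratories,
however, already sequence targeted gene panels; computing the PRS from the
same sequencing run removes the need for a separate genotyping platform.
Targeted sequencing brings its own failure mode: a minority of score
variants sit in low-complexity regions that cannot be covered reliably.

`prsseq` implements the sequencing-based PRS workflow for clinical
laboratories and method developers:

* **Scoring.** For sample *i*, `PRS_i = Σ_j w_j · d_ij`, where `w_j` is the
  per-effect-allele log-odds weight of variant *j* and `d_ij ∈ {0, 1, 2}`
  its effect-allele dosage. Dosages are read from a VCF; when the effect
  allele is the REF allele the ALT count is reversed (`d = 2 − ALT count`).
* **Proxy substitution.** A variant that cannot be sequenced is replaced by
  a surrogate SNP in strong linkage disequilibrium. The surrogate's dosage
  is used with the *original* variant's weight; when the two effect alleles
  are in repulsion (negative LD, `D < 0`) the observed dosage is reversed,
  `d → 2 − d`. Sites with no usable surrogate fall back to the wild-type
  genotype (dosage 0), as do sporadic missing calls — every fallback is
  logged per sample and variant.
* **LD toolkit.** `D`, `D′` and `r²` from two-locus haplotype counts, and
  candidate-proxy ranking (r² first, then D′, then distance, inside a 50 kb
  window) producing ready-to-use proxy-map rows.
* **Validation battery.** Carrier-dichotomy confusion metrics
  (sensitivity/specificity/PPV/NPV, overall and restricted to
  array-genotyped variants), exact three-level genotype concordance per
  variant and per sample, allele-frequency comparison, PRS coefficient of
  determination, per-variant coverage QC (30x/100x mean-depth flags) and
  Hardy–Weinberg chi-square screening.
* **Risk categorization.** NICE category assignment for lifetime
  (<17 / 17–30 / >30 %) and 10-year (<3 / 3–8 / >8 %) breast-cancer risks
  and category-change cross-tabulation between two methods. Risk
  percentages (e.g. CanRisk output) are inputs; the risk model itself is
  out of scope.
* **Cohort simulator.** Synthetic truth cohorts with controlled two-locus
  LD, array observations with separate miscall rates for genotyped and
  imputed markers, and sequencing observations with negative-binomial
  depth, depth-dependent dropout, read-level genotype likelihoods and
  systematic low-complexity miscalls — so the whole pipeline is testable
  without patient data.

## Worked example

```r
library(prsseq)

study <- simulate_study(n_samples = 154, seed = 42)   # paired array + NGS cohort
scores_array <- compute_prs(study$array, study$model)
scores_ngs   <- compute_prs(study$ngs$dosage, study$model, study$proxy_map)
head(scores_ngs, 4)
#>   sample_id         prs n_direct n_proxy n_reversed n_wildtype_fallback
#> 1     S0001 -0.08938324      284      25          2                   2
#> 2     S0002  0.07264007      284      25          2                   2
#> 3     S0003  1.23401714      284      25          2                   2
#> 4     S0004  0.71089927      284      25          2                   2
```

Each of the 313 variants resolves to exactly one path: here 284 scored
directly, 25 through positively oriented surrogates, 2 through reversed
(negative-LD) surrogates, and 2 as wild-type fallback — the sites with no
sequenceable surrogate.

```r
coefficient_of_determination(scores_array$prs, scores_ngs$prs)
#> [1] 0.826
ref  <- resolve_dosage_matrix(study$array, study$model)$dosage
test <- resolve_dosage_matrix(study$ngs$dosage, study$model, study$proxy_map)$dosage
confusion_metrics(confusion_counts(ref, test))
#> sensitivity specificity         ppv         npv
#>       98.12       96.95       98.71       95.59
qc <- depth_qc(study$ngs$depth[, study$model$variant_id])
sum(qc$flag == "low")
#> [1] 15
```

The sensitivity/specificity are percentages of carrier calls (≥1 effect
allele) agreeing with the array reference; the 15 low-flagged sites are the
simulated panel's mean-depth < 30x variants.

A command-line wrapper over the same functions ships at
`inst/cli/prsseq.R` with subcommands `score`, `validate`, `simulate`,
`proxy-rank`, `categorize`, `compare-categories` and `depth-qc`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","prsseq.R",package="prsseq"))')" \
    score --model model.tsv --proxy-map proxy_map.tsv --vcf calls.vcf --out scores.tsv
```

## Vignette

`vignettes/prs-by-sequencing.Rmd` documents the model, the proxy-resolution
semantics, every tunable threshold with its default, the simulator's error
model and its limitations.
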