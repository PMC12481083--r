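Package: prsseq
Title: Polygenic Risk Score Calculation and Validation for Targeted Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the 313-variant breast-cancer polygenic risk score (PRS313)
    from targeted next-generation sequencing genotypes, with linkage-disequilibrium
    proxy substitution for unsequenceable sites, orientation-aware dosage reversal,
    and wild-type fallback for missing calls. Includes a method-comparison
    validation battery (carrier-based confusion metrics, three-level genotype
    concordance, allele-frequency and score correlation, coverage QC,
    Hardy-Weinberg screening), NICE risk-category assignment for lifetime and
    10-year breast-cancer risks, and a cohort simulator producing paired
    array-plus-imputation and sequencing observations with controlled LD,
    genotyping error, and depth-dependent dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
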