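---
title: "Computing a polygenic risk score from targeted sequencing: model, proxy resolution and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing a polygenic risk score from targeted sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsseq)
```

## The scoring model

A polygenic risk score is a weighted sum over a fixed panel of risk
variants. For sample $i$,

$$\mathrm{PRS}_i \;=\; \sum_{j=1}^{m} w_j \, d_{ij},$$

where $w_j$ is the per-effect-allele log-odds coefficient of variant $j$
and $d_{ij} \in \{0,1,2\}$ the number of effect-allele copies in the
diploid genotype. The effect allele may be either REF or ALT of the VCF
representation; when it is REF, the dosage is $2$ minus the ALT-allele
count. Hard genotype calls are used (the most probable genotype), not
expected dosages: targeted sequencing at the depths this workflow assumes
makes the called genotype essentially deterministic, and the array
reference pipeline converts its most probable genotype the same way. The
score is a plain sum, so it is invariant under variant ordering and bounded
by $\sum_j \min(0, 2w_j) \le \mathrm{PRS} \le \sum_j \max(0, 2w_j)$ — both
properties are asserted in the test suite.

Scores are computed and stored at full floating precision; rounding
(conventionally 4 decimals for display) is left to the formatting layer.

## Proxy resolution

A targeted panel cannot reliably sequence every score variant: sites in
homopolymers and repeats yield low or zero coverage, or systematically
wrong calls. The remedy is a *proxy map*. Each entry either

* **substitutes** a surrogate SNP in strong linkage disequilibrium with the
  original variant — the surrogate's observed dosage enters the sum with
  the *original* variant's weight, because the substitution replaces the
  genotyping of the site, not its effect estimate; or
* **assumes wild-type** (dosage 0) when no usable surrogate exists — the
  wild-type genotype is the most frequent in the population, making 0 the
  modal dosage and the least-bad constant guess.

Orientation matters. Writing $A$/$B$ for the effect alleles at the original
and surrogate locus, the LD coefficient is $D = p_{AB} - p_A p_B$. When
$D < 0$ the two effect alleles repel: the surrogate's effect-aligned allele
travels with the original's *non*-effect allele, so an observed surrogate
dosage $d$ maps to an effective original dosage $2 - d$. This reversal is
an involution ($d \mapsto 2-(2-d) = d$), which the suite checks for all
dosages.

Missing observations — a surrogate absent from the VCF, a dropout below the
depth cutoff, a half-called genotype — are scored as wild-type too, and
logged per sample and variant as `missing_as_wildtype`. The fallback is
applied regardless of the weight's sign: choosing the dosage that minimizes
the score contribution instead would bias scores downward for positive
weights, whereas dosage 0 is simply the most probable genotype whenever the
effect allele is the minor allele, and the resolution log keeps every such
cell auditable. The policy deliberately never errors: a clinical score must
be computable for every sample, with the degradation surfaced rather than
fatal.

## LD statistics and proxy ranking

From the four two-locus haplotype counts the toolkit computes
$D$, $D' = |D|/D_{\max}$ and $r^2 = D^2/(p_A q_A p_B q_B)$, with
$D_{\max} = \min(p_A q_B,\, q_A p_B)$ for $D>0$ and
$\min(p_A p_B,\, q_A q_B)$ for $D<0$. A monomorphic locus makes LD
undefined and is an error. $D'=0$ is reported when $D=0$ exactly.

Candidate surrogates for a dead site are ranked inside a window
(default 50 kb, the span over which useful LD partners are realistically
found) by $r^2$ descending, then $D'$ descending, then distance ascending.
$r^2$ leads the sort because it directly bounds the accuracy of dosage
substitution ($r^2$ is the squared correlation of the two dosage
variables); $D'$ only tells whether recombination has separated the
alleles. Repeat/low-complexity exclusion is a caller-supplied flag: no
programmatic repeat-masking source is bundled, and in practice this
judgement is made by inspecting the genomic context. An empty ranking is
not an error — it is the signal to fall back to `assume_wildtype`.

## Validation battery

Two genotype-comparison rules coexist, answering different questions:

* **Carrier dichotomy** for the confusion matrix: a call is positive when
  it carries at least one effect allele. Both carriers → TP, both
  non-carriers → TN, test-only carrier → FP, reference-only → FN, so every
  sample–variant pair lands in exactly one cell and the four counts always
  sum to samples × variants (asserted on every synthetic cohort). A
  heterozygous/homozygous swap is a TP here. Metrics are
  $\mathrm{sens} = 100\,\mathrm{TP}/(\mathrm{TP+FN})$,
  $\mathrm{spec} = 100\,\mathrm{TN}/(\mathrm{TN+FP})$,
  $\mathrm{PPV} = 100\,\mathrm{TP}/(\mathrm{TP+FP})$,
  $\mathrm{NPV} = 100\,\mathrm{TN}/(\mathrm{TN+FN})$; a zero denominator
  yields NA, never 0. Reported percentages are rounded half-up to 2
  decimals; raw values are retained in machine-readable output.
* **Three-level concordance** for panel QC: exact equality of the
  non-carrier / heterozygous / homozygous genotype, per variant (fraction
  of samples matching) and per sample (fraction of variants matching),
  over evaluable (both-called) pairs. Variants below a threshold (default
  0.90) are flagged for redesign.

The confusion comparison can be restricted to the array-genotyped
(non-imputed) stratum to separate sequencing error from imputation error —
on real data the two strata differ dramatically, because imputation, not
array chemistry, dominates the reference method's error.

Additional checks: effect-allele frequencies
($\hat p = \sum_i d_{ij} / 2n_j$ over called samples), the coefficient of
determination between two score or frequency vectors (squared Pearson
correlation — note it is sign-blind), per-variant mean-depth QC with `low`
below 30x and `good` above 100x (30x is the minimal per-target depth the
panel design aims for; 100x is comfortable coverage), and a 1-df
Hardy–Weinberg chi-square per marker at the estimated allele frequency
(monomorphic markers fit trivially: $\chi^2 = 0$, $p = 1$).

## Risk categories

Risk percentages computed externally (CanRisk/BOADICEA — a large clinical
model this package deliberately treats as an upstream input) are binned
into the NICE bands: lifetime risk below 17 % near-population, 17 % up to
but excluding 30 % moderate, 30 % and above high; 10-year risk below 3 %
near-population, 3 % to 8 % inclusive moderate, above 8 % high. The
asymmetry of the upper boundaries (lifetime 30 is high, ten-year 8 is
still moderate) follows the guideline wording. Category changes between
two methods are counted over records matched by subject, scenario and
horizon, with the percentage reported at one decimal and at integer
display rounding.

## The simulator and what it does (not) show

`simulate_study()` generates the whole paired-method experiment. Its
defaults are the study geometry: 154 samples, 313 variants of which 105
array-genotyped and 208 imputed, 29 low-complexity sites of which 27 get
surrogates (2 in negative LD) and 2 fall back to wild-type, and 15 sites
with mean depth below 30x. Other defaults, with rationale:

| parameter | default | why |
|---|---|---|
| effect-allele frequency | uniform on [0.05, 0.95] | spans common-variant frequencies while keeping small cohorts polymorphic |
| weight distribution | N(0, 0.06) | yields a population score sd near 0.6 for 313 variants, matching published score spreads |
| array miscall, genotyped | 0.001 | direct array typing is nearly exact |
| array miscall, imputed | 0.03 | imputed calls carry the reference method's real error; chosen to put imputed-site concordance in the mid-90s |
| panel mean depth | 559x (gamma across sites, NB dispersion 10 per cell) | deep targeted panels are overdispersed around a high mean |
| dropout threshold | 8 reads per call | below ~8 reads a diploid genotype is not confidently callable; distinct from the 30x *mean*-depth QC flag |
| per-read error | 0.001 | post-filter base error of modern short-read chemistry |
| low-complexity site error | 0.4 | systematic mismapping that depth does not fix, producing the <50 % concordance seen at the worst sites |

Imputation error is modelled as independent per-call miscalls (uniform over
the two other genotypes), not as haplotype-reference mis-phasing: only the
outcome (concordance) is quantified in method comparisons, not the
mechanism, and the independent-miscall model reproduces that outcome with
one interpretable parameter. Sequencing genotypes are called by maximum
likelihood from binomial read sampling of the two alleles with symmetric
per-read error — the simplest mechanism that makes accuracy rise with
depth. Linked pairs are drawn from the four-haplotype distribution
$p_{AB} = p_A p_B + D$ etc., with $D = r\sqrt{p_A q_A p_B q_B}$ and an
infeasible $(p_A, p_B, r)$ triple rejected with the feasible range named.
Surrogate frequencies are matched ($p_B = p_A$, or $1-p_A$ for repulsion)
so that any $|r| \le 1$ is feasible.

What passing tests on this generator demonstrate: the arithmetic of
scoring, reversal and fallback; that the validation statistics estimate
their targets (injected error $\varepsilon$ → concordance
$1-\varepsilon$ within binomial error; realized $r^2$ → requested $r^2$);
and that proxy quality orders score recovery (score $R^2$ against truth is
monotone in surrogate $r^2$, with a perfect surrogate matching direct
genotyping and wild-type fallback at the bottom). What they do **not**
show: real-data values of sensitivity or score $R^2$, which depend on a
particular cohort's allele frequencies, imputation panel and sequencing
chemistry; linkage structure beyond two loci; batch effects; or
reference-panel-driven, haplotype-correlated imputation errors. The
simulator's error rates were fixed from the qualitative behaviour they must
reproduce, not fitted to any published table.

## Numerical and design choices

* Percent rounding is half-up (`round_half_up()`), matching how clinical
  tables are conventionally printed; base R's banker's rounding would
  disagree on exact halves.
* Chromosome names are accepted with or without the `chr` prefix and
  compared bare; ref/alt pairs are left-aligned to their minimal
  representation (suffix first, then prefix) so indels match their VCF
  normalization.
* Genotype parsing: phased and unphased separators are equivalent;
  half-calls, non-diploid calls and genotypes involving a foreign ALT
  allele of a multiallelic record are missing, never guessed.
* Proxy ranking tie-breaks and the ML genotype caller break exact ties
  deterministically (first/lowest), so identical inputs give identical
  outputs.
* Tests run the statistical checks at reduced but adequate sizes — 5,000
  samples for error-rate recovery (binomial SE ≈ 0.2 % at
  $\varepsilon = 0.05$), 2,000 samples × 10 proxied sites for the
  proxy-efficacy ordering, 10,000 haplotypes for LD convergence — sizes at
  which the expected effects exceed three standard errors.

## Limitations

* The package consumes called genotypes (VCF) and read-depth tables; it
  does not align reads, call variants, phase or impute.
* Proxy discovery ranks caller-supplied candidates; it does not query
  population LD services, and repeat-masking is manual.
* Published per-variant weights are required user input — they are not
  bundled and not fetched from external catalogues.
* The empirical step of a real panel redesign — sequencing candidate
  surrogates and keeping only those that outperform the original site —
  requires wet-lab iteration and is documented, not automated.
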