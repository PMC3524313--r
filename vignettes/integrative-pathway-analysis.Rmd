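---
title: "Integrative pathway analysis of GWAS and expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative pathway analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Single-marker tests of genome-wide association (GWAS) data and single-gene
tests of expression data both struggle when a disease works through many
functionally related genes, each contributing weakly. Gene-set (pathway)
analysis aggregates evidence over such groups, and doing it on two
platforms at once — allele-frequency differences in a case/control GWAS
and mean-expression differences in a matched case/control expression study
— lets each platform corroborate the other. `intpath` implements that
workflow end to end: per-SNP allelic association with quality control,
SNP-to-gene mapping, four permutation-based gene-set tests on the GWAS
arm, signal-to-noise GSEA on the expression arm, and Fisher's combined
probability test across the two.

Pathway tests divide by their null hypothesis. *Competitive* tests ask
whether a set is more associated than the rest of the genome (here: GSEA
on gene statistics, and SNP-resampling over-representation in the
ALIGATOR style). *Self-contained* tests ask whether the set is associated
at all (here: the SNP ratio test and the LD-pruned set-based
mean-chi-square test). The four cover both camps deliberately: their
answers differ, and the differences are informative.

# The statistics

## Allelic association and gene-wise statistics

Each SNP is tested with the basic allelic test: the 2x2 table of
minor/major allele counts in cases and controls (2N alleles per class,
missing calls excluded), Pearson chi-square with 1 df and no continuity
correction. Genomic inflation is summarized by
`lambda = median(chi2) / qchisq(0.5, 1)` and reported descriptively only —
no correction is applied, matching the descriptive use of lambda in this
kind of analysis.

A gene's representative statistic is the maximum chi-square over the SNPs
mapped to it: a SNP belongs to a gene when it lies within the gene body or
within 20 kb of either boundary (inclusive at exactly 20 kb; strand
ignored; a SNP in two overlapping windows counts for both genes).
Max-over-SNPs favours genes with at least one strong signal and is the
convention of the GWAS-GSEA lineage this package follows.

## The enrichment score

Genes are ranked by their statistic (descending). Walking the ranking, the
running sum rises by `|s_i|^w / sum_members |s_j|^w` at a member gene and
falls by `1/(N - N_members)` at a non-member; the enrichment score (ES) is
the signed value of maximum absolute departure from zero. `w = 1`
(weighted, the default) follows the expression-GSEA tradition; `w = 0`
gives the classic Kolmogorov-Smirnov statistic. The normalized score
divides ES by the mean of same-signed permutation ES values.

## Permutation nulls

All self-contained tests and both GSEA variants swap case/control labels
and recompute *everything* downstream of the labels — allelic tests, gene
statistics, snr values, LD-pruned selections — in every permutation.
Swapping labels rather than genotypes preserves the LD structure among
SNPs, which is what makes the nulls honest. The empirical P-value uses the
`(b + 1)/(B + 1)` convention (the observed statistic counts as one of its
own permutations), so P is never zero and Fisher combination downstream
stays finite. GSEA nominal P-values are computed against the same-signed
portion of the permutation ES distribution, the convention of the original
GSEA: with a sign-symmetric ES null, counting both tails in one pool would
cap every P near 0.5.

The SNP-resampling test is the exception: instead of permuting phenotypes
it draws random SNPs without replacement until the drawn SNPs hit exactly
as many distinct genes as the observed count of "significant genes"
(genes holding at least one SNP with P < 0.05); a draw that would
overshoot because one SNP adds several new genes is discarded and the walk
continues. Each set is then scored by how many of its genes appear in the
replicate's list.

## The set-based test

Per set, SNPs are selected greedily: take the most significant remaining
SNP with P below the cutoff, discard every remaining SNP with dosage
r-squared above 0.5 to it, repeat up to 5 selections. The score is the
mean chi-square of the selection (0 if nothing is selected). r-squared is
the squared Pearson correlation of dosage vectors (composite LD — no
phasing is attempted or needed), and because LD is a property of the
genotypes it is computed once per set and reused across permutations.

## Expression arm

Expression preprocessing: optional quantile normalization (all samples
forced to the common distribution of row-mean order statistics, ties
averaged), probe-to-gene collapsing by element-wise median, and Welch's
two-sample t-test with Benjamini-Hochberg FDR. The GSEA ranking statistic
is the signal-to-noise ratio `(mu_case - mu_ctrl)/(sd_case + sd_ctrl)`
with each class SD floored at `0.2 |class mean|` so it is always finite;
the floor constant follows the original GSEA implementation and is
configurable in spirit (it is a documented constant in the code).
Welch rather than Student because the two classes need not share a
variance and are rarely the same size; BH because no particular FDR scheme
is canonical for the t-test step.

## Cross-platform combination

For every pathway eligible on both platforms (present in both filtered
collections), Fisher's method combines the two nominal P-values:
`chi2 = -2 (ln p_gwas + ln p_expr)` referred to chi-square with 4 df. BH
FDR is computed over the intersection. Significance is two-tiered:
tier 1 is nominal `P < 0.01`, tier 2 is `FDR < 0.2`; both strict. The
loose FDR cutoff is intentional — cross-platform signals are expected to
be weak, and the second tier exists to avoid discarding marginal but
concordant pathways.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| QC: min call rate | 0.90 | fraction | drop SNPs typed in < 90% of samples (strict `<`) |
| QC: min MAF | 0.05 | fraction | rare SNPs carry unstable chi-square tables |
| QC: max sample missingness | 0.10 | fraction | drop samples with > 10% missing calls, before SNP filters |
| SNP-gene flank | 20,000 | bp | regulatory neighbourhood; boundary inclusive |
| set size bounds | 5-250 | genes | below 5 a set is a gene test, above 250 a chromosome test; measured after universe intersection |
| permutations | 1000 | swaps | 10,000 SNP resamples for the resampling test (its unit is the SNP, so replicates are cheap) |
| SNP significance cut | 0.05 | P | shared by ratio, resampling and set-based tests |
| LD prune r2 | 0.5 | — | composite-LD threshold of the set-based test |
| max selected SNPs | 5 | count | cap on the greedy selection per set |
| GSEA weight | 1 | exponent | 0 gives the unweighted KS variant |
| tier cuts | 0.01 / 0.2 | P / FDR | strict inequalities |

Filter order inside QC is: samples first, then SNPs, with MAF and call
rate recomputed after the sample drop — the order is not dictated by the
statistics, so it is fixed explicitly and reported.

# The synthetic-data generator

Real controlled-access genotypes and the matching expression series cannot
ship with a package, so every stage is validated on synthetic studies with
known truth. The generator emulates the *structure* that the methods
exercise, not human genetics in general:

- **Genome**: genes tiled in disjoint 50 kb windows (10 kb body, 20 kb
  flank each side) on one synthetic chromosome, so the default flank maps
  every SNP to exactly one gene and mapping is unambiguous by design.
- **Genotypes**: per gene, dosages from a latent-Gaussian threshold model
  — two independent haplotypes per sample, each sharing one gene-level
  Gaussian factor with weight `sqrt(rho)` — giving exchangeable
  within-gene LD (`rho = 0.6` by default) and independence between genes.
  Minor-allele frequencies are uniform on 0.1-0.5.
- **Phenotype**: logistic disease model,
  `logit P(case) = alpha + sum(causal log-OR x dosage)`, with `alpha`
  solved so the expected case fraction matches the target; sampling
  proceeds in batches until the exact class counts are reached. A logistic
  model (rather than liability threshold) keeps per-SNP odds ratios
  interpretable and matches the allelic test being validated.
- **Planted effects**: one designated pathway; half of its genes carry one
  causal SNP each at log-OR 0.35, and the same genes are shifted by
  +1 log2 unit in cases (noise SD 0.5) in the expression matrix. 300
  cases, 300 controls, 300 genes x 5 SNPs, 50 sets of 20 genes.

Defaults were chosen once as a realistic mid-power regime: log-OR 0.35
(odds ratio ~1.4) per causal variant at these sample sizes gives per-SNP
power around 0.5-0.85 depending on the drawn MAF, so pathway-level
aggregation is genuinely needed — single SNPs do not reach genome-wide
significance, which is exactly the regime pathway analysis exists for.

What the generator does **not** emulate: realistic recombination maps and
long-range LD, population structure, genotyping error, probe-level
microarray artefacts, and correlated expression networks. Passing tests
therefore demonstrate statistical correctness of the machinery (nulls,
scores, permutation logic), not performance on real human data.

With 50 sets x 20 genes drawn from 300 genes, sets overlap each other
(each gene sits in ~3 sets on average) — as real pathway collections do.
One consequence is worth knowing: sets that share several planted effect
genes are genuinely enriched too, and at modest permutation counts every
super-significant set hits the empirical-P floor, where ranking among them
is resolution noise rather than evidence.

# Numerical and design choices

- **Minor-allele ties** (MAF exactly 0.5) break to the lexicographically
  smaller allele; **gene-statistic ties** to the smaller position, then
  SNP id; **ranking ties** in GSEA to the gene identifier. All are logged;
  the point is bit-identical reruns.
- **Degenerate allele tables** (a zero margin) score chi2 = 0, P = 1 and
  are flagged rather than erroring: monomorphic-in-sample SNPs appear
  routinely inside permutations.
- **Empty selections** in the set-based test score 0 with P = 1; sets with
  no mapped SNPs are dropped from the ratio test with a warning.
- **Probabilities of zero** are rejected by `fisher_combine()` with an
  instruction to clamp at `1/(B+1)`; the empirical-P convention guarantees
  this cannot arise from in-package callers.
- **The ES fast path**: per permutation the running sum is evaluated only
  at member positions and the positions just before them (it is piecewise
  linear in between and ends at zero), which matches the full walk exactly
  and is what makes rerunning GSEA inside 200-1000 permutations cheap. The
  equivalence is tested against a brute-force walk and against an
  independent implementation.
- **Sizes used in the validation suite**: null calibration runs 200 sets x
  200 permutations on a 1500-SNP, 600-sample study; recovery runs 25
  replicate studies at 200 swaps (1000 resamples). These sizes were chosen
  to make the Monte-Carlo error small relative to the assertions while the
  whole suite stays interactive.

# Known limitations

- **SRT conservatism.** The SNP-ratio statistic is discrete (an integer
  count over the set's SNPs, coarsened further by LD), and the
  tie-inclusive `(b+1)/(B+1)` convention makes its empirical P
  super-uniform: valid (type-I error at or below nominal) but
  conservative, with mean null P around 0.55-0.60 for 50-SNP sets. This is
  a property of the published method, reproduced faithfully, and it fades
  as sets grow.
- **Within-study dependence.** All sets in one study share the genotypes
  and the permutation ensemble, so their empirical P-values are correlated
  and drift together with the study-wide association level. Distributional
  statements (e.g. "null P-values are uniform") are meaningful marginally
  over independent studies, and the test suite checks them that way; a
  uniformity test applied to the sets of a single study rejects far more
  often than its nominal level even when the method is exactly correct.
- **Fisher independence.** Combining platforms with Fisher's method
  assumes the two P-values are independent — reasonable for two disjoint
  cohorts, not guaranteed in general; no dependence-adjusted variant
  (e.g. Brown's method) is provided.
- **Resampling test power.** The gene-count statistic discards effect
  magnitude, so the SNP-resampling test is the least powered of the four
  at moderate effect sizes; in validation runs it recovers the planted
  pathway less reliably than the other three, and analyses should read its
  negatives accordingly.

# Reproducibility

Every stochastic function takes a `permutation_plan(n_perm, seed, scheme)`
or a seeded config and derives all randomness from that seed; the
permutation recipe (column b is `sample()` number b of the case-indicator
vector after `set.seed(seed)`) is documented and frozen, so identical
inputs give byte-identical result tables. `run_pipeline()` writes a config
snapshot next to its outputs; re-running on the snapshot reproduces them
exactly.
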