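# Quality control, the basic allelic test, and genomic inflation.
#
# The allelic test compares minor-allele counts between cases and controls
# in a 2x2 table with 2N alleles per class (Pearson chi-square, 1 df, no
# continuity correction). A vectorized engine computes the statistic for
# every SNP against many case/control label assignments at once; the whole
# phenotype-permutation machinery downstream rides on it.

#' Quality-control thresholds
#'
#' Defaults follow common GWAS practice: drop samples with > 10% missing
#' genotypes, then SNPs with call rate < 90%, minor allele frequency < 0.05
#' (recomputed after sample removal), or monomorphic genotypes. All
#' comparisons are strict, so boundary values survive.
#'
#' @param min_call_rate Minimum SNP call rate (fraction).
#' @param min_maf Minimum minor-allele frequency.
#' @param max_sample_missing Maximum per-sample missing fraction.
#' @param drop_monomorphic Drop SNPs with a single observed allele?
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          max_sample_missing = 0.10, drop_monomorphic = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_sample_missing = max_sample_missing,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_thresholds")
}

# Per-SNP minor-allele frequency from a dosage matrix (missing excluded).
.snp_maf <- function(dosage) {
  nonmiss <- rowSums(!is.na(dosage))
  cnt <- rowSums(dosage, na.rm = TRUE)
  f <- ifelse(nonmiss > 0, cnt / (2 * nonmiss), NA_real_)
  pmin(f, 1 - f)
}

#' Apply quality control to a genotype study
#'
#' Filter order: (1) samples with missingness > `max_sample_missing`,
#' then (2) SNPs with call rate < `min_call_rate`, MAF < `min_maf`
#' (recomputed after the sample drop), or monomorphic status. The result is
#' independent of input row order.
#'
#' @param study A [genotype_study()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `study` (filtered) and `report` (counts dropped per rule).
#' @export
apply_qc <- function(study, thresholds = qc_thresholds()) {
  stopifnot(inherits(study, "genotype_study"))
  th <- thresholds
  d <- study$dosage

  samp_miss <- colMeans(is.na(d))
  keep_samp <- samp_miss <= th$max_sample_missing
  n_samp_dropped <- sum(!keep_samp)
  if (!any(keep_samp)) stop("empty study: all samples removed by QC")
  d2 <- d[, keep_samp, drop = FALSE]
  pheno <- study$phenotype[keep_samp]

  call_rate <- rowMeans(!is.na(d2))
  maf <- .snp_maf(d2)
  low_call <- call_rate < th$min_call_rate
  low_maf <- !is.na(maf) & maf < th$min_maf
  mono <- is.na(maf) | maf == 0
  drop_snp <- low_call | low_maf | (th$drop_monomorphic & mono)
  if (all(drop_snp)) stop("empty study: all SNPs removed by QC")

  keep <- which(!drop_snp)
  out <- genotype_study(study$snp_ids[keep], study$chrom[keep],
                        study$pos[keep], d2[keep, , drop = FALSE],
                        study$sample_ids[keep_samp], pheno)
  report <- list(samples_dropped = n_samp_dropped,
                 snps_low_call_rate = sum(low_call),
                 snps_low_maf = sum(low_maf & !low_call &
                                      !(th$drop_monomorphic & mono)),
                 snps_monomorphic = sum(th$drop_monomorphic & mono &
                                          !low_call),
                 snps_retained = length(keep),
                 samples_retained = sum(keep_samp))
  list(study = out, report = report)
}

# Vectorized allelic chi-square for all SNPs against B case-indicator
# columns. `case_ind` is samples x B with entries 1 (case) / 0 (control).
# Returns a SNPs x B matrix of 1-df Pearson chi-square statistics;
# degenerate tables (a zero margin) give 0.
.allelic_chi2_matrix <- function(dosage, case_ind) {
  case_ind <- as.matrix(case_ind)
  miss <- is.na(dosage)
  d0 <- dosage
  d0[miss] <- 0
  obs <- 1 - miss  # non-missing indicator
  a_case <- d0 %*% case_ind                 # minor alleles in cases
  n_case <- 2 * (obs %*% case_ind)          # alleles typed in cases
  a_tot <- rowSums(d0)
  n_tot <- 2 * rowSums(obs)
  a_ctrl <- a_tot - a_case
  n_ctrl <- n_tot - n_case
  # Pearson chi2 for [[a_case, n_case-a_case], [a_ctrl, n_ctrl-a_ctrl]]
  num <- (a_case * (n_ctrl - a_ctrl) - (n_case - a_case) * a_ctrl)^2 * n_tot
  den <- n_case * n_ctrl * a_tot * (n_tot - a_tot)
  chi2 <- ifelse(den > 0, num / den, 0)
  chi2[n_tot == 0, ] <- 0
  chi2
}

#' Basic allelic test for one SNP
#'
#' Builds the 2x2 table of minor/major allele counts in cases and controls
#' (2N alleles per class, missing calls excluded) and computes the Pearson
#' chi-square statistic without continuity correction with its 1-df
#' upper-tail P-value. A table with a zero allele margin is flagged
#' degenerate and reported as chi2 = 0, p = 1.
#'
#' @param dosage Numeric vector of minor-allele dosages (0/1/2, NA missing).
#' @param phenotype Character vector, "case"/"control", same length.
#' @return data.frame with `chi2`, `p`, `maf`, `call_rate`, `degenerate`.
#' @export
allelic_test <- function(dosage, phenotype) {
  stopifnot(length(dosage) == length(phenotype))
  ok <- !is.na(dosage)
  if (length(unique(phenotype[ok])) < 2L)
    stop("both classes must be present after removing missing dosages")
  m <- matrix(dosage, nrow = 1)
  ci <- matrix(as.numeric(phenotype == "case"), ncol = 1)
  chi2 <- .allelic_chi2_matrix(m, ci)[1, 1]
  maf <- .snp_maf(m)
  degen <- is.na(maf) || maf == 0 || maf == 1
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             maf = maf, call_rate = mean(ok), degenerate = degen)
}

#' Allelic association for every SNP in a study
#'
#' @param study A [genotype_study()].
#' @return data.frame: `snp`, `chr`, `pos`, `maf`, `call_rate`, `chi2`, `p`.
#' @export
assoc_table <- function(study) {
  stopifnot(inherits(study, "genotype_study"))
  ci <- matrix(as.numeric(study$phenotype == "case"), ncol = 1)
  chi2 <- .allelic_chi2_matrix(study$dosage, ci)[, 1]
  data.frame(snp = study$snp_ids, chr = study$chrom, pos = study$pos,
             maf = .snp_maf(study$dosage),
             call_rate = rowMeans(!is.na(study$dosage)),
             chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' lambda_GC = median(observed chi-square) / median of the 1-df chi-square
#' distribution (qchisq(0.5, 1) ~ 0.4549). Reported descriptively; no
#' correction is applied to the statistics.
#'
#' @param chi2 Numeric vector of 1-df chi-square statistics, or a data.frame
#'   with a `chi2` column (e.g. from [assoc_table()]).
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(chi2) {
  if (is.data.frame(chi2)) chi2 <- chi2$chi2
  stopifnot(length(chi2) >= 1)
  stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
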