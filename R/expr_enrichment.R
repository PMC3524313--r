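# Expression preprocessing (quantile normalization, probe collapsing,
# Welch t differential expression with a signal-to-noise ranking statistic)
# and GSEA on the expression platform. The enrichment machinery is the same
# code path as the GWAS arm; only the ranking statistic and the permutation
# recomputation differ.

#' Quantile-normalize a gene x sample matrix
#'
#' Every column is forced to share the distribution of row-wise means of
#' the column order statistics; ties are averaged. Delegates to
#' `limma::normalizeQuantiles`. A column with all-identical values is
#' handled (all entries become the mean quantile) with a warning.
#'
#' @param values Numeric gene x sample matrix (>= 2 samples).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 samples")
  if (nrow(values) == 1L) {  # single quantile: every entry the row mean
    out <- values
    out[] <- mean(values)
    return(out)
  }
  const <- apply(values, 2, function(x) length(unique(x)) == 1L)
  if (any(const) && nrow(values) > 1L)
    warning("column(s) with all-identical values: ",
            paste(colnames(values)[const], collapse = ", "))
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Collapse probe rows to gene rows by element-wise median
#'
#' @param values Probe x sample matrix with probe ids as row names.
#' @param probe_to_gene Named character vector: probe id -> gene id.
#'   Probes without a mapping are dropped with a warning.
#' @return Gene x sample matrix; single-probe genes pass through unchanged.
#'   Gene order follows first appearance of each gene in the probe order.
#' @export
collapse_probes <- function(values, probe_to_gene) {
  values <- as.matrix(values)
  probes <- rownames(values)
  if (is.null(probes)) stop("values must carry probe ids as row names")
  gene <- probe_to_gene[probes]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    warning(sum(unmapped), " unmapped probe(s) dropped")
    values <- values[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  if (nrow(values) == 0L) stop("no mapped probes remain")
  genes <- unique(gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes) {
    rows <- which(gene == g)
    out[g, ] <- if (length(rows) == 1L) values[rows, ]
                else apply(values[rows, , drop = FALSE], 2, stats::median)
  }
  out
}

# Signal-to-noise ratios for every gene against B case-indicator columns
# (samples x B). Per-class SDs are floored at 0.2 * |class mean| (the
# convention of the original expression GSEA); a gene constant and zero in
# both classes gets snr 0 instead of 0/0.
.snr_matrix <- function(values, case_ind) {
  case_ind <- as.matrix(case_ind)
  n1 <- colSums(case_ind)           # cases per column (constant for swaps)
  n0 <- nrow(case_ind) - n1
  s1 <- values %*% case_ind
  sq1 <- values^2 %*% case_ind
  st <- rowSums(values)
  sqt <- rowSums(values^2)
  mu1 <- sweep(s1, 2, n1, "/")
  mu0 <- sweep(-sweep(s1, 1, st, "-"), 2, n0, "/")  # (st - s1)/n0
  v1 <- sweep(sq1 - sweep(mu1^2, 2, n1, "*"), 2, n1 - 1, "/")
  sq0 <- -sweep(sq1, 1, sqt, "-")                   # sqt - sq1
  v0 <- sweep(sq0 - sweep(mu0^2, 2, n0, "*"), 2, n0 - 1, "/")
  sd1 <- pmax(sqrt(pmax(v1, 0)), 0.2 * abs(mu1))
  sd0 <- pmax(sqrt(pmax(v0, 0)), 0.2 * abs(mu0))
  den <- sd1 + sd0
  num <- mu1 - mu0
  out <- ifelse(den > 0, num / den, 0)
  rownames(out) <- rownames(values)
  out
}

#' Differential expression by Welch's t-test
#'
#' Per gene: Welch (unequal-variance) two-sample t between cases and
#' controls, BH-adjusted P-values across genes, the class-mean difference
#' on the log2 scale (input is assumed log2), and the signal-to-noise
#' ratio `(mu_case - mu_control) / (sd_case + sd_control)` with each class
#' SD floored at `0.2 * |class mean|` so it is always finite.
#'
#' @param study An [expression_study()] with >= 2 samples per class.
#' @return data.frame: `gene`, `log2_ratio`, `t_stat`, `p`, `fdr`, `snr`.
#' @export
differential_expression <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  case <- study$phenotype == "case"
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples per class")
  x1 <- study$values[, case, drop = FALSE]
  x0 <- study$values[, !case, drop = FALSE]
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - mu0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- ifelse(se2 > 0, (mu1 - mu0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)), 1)
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  snr <- .snr_matrix(study$values, matrix(as.numeric(case), ncol = 1))[, 1]
  data.frame(gene = study$gene_ids, log2_ratio = mu1 - mu0, t_stat = t_stat,
             p = p, fdr = stats::p.adjust(p, method = "BH"), snr = snr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GSEA on two-class expression data
#'
#' Genes are ranked by signal-to-noise ratio (descending); the enrichment
#' score, NES, empirical P and FDR are computed exactly as in the GWAS arm
#' (shared code path). Permutations swap the phenotype labels and recompute
#' every snr.
#'
#' @param study An [expression_study()] with >= 2 samples per class.
#' @param sets A [gene_set_collection()] filtered to the expression
#'   universe.
#' @param plan A phenotype-swap [permutation_plan()].
#' @param weight_exponent KS weight exponent (default 1).
#' @param fdr_method `"pooled"` (default) or `"BH"`.
#' @return data.frame: `set`, `size`, `score` (ES), `nes`, `p`, `fdr`.
#' @export
gsea_expression <- function(study, sets, plan = permutation_plan(),
                            weight_exponent = 1,
                            fdr_method = c("pooled", "BH")) {
  stopifnot(inherits(study, "expression_study"),
            inherits(sets, "gene_set_collection"))
  if (plan$scheme != "phenotype-swap")
    stop("expression GSEA requires a phenotype-swap plan")
  case <- study$phenotype == "case"
  if (sum(case) < 2L || sum(!case) < 2L)
    stop("need at least 2 samples per class")
  ci <- matrix(as.numeric(case), ncol = 1)
  snr_obs <- .snr_matrix(study$values, ci)[, 1]
  names(snr_obs) <- study$gene_ids
  P <- .perm_case_matrix(study$phenotype, plan$n_perm, plan$seed)
  snr_perm <- .snr_matrix(study$values, P)
  rownames(snr_perm) <- study$gene_ids
  .gsea_table(snr_obs, snr_perm, sets$sets, weight_exponent, fdr_method)
}
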