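# The four GWAS pathway tests over one shared permutation engine:
#   - GSEA on max-chi2 gene statistics with phenotype swapping (competitive)
#   - SNP-resampling gene-count over-representation, ALIGATOR style
#     (competitive)
#   - SNP ratio test (self-contained)
#   - LD-pruned set-based mean-chi-square test (self-contained)
# Phenotype-swap tests re-run the full allelic test in every permutation.

# Chi-square statistics for every SNP under B phenotype swaps.
# Returns list(obs = vector, perm = SNPs x B matrix).
.perm_chi2 <- function(study, plan) {
  if (plan$scheme != "phenotype-swap")
    stop("this test requires a phenotype-swap permutation plan")
  if (min(table(study$phenotype)) < 2L)
    stop("need at least 2 samples per class")
  ci <- matrix(as.numeric(study$phenotype == "case"), ncol = 1)
  obs <- .allelic_chi2_matrix(study$dosage, ci)[, 1]
  P <- .perm_case_matrix(study$phenotype, plan$n_perm, plan$seed)
  perm <- .allelic_chi2_matrix(study$dosage, P)
  list(obs = stats::setNames(obs, study$snp_ids), perm = perm)
}

# Per-gene maximum over SNP rows of a statistic matrix (genes x columns).
.gene_max <- function(stat_matrix, row_groups) {
  out <- vapply(row_groups, function(idx) {
    if (length(idx) == 1L) stat_matrix[idx, ]
    else do.call(pmax, lapply(idx, function(i) stat_matrix[i, ]))
  }, numeric(ncol(stat_matrix)))
  if (is.null(dim(out)))  # single permutation column
    matrix(out, ncol = 1, dimnames = list(names(row_groups), NULL))
  else t(out)
}

# Row indices (into a SNP-id-ordered matrix) for each gene with >= 1 SNP.
.gene_row_groups <- function(map, snp_ids) {
  groups <- lapply(map$gene_to_snps, function(ids) {
    i <- match(ids, snp_ids)
    i[!is.na(i)]
  })
  groups[lengths(groups) > 0L]
}

#' GSEA over GWAS gene statistics
#'
#' Genes are ranked by their representative (maximum) allelic chi-square;
#' the weighted KS enrichment score is computed per set; significance comes
#' from phenotype-label swaps with the allelic tests and gene statistics
#' recomputed in every permutation. NES divides ES by the mean permuted ES
#' of the same sign; the empirical P mirrors the ES sign; FDR uses the
#' pooled permuted-NES scheme (or BH via `fdr_method`).
#'
#' @param study A QC'd [genotype_study()].
#' @param map A [map_snps_to_genes()] result for the study's SNPs.
#' @param sets A [gene_set_collection()] already filtered to the gene
#'   universe (see [filter_gene_sets()]).
#' @param plan A phenotype-swap [permutation_plan()].
#' @param weight_exponent KS weight exponent (default 1; 0 = classic KS).
#' @param fdr_method `"pooled"` (default) or `"BH"`.
#' @return data.frame: `set`, `size`, `score` (ES), `nes`, `p`, `fdr`.
#' @export
gsea_gwas <- function(study, map, sets, plan = permutation_plan(),
                      weight_exponent = 1, fdr_method = c("pooled", "BH")) {
  stopifnot(inherits(study, "genotype_study"),
            inherits(sets, "gene_set_collection"))
  pc <- .perm_chi2(study, plan)
  groups <- .gene_row_groups(map, study$snp_ids)
  if (length(groups) == 0L) stop("no gene has a mapped SNP")
  stat_obs <- vapply(groups, function(idx) max(pc$obs[idx]), numeric(1))
  stat_perm <- .gene_max(pc$perm, groups)
  .gsea_table(stat_obs, stat_perm, sets$sets, weight_exponent, fdr_method)
}

#' SNP-resampling gene-count over-representation test (ALIGATOR style)
#'
#' A gene is "significant" when it contains at least one SNP with allelic
#' P below `p_cut`; each gene counts once however many such SNPs it has.
#' The observed score of a set is its number of significant member genes.
#' Null replicates draw SNPs uniformly without replacement until the drawn
#' SNPs hit exactly as many distinct genes as the observed significant-gene
#' count (a draw that would overshoot because one SNP adds several new
#' genes is discarded and the walk continues), then each set is scored on
#' the replicate's gene list.
#'
#' @param assoc data.frame from [assoc_table()].
#' @param map A [map_snps_to_genes()] result.
#' @param sets A filtered [gene_set_collection()].
#' @param p_cut SNP significance cutoff (default 0.05).
#' @param plan A snp-resample [permutation_plan()] (default 10,000 draws).
#' @return data.frame: `set`, `size`, `score` (significant-gene count),
#'   `nes` (NA), `p`, `fdr` (BH over the empirical P-values).
#' @export
aligator <- function(assoc, map, sets, p_cut = 0.05,
                     plan = permutation_plan(10000, scheme = "snp-resample")) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (plan$scheme != "snp-resample")
    stop("the resampling test requires a snp-resample plan")
  snp_genes <- map$snp_to_genes
  mapped <- names(snp_genes)[lengths(snp_genes) > 0L]
  mapped <- intersect(mapped, assoc$snp)
  if (length(mapped) == 0L) stop("no mapped SNP has an association result")
  p_by_snp <- stats::setNames(assoc$p, assoc$snp)[mapped]
  genes_of <- snp_genes[mapped]
  all_genes <- unique(unlist(genes_of, use.names = FALSE))

  sig_snps <- mapped[p_by_snp < p_cut]
  sig_genes <- unique(unlist(genes_of[sig_snps], use.names = FALSE))
  target <- length(sig_genes)

  set_names <- names(sets$sets)
  obs <- vapply(sets$sets, function(g) length(intersect(g, sig_genes)),
                numeric(1))
  R <- plan$n_perm
  if (target == 0L) {
    warning("no significant genes at p < ", p_cut, "; all empirical P = 1")
    return(data.frame(set = set_names, size = lengths(sets$sets),
                      score = obs, nes = NA_real_, p = rep(1, length(obs)),
                      fdr = rep(1, length(obs)),
                      stringsAsFactors = FALSE, row.names = NULL))
  }

  gene_index <- stats::setNames(seq_along(all_genes), all_genes)
  single <- all(lengths(genes_of) == 1L)
  gene_of1 <- if (single) unlist(genes_of, use.names = FALSE) else NULL
  n_snp <- length(mapped)
  set_mask <- vapply(sets$sets, function(g) {
    m <- logical(length(all_genes)); m[gene_index[intersect(g, all_genes)]] <- TRUE; m
  }, logical(length(all_genes)))

  set.seed(plan$seed)
  counts <- matrix(0L, nrow = R, ncol = length(set_names))
  for (r in seq_len(R)) {
    if (single) {
      ord <- sample.int(n_snp)
      g <- gene_of1[ord]
      first <- !duplicated(g)
      k <- which(cumsum(first) == target & first)[1]
      rep_genes <- g[first][seq_len(target)]
      hit <- logical(length(all_genes))
      hit[gene_index[rep_genes]] <- TRUE
    } else {
      hit <- .resample_gene_list(genes_of, gene_index, target, n_snp,
                                 length(all_genes))
    }
    counts[r, ] <- colSums(set_mask & hit)
  }
  p_emp <- vapply(seq_along(obs), function(i) {
    (1 + sum(counts[, i] >= obs[i])) / (R + 1)
  }, numeric(1))
  data.frame(set = set_names, size = lengths(sets$sets), score = obs,
             nes = NA_real_, p = p_emp,
             fdr = stats::p.adjust(p_emp, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# One resampling replicate for the general (multi-gene-per-SNP) case:
# walk a shuffled SNP order, accumulating distinct genes; skip a SNP whose
# novel genes would push the count past the target; stop at equality.
.resample_gene_list <- function(genes_of, gene_index, target, n_snp, n_gene) {
  for (attempt in 1:100) {
    ord <- sample.int(n_snp)
    hit <- logical(n_gene)
    count <- 0L
    for (s in ord) {
      gi <- gene_index[genes_of[[s]]]
      new <- gi[!hit[gi]]
      k <- length(new)
      if (k == 0L) next
      if (count + k > target) next  # overshoot: discard this SNP, redraw
      hit[new] <- TRUE
      count <- count + k
      if (count == target) return(hit)
    }
  }
  stop("resampling could not reach the target significant-gene count")
}

#' SNP ratio test
#'
#' The observed score of a set is the fraction of its mapped SNPs with
#' allelic P below `p_cut` (a SNP shared between two member genes counts
#' once per pathway). Phenotype-label swaps recompute every allelic test
#' and the ratios; the empirical P counts permuted ratios at least as
#' large.
#'
#' @inheritParams gsea_gwas
#' @param assoc data.frame from [assoc_table()] (observed statistics).
#' @param p_cut SNP significance cutoff (default 0.05).
#' @return data.frame: `set`, `size`, `score` (ratio), `nes` (NA), `p`,
#'   `fdr` (BH). Sets with zero mapped SNPs are dropped with a warning.
#' @export
snp_ratio_test <- function(study, map, sets, p_cut = 0.05,
                           plan = permutation_plan()) {
  stopifnot(inherits(study, "genotype_study"),
            inherits(sets, "gene_set_collection"))
  pc <- .perm_chi2(study, plan)
  crit <- stats::qchisq(p_cut, df = 1, lower.tail = FALSE)  # p<cut <=> chi2>crit
  set_snp_rows <- lapply(sets$sets, function(g) {
    ids <- unique(unlist(map$gene_to_snps[g], use.names = FALSE))
    i <- match(ids, study$snp_ids)
    i[!is.na(i)]
  })
  empty <- lengths(set_snp_rows) == 0L
  if (any(empty)) {
    warning("dropping set(s) with no mapped SNPs: ",
            paste(names(sets$sets)[empty], collapse = ", "))
    set_snp_rows <- set_snp_rows[!empty]
  }
  if (length(set_snp_rows) == 0L) stop("no set has mapped SNPs")
  sig_obs <- pc$obs > crit
  sig_perm <- pc$perm > crit
  res <- lapply(names(set_snp_rows), function(nm) {
    rows <- set_snp_rows[[nm]]
    n <- length(rows)
    ratio <- sum(sig_obs[rows]) / n
    perm_ratio <- if (n == 1L) as.numeric(sig_perm[rows, ])
                  else colSums(sig_perm[rows, , drop = FALSE]) / n
    data.frame(set = nm, size = length(sets$sets[[nm]]), score = ratio,
               nes = NA_real_,
               p = empirical_pvalue(ratio, perm_ratio, "ge"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

# Greedy LD-pruned selection on a chi-square vector. r2 is the SNP x SNP
# squared-correlation matrix; crit the chi-square significance threshold.
# Pick the largest-chi2 eligible SNP, drop everything with r2 > r2_cut to
# it (including itself), repeat until max_snps selected or none eligible.
.greedy_select <- function(chi2, r2, crit, r2_cut, max_snps) {
  remaining <- seq_along(chi2)
  sel <- integer(0)
  while (length(sel) < max_snps && length(remaining)) {
    elig <- remaining[chi2[remaining] > crit]
    if (length(elig) == 0L) break
    best <- elig[which.max(chi2[elig])]
    sel <- c(sel, best)
    r2b <- r2[best, remaining]
    r2b[is.na(r2b)] <- 0  # zero-variance dosage: treated as unlinked
    remaining <- remaining[r2b <= r2_cut]
  }
  sel
}

#' Greedy selection of independent significant SNPs
#'
#' Repeatedly picks the smallest-P remaining SNP with P below `p_cut` and
#' removes all remaining SNPs in LD with it (r-squared above `r2_cut`,
#' computed as the squared Pearson correlation of dosage vectors over
#' samples non-missing in both), stopping after `max_snps` selections or
#' when no eligible SNP remains.
#'
#' @param set_snps Character vector of candidate SNP ids.
#' @param assoc data.frame from [assoc_table()] covering `set_snps`.
#' @param dosage Dosage matrix with SNP ids as row names.
#' @param r2_cut LD pruning threshold (default 0.5).
#' @param p_cut Significance cutoff (default 0.05).
#' @param max_snps Maximum selections (default 5).
#' @return Character vector of selected SNP ids (possibly empty).
#' @export
select_independent_snps <- function(set_snps, assoc, dosage, r2_cut = 0.5,
                                    p_cut = 0.05, max_snps = 5) {
  stopifnot(all(set_snps %in% rownames(dosage)))
  idx <- match(set_snps, assoc$snp)
  if (anyNA(idx)) stop("association results missing for some SNPs")
  chi2 <- assoc$chi2[idx]
  d <- dosage[set_snps, , drop = FALSE]
  r2 <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))^2
  crit <- stats::qchisq(p_cut, df = 1, lower.tail = FALSE)
  sel <- .greedy_select(chi2, r2, crit, r2_cut, max_snps)
  set_snps[sel]
}

#' LD-pruned set-based mean-chi-square test
#'
#' Per set, greedily selects up to `max_snps` significant SNPs pruned at
#' `r2_cut` (see [select_independent_snps()]); the observed score is the
#' mean allelic chi-square of the selection (0 when nothing is selected).
#' Phenotype swaps recompute the allelic tests and re-run the selection
#' (LD is a property of the genotypes, so the r-squared matrix is fixed);
#' the empirical P counts permuted means at least as large.
#'
#' @inheritParams snp_ratio_test
#' @param r2_cut LD pruning threshold (default 0.5).
#' @param max_snps Maximum SNPs selected per set (default 5).
#' @return data.frame: `set`, `size`, `score` (mean chi2), `nes` (NA), `p`,
#'   `fdr` (BH).
#' @export
set_based_test <- function(study, map, sets, r2_cut = 0.5, p_cut = 0.05,
                           max_snps = 5, plan = permutation_plan()) {
  stopifnot(inherits(study, "genotype_study"),
            inherits(sets, "gene_set_collection"))
  pc <- .perm_chi2(study, plan)
  crit <- stats::qchisq(p_cut, df = 1, lower.tail = FALSE)
  B <- plan$n_perm
  res <- lapply(names(sets$sets), function(nm) {
    ids <- unique(unlist(map$gene_to_snps[sets$sets[[nm]]], use.names = FALSE))
    rows <- match(ids, study$snp_ids)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L)
      return(data.frame(set = nm, size = length(sets$sets[[nm]]), score = 0,
                        nes = NA_real_, p = 1, stringsAsFactors = FALSE))
    d <- study$dosage[rows, , drop = FALSE]
    r2 <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))^2
    score_of <- function(chi2) {
      sel <- .greedy_select(chi2, r2, crit, r2_cut, max_snps)
      if (length(sel)) mean(chi2[sel]) else 0
    }
    obs <- score_of(pc$obs[rows])
    perm <- vapply(seq_len(B), function(b) score_of(pc$perm[rows, b]),
                   numeric(1))
    data.frame(set = nm, size = length(sets$sets[[nm]]), score = obs,
               nes = NA_real_, p = empirical_pvalue(obs, perm, "ge"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
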