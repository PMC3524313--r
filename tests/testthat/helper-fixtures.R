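# Shared fixtures and independent oracles, built in code at test time.

# Small genotype study with known dosages: n1 cases then n0 controls.
toy_study <- function(dosage, n_case, n_control, pos = NULL) {
  n_snp <- nrow(dosage)
  genotype_study(
    snp_ids = paste0("s", seq_len(n_snp)),
    chrom = rep("1", n_snp),
    pos = if (is.null(pos)) seq_len(n_snp) * 1000 else pos,
    dosage = dosage,
    sample_ids = paste0("I", seq_len(n_case + n_control)),
    phenotype = rep(c("case", "control"), c(n_case, n_control))
  )
}

# Independent enrichment-score oracle: explicit cumulative-sum walk.
naive_es <- function(ranked_stats, membership, w = 1) {
  n <- length(ranked_stats)
  m <- sum(membership)
  wt <- abs(ranked_stats)^w
  nr <- sum(wt[membership])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (membership[i]) {
      cur + (if (nr > 0) wt[i] / nr else 1 / m)
    } else {
      cur - 1 / (n - m)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Naive Benjamini-Hochberg step-up with monotonicity, order-stable.
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Reproduce the package's documented permutation recipe.
perm_labels <- function(phenotype, n_perm, seed) {
  ci <- as.numeric(phenotype == "case")
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) sample(ci), numeric(length(ci)))
}
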