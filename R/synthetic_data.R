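# Synthetic case/control studies with known planted pathway effects.
#
# Genotypes: biallelic SNPs in within-gene LD blocks (latent-Gaussian
# threshold model, exchangeable correlation, independence between genes),
# a binary phenotype from a logistic model with per-SNP log odds ratios on
# minor-allele dosage. Expression: gene x sample log2 values with a mean
# shift in cases for the planted genes. Everything is driven by one integer
# seed, so studies are exactly reproducible.

#' Configuration for a synthetic study
#'
#' Defaults describe the standard validation conditions used throughout the
#' package: 300 cases / 300 controls, 300 genes x 5 SNPs (1500 SNPs) in LD
#' blocks with latent correlation 0.6, 50 gene sets of 20 genes, one
#' planted set whose genes carry allelic effects of log odds ratio 0.35
#' (half of its genes, one causal SNP each) and expression shifts of 1 log2
#' unit against residual noise sd 0.5.
#'
#' @param n_case,n_control Sample counts per class.
#' @param n_genes Number of genes.
#' @param snps_per_gene SNPs per gene.
#' @param ld_block_rho Latent within-gene correlation in `[0, 1)`.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param n_sets Number of gene sets.
#' @param genes_per_set Genes per set (drawn without replacement).
#' @param planted_sets Names of sets carrying effects (sets are named
#'   "set1", "set2", ...); `character(0)` gives a null study.
#' @param planted_fraction Fraction of a planted set's genes with effects.
#' @param allelic_log_or Per-causal-SNP log odds ratio on dosage.
#' @param expr_delta_log2 Expression shift (log2) of effect genes in cases.
#' @param expr_sigma Residual expression noise sd.
#' @param seed Integer seed (keep below 2^31 - 3; internal stages use
#'   `seed`, `seed + 1`, `seed + 2`).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 300, n_control = 300, n_genes = 300,
                             snps_per_gene = 5, ld_block_rho = 0.6,
                             maf_range = c(0.1, 0.5), n_sets = 50,
                             genes_per_set = 20, planted_sets = "set1",
                             planted_fraction = 0.5, allelic_log_or = 0.35,
                             expr_delta_log2 = 1.0, expr_sigma = 0.5,
                             seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, n_genes >= 1, snps_per_gene >= 1,
            ld_block_rho >= 0, ld_block_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_sets >= 1, genes_per_set >= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            expr_sigma > 0)
  if (genes_per_set > n_genes) stop("genes_per_set exceeds n_genes")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic genome, gene sets, and the truth record
#'
#' Genes are tiled on one chromosome in disjoint 50 kb windows (10 kb gene
#' body, 20 kb flank on each side), so with the default flank every SNP
#' maps to exactly one gene. SNP minor-allele frequencies are drawn
#' uniformly from `maf_range`. Sets draw genes without replacement; each
#' planted set receives `round(planted_fraction * genes_per_set)` effect
#' genes with one causal SNP each.
#'
#' @param config A [synthetic_config()].
#' @return List: `genes` (data.frame gene/chrom/start/end), `snps`
#'   (data.frame snp/chr/pos/maf/gene), `sets` (a
#'   [gene_set_collection()]), `truth` (planted set names, effect-gene and
#'   causal-SNP flags).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  m <- config$snps_per_gene
  gene_ids <- paste0("G", seq_len(n_genes))
  start <- (seq_len(n_genes) - 1) * 50000 + 20001
  genes <- data.frame(gene = gene_ids, chrom = "1", start = start,
                      end = start + 9999, stringsAsFactors = FALSE)
  # SNPs evenly spaced through the gene body
  offs <- round((seq_len(m) - 0.5) / m * 9999)
  snps <- data.frame(
    snp = paste0("rs_", rep(gene_ids, each = m), "_", rep(seq_len(m), n_genes)),
    chr = "1",
    pos = rep(start, each = m) + rep(offs, n_genes),
    maf = stats::runif(n_genes * m, config$maf_range[1], config$maf_range[2]),
    gene = rep(gene_ids, each = m),
    stringsAsFactors = FALSE
  )
  set_names <- paste0("set", seq_len(config$n_sets))
  sets <- lapply(set_names, function(nm) sample(gene_ids, config$genes_per_set))
  names(sets) <- set_names
  unknown <- setdiff(config$planted_sets, set_names)
  if (length(unknown)) stop("unknown planted set(s): ",
                            paste(unknown, collapse = ", "))
  n_eff <- round(config$planted_fraction * config$genes_per_set)
  effect_genes <- character(0)
  for (nm in config$planted_sets)
    effect_genes <- union(effect_genes, sample(sets[[nm]], n_eff))
  causal_snps <- vapply(effect_genes, function(g) {
    sample(snps$snp[snps$gene == g], 1)
  }, character(1))
  truth <- list(
    planted_sets = config$planted_sets,
    gene_effect = stats::setNames(gene_ids %in% effect_genes, gene_ids),
    snp_causal = stats::setNames(snps$snp %in% causal_snps, snps$snp)
  )
  list(genes = genes, snps = snps,
       sets = gene_set_collection(sets, universe = gene_ids),
       truth = truth)
}

# One batch of dosages: latent-Gaussian threshold model. Per gene and
# haplotype, z = sqrt(rho) * u_gene + sqrt(1-rho) * e_snp; the minor allele
# is carried when z < qnorm(maf). Dosage = sum over the two haplotypes.
.gen_dosage_batch <- function(genome, rho, n) {
  snps <- genome$snps
  genes <- unique(snps$gene)
  d <- matrix(0L, nrow = nrow(snps), ncol = n)
  thr <- stats::qnorm(snps$maf)
  a <- sqrt(rho); b <- sqrt(1 - rho)
  for (g in genes) {
    rows <- which(snps$gene == g)
    m <- length(rows)
    for (h in 1:2) {
      u <- stats::rnorm(n)
      z <- a * matrix(u, nrow = m, ncol = n, byrow = TRUE) +
        b * matrix(stats::rnorm(m * n), nrow = m)
      d[rows, ] <- d[rows, ] + (z < thr[rows])
    }
  }
  d
}

#' Generate genotypes with a logistic disease model
#'
#' Dosages come from the latent-Gaussian LD-block model; the phenotype from
#' `logit P(case) = alpha + sum(causal log OR x dosage)` with `alpha`
#' solved so the expected case fraction matches `n_case / (n_case +
#' n_control)`. Sampling continues in batches until the exact class counts
#' are reached (bounded retries).
#'
#' @param config A [synthetic_config()].
#' @param genome A [generate_genome()] result.
#' @param truth Truth record (defaults to `genome$truth`).
#' @return A [genotype_study()] with `n_case` cases followed by
#'   `n_control` controls.
#' @export
generate_genotypes <- function(config, genome, truth = genome$truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n_case <- config$n_case; n_control <- config$n_control
  target_k <- n_case / (n_case + n_control)
  beta <- ifelse(truth$snp_causal[genome$snps$snp], config$allelic_log_or, 0)

  pool_n <- 2L * (n_case + n_control)
  d <- .gen_dosage_batch(genome, config$ld_block_rho, pool_n)
  eta <- as.numeric(crossprod(d, beta))
  f <- function(a) mean(stats::plogis(a + eta)) - target_k
  if (f(-30) > 0 || f(30) < 0)
    stop("unattainable class counts: extreme odds ratios")
  alpha <- stats::uniroot(f, c(-30, 30), tol = 1e-8)$root

  case_cols <- list(); ctrl_cols <- list()
  n_case_got <- 0L; n_ctrl_got <- 0L
  for (attempt in 1:50) {
    y <- stats::rbinom(ncol(d), 1, stats::plogis(alpha + eta))
    if (n_case_got < n_case) {
      take <- which(y == 1)[seq_len(min(sum(y == 1), n_case - n_case_got))]
      if (length(take)) {
        case_cols[[length(case_cols) + 1L]] <- d[, take, drop = FALSE]
        n_case_got <- n_case_got + length(take)
      }
    }
    if (n_ctrl_got < n_control) {
      take <- which(y == 0)[seq_len(min(sum(y == 0), n_control - n_ctrl_got))]
      if (length(take)) {
        ctrl_cols[[length(ctrl_cols) + 1L]] <- d[, take, drop = FALSE]
        n_ctrl_got <- n_ctrl_got + length(take)
      }
    }
    if (n_case_got >= n_case && n_ctrl_got >= n_control) break
    d <- .gen_dosage_batch(genome, config$ld_block_rho, pool_n)
    eta <- as.numeric(crossprod(d, beta))
  }
  if (n_case_got < n_case || n_ctrl_got < n_control)
    stop("unattainable class counts after bounded retries")

  dosage <- cbind(do.call(cbind, case_cols), do.call(cbind, ctrl_cols))
  n <- n_case + n_control
  genotype_study(snp_ids = genome$snps$snp, chrom = genome$snps$chr,
                 pos = genome$snps$pos, dosage = dosage,
                 sample_ids = paste0("S", seq_len(n)),
                 phenotype = rep(c("case", "control"), c(n_case, n_control)))
}

#' Generate a two-class expression study with planted shifts
#'
#' Values are `baseline_gene + delta * effect * case + noise`, with
#' gene-level baselines N(8, 1), the planted shift `expr_delta_log2`
#' applied to effect genes in cases only, and residual noise
#' N(0, expr_sigma^2). Sample order (cases first, then controls) matches
#' [generate_genotypes()] under a shared seed.
#'
#' @inheritParams generate_genotypes
#' @return An [expression_study()].
#' @export
generate_expression <- function(config, genome, truth = genome$truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  gene_ids <- genome$genes$gene
  n_g <- length(gene_ids)
  n <- config$n_case + config$n_control
  case <- rep(c(1, 0), c(config$n_case, config$n_control))
  baseline <- stats::rnorm(n_g, mean = 8, sd = 1)
  effect <- as.numeric(truth$gene_effect[gene_ids])
  vals <- matrix(baseline, nrow = n_g, ncol = n) +
    config$expr_delta_log2 * outer(effect, case) +
    matrix(stats::rnorm(n_g * n, sd = config$expr_sigma), nrow = n_g)
  expression_study(gene_ids, vals, paste0("S", seq_len(n)),
                   rep(c("case", "control"),
                       c(config$n_case, config$n_control)))
}

#' Simulate a complete cross-platform study
#'
#' Convenience wrapper: genome + gene sets + truth, genotype study,
#' expression study, all from one config.
#'
#' @param config A [synthetic_config()].
#' @return List: `config`, `genome`, `truth`, `genotypes`, `expression`,
#'   `sets`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  genome <- generate_genome(config)
  list(config = config, genome = genome, truth = genome$truth,
       genotypes = generate_genotypes(config, genome),
       expression = generate_expression(config, genome),
       sets = genome$sets)
}
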