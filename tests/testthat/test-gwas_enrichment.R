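test_that("enrichment score matches the brute-force running-sum walk", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    m <- sample(1:(n - 1), 1)
    stats <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    member <- seq_len(n) %in% sample(n, m)
    w <- sample(c(0, 1), 1)
    es <- enrichment_score(stats, member, w)
    expect_equal(es$es, naive_es(stats, member, w), tolerance = 1e-12)
    expect_equal(es$es, es$running[es$peak])
    expect_true(abs(es$es) <= 1 + 1e-12)
  }
})

test_that("enrichment score agrees with the fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    stats <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranks <- sort(sample(n, sample(3:10, 1)))
    es <- enrichment_score(stats, seq_len(n) %in% ranks, 1)
    ref <- fgsea::calcGseaStat(stats, selectedStats = ranks, gseaParam = 1)
    expect_equal(es$es, ref, tolerance = 1e-10)
  }
})

test_that("enrichment score handles the degenerate memberships", {
  # all genes members: ES = 1 at the last index
  es <- enrichment_score(sort(rnorm(10), decreasing = TRUE), rep(TRUE, 10))
  expect_equal(es$es, 1)
  expect_equal(es$peak, 10)
  # single member ranked first, classic KS: ES = 1 at index 1
  es2 <- enrichment_score(seq(100, 1), c(TRUE, rep(FALSE, 99)),
                          weight_exponent = 0)
  expect_equal(es2$es, 1)
  expect_equal(es2$peak, 1)
  expect_error(enrichment_score(c(3, 2, 1), rep(FALSE, 3)), "no set members")
  expect_error(enrichment_score(c(1, 2, 3), c(TRUE, FALSE, TRUE)),
               "descending")
})

test_that("empirical P-value follows the (b+1)/(B+1) convention", {
  expect_equal(empirical_pvalue(10, rep(1, 999)), 0.001)
  expect_equal(empirical_pvalue(0, seq_len(999)), 1.0)
  expect_equal(empirical_pvalue(5, 5), 1.0)           # B = 1 tie
  expect_equal(empirical_pvalue(1, c(0, 2)), 2 / 3)
  expect_equal(empirical_pvalue(1, c(0, 2), "le"), 2 / 3)
})

test_that("greedy LD selection follows the documented rule", {
  # A(p=.001), B(p=.002, r2(A,B)=0.8), C(p=.5): selection = {A}
  n <- 200
  set.seed(41)
  a <- rbinom(n, 2, 0.3)
  b <- a
  flip <- sample(n, 25)                 # correlated but not identical
  b[flip] <- rbinom(25, 2, 0.3)
  cc <- rbinom(n, 2, 0.3)
  dosage <- rbind(A = a, B = b, C = cc)
  stopifnot(cor(a, b)^2 > 0.5)
  assoc <- data.frame(snp = c("A", "B", "C"), chi2 = qchisq(c(0.001, 0.002, 0.5), 1, lower.tail = FALSE),
                      p = c(0.001, 0.002, 0.5))
  sel <- select_independent_snps(c("A", "B", "C"), assoc, dosage)
  expect_identical(sel, "A")

  # identical dosage vectors: r2 = 1, the second SNP is always pruned
  dosage2 <- rbind(A = a, B = a)
  assoc2 <- data.frame(snp = c("A", "B"), chi2 = c(12, 11),
                       p = c(0.0005, 0.001))
  expect_identical(select_independent_snps(c("A", "B"), assoc2, dosage2),
                   "A")

  # 7 independent significant SNPs, max 5: exactly the 5 smallest P
  set.seed(42)
  dosage3 <- matrix(rbinom(7 * n, 2, 0.4), nrow = 7,
                    dimnames = list(paste0("s", 1:7), NULL))
  p <- c(0.04, 0.001, 0.02, 0.03, 0.01, 0.002, 0.045)
  assoc3 <- data.frame(snp = paste0("s", 1:7),
                       chi2 = qchisq(p, 1, lower.tail = FALSE), p = p)
  sel3 <- select_independent_snps(paste0("s", 1:7), assoc3, dosage3)
  expect_length(sel3, 5)
  expect_setequal(sel3, paste0("s", c(2, 6, 5, 3, 4)))
})

test_that("SRT scores equal the significant-SNP fraction from the assoc table", {
  set.seed(51)
  sim <- simulate_study(synthetic_config(n_case = 60, n_control = 60,
                                         n_genes = 40, n_sets = 8,
                                         genes_per_set = 6,
                                         planted_sets = character(0),
                                         seed = 51))
  st <- sim$genotypes
  map <- map_snps_to_genes(st, sim$genome$genes)
  assoc <- assoc_table(st)
  sets <- filter_gene_sets(sim$sets, universe = sim$genome$genes$gene)
  res <- snp_ratio_test(st, map, sets, p_cut = 0.05,
                        plan = permutation_plan(50, seed = 5))
  p_by_snp <- setNames(assoc$p, assoc$snp)
  for (i in seq_len(nrow(res))) {
    ids <- unique(unlist(map$gene_to_snps[sets$sets[[res$set[i]]]]))
    expect_equal(res$score[i], mean(p_by_snp[ids] < 0.05))
  }
  # monotonicity: raising p_cut never decreases an observed ratio
  res2 <- snp_ratio_test(st, map, sets, p_cut = 0.2,
                         plan = permutation_plan(50, seed = 5))
  expect_true(all(res2$score >= res$score))
})

test_that("ALIGATOR matches the hypergeometric tail with one SNP per gene", {
  # 10 genes, 1 SNP each, 2 significant; the set is the 2 significant genes.
  genes <- data.frame(gene = paste0("G", 1:10), chrom = "1",
                      start = (0:9) * 50000 + 20001,
                      end = (0:9) * 50000 + 30000)
  snps <- data.frame(snp = paste0("s", 1:10), chr = "1",
                     pos = genes$start + 100)
  m <- map_snps_to_genes(snps, genes)
  assoc <- data.frame(snps, chi2 = 1, p = c(0.01, 0.01, rep(0.5, 8)))
  sets <- gene_set_collection(list(hit = c("G1", "G2"),
                                   null = c("G5", "G6", "G7")))
  R <- 2000
  res <- aligator(assoc, m, sets, p_cut = 0.05,
                  plan = permutation_plan(R, seed = 9, scheme = "snp-resample"))
  # P(both of 2 random genes land in the set) = 1/choose(10,2) = 1/45
  p_true <- 1 / 45
  expected <- (1 + R * p_true) / (R + 1)
  mc_se <- sqrt(p_true * (1 - p_true) / R)
  expect_lt(abs(res$p[res$set == "hit"] - expected), 3 * mc_se)
  expect_equal(res$score[res$set == "hit"], 2)

  # p_cut = 1: every gene significant, every replicate reproduces the
  # observed counts, all P = 1
  res2 <- aligator(assoc, m, sets, p_cut = 1,
                   plan = permutation_plan(50, seed = 9, scheme = "snp-resample"))
  expect_true(all(res2$p == 1))

  # no significant genes at all: warning and all P = 1
  assoc$p <- rep(0.5, 10)
  expect_warning(res3 <- aligator(assoc, m, sets, p_cut = 0.05,
                                  plan = permutation_plan(50, seed = 9,
                                                          scheme = "snp-resample")),
                 "no significant genes")
  expect_true(all(res3$p == 1))
})

test_that("set-based test on a single-SNP set equals the direct permutation P", {
  set.seed(61)
  n <- 60
  d <- matrix(rbinom(3 * n, 2, 0.3), nrow = 3)
  st <- toy_study(d, n / 2, n / 2)
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = "1",
                      start = c(500, 100500, 200500), end = c(1500, 101500, 201500))
  st$pos <- c(1000, 101000, 201000)
  map <- map_snps_to_genes(st, genes, flank_bp = 0)
  sets <- gene_set_collection(list(solo = "G1"))
  B <- 199
  plan <- permutation_plan(B, seed = 17)
  res <- set_based_test(st, map, sets, p_cut = 1, plan = plan)
  # oracle: same documented permutation recipe, public allelic_test per swap
  labs <- perm_labels(st$phenotype, B, 17)
  obs <- allelic_test(d[1, ], st$phenotype)$chi2
  perm <- apply(labs, 2, function(ci)
    allelic_test(d[1, ], ifelse(ci == 1, "case", "control"))$chi2)
  expect_equal(res$score[1], obs, tolerance = 1e-12)
  expect_equal(res$p[1], empirical_pvalue(obs, perm, "ge"))
})

test_that("set-based scores an empty selection as 0 with P = 1", {
  set.seed(62)
  d <- matrix(rep(rbinom(30, 2, 0.3), each = 2), nrow = 2)  # 2 identical SNPs
  st <- toy_study(d, 15, 15)
  genes <- data.frame(gene = "G1", chrom = "1", start = 500, end = 2500)
  map <- map_snps_to_genes(st, genes, flank_bp = 0)
  sets <- gene_set_collection(list(s = "G1"))
  # impossible cutoff: nothing is ever selected
  res <- set_based_test(st, map, sets, p_cut = 1e-12,
                        plan = permutation_plan(30, seed = 3))
  expect_equal(res$score, 0)
  expect_equal(res$p, 1)
})

test_that("all four GWAS tests are seed-deterministic", {
  sim <- simulate_study(synthetic_config(n_case = 50, n_control = 50,
                                         n_genes = 30, n_sets = 6,
                                         genes_per_set = 5, seed = 77))
  st <- sim$genotypes
  map <- map_snps_to_genes(st, sim$genome$genes)
  assoc <- assoc_table(st)
  sets <- filter_gene_sets(sim$sets, universe = sim$genome$genes$gene)
  plan <- permutation_plan(40, seed = 23)
  rplan <- permutation_plan(200, seed = 23, scheme = "snp-resample")
  run <- function() list(
    g = gsea_gwas(st, map, sets, plan),
    a = aligator(assoc, map, sets, plan = rplan),
    s = snp_ratio_test(st, map, sets, plan = plan),
    b = set_based_test(st, map, sets, plan = plan)
  )
  expect_identical(run(), run())
})

test_that("GSEA empirical P honours the B = 1 formula and rejects bad plans", {
  sim <- simulate_study(synthetic_config(n_case = 30, n_control = 30,
                                         n_genes = 20, n_sets = 4,
                                         genes_per_set = 5, seed = 88))
  st <- sim$genotypes
  map <- map_snps_to_genes(st, sim$genome$genes)
  sets <- filter_gene_sets(sim$sets, universe = sim$genome$genes$gene)
  res <- gsea_gwas(st, map, sets, permutation_plan(1, seed = 2))
  expect_true(all(res$p %in% c(0.5, 1.0)))
  expect_error(gsea_gwas(st, map, sets,
                         permutation_plan(10, 1, "snp-resample")),
               "phenotype-swap")
})
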