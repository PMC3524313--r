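test_that("SNP-to-gene mapping includes the flank boundary", {
  genes <- data.frame(gene = c("GA", "GB"), chrom = "1",
                      start = c(10000, 30000), end = c(20000, 40000))
  snps <- data.frame(snp = c("s_in", "s_edge", "s_out"), chr = "1",
                     pos = c(15000, 10000, 9999))
  m <- map_snps_to_genes(snps, genes, flank_bp = 20000)
  expect_true("s_in" %in% m$gene_to_snps$GA)
  expect_true("s_edge" %in% m$gene_to_snps$GB)   # exactly 20 kb upstream
  expect_false("s_out" %in% m$gene_to_snps$GB)   # 20,001 bp away
  # SNPs inside two overlapping flank windows map to both genes
  expect_setequal(m$snp_to_genes$s_in, c("GA", "GB"))    # 15 kb from GB
  expect_setequal(m$snp_to_genes$s_edge, c("GA", "GB"))
})

test_that("mapping is invariant to SNP input order and keeps empty genes", {
  set.seed(8)
  genes <- data.frame(gene = paste0("G", 1:5), chrom = "1",
                      start = (0:4) * 50000 + 20001,
                      end = (0:4) * 50000 + 30000)
  snps <- data.frame(snp = paste0("s", 1:30), chr = "1",
                     pos = sample(1:200000, 30))
  m1 <- map_snps_to_genes(snps, genes)
  m2 <- map_snps_to_genes(snps[sample(30), ], genes)
  expect_identical(m1$gene_to_snps, m2$gene_to_snps)
  expect_identical(names(m1$gene_to_snps), genes$gene)
})

test_that("gene statistic is the max-chi2 SNP with position tie-break", {
  genes <- data.frame(gene = "G1", chrom = "1", start = 1000, end = 99000)
  snps <- data.frame(snp = c("a", "b", "c"), chr = "1",
                     pos = c(2000, 3000, 4000))
  m <- map_snps_to_genes(snps, genes, flank_bp = 0)
  assoc <- data.frame(snp = c("a", "b", "c"), chr = "1",
                      pos = c(2000, 3000, 4000), chi2 = c(1.2, 7.4, 0.3),
                      p = pchisq(c(1.2, 7.4, 0.3), 1, lower.tail = FALSE))
  gs <- gene_statistics(assoc, m)
  expect_equal(gs$chi2, 7.4)
  expect_equal(gs$snp, "b")

  assoc$chi2 <- c(7.4, 7.4, 0.3)  # tie: smaller position wins
  assoc$p <- pchisq(assoc$chi2, 1, lower.tail = FALSE)
  expect_message(gs2 <- gene_statistics(assoc, m), "tie")
  expect_equal(gs2$snp, "a")
})

test_that("gene statistics match brute force on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    n_gene <- 6
    genes <- data.frame(gene = paste0("G", 1:n_gene), chrom = "1",
                        start = (0:(n_gene - 1)) * 50000 + 20001,
                        end = (0:(n_gene - 1)) * 50000 + 30000)
    n_snp <- 40
    snps <- data.frame(snp = paste0("s", 1:n_snp), chr = "1",
                       pos = sample(seq_len(n_gene * 50000), n_snp))
    chi2 <- rchisq(n_snp, 1)
    assoc <- data.frame(snps, chi2 = chi2,
                        p = pchisq(chi2, 1, lower.tail = FALSE))
    m <- map_snps_to_genes(snps, genes)
    gs <- gene_statistics(assoc, m)
    for (i in seq_len(nrow(gs))) {
      ids <- m$gene_to_snps[[gs$gene[i]]]
      expect_equal(gs$chi2[i], max(assoc$chi2[assoc$snp %in% ids]))
    }
  }
})

test_that("set-size filter intersects with the universe and uses inclusive bounds", {
  sets <- list(tiny = paste0("g", 1:4),          # effective 4 -> dropped
               edge5 = paste0("g", 1:5),         # 5 -> kept
               outside = paste0("x", 1:10),      # universe-empty -> dropped
               big = paste0("g", 1:250),         # 250 -> kept
               toobig = paste0("g", 1:251))      # 251 -> dropped
  col <- gene_set_collection(sets)
  universe <- paste0("g", 1:251)
  out <- filter_gene_sets(col, universe)
  expect_setequal(names(out$sets), c("edge5", "big"))
  rep <- attr(out, "size_report")
  expect_equal(rep$effective_size[rep$set == "outside"], 0)
  # idempotence
  out2 <- filter_gene_sets(out, universe)
  expect_identical(out2$sets, out$sets)
  expect_error(filter_gene_sets(col, character(0)), "empty gene universe")
})

test_that("GWAS-derived gene sets honour k, the P cutoff, and ties", {
  set.seed(4)
  stats <- data.frame(gene = paste0("G", 1:100), snp = paste0("s", 1:100),
                      chi2 = rchisq(100, 1))
  stats$p <- pchisq(stats$chi2, 1, lower.tail = FALSE)
  d <- suppressWarnings(derive_gwas_gene_sets(stats, top_k = 30, p_cut = 1e-4))
  expect_length(d$sets[[1]], 30)
  expect_setequal(d$sets[[1]], stats$gene[order(stats$p)][1:30])
  w1 <- capture_warnings(derive_gwas_gene_sets(stats[1:10, ], top_k = 30))
  expect_match(w1, "fewer genes", all = FALSE)
  w2 <- capture_warnings(derive_gwas_gene_sets(stats, p_cut = 1e-12))
  expect_match(w2, "threshold set", all = FALSE)
})

test_that("DEG sets are nested across log2-ratio thresholds", {
  set.seed(14)
  de <- data.frame(gene = paste0("g", 1:500),
                   log2_ratio = rnorm(500, sd = 1.5),
                   fdr = runif(500))
  d <- suppressWarnings(derive_deg_gene_sets(de))
  # brute-force membership oracle
  for (x in c(1, 1.5, 2)) {
    nm <- paste0("DEG_LR_", format(x))
    if (!nm %in% names(d$sets)) next
    expect_setequal(d$sets[[nm]], de$gene[de$fdr < 0.05 & abs(de$log2_ratio) > x])
  }
  if (all(c("DEG_LR_1", "DEG_LR_1.5") %in% names(d$sets)))
    expect_true(all(d$sets$`DEG_LR_1.5` %in% d$sets$DEG_LR_1))
  if (all(c("DEG_LR_1.5", "DEG_LR_2") %in% names(d$sets)))
    expect_true(all(d$sets$DEG_LR_2 %in% d$sets$`DEG_LR_1.5`))
  # gene with FDR .01, LR -1.6 is in LR_1 and LR_1.5 but not LR_2
  de2 <- rbind(de, data.frame(gene = "target", log2_ratio = -1.6, fdr = 0.01))
  d2 <- suppressWarnings(derive_deg_gene_sets(de2))
  expect_true("target" %in% d2$sets$DEG_LR_1)
  expect_true("target" %in% d2$sets$`DEG_LR_1.5`)
  expect_false("target" %in% d2$sets$DEG_LR_2)
})
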