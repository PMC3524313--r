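#!/usr/bin/env Rscript
# The four pathway tests on the GWAS arm, at the standard parameters:
# 1000 phenotype swaps (10,000 SNP resamples for the resampling test),
# SNP significance cut 0.05, LD pruning r2 > 0.5 with at most 5 SNPs per
# set. Competitive tests: GSEA over max-chi2 gene statistics, and
# ALIGATOR-style SNP resampling. Self-contained tests: the SNP ratio test
# and the LD-pruned set-based mean-chi-square test.

library(intpath)

data_dir <- "results/data"
out <- "results"

study <- apply_qc(read_plink_text(file.path(data_dir, "study.ped"),
                                  file.path(data_dir, "study.map")))$study
genes <- read_gene_bed(file.path(data_dir, "genes.bed"))
collection <- read_gmt(file.path(data_dir, "pathways.gmt"))
deg_path <- file.path(out, "deg_derived_sets.gmt")
if (file.exists(deg_path)) {
  deg <- read_gmt(deg_path)
  collection <- gene_set_collection(c(collection$sets, deg$sets))
}

assoc <- assoc_table(study)
map <- map_snps_to_genes(study, genes)
gstats <- gene_statistics(assoc, map)
sets <- filter_gene_sets(collection, universe = gstats$gene)
cat(length(sets), "of", length(collection), "gene sets eligible (size 5-250",
    "after intersection with the", nrow(gstats), "scoreable genes)\n")

plan <- permutation_plan(1000, seed = 42)
rplan <- permutation_plan(10000, seed = 42, scheme = "snp-resample")

res <- list(
  gsea_gwas = gsea_gwas(study, map, sets, plan),
  aligator = aligator(assoc, map, sets, plan = rplan),
  srt = snp_ratio_test(study, map, sets, plan = plan),
  set_based = set_based_test(study, map, sets, plan = plan)
)
for (nm in names(res)) {
  tab <- tier_select(res[[nm]])
  write_results_table(tab, file.path(out, paste0(nm, ".tsv")))
  top <- tab[which.min(tab$p), ]
  cat(sprintf("%-10s: %2d sets at P<0.01, %2d at FDR<0.2; top %s (p=%.3g)\n",
              nm, sum(tab$tier1), sum(tab$tier2), top$set, top$p))
}
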