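#!/usr/bin/env Rscript
# Simulate the cross-platform study that the rest of the workflow analyses:
# a case/control genotype panel (300 + 300 samples, 300 genes x 5 SNPs in
# LD blocks) and a matched expression matrix, with one planted pathway
# ("set1") whose genes carry allelic effects (log OR 0.35, half the set)
# and expression shifts (+1 log2 unit in cases). Everything is written as
# the plain-text formats the pipeline reads (PED/MAP, BED, GMT, TSV).

library(intpath)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 42)
sim <- simulate_study(cfg)

write_plink_text(sim$genotypes, file.path(out, "study.ped"),
                 file.path(out, "study.map"))
write_gene_bed(sim$genome$genes, file.path(out, "genes.bed"))
write_gmt(sim$sets, file.path(out, "pathways.gmt"))
write_expression(sim$expression, file.path(out, "expression.tsv"),
                 file.path(out, "phenotype.tsv"))
jsonlite::write_json(
  list(planted_sets = sim$truth$planted_sets,
       effect_genes = names(which(sim$truth$gene_effect)),
       causal_snps = names(which(sim$truth$snp_causal))),
  file.path(out, "truth.json"), auto_unbox = FALSE)

cat("Simulated study written to", out, "\n")
cat("  SNPs:", length(sim$genotypes$snp_ids),
    " samples:", length(sim$genotypes$sample_ids), "\n")
cat("  planted pathway:", sim$truth$planted_sets,
    "(", sum(sim$truth$gene_effect), "effect genes,",
    sum(sim$truth$snp_causal), "causal SNPs )\n")
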