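#!/usr/bin/env Rscript
# Genotype QC, single-SNP allelic association, genomic inflation, and the
# gene-wise representative statistics (max chi-square SNP per gene within
# a 20 kb flank). Also derives the cross-platform gene sets: the top-30
# and P < 1e-4 gene lists for the expression arm, and the DEG_LR_x sets
# for the GWAS arm.

library(intpath)

data_dir <- "results/data"
out <- "results"

study <- read_plink_text(file.path(data_dir, "study.ped"),
                         file.path(data_dir, "study.map"))
genes <- read_gene_bed(file.path(data_dir, "genes.bed"))

qc <- apply_qc(study, qc_thresholds())
cat("QC:", qc$report$snps_retained, "SNPs and",
    qc$report$samples_retained, "samples retained (",
    qc$report$snps_low_call_rate, "low call rate /",
    qc$report$snps_low_maf, "low MAF /",
    qc$report$snps_monomorphic, "monomorphic dropped )\n")
study <- qc$study

assoc <- assoc_table(study)
cat(sprintf("Genomic inflation lambda = %.3f\n", genomic_inflation(assoc)))
write.table(assoc, file.path(out, "association.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

map <- map_snps_to_genes(study, genes, flank_bp = 20000)
gstats <- gene_statistics(assoc, map)
write.table(gstats, file.path(out, "gene_statistics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Gene-wise statistics for", nrow(gstats), "genes; top gene:",
    gstats$gene[which.min(gstats$p)],
    sprintf("(p = %.2g)\n", min(gstats$p)))

# gene sets derived from the GWAS ranking, for the expression arm
gws <- tryCatch(derive_gwas_gene_sets(gstats),
                warning = function(w) suppressWarnings(derive_gwas_gene_sets(gstats)))
write_gmt(gws, file.path(out, "gwas_derived_sets.gmt"))

# gene sets derived from differential expression, for the GWAS arm
expr <- read_expression(file.path(data_dir, "expression.tsv"),
                        file.path(data_dir, "phenotype.tsv"))
de <- differential_expression(expr)
write.table(de, file.path(out, "differential_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
deg <- tryCatch(suppressWarnings(derive_deg_gene_sets(de)),
                error = function(e) NULL)
if (!is.null(deg)) {
  write_gmt(deg, file.path(out, "deg_derived_sets.gmt"))
  cat("DEG sets:", paste(sprintf("%s (%d)", names(deg$sets),
                                 lengths(deg$sets)), collapse = ", "), "\n")
} else {
  cat("No DEG sets passed FDR < 0.05 at any log2-ratio threshold\n")
}
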