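#!/usr/bin/env Rscript
# Cross-platform integration: Fisher's combined probability test over the
# pathways eligible on both arms (set-based test P x expression GSEA P,
# chi-square with 4 df), BH FDR over the intersection, two-tier calls
# (nominal P < 0.01; FDR < 0.2), and the overlap of the per-method
# significant lists.

library(intpath)

out <- "results"
gwas <- read.delim(file.path(out, "set_based.tsv"))
expr <- read.delim(file.path(out, "gsea_expression.tsv"))

combined <- combine_platforms(gwas, expr)
write_results_table(combined, file.path(out, "combined.tsv"))
cat(nrow(combined), "pathways eligible on both platforms;",
    sum(combined$tier1), "with combined P < 0.01\n")
cat("Top pathways by combined P:\n")
top <- combined[1:min(5, nrow(combined)), ]
for (i in seq_len(nrow(top)))
  cat(sprintf("  %-8s p_gwas=%.3g p_expr=%.3g chi2=%.2f p_comb=%.3g fdr=%.3g\n",
              top$set[i], top$p_gwas[i], top$p_expr[i], top$chi2[i],
              top$p_combined[i], top$fdr[i]))

# overlap of the significant lists (tier 1 or tier 2) across methods
lists <- lapply(c(gsea_gwas = "gsea_gwas", set_based = "set_based",
                  srt = "srt", gsea_expr = "gsea_expression"),
                function(f) {
                  t <- read.delim(file.path(out, paste0(f, ".tsv")))
                  t$set[t$tier1 | t$tier2]
                })
ov <- overlap_summary(lists)
write.table(ov$regions, file.path(out, "overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Pathways shared by >= m methods:\n")
print(ov$shared, row.names = FALSE)
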