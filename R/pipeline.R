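# End-to-end orchestration: QC -> allelic association -> SNP-to-gene
# mapping -> four GWAS set tests -> expression arm (normalization, DE,
# GSEA) -> Fisher combination -> tier calls and overlap summary. One config
# (R list or YAML file), one output directory, fully seeded.

.default_params <- function() {
  list(
    flank_bp = 20000,
    min_set_size = 5, max_set_size = 250,
    qc = list(min_call_rate = 0.90, min_maf = 0.05,
              max_sample_missing = 0.10),
    n_perm = 1000, aligator_n_perm = 10000,
    p_cut = 0.05, r2_cut = 0.5, max_snps = 5,
    weight_exponent = 1,
    tier_p_cut = 0.01, tier_fdr_cut = 0.2,
    derived_sets = TRUE,
    quantile_normalize = FALSE
  )
}

.merge_params <- function(user) {
  p <- .default_params()
  for (nm in names(user)) {
    if (nm == "qc") for (q in names(user$qc)) p$qc[[q]] <- user$qc[[q]]
    else p[[nm]] <- user[[nm]]
  }
  p
}

#' Run the full integrative pathway analysis
#'
#' Stages, in order: input loading (files or a synthetic study), genotype
#' QC, allelic association with genomic inflation, SNP-to-gene mapping,
#' set-size filtering per platform, the four GWAS set tests, expression
#' differential expression and GSEA, Fisher combination of the set-based
#' and expression-GSEA P-values over the pathways eligible on both
#' platforms, tier flags, and the cross-method overlap summary. Every
#' output is written under `out_dir` together with a config snapshot
#' (`config.yaml`) and a run log; re-running on the snapshot reproduces the
#' outputs byte-identically.
#'
#' @param config An R list or the path to a YAML file. Top-level fields:
#'   `seed` (integer), exactly one of `synthetic` (a list of
#'   [synthetic_config()] arguments) or `files` (list with `ped`, `map`,
#'   `bed`, `gmt`, `expr_matrix`, `expr_pheno`), and optional `params`
#'   overriding the defaults (see Details).
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output and just returns the tables.
#' @details Default parameters: 20 kb flank; set sizes 5-250; QC call rate
#'   0.90 / MAF 0.05 / sample missingness 0.10; 1000 phenotype swaps
#'   (10,000 SNP resamples for the resampling test); SNP significance cut
#'   0.05; LD pruning r2 0.5, max 5 SNPs; tier cuts P < 0.01 and
#'   FDR < 0.2.
#' @return Invisibly, a list with the per-method result tables
#'   (`gsea_gwas`, `aligator`, `srt`, `set_based`, `de`, `gsea_expr`,
#'   `combined`, `overlap`), the QC report, `lambda`, and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  has_syn <- !is.null(config$synthetic)
  has_files <- !is.null(config$files)
  if (has_syn == has_files)
    stop("config error: provide exactly one of 'synthetic' or 'files'")
  params <- .merge_params(config$params)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  # ---- stage: inputs -------------------------------------------------
  if (has_syn) {
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- seed
    if (!is.null(syn_args$maf_range)) syn_args$maf_range <- as.numeric(syn_args$maf_range)
    if (!is.null(syn_args$planted_sets)) syn_args$planted_sets <- as.character(syn_args$planted_sets)
    scfg <- do.call(synthetic_config, syn_args)
    sim <- simulate_study(scfg)
    study <- sim$genotypes
    genes <- sim$genome$genes
    collection <- sim$sets
    expr <- sim$expression
    note("inputs: synthetic study, seed ", scfg$seed)
  } else {
    f <- config$files
    need <- c("ped", "map", "bed", "gmt", "expr_matrix", "expr_pheno")
    miss <- setdiff(need, names(f))
    if (length(miss)) stop("config error: missing file entries: ",
                           paste(miss, collapse = ", "))
    absent <- unlist(f[need])[!file.exists(unlist(f[need]))]
    if (length(absent)) stop("config error: file(s) not found: ",
                             paste(absent, collapse = ", "))
    study <- read_plink_text(f$ped, f$map)
    genes <- read_gene_bed(f$bed)
    collection <- read_gmt(f$gmt)
    expr <- read_expression(f$expr_matrix, f$expr_pheno)
    note("inputs: files")
  }

  # ---- stage: QC + association --------------------------------------
  qc <- apply_qc(study, qc_thresholds(
    min_call_rate = params$qc$min_call_rate, min_maf = params$qc$min_maf,
    max_sample_missing = params$qc$max_sample_missing))
  study <- qc$study
  note("qc: ", qc$report$snps_retained, " SNPs / ",
       qc$report$samples_retained, " samples retained")
  assoc <- assoc_table(study)
  lambda <- genomic_inflation(assoc)
  note(sprintf("association: lambda_GC = %.3f", lambda))

  # ---- stage: mapping + gene statistics -----------------------------
  map <- map_snps_to_genes(study, genes, flank_bp = params$flank_bp)
  gstats <- gene_statistics(assoc, map)
  note("mapping: ", nrow(gstats), " genes with >= 1 SNP")

  # ---- stage: gene set collections per platform ---------------------
  if (params$quantile_normalize)
    expr$values <- quantile_normalize(expr$values)
  de <- differential_expression(expr)
  gwas_coll <- collection
  expr_coll <- collection
  if (isTRUE(params$derived_sets)) {
    deg <- tryCatch(suppressWarnings(derive_deg_gene_sets(de)),
                    error = function(e) NULL)
    if (!is.null(deg)) {
      gwas_coll <- gene_set_collection(c(gwas_coll$sets, deg$sets))
      note("derived sets (GWAS arm): ", paste(names(deg$sets), collapse = ", "))
    }
    gws <- tryCatch(suppressWarnings(derive_gwas_gene_sets(gstats)),
                    error = function(e) NULL)
    if (!is.null(gws)) {
      expr_coll <- gene_set_collection(c(expr_coll$sets, gws$sets))
      note("derived sets (expression arm): ",
           paste(names(gws$sets), collapse = ", "))
    }
  }
  gwas_sets <- filter_gene_sets(gwas_coll, universe = gstats$gene,
                                min_size = params$min_set_size,
                                max_size = params$max_set_size)
  expr_sets <- filter_gene_sets(expr_coll, universe = expr$gene_ids,
                                min_size = params$min_set_size,
                                max_size = params$max_set_size)
  note("sets: ", length(gwas_sets), " eligible on GWAS arm, ",
       length(expr_sets), " on expression arm")

  # ---- stage: four GWAS tests ---------------------------------------
  plan_swap <- permutation_plan(params$n_perm, seed, "phenotype-swap")
  plan_resample <- permutation_plan(params$aligator_n_perm, seed,
                                    "snp-resample")
  res_gsea <- gsea_gwas(study, map, gwas_sets, plan_swap,
                        weight_exponent = params$weight_exponent)
  res_alig <- aligator(assoc, map, gwas_sets, p_cut = params$p_cut,
                       plan = plan_resample)
  res_srt <- suppressWarnings(
    snp_ratio_test(study, map, gwas_sets, p_cut = params$p_cut,
                   plan = plan_swap))
  res_set <- set_based_test(study, map, gwas_sets, r2_cut = params$r2_cut,
                            p_cut = params$p_cut,
                            max_snps = params$max_snps, plan = plan_swap)

  # ---- stage: expression GSEA ---------------------------------------
  res_expr <- gsea_expression(expr, expr_sets, plan_swap,
                              weight_exponent = params$weight_exponent)

  # ---- stage: combination + tiers + overlap -------------------------
  combined <- combine_platforms(res_set, res_expr,
                                p_cut = params$tier_p_cut,
                                fdr_cut = params$tier_fdr_cut)
  tiered <- lapply(list(gsea_gwas = res_gsea, aligator = res_alig,
                        srt = res_srt, set_based = res_set,
                        gsea_expr = res_expr),
                   tier_select, p_cut = params$tier_p_cut,
                   fdr_cut = params$tier_fdr_cut)
  sig_lists <- lapply(tiered[c("gsea_gwas", "set_based", "srt", "gsea_expr")],
                      function(t) t$set[t$tier1 | t$tier2])
  overlap <- overlap_summary(sig_lists)
  note("combined: ", nrow(combined), " pathways eligible on both platforms; ",
       sum(combined$tier1), " with combined P < ", params$tier_p_cut)

  out <- list(gsea_gwas = tiered$gsea_gwas, aligator = tiered$aligator,
              srt = tiered$srt, set_based = tiered$set_based, de = de,
              gsea_expr = tiered$gsea_expr, combined = combined,
              overlap = overlap, qc_report = qc$report, lambda = lambda,
              log = log)

  # ---- stage: reports ------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(gsea_gwas = "gsea_gwas.tsv", aligator = "aligator.tsv",
               srt = "srt.tsv", set_based = "set_based.tsv",
               gsea_expr = "gsea_expression.tsv", combined = "combined.tsv")
    for (nm in names(paths))
      write_results_table(out[[nm]], file.path(out_dir, paths[nm]))
    utils::write.table(de, file.path(out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(overlap$regions, file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    snapshot <- config
    snapshot$seed <- seed
    snapshot$params <- params
    yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
    writeLines(log, file.path(out_dir, "run.log"))
    out$paths <- file.path(out_dir, c(paths, "differential_expression.tsv",
                                      "overlap.tsv", "config.yaml", "run.log"))
  }
  invisible(out)
}
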