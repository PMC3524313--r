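# SNP-to-gene assignment with a flanking window, gene-wise representative
# statistics (max chi-square), set-size filtering, and cross-platform
# derived gene sets.

#' Map SNPs to genes within a flanking window
#'
#' A SNP is assigned to every gene for which it lies within
#' `[start - flank_bp, end + flank_bp]` (inclusive on both sides, strand
#' ignored). Genes with no SNPs are present with empty SNP lists.
#'
#' @param snps data.frame with `snp`, `chr`, `pos` (e.g. from [assoc_table()]
#'   or a [genotype_study()]'s fields).
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive, as from [read_gene_bed()]).
#' @param flank_bp Flanking distance in base pairs (default 20,000).
#' @return List of class `snp_gene_map`: `gene_to_snps` (named list, gene ->
#'   SNP ids ordered by position), `snp_to_genes` (named list), `flank_bp`.
#' @export
map_snps_to_genes <- function(snps, genes, flank_bp = 20000) {
  if (inherits(snps, "genotype_study"))
    snps <- data.frame(snp = snps$snp_ids, chr = snps$chrom, pos = snps$pos)
  stopifnot(all(c("snp", "chr", "pos") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  ord <- order(snps$chr, snps$pos, snps$snp)  # order-independence of input
  snps <- snps[ord, , drop = FALSE]
  gene_to_snps <- stats::setNames(vector("list", nrow(genes)), genes$gene)
  snp_to_genes <- stats::setNames(vector("list", nrow(snps)), snps$snp)
  for (i in seq_len(nrow(genes))) {
    sel <- snps$chr == genes$chrom[i] &
      snps$pos >= genes$start[i] - flank_bp &
      snps$pos <= genes$end[i] + flank_bp
    ids <- snps$snp[sel]
    gene_to_snps[[i]] <- ids
    for (s in ids) snp_to_genes[[s]] <- c(snp_to_genes[[s]], genes$gene[i])
  }
  structure(list(gene_to_snps = gene_to_snps, snp_to_genes = snp_to_genes,
                 flank_bp = flank_bp),
            class = "snp_gene_map")
}

#' Gene-wise representative statistics
#'
#' Each gene is represented by its maximum-chi-square SNP among the SNPs
#' mapped to it; the gene-wise P is that SNP's P. A tie at the maximum is
#' broken to the smaller base-pair position, then the smaller SNP id
#' (logged). Genes with no mapped SNPs are omitted.
#'
#' @param assoc data.frame from [assoc_table()] covering all mapped SNPs.
#' @param map A [map_snps_to_genes()] result.
#' @return data.frame: `gene`, `snp`, `chi2`, `p`.
#' @export
gene_statistics <- function(assoc, map) {
  stopifnot(inherits(map, "snp_gene_map"))
  idx <- stats::setNames(seq_len(nrow(assoc)), assoc$snp)
  genes <- names(map$gene_to_snps)
  rows <- vector("list", length(genes))
  tie_seen <- FALSE
  for (k in seq_along(genes)) {
    ids <- map$gene_to_snps[[k]]
    if (length(ids) == 0L) next
    if (anyNA(idx[ids]))
      stop("gene ", genes[k], ": mapped SNP lacks an association result")
    sub <- assoc[idx[ids], , drop = FALSE]
    mx <- max(sub$chi2)
    cand <- which(sub$chi2 == mx)
    if (length(cand) > 1L) {
      tie_seen <- TRUE
      cand <- cand[order(sub$pos[cand], sub$snp[cand])]
    }
    j <- cand[1]
    rows[[k]] <- data.frame(gene = genes[k], snp = sub$snp[j],
                            chi2 = sub$chi2[j], p = sub$p[j],
                            stringsAsFactors = FALSE)
  }
  if (tie_seen)
    message("gene_statistics: max-chi2 ties broken by position, then SNP id")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Filter gene sets by effective size
#'
#' Each set is intersected with the platform universe first; sets whose
#' effective size falls in `[min_size, max_size]` (inclusive) are kept.
#'
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of scoreable genes.
#' @param min_size,max_size Inclusive size bounds (defaults 5 and 250).
#' @return A [gene_set_collection()] restricted to the universe, with a
#'   `size_report` attribute recording original and effective sizes.
#' @export
filter_gene_sets <- function(collection, universe, min_size = 5,
                             max_size = 250) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(universe) == 0L) stop("empty gene universe")
  inter <- lapply(collection$sets, intersect, y = universe)
  eff <- lengths(inter)
  keep <- eff >= min_size & eff <= max_size
  report <- data.frame(set = names(collection$sets),
                       original_size = lengths(collection$sets),
                       effective_size = eff, kept = keep,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  out <- gene_set_collection(inter[keep], universe = universe,
                             provenance = collection$provenance[names(inter)[keep]])
  attr(out, "size_report") <- report
  out
}

#' Gene sets derived from GWAS gene-wise statistics
#'
#' Two sets for cross-platform evaluation on the expression side: the
#' `top_k` genes with smallest gene-wise P (ties at the k-th P broken by
#' gene name, logged), and all genes with P below `p_cut`.
#'
#' @param stats data.frame from [gene_statistics()].
#' @param top_k Number of top genes (default 30).
#' @param p_cut P-value cutoff for the second set (default 1e-4).
#' @return A [gene_set_collection()] with sets `GWAS_Top<k>` and
#'   `GWAS_TopP<cut>`; the threshold set may be empty and is then omitted
#'   with a warning.
#' @export
derive_gwas_gene_sets <- function(stats, top_k = 30, p_cut = 1e-4) {
  stopifnot(nrow(stats) >= 1)
  ord <- order(stats$p, stats$gene)
  if (nrow(stats) < top_k) {
    warning("fewer genes (", nrow(stats), ") than top_k = ", top_k,
            "; using all genes")
    top_k <- nrow(stats)
  } else {
    kth <- stats$p[ord][top_k]
    if (sum(stats$p == kth) > 1L)
      message("derive_gwas_gene_sets: tie at rank ", top_k,
              " broken by gene name")
  }
  top <- stats$gene[ord][seq_len(top_k)]
  thr <- stats$gene[stats$p < p_cut]
  sets <- list()
  sets[[paste0("GWAS_Top", top_k)]] <- top
  if (length(thr)) {
    sets[[paste0("GWAS_TopP", format(p_cut))]] <- thr
  } else {
    warning("no gene with p < ", p_cut, "; threshold set omitted")
  }
  gene_set_collection(sets)
}

#' Gene sets of differentially expressed genes at log2-ratio thresholds
#'
#' `DEG_LR_x` = genes with FDR < `fdr_cut` and |log2 ratio| > x. The sets
#' are nested by construction: higher thresholds give subsets.
#'
#' @param de data.frame with `gene`, `log2_ratio`, `fdr` (see
#'   [differential_expression()]).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param lr_thresholds Absolute log2-ratio thresholds (default 1, 1.5, 2).
#' @return A [gene_set_collection()]; thresholds yielding empty sets are
#'   omitted with a warning.
#' @export
derive_deg_gene_sets <- function(de, fdr_cut = 0.05,
                                 lr_thresholds = c(1, 1.5, 2)) {
  stopifnot(all(c("gene", "log2_ratio", "fdr") %in% names(de)))
  sets <- list()
  for (x in lr_thresholds) {
    g <- de$gene[de$fdr < fdr_cut & abs(de$log2_ratio) > x]
    nm <- paste0("DEG_LR_", format(x))
    if (length(g)) sets[[nm]] <- g
    else warning("no genes pass FDR < ", fdr_cut, " with |LR| > ", x,
                 "; set ", nm, " omitted")
  }
  if (length(sets) == 0L) stop("no non-empty DEG sets at any threshold")
  gene_set_collection(sets)
}
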