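#' Construct a gene set collection
#'
#' A named collection of gene sets sharing one gene universe. Gene sets are
#' character vectors of gene identifiers; identifiers are treated as opaque
#' strings throughout.
#'
#' @param sets Named list of character vectors. Set names must be unique,
#'   every set non-empty, and no gene may appear twice within one set.
#' @param universe Optional character vector of all scoreable genes on the
#'   current platform. `NULL` means "not yet restricted".
#' @param provenance Optional named character vector of free-text provenance,
#'   one entry per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, provenance = NULL) {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (length(sets) && (is.null(nm) || any(nm == "") || anyDuplicated(nm)))
    stop("gene set names must be present and unique")
  for (i in seq_along(sets)) {
    g <- sets[[i]]
    if (!is.character(g) || length(g) == 0L)
      stop("set '", nm[i], "' is empty or not a character vector")
    if (anyDuplicated(g))
      stop("set '", nm[i], "' contains duplicate genes")
  }
  if (!is.null(provenance)) provenance <- provenance[nm]
  structure(
    list(sets = sets, universe = universe, provenance = provenance),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets")
  if (!is.null(x$universe)) cat(",", length(x$universe), "universe genes")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Construct a case/control genotype study
#'
#' Holds a SNP x sample minor-allele dosage matrix together with SNP
#' coordinates and a binary phenotype. Dosages count copies of the minor
#' allele (0, 1, 2) with `NA` for missing calls.
#'
#' @param snp_ids Character vector of SNP identifiers (unique, ordered).
#' @param chrom Chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP (non-negative).
#' @param dosage Integer/numeric matrix, SNPs in rows, samples in columns.
#' @param sample_ids Character vector of sample identifiers.
#' @param phenotype Character/factor per sample, values "case"/"control";
#'   both classes must be present.
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(snp_ids, chrom, pos, dosage, sample_ids, phenotype) {
  dosage <- as.matrix(dosage)
  phenotype <- as.character(phenotype)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  if (length(snp_ids) != nrow(dosage) || length(sample_ids) != ncol(dosage))
    stop("dosage dimensions do not match SNP/sample counts")
  if (length(chrom) != length(snp_ids) || length(pos) != length(snp_ids))
    stop("chrom/pos length must match snp_ids")
  if (any(pos < 0)) stop("positions must be non-negative")
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype values must be 'case' or 'control'")
  if (length(unique(phenotype)) < 2L)
    stop("phenotype must contain both classes")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("dosage entries must be in {0,1,2,NA}")
  dimnames(dosage) <- list(snp_ids, sample_ids)
  structure(
    list(snp_ids = as.character(snp_ids), chrom = as.character(chrom),
         pos = as.numeric(pos), dosage = dosage,
         sample_ids = as.character(sample_ids), phenotype = phenotype),
    class = "genotype_study"
  )
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("genotype_study:", length(x$snp_ids), "SNPs x", length(x$sample_ids),
      "samples (", sum(x$phenotype == "case"), "cases /",
      sum(x$phenotype == "control"), "controls )\n")
  invisible(x)
}

#' Construct a two-class expression study
#'
#' @param gene_ids Character vector of gene identifiers (row order).
#' @param values Numeric gene x sample matrix (assumed log2 scale).
#' @param sample_ids Character vector of sample identifiers.
#' @param phenotype Character per sample in {"case","control"}; no missing.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(gene_ids, values, sample_ids, phenotype) {
  values <- as.matrix(values)
  phenotype <- as.character(phenotype)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("values dimensions do not match gene/sample counts")
  if (anyNA(phenotype) || !all(phenotype %in% c("case", "control")))
    stop("phenotype must be 'case'/'control' with no missing values")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(gene_ids = as.character(gene_ids), values = values,
         sample_ids = as.character(sample_ids), phenotype = phenotype),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}
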