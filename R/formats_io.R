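# Readers and writers for the external formats the pipeline touches:
# GMT gene sets, PLINK text PED/MAP, BED4 gene models, TSV expression
# matrices, and the fixed-layout results table. All readers are line-ending
# agnostic (\n and \r\n).

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated
#' (MSigDB dialect). Duplicate genes within a line are dropped with a
#' warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  prov <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    name <- f[1]
    if (name %in% names(sets))
      stop("duplicate gene set name '", name, "' at line ", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " (", name, "): duplicate genes removed")
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop("GMT line ", i, " (", name, "): no genes")
    sets[[name]] <- genes
    prov[name] <- f[2]
  }
  gene_set_collection(sets, provenance = prov)
}

#' Write a gene set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  prov <- collection$provenance
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(prov) && !is.na(prov[nm])) prov[[nm]] else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Dosages count copies of the minor allele per SNP; the minor allele is
#' determined from non-missing calls, with a frequency tie broken to the
#' lexicographically smaller allele (logged via `message()`). PED column 6
#' carries the phenotype (1 = control, 2 = case); "0" alleles are missing.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file (chrom, snp id, cM, bp).
#' @return A [genotype_study()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- .read_lines(map_path)
  map_lines <- map_lines[nzchar(map_lines)]
  map <- do.call(rbind, strsplit(trimws(map_lines), "[ \t]+"))
  if (ncol(map) < 4L) stop("MAP file needs >= 4 columns")
  snp_ids <- map[, 2]
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in MAP")
  n_snp <- nrow(map)

  ped_lines <- .read_lines(ped_path)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  ped <- strsplit(trimws(ped_lines), "[ \t]+")
  n_samp <- length(ped)
  if (n_samp == 0L) stop("empty PED file")
  want <- 6L + 2L * n_snp
  lens <- lengths(ped)
  if (any(lens != want))
    stop("PED/MAP mismatch: expected ", want, " fields per PED line, got ",
         lens[which(lens != want)[1]], " at line ", which(lens != want)[1])
  ped <- matrix(unlist(ped), nrow = n_samp, byrow = TRUE)

  sample_ids <- ped[, 2]
  pheno_code <- ped[, 6]
  if (!all(pheno_code %in% c("1", "2")))
    stop("PED phenotype must be 1 (control) or 2 (case)")
  phenotype <- ifelse(pheno_code == "2", "case", "control")

  al <- ped[, -(1:6), drop = FALSE]
  if (!all(al %in% c("A", "C", "G", "T", "0")))
    stop("allele codes must be in {A,C,G,T,0}")

  dosage <- matrix(NA_integer_, nrow = n_snp, ncol = n_samp)
  for (j in seq_len(n_snp)) {
    a1 <- al[, 2L * j - 1L]
    a2 <- al[, 2L * j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    if (length(obs) == 0L) next  # all missing: dosage stays NA
    tab <- sort(table(obs))
    alleles <- names(tab)
    if (length(alleles) > 2L)
      stop("SNP ", snp_ids[j], ": more than two alleles observed")
    if (length(alleles) == 2L && tab[1] == tab[2]) {
      minor <- sort(alleles)[1]
      message("SNP ", snp_ids[j], ": allele frequency tie, minor = ", minor)
    } else {
      minor <- alleles[1]
    }
    d <- (a1 == minor) + (a2 == minor)
    d[miss] <- NA_integer_
    dosage[j, ] <- d
  }

  genotype_study(snp_ids = snp_ids, chrom = map[, 1],
                 pos = as.numeric(map[, 4]), dosage = dosage,
                 sample_ids = sample_ids, phenotype = phenotype)
}

#' Write a genotype study as PLINK text PED/MAP
#'
#' Dosages are rendered with synthetic alleles A (major) and G (minor);
#' missing dosage becomes "0 0". Used mainly to materialize synthetic
#' studies on disk.
#'
#' @param study A [genotype_study()].
#' @param ped_path,map_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_plink_text <- function(study, ped_path, map_path) {
  stopifnot(inherits(study, "genotype_study"))
  map <- paste(study$chrom, study$snp_ids, 0, format(study$pos, scientific = FALSE, trim = TRUE),
               sep = "\t")
  writeLines(map, map_path)
  code <- c("A A", "A G", "G G")
  n_samp <- length(study$sample_ids)
  lines <- character(n_samp)
  for (i in seq_len(n_samp)) {
    d <- study$dosage[, i]
    calls <- ifelse(is.na(d), "0 0", code[d + 1L])
    ph <- if (study$phenotype[i] == "case") "2" else "1"
    lines[i] <- paste(c(paste0("F", i), study$sample_ids[i], "0", "0", "1",
                        ph, calls), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read gene models from a BED file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' package's 1-based inclusive convention (`start+1 .. end`). The name
#' column (4th) is required; strand is ignored.
#'
#' @param path Path to a BED4+ file.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), in file order.
#' @export
read_gene_bed <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 4L))
    stop("BED line ", which(lengths(f) < 4L)[1],
         ": gene name (column 4) is required")
  chrom <- vapply(f, `[`, character(1), 1)
  start0 <- as.numeric(vapply(f, `[`, character(1), 2))
  end0 <- as.numeric(vapply(f, `[`, character(1), 3))
  gene <- vapply(f, `[`, character(1), 4)
  if (any(is.na(start0)) || any(is.na(end0))) stop("non-numeric BED coordinates")
  if (any(end0 <= start0))
    stop("BED line ", which(end0 <= start0)[1],
         ": zero-length or inverted interval")
  if (anyDuplicated(gene))
    stop("duplicate gene id in BED: ", gene[duplicated(gene)][1])
  data.frame(gene = gene, chrom = chrom, start = start0 + 1, end = end0,
             stringsAsFactors = FALSE)
}

#' Write gene models to BED4
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive, as returned by [read_gene_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  writeLines(paste(genes$chrom,
                   format(genes$start - 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene, sep = "\t"), path)
  invisible(path)
}

#' Read an expression matrix plus phenotype file
#'
#' The matrix is TSV with a header row of sample ids and gene ids in the
#' first column. The phenotype file is two-column TSV (sample id, label in
#' {case, control}) with or without a header. Sample order follows the
#' matrix header.
#'
#' @param matrix_path Path to the gene x sample TSV.
#' @param phenotype_path Path to the sample phenotype TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, phenotype_path) {
  lines <- .read_lines(matrix_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty expression matrix")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- hdr[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(body) != length(hdr)))
    stop("expression matrix row ", which(lengths(body) != length(hdr))[1],
         " has the wrong number of fields")
  gene_ids <- vapply(body, `[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric expression value at row ", i + 1L, " (gene ",
           gene_ids[i], "), column ", j + 1L, " (sample ", sample_ids[j], ")")
    }
    vals[i, ] <- v
  }

  ph_lines <- .read_lines(phenotype_path)
  ph_lines <- ph_lines[nzchar(ph_lines)]
  ph <- do.call(rbind, strsplit(ph_lines, "[ \t]+"))
  if (ncol(ph) < 2L) stop("phenotype file needs 2 columns: sample, label")
  if (!ph[1, 2] %in% c("case", "control")) ph <- ph[-1, , drop = FALSE]  # header
  labels <- stats::setNames(ph[, 2], ph[, 1])
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("samples missing from phenotype file: ",
         paste(missing, collapse = ", "))
  expression_study(gene_ids, vals, sample_ids,
                   phenotype = unname(labels[sample_ids]))
}

#' Write an expression study to TSV (matrix + phenotype)
#'
#' @param study An [expression_study()].
#' @param matrix_path,phenotype_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_expression <- function(study, matrix_path, phenotype_path) {
  stopifnot(inherits(study, "expression_study"))
  hdr <- paste(c("gene", study$sample_ids), collapse = "\t")
  rows <- vapply(seq_along(study$gene_ids), function(i) {
    paste(c(study$gene_ids[i], format(study$values[i, ], digits = 15,
                                      scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), matrix_path)
  writeLines(c("sample\tphenotype",
               paste(study$sample_ids, study$phenotype, sep = "\t")),
             phenotype_path)
  invisible(c(matrix = matrix_path, phenotype = phenotype_path))
}

#' Write an enrichment/combined results table to TSV
#'
#' Columns are emitted in the canonical order (set, size, score, nes, p,
#' p_gwas, p_expr, chi2, p_combined, fdr, tier1, tier2), restricted to
#' those present. Rows are sorted by
#' ascending p, ties broken by set name; floats use `%.6g`; `NA`/`NaN`
#' serialize as "NA". Output bytes are deterministic for identical input.
#'
#' @param results data.frame carrying at least `set` and `p`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  canon <- c("set", "size", "score", "nes", "p", "p_gwas", "p_expr", "chi2",
             "p_combined", "fdr", "tier1", "tier2")
  keep <- intersect(canon, names(results))
  if (!"set" %in% keep) stop("results must carry a 'set' column")
  pcol <- if ("p" %in% keep) "p" else if ("p_combined" %in% keep) "p_combined" else NULL
  res <- results[, keep, drop = FALSE]
  if (nrow(res) && !is.null(pcol))
    res <- res[order(res[[pcol]], res$set), , drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.6g", x)
      out[!is.finite(x)] <- "NA"
      out[is.na(x)] <- "NA"
      out
    } else if (is.logical(x)) {
      ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
    } else as.character(x)
  }
  body <- if (nrow(res)) {
    cols <- lapply(res, fmt)
    do.call(paste, c(cols, sep = "\t"))
  } else character()
  con <- file(path, open = "wb")  # fixed \n regardless of OS
  on.exit(close(con))
  writeLines(c(paste(keep, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}
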