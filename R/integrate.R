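# Cross-platform integration: Fisher's combined probability test over the
# pathways eligible on both platforms, BH FDR, the two-tier significance
# calls, and Venn-style overlap summaries across methods.

#' Fisher's combined probability test
#'
#' chi2 = -2 * sum(ln p_i), referred to the chi-square distribution with
#' 2k degrees of freedom (valid for independent tests of the same
#' hypothesis).
#'
#' @param p_values Numeric vector of k P-values, each in (0, 1].
#' @return List: `chi2`, `p_combined`, `df`.
#' @export
fisher_combine <- function(p_values) {
  k <- length(p_values)
  stopifnot(k >= 1)
  if (any(is.na(p_values)) || any(p_values > 1) || any(p_values < 0))
    stop("p-values must lie in (0, 1]")
  if (any(p_values == 0))
    stop("p = 0 cannot be combined; clamp empirical P-values at 1/(B+1) ",
         "(the (b+1)/(B+1) convention guarantees this upstream)")
  chi2 <- -2 * sum(log(p_values))
  list(chi2 = chi2,
       p_combined = stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE),
       df = 2L * k)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-stable
#' (adjusted values are returned in the input order). Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted P-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Two-tier significance calls
#'
#' Tier 1 is the loose nominal call (P < `p_cut`, default 0.01); tier 2 the
#' FDR call (FDR < `fdr_cut`, default 0.2). Both inequalities are strict,
#' so boundary values are not flagged.
#'
#' @param results data.frame carrying `p` and `fdr` (any enrichment or
#'   combined table).
#' @param p_cut Nominal P cutoff.
#' @param fdr_cut FDR cutoff.
#' @return `results` with logical columns `tier1`, `tier2` appended.
#' @export
tier_select <- function(results, p_cut = 0.01, fdr_cut = 0.2) {
  stopifnot(all(c("p", "fdr") %in% names(results)))
  results$tier1 <- results$p < p_cut
  results$tier2 <- results$fdr < fdr_cut
  results
}

#' Combine GWAS and expression pathway results with Fisher's method
#'
#' Restricted to the pathways present in both tables ("eligible for both
#' platforms"). Per pathway, the two nominal P-values are combined
#' (chi-square with 4 df); BH FDR is computed over the intersection; tier
#' flags use [tier_select()] cutoffs.
#'
#' @param gwas,expr data.frames carrying `set` and `p` (one row per set).
#' @param p_cut,fdr_cut Tier cutoffs passed to [tier_select()].
#' @return data.frame sorted by ascending combined P: `set`, `p_gwas`,
#'   `p_expr`, `chi2`, `p_combined`, `fdr`, `tier1`, `tier2`. The counts of
#'   sets excluded from each platform are attached as attribute
#'   `n_excluded`.
#' @export
combine_platforms <- function(gwas, expr, p_cut = 0.01, fdr_cut = 0.2) {
  stopifnot(all(c("set", "p") %in% names(gwas)),
            all(c("set", "p") %in% names(expr)))
  common <- intersect(gwas$set, expr$set)
  if (length(common) == 0L) stop("no pathway is present on both platforms")
  common <- sort(common)  # input-order invariance
  pg <- gwas$p[match(common, gwas$set)]
  pe <- expr$p[match(common, expr$set)]
  comb <- lapply(seq_along(common), function(i) fisher_combine(c(pg[i], pe[i])))
  out <- data.frame(set = common, p_gwas = pg, p_expr = pe,
                    chi2 = vapply(comb, `[[`, numeric(1), "chi2"),
                    p_combined = vapply(comb, `[[`, numeric(1), "p_combined"),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_combined)
  out$tier1 <- out$p_combined < p_cut
  out$tier2 <- out$fdr < fdr_cut
  out <- out[order(out$p_combined, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- c(gwas = nrow(gwas) - length(common),
                               expr = nrow(expr) - length(common))
  out
}

#' Venn-style overlap of significant pathway lists
#'
#' Given 2-4 named character vectors of significant pathways (typically the
#' union of tier-1 and tier-2 calls per method), counts every region of the
#' Venn partition and the number of pathways shared by at least m methods.
#'
#' @param lists Named list of 2-4 character vectors.
#' @return List: `regions` (data.frame `region`, `count`; region labels
#'   like "A&B" for "in A and B and nothing else") and `shared`
#'   (data.frame `m`, `count` of pathways in >= m lists).
#' @export
overlap_summary <- function(lists) {
  k <- length(lists)
  if (k < 2L || k > 4L) stop("overlap_summary takes 2 to 4 result lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists, use.names = FALSE))
  member <- vapply(lists, function(x) universe %in% x, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(lists)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  regions <- data.frame(
    region = apply(combos, 1, function(r) paste(names(lists)[as.logical(r)],
                                                collapse = "&")),
    count = apply(combos, 1, function(r) {
      if (length(universe) == 0L) return(0L)
      sum(apply(member, 1, function(row) all(row == as.logical(r))))
    }),
    stringsAsFactors = FALSE
  )
  rownames(regions) <- NULL
  n_in <- if (length(universe)) rowSums(member) else integer(0)
  shared <- data.frame(m = seq_len(k),
                       count = vapply(seq_len(k), function(m) sum(n_in >= m),
                                      integer(1)))
  list(regions = regions, shared = shared)
}
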