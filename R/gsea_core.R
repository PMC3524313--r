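# Shared machinery: permutation plans, the empirical P-value convention,
# and the weighted Kolmogorov-Smirnov enrichment score with its
# normalization and permutation-based FDR. Both the GWAS and the expression
# arm run through .gsea_table().

#' Describe a permutation scheme
#'
#' @param n_perm Number of permutations / resampling replicates. Defaults in
#'   the pipeline: 1000 phenotype swaps; 10,000 SNP resamples for the
#'   resampling test.
#' @param seed Integer RNG seed; every permutation-based function derives
#'   its random stream from this alone, so identical plans give
#'   byte-identical results.
#' @param scheme `"phenotype-swap"` (case/control labels permuted) or
#'   `"snp-resample"` (SNPs drawn without replacement).
#' @return A list of class `permutation_plan`.
#' @export
permutation_plan <- function(n_perm = 1000, seed = 1,
                             scheme = c("phenotype-swap", "snp-resample")) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1, is.finite(seed))
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scheme = scheme),
            class = "permutation_plan")
}

# Case-indicator permutation matrix: samples x B, each column an
# independent uniform shuffle of the observed 0/1 case labels.
# Recipe (stable across versions of this package): set.seed(seed), then
# column b = sample(indicator) for b = 1..B.
.perm_case_matrix <- function(phenotype, n_perm, seed) {
  ci <- as.numeric(phenotype == "case")
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) sample(ci), numeric(length(ci)))
}

#' Empirical P-value of an observed statistic
#'
#' Uses the (b + 1) / (B + 1) convention: the observed value counts as one
#' of its own permutations, so P is never zero and downstream Fisher
#' combination stays finite.
#'
#' @param observed Scalar observed statistic.
#' @param permuted Numeric vector of permutation statistics.
#' @param direction `"ge"` if large values are extreme, `"le"` otherwise.
#' @return Empirical P in `[1/(B+1), 1]`.
#' @export
empirical_pvalue <- function(observed, permuted, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(length(permuted) >= 1)
  hits <- if (direction == "ge") sum(permuted >= observed)
          else sum(permuted <= observed)
  (1 + hits) / (length(permuted) + 1)
}

#' Weighted KS enrichment score
#'
#' Walks the ranked gene list: at a member gene the running sum rises by
#' `|stat|^w / sum(|stat|^w over members)`, at a non-member it falls by
#' `1/(N - N_members)`. The enrichment score is the running-sum value of
#' maximum absolute departure from zero (signed). With `weight_exponent =
#' 0` this is the classic (equal-weight) KS statistic. If all member
#' weights are zero (possible with `w > 0` and all-zero statistics) the
#' walk falls back to equal member increments.
#'
#' @param ranked_stats Numeric vector of gene statistics sorted descending.
#' @param membership Logical vector: is the gene at this rank a set member?
#' @param weight_exponent Non-negative weight exponent (default 1).
#' @return List: `es`, `peak` (index of the extreme), `running` (full
#'   running sum).
#' @export
enrichment_score <- function(ranked_stats, membership, weight_exponent = 1) {
  n <- length(ranked_stats)
  stopifnot(length(membership) == n, n >= 1)
  if (is.unsorted(rev(ranked_stats)) && is.unsorted(-ranked_stats))
    stop("ranked_stats must be sorted in descending order")
  membership <- as.logical(membership)
  m <- sum(membership)
  if (m == 0L) stop("no set members present in the ranking")
  if (m == n) {  # every gene a member: sum of increments is 1, peak at end
    w <- abs(ranked_stats)^weight_exponent
    if (sum(w) == 0) w <- rep(1, n)
    running <- cumsum(w / sum(w))
    return(list(es = 1, peak = n, running = running))
  }
  w <- abs(ranked_stats)^weight_exponent
  nr <- sum(w[membership])
  inc <- if (nr > 0) w / nr else rep(1 / m, n)
  step <- ifelse(membership, inc, -1 / (n - m))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

# Sparse-walk ES: identical result to enrichment_score() but O(m log m)
# given the ranks of the member genes. Candidate extrema occur only at a
# member position or immediately before one (the walk is piecewise linear,
# decreasing between members and ending at zero).
.es_sparse <- function(n, ranks, w_hit) {
  m <- length(ranks)
  if (m == n) return(1)
  nr <- sum(w_hit)
  hit_inc <- if (nr > 0) w_hit / nr else rep(1 / m, m)
  miss <- 1 / (n - m)
  H <- cumsum(hit_inc)
  j <- seq_len(m)
  at_hit <- H - (ranks - j) * miss             # value at each member rank
  before <- c(0, H[-m]) - (ranks - j) * miss   # value just before each member
  cand <- c(at_hit, before)
  cand[which.max(abs(cand))]
}

# GSEA over a statistic matrix. stat_obs: named numeric vector (genes);
# stat_perm: genes x B matrix, same row order; sets: named list of gene id
# vectors (assumed subset of names(stat_obs)). Ranking ties are broken by
# gene id for determinism. Returns the standard result table.
.gsea_table <- function(stat_obs, stat_perm, sets, weight_exponent = 1,
                        fdr_method = c("pooled", "BH")) {
  fdr_method <- match.arg(fdr_method)
  genes <- names(stat_obs)
  n <- length(genes)
  set_idx <- lapply(sets, function(g) {
    i <- match(g, genes)
    i[!is.na(i)]
  })
  if (any(lengths(set_idx) == 0L))
    stop("set(s) with no genes in the ranking: ",
         paste(names(sets)[lengths(set_idx) == 0L], collapse = ", "))
  B <- ncol(stat_perm)
  n_sets <- length(sets)

  es_for_column <- function(stat) {
    ord <- order(-stat, genes)          # descending, id-stable ties
    pos <- integer(n); pos[ord] <- seq_len(n)
    s_sorted <- stat[ord]
    w_sorted <- abs(s_sorted)^weight_exponent
    vapply(set_idx, function(idx) {
      r <- sort.int(pos[idx])
      .es_sparse(n, r, w_sorted[r])
    }, numeric(1))
  }

  es_obs <- es_for_column(stat_obs)
  es_perm <- matrix(0, nrow = n_sets, ncol = B)
  for (b in seq_len(B)) es_perm[, b] <- es_for_column(stat_perm[, b])

  p_emp <- numeric(n_sets)
  nes_obs <- numeric(n_sets)
  nes_perm <- matrix(NA_real_, nrow = n_sets, ncol = B)
  for (i in seq_len(n_sets)) {
    perm <- es_perm[i, ]
    # nominal P against the same-signed portion of the permutation null
    # (the convention of the original GSEA): keeps P uniform under a
    # symmetric ES null instead of folding both tails into one count
    if (es_obs[i] >= 0) {
      pool <- perm[perm >= 0]
      p_emp[i] <- (1 + sum(pool >= es_obs[i])) / (length(pool) + 1)
    } else {
      pool <- perm[perm < 0]
      p_emp[i] <- (1 + sum(pool <= es_obs[i])) / (length(pool) + 1)
    }
    mp <- mean(perm[perm >= 0])
    mn <- mean(perm[perm < 0])
    nes_obs[i] <- if (es_obs[i] >= 0) {
      if (is.nan(mp) || mp == 0) NA_real_ else es_obs[i] / mp
    } else {
      if (is.nan(mn)) NA_real_ else -es_obs[i] / mn
    }
    pos <- perm >= 0
    nes_perm[i, pos] <- if (is.nan(mp) || mp == 0) NA else perm[pos] / mp
    nes_perm[i, !pos] <- if (is.nan(mn)) NA else -perm[!pos] / mn
  }

  fdr <- if (fdr_method == "BH") {
    stats::p.adjust(p_emp, method = "BH")
  } else {
    .gsea_pooled_fdr(nes_obs, nes_perm)
  }

  data.frame(set = names(sets), size = lengths(set_idx), score = es_obs,
             nes = nes_obs, p = p_emp, fdr = fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Pooled-NES FDR (the scheme of the original expression GSEA): for a set
# with NES* >= 0, the FDR estimate is the fraction of pooled permuted NES
# values >= NES* among non-negative ones, divided by the fraction of
# observed NES >= NES* among non-negative observed NES; mirrored for
# negative NES. Clamped to [0, 1].
.gsea_pooled_fdr <- function(nes_obs, nes_perm) {
  pool <- as.vector(nes_perm)
  pool <- pool[!is.na(pool)]
  vapply(seq_along(nes_obs), function(i) {
    x <- nes_obs[i]
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      pp <- pool[pool >= 0]
      oo <- nes_obs[!is.na(nes_obs) & nes_obs >= 0]
      num <- if (length(pp)) mean(pp >= x) else 0
      den <- mean(oo >= x)
    } else {
      pp <- pool[pool < 0]
      oo <- nes_obs[!is.na(nes_obs) & nes_obs < 0]
      num <- if (length(pp)) mean(pp <= x) else 0
      den <- mean(oo <= x)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
}
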