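enrichment_result <- function(observed, null_values, p_value, estimator_tag, seed) {
  structure(list(observed = observed,
                 null_mean = mean(null_values),
                 null_sd = stats::sd(null_values),
                 n_draws = length(null_values),
                 p_value = p_value,
                 estimator_tag = estimator_tag,
                 seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult (%s): observed = %.4g, null %.4g +/- %.4g (%d draws), p = %.4g\n",
              x$estimator_tag, x$observed, x$null_mean, x$null_sd,
              x$n_draws, x$p_value))
  invisible(x)
}

#' Permutation test of a group's mean projected pattern value
#'
#' Tests whether the cells (or samples) of one group carry higher projected
#' pattern values than expected by chance: the observed statistic is the
#' target group's mean, the null is the distribution of that group-size mean
#' under label permutations that preserve all group sizes, and the p-value
#' uses the add-one estimator `(r + 1) / (n_perm + 1)`, which can never
#' reach zero.
#'
#' @param values numeric vector of projected pattern values, one per cell.
#' @param labels group (cell-type) label per cell.
#' @param target_group the group to test.
#' @param n_perm number of permutations (>= 99; use >= 99999 to resolve
#'   p-values near 1e-5).
#' @param seed integer seed.
#' @param alternative `"greater"` (default; enrichment of high values),
#'   `"less"`, or `"two.sided"`.
#' @return an `EnrichmentResult`.
#' @export
group_mean_permutation_test <- function(values, labels, target_group,
                                        n_perm = 9999L, seed = 1L,
                                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(values) != length(labels)) stop("values and labels differ in length")
  n_t <- sum(labels == target_group)
  if (n_t == 0L) stop("target group '", target_group, "' has no members")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  observed <- mean(values[labels == target_group])
  set.seed(seed)
  n <- length(values)
  null <- vapply(seq_len(n_perm),
                 function(i) mean(values[sample.int(n, n_t)]), numeric(1))
  p_hi <- (sum(null >= observed) + 1) / (n_perm + 1)
  p_lo <- (sum(null <= observed) + 1) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_hi, less = p_lo,
              two.sided = min(1, 2 * min(p_hi, p_lo)))
  enrichment_result(observed, null, p, paste0("group_mean_permutation_", alternative),
                    seed)
}

#' Cumulative rank of a gene set within an amplitude ranking
#'
#' Sums the ranks of the set's genes in a [rank_genes_by_amplitude()]
#' ordering. A low sum means the set concentrates at the top of the pattern.
#' Genes absent from the ranking are reported by name and excluded from the
#' statistic.
#'
#' @param ranked data.frame with columns `gene` and `rank`.
#' @param set character vector of gene IDs.
#' @param set_name label used in error messages.
#' @return list with `sum_rank`, `ranks` (named, present genes), `absent`,
#'   `n_present`.
#' @export
cumulative_rank_statistic <- function(ranked, set, set_name = "gene set") {
  set <- unique(set)
  idx <- match(set, ranked$gene)
  present <- !is.na(idx)
  if (!any(present))
    stop("no gene of '", set_name, "' is present in the ranking")
  ranks <- stats::setNames(ranked$rank[idx[present]], set[present])
  list(sum_rank = sum(ranks), ranks = ranks, absent = set[!present],
       n_present = sum(present))
}

#' Background model of summed gene-set ranks
#'
#' Monte-Carlo null for [cumulative_rank_statistic()]: each iteration draws
#' `set_size` distinct ranks uniformly from `1..n_genes` (without
#' replacement within a draw), repeated for each of `n_patterns` patterns.
#' Defaults (20 ranks, 10,000 iterations, 30 patterns) are the background
#' configuration used for the neutrophil signature analyses.
#'
#' @param n_genes size of the ranking.
#' @param set_size ranks per draw.
#' @param iterations Monte-Carlo iterations per pattern.
#' @param n_patterns number of patterns the background covers.
#' @param seed integer seed.
#' @return list with `sums` (all `iterations * n_patterns` draw sums),
#'   `mean_sum`, and `mean_rank` (grand mean of individual sampled ranks,
#'   the "mean background signature rank").
#' @export
background_rank_model <- function(n_genes, set_size = 20L, iterations = 10000L,
                                  n_patterns = 30L, seed = 1L) {
  if (set_size > n_genes)
    stop("set_size (", set_size, ") exceeds n_genes (", n_genes, ")")
  if (set_size < 1L) stop("set_size must be positive")
  set.seed(seed)
  n_draws <- iterations * n_patterns
  sums <- vapply(seq_len(n_draws),
                 function(i) sum(sample.int(n_genes, set_size)), numeric(1))
  list(sums = sums, mean_sum = mean(sums), mean_rank = mean(sums) / set_size)
}

#' Exact two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with a two-sided p-value, computed exactly
#' when `n * m <= 10000` and asymptotically (with a tag) otherwise.
#'
#' @param x,y numeric samples (non-empty, no NA/NaN).
#' @return list with `D`, `p`, and `method_tag` (`"exact"` or
#'   `"asymptotic"`).
#' @export
ks_exact_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA/NaN")
  exact <- length(x) * length(y) <= 10000
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       method_tag = if (exact) "exact" else "asymptotic")
}

#' Mean-rank permutation test of a gene set
#'
#' Ranks all genes by a per-gene statistic (rank 1 = largest; ties get
#' average ranks), takes the mean rank of the set's genes as the observed
#' statistic, and compares it with mean ranks of random same-size gene
#' draws. The two-sided p doubles the smaller add-one tail estimate.
#'
#' @param statistic named numeric vector, one value per gene (e.g. a pattern
#'   amplitude column).
#' @param set character vector of gene IDs (>= 2 present in `statistic`).
#' @param n_perm random draws.
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"less"` (enriched at the
#'   top, i.e. small mean rank), or `"greater"`.
#' @return an `EnrichmentResult` (observed = mean rank of the set).
#' @export
gene_set_rank_test <- function(statistic, set, n_perm = 9999L, seed = 1L,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(names(statistic))) stop("statistic must be named by gene")
  ranks <- rank(-statistic, ties.method = "average")
  present <- intersect(unique(set), names(statistic))
  if (length(present) < 2L)
    stop("fewer than 2 set genes present in the statistic")
  observed <- mean(ranks[present])
  set.seed(seed)
  G <- length(ranks); m <- length(present)
  null <- vapply(seq_len(n_perm),
                 function(i) mean(ranks[sample.int(G, m)]), numeric(1))
  p_lo <- (sum(null <= observed) + 1) / (n_perm + 1)
  p_hi <- (sum(null >= observed) + 1) / (n_perm + 1)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_lo, p_hi)),
              less = p_lo, greater = p_hi)
  enrichment_result(observed, null, p, paste0("mean_rank_permutation_", alternative),
                    seed)
}
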