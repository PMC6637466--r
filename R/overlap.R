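#' Two-sided exact binomial sign test
#'
#' Exact two-sided binomial test of `k` successes in `n` trials at success
#' probability one half: the p-value sums the probabilities of all outcomes no
#' more likely than the observed one.
#'
#' @param k number of concordant pairs.
#' @param n number of pairs tested.
#' @return the two-sided p-value.
#' @export
binomial_sign_test <- function(k, n) {
  if (n < 1L) stop("binomial_sign_test: n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("binomial_sign_test: k must lie in [0, n]", call. = FALSE)
  stats::binom.test(k, n, p = 0.5)$p.value
}

#' Effect-direction concordance between two MWAS tables
#'
#' Selects CpGs below the discovery-table p-value threshold that are also
#' present in the testing table, counts pairs whose effects share a sign, and
#' tests the count against chance with the exact binomial sign test. CpGs with
#' an exactly zero effect in either table carry no direction and are excluded
#' (their count is reported).
#'
#' @param discovery,testing MWAS result data.frames (`cpg`, `effect`, `p`).
#' @param threshold discovery selection threshold (default `1e-4`).
#' @return list of class `concordance_result`: `discovery_threshold`,
#'   `n_total`, `n_concordant`, `n_zero_excluded`, `p` (NA with
#'   `flagged = TRUE` when no testable pairs remain).
#' @export
sign_concordance <- function(discovery, testing, threshold = 1e-4) {
  sel <- discovery[discovery$p < threshold, c("cpg", "effect")]
  shared <- merge(sel, testing[, c("cpg", "effect")], by = "cpg",
                  suffixes = c("_d", "_t"))
  zero <- shared$effect_d == 0 | shared$effect_t == 0
  n_zero <- sum(zero)
  shared <- shared[!zero, , drop = FALSE]
  n_total <- nrow(shared)
  n_conc <- sum(sign(shared$effect_d) == sign(shared$effect_t))
  res <- list(discovery_threshold = threshold, n_total = n_total,
              n_concordant = n_conc, n_zero_excluded = n_zero,
              p = if (n_total > 0L) binomial_sign_test(n_conc, n_total) else NA_real_,
              flagged = n_total == 0L)
  class(res) <- "concordance_result"
  res
}

#' One-sided rank-sum shift test between two MWAS tables
#'
#' Tests whether CpGs nominally significant in a discovery table are shifted
#' toward lower p-values in a testing table: selected = shared CpGs with
#' discovery p below `selection_threshold`; their testing-table p-values are
#' compared with those of all other shared CpGs by a one-sided Wilcoxon
#' rank-sum test (alternative: selected p-values are stochastically smaller).
#' The exact null distribution is enumerated when both groups have at most 10
#' untied values; otherwise the normal approximation with tie and continuity
#' corrections is used.
#'
#' @param discovery,testing MWAS result data.frames (`cpg`, `p`).
#' @param selection_threshold discovery threshold (default `0.01`).
#' @return list of class `shift_result`: `selection_threshold`, `n_selected`,
#'   `n_rest`, `w_statistic`, `p_one_sided`, `flagged`.
#' @export
pvalue_shift_test <- function(discovery, testing, selection_threshold = 0.01) {
  shared <- merge(discovery[, c("cpg", "p")], testing[, c("cpg", "p")],
                  by = "cpg", suffixes = c("_d", "_t"))
  sel <- shared$p_d < selection_threshold
  x <- shared$p_t[sel]
  y <- shared$p_t[!sel]
  if (length(x) == 0L || length(y) == 0L) {
    res <- list(selection_threshold = selection_threshold,
                n_selected = length(x), n_rest = length(y),
                w_statistic = NA_real_, p_one_sided = NA_real_, flagged = TRUE)
    class(res) <- "shift_result"
    return(res)
  }
  res <- rank_sum_shift(x, y, selection_threshold)
  class(res) <- "shift_result"
  res
}

# shared core: one-sided Wilcoxon that x is stochastically smaller than y
rank_sum_shift <- function(x, y, selection_threshold) {
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= 10L && length(y) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = use_exact,
                       correct = TRUE)
  )
  list(selection_threshold = selection_threshold,
       n_selected = length(x), n_rest = length(y),
       w_statistic = unname(wt$statistic), p_one_sided = wt$p.value,
       flagged = FALSE)
}

#' Z-score correlation between two MWAS tables
#'
#' Pearson correlation of z-scores over shared CpGs, optionally restricted to
#' CpGs below a p-value threshold in table a or table b.
#'
#' @param res_a,res_b MWAS result data.frames (`cpg`, `z`, `p`).
#' @param restrict_threshold optional p-value threshold for restriction.
#' @param restrict_side which table's p-values drive the restriction:
#'   `"none"`, `"a"` or `"b"`.
#' @return list with `r`, `ci`, `p`, `n` (from [stats::cor.test()]).
#' @export
zscore_correlation <- function(res_a, res_b, restrict_threshold = NULL,
                               restrict_side = c("none", "a", "b")) {
  restrict_side <- match.arg(restrict_side)
  shared <- merge(res_a[, c("cpg", "z", "p")], res_b[, c("cpg", "z", "p")],
                  by = "cpg", suffixes = c("_a", "_b"))
  if (!is.null(restrict_threshold) && restrict_side != "none") {
    keep <- if (restrict_side == "a") shared$p_a < restrict_threshold
            else shared$p_b < restrict_threshold
    shared <- shared[keep, , drop = FALSE]
  }
  if (nrow(shared) < 3L) {
    stop("zscore_correlation: fewer than 3 shared CpGs after restriction",
         call. = FALSE)
  }
  ct <- stats::cor.test(shared$z_a, shared$z_b)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), p = ct$p.value,
       n = nrow(shared))
}
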