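# The group-segregation statistic: significant-sequence counts over every
# balanced bipartition of the samples, the expected count under uniform
# allocation, and the exact binomial point probability of the case count.
#
# For six samples there are C(6,3)/2 = 10 unordered balanced bipartitions;
# under a uniform allocation each significant event lands on any one
# bipartition with probability 1/10. All probability arithmetic is done in
# log space: the observed probabilities sit around 1e-43, far below where
# naive products are safe.

#' Enumerate balanced bipartitions
#'
#' All unordered splits of `2m` sample ids into two groups of `m`. The
#' canonical form places the side containing the smallest id first, which
#' halves the `C(2m, m)` ordered splits to `C(2m, m) / 2` and removes
#' duplicates.
#'
#' @param sample_ids Character (or atomic) vector of even length.
#' @return List of bipartitions, each a list with `side_a` and `side_b`.
#' @examples
#' length(enumerate_bipartitions(paste0("S", 1:6)))  # 10
#' @export
enumerate_bipartitions <- function(sample_ids) {
  n <- length(sample_ids)
  if (n < 2L || n %% 2L != 0L)
    stop("`sample_ids` must have even length >= 2")
  if (anyDuplicated(sample_ids)) stop("`sample_ids` must be distinct")
  m <- n %/% 2L
  anchor <- sample_ids[1L]
  rest <- sample_ids[-1L]
  combos <- utils::combn(rest, m - 1L, simplify = FALSE)
  lapply(combos, function(co) {
    side_a <- c(anchor, co)
    list(side_a = side_a, side_b = setdiff(sample_ids, side_a))
  })
}

#' Significant-sequence counts per bipartition
#'
#' For each balanced bipartition of the samples, the number of comparing
#' sequences whose frequencies differ significantly (two-tailed
#' pooled-variance t-test, `p < alpha`) between the two sides. A sequence
#' may count toward several bipartitions.
#'
#' @param table Species-by-sample frequency matrix from
#'   [species_frequency_table()] (columns named by sample id).
#' @param bipartitions List from [enumerate_bipartitions()]; default:
#'   enumerated from the table's columns.
#' @param alpha Significance level (default 0.05).
#' @return Integer vector of counts, one per bipartition, named
#'   `"id1+id2+id3"` by each bipartition's `side_a`.
#' @export
count_significant_per_bipartition <- function(table, bipartitions = NULL,
                                              alpha = 0.05) {
  ids <- colnames(table)
  if (is.null(bipartitions)) bipartitions <- enumerate_bipartitions(ids)
  vapply(bipartitions, function(bp) {
    ia <- match(bp$side_a, ids); ib <- match(bp$side_b, ids)
    if (anyNA(ia) || anyNA(ib)) stop("bipartition ids missing from `table`")
    sum(.t_test_rows(table, ia, ib)$p < alpha)
  }, integer(1),
  USE.NAMES = FALSE) -> counts
  names(counts) <- vapply(bipartitions,
                          function(bp) paste(bp$side_a, collapse = "+"), "")
  counts
}

#' Expected significant count under uniform allocation
#'
#' With `S_case` significant sequences on the case bipartition and
#' `S_other` summed over the remaining bipartitions, the expected count on
#' any one of the `B` bipartitions under a uniform allocation is
#' `(S_case + S_other) / B`.
#'
#' @param s_case,s_other Nonnegative counts.
#' @param B Number of balanced bipartitions (10 for six samples).
#' @return The expected count (real).
#' @examples
#' expected_count(79, 54)    # 13.3
#' expected_count(109, 141)  # 25.0
#' @export
expected_count <- function(s_case, s_other, B = 10L) {
  if (B <= 0) stop("`B` must be positive")
  if (s_case < 0 || s_other < 0) stop("counts must be nonnegative")
  (s_case + s_other) / B
}

#' Exact binomial point probability
#'
#' The probability mass `C(n, k) p^k (1 - p)^(n - k)` computed in log
#' space via log-gamma, so values far below double underflow thresholds
#' in intermediate products (e.g. 1e-43) are exact to full double
#' precision.
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @param log If `TRUE`, return the log probability.
#' @return The point probability (or its log).
#' @examples
#' binomial_point_probability(1, 2, 0.5)      # 0.5
#' binomial_point_probability(109, 250, 0.1)  # ~4.2e-43
#' @export
binomial_point_probability <- function(k, n, p, log = FALSE) {
  if (any(k < 0 | k > n)) stop("`k` must lie in [0, n]")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  lp <- lchoose(n, k) +
    ifelse(k == 0, 0, k * base::log(p)) +
    ifelse(k == n, 0, (n - k) * log1p(-p))
  if (log) lp else exp(lp)
}

#' Group-segregation test over balanced bipartitions
#'
#' Assembles the full segregation statistic for a case grouping: the
#' significant-sequence count for every balanced bipartition, the total
#' `n = S_case + S_other`, the expected per-bipartition count `E = n / B`,
#' the exact binomial point probability of the case count at
#' `p = 1 / B`, and -- as a labelled alternative -- the upper-tail
#' probability `P(X >= S_case)`. The case bipartition's rank among all
#' counts is reported (rank 1 = largest count).
#'
#' @param table Species-by-sample frequency matrix from
#'   [species_frequency_table()].
#' @param case_bipartition List with `side_a`, `side_b` (the case split);
#'   must be one of the enumerated balanced bipartitions.
#' @param alpha Significance level for the per-bipartition t-tests.
#' @return Object of class `segregation_test`: per-bipartition counts,
#'   `s_case`, `s_other`, `n`, `B`, `expected`, `p_point`,
#'   `p_upper_tail`, `case_rank`.
#' @export
segregation_test <- function(table, case_bipartition, alpha = 0.05) {
  ids <- colnames(table)
  bps <- enumerate_bipartitions(ids)
  keys <- vapply(bps, function(bp)
    paste(sort(c(paste(sort(bp$side_a), collapse = "+"),
                 paste(sort(bp$side_b), collapse = "+"))), collapse = "|"), "")
  case_key <- paste(sort(c(paste(sort(case_bipartition$side_a), collapse = "+"),
                           paste(sort(case_bipartition$side_b), collapse = "+"))),
                    collapse = "|")
  ci <- match(case_key, keys)
  if (is.na(ci)) stop("`case_bipartition` is not a balanced bipartition of the samples")
  counts <- count_significant_per_bipartition(table, bps, alpha)
  s_case <- counts[[ci]]
  n <- sum(counts)
  B <- length(bps)
  res <- list(
    counts = counts, case_index = ci,
    s_case = s_case, s_other = n - s_case, n = n, B = B,
    expected = expected_count(s_case, n - s_case, B),
    p_alloc = 1 / B,
    p_point = binomial_point_probability(s_case, n, 1 / B),
    p_upper_tail = if (n == 0) 1 else
      pbinom(s_case - 1L, n, 1 / B, lower.tail = FALSE),
    case_rank = as.integer(rank(-counts, ties.method = "min")[ci]),
    alpha = alpha)
  class(res) <- "segregation_test"
  res
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("<segregation_test>\n")
  cat(sprintf("  bipartitions: %d   significant events: %d\n", x$B, x$n))
  cat(sprintf("  case count S_case = %d (rank %d of %d), others sum to %d\n",
              x$s_case, x$case_rank, x$B, x$s_other))
  cat(sprintf("  expected per bipartition E = %.4g\n", x$expected))
  cat(sprintf("  binomial point probability P = %.3g (upper tail %.3g)\n",
              x$p_point, x$p_upper_tail))
  invisible(x)
}

#' @export
summary.segregation_test <- function(object, ...) {
  data.frame(bipartition = names(object$counts),
             count = as.integer(object$counts),
             is_case = seq_along(object$counts) == object$case_index,
             row.names = NULL)
}
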