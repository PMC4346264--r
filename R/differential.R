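# Per-length top-N comparing-sequence construction and the two-sample
# pooled-variance (Student) t-test on species frequencies.

#' Top-N species per length stratum
#'
#' For each insert length in the window, the `N` sequences with the
#' highest read counts in the sample. Ties at the rank-N boundary are
#' broken lexicographically so the result is deterministic; strata with
#' fewer than `N` species return all of them.
#'
#' @param sample A [sample_library()].
#' @param N Number of species per length (>= 1).
#' @param lo,hi Analysis window (defaults 5 and 40 nt).
#' @return Data frame with columns `length`, `sequence`, `count`, `rank`,
#'   and a logical attribute `"tie_at_boundary"` marking strata where the
#'   cut fell inside a tie.
#' @examples
#' s <- sample_library("S1", c(AAAAA = 5L, CCCCC = 5L, GGGGG = 3L))
#' top_n_species(s, N = 1)
#' @export
top_n_species <- function(sample, N = 5L, lo = 5L, hi = 40L) {
  stopifnot(inherits(sample, "sample_library"), N >= 1L)
  seqs <- names(sample$counts)
  lens <- nchar(seqs)
  in_win <- lens >= lo & lens <= hi
  seqs <- seqs[in_win]; cnts <- sample$counts[in_win]; lens <- lens[in_win]
  res <- list(); ties <- logical(0)
  for (L in sort(unique(lens))) {
    sel <- lens == L
    s <- seqs[sel]; k <- cnts[sel]
    o <- order(-k, s)
    take <- min(N, length(s))
    # tie at the boundary: the first excluded count equals the last included
    ties[as.character(L)] <- length(s) > take && k[o][take + 1L] == k[o][take]
    res[[as.character(L)]] <- data.frame(
      length = L, sequence = s[o][seq_len(take)],
      count = as.integer(k[o][seq_len(take)]), rank = seq_len(take),
      row.names = NULL)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(length = integer(0), sequence = character(0),
               count = integer(0), rank = integer(0))
  rownames(out) <- NULL
  structure(out, tie_at_boundary = ties)
}

#' Comparing-sequence set across samples
#'
#' The de-duplicated union, over all samples and lengths, of each sample's
#' per-length top-N species -- the sequence set every group comparison is
#' run on. Ordered by length, then sequence.
#'
#' @param samples List of [sample_library()] objects (>= 2).
#' @param N Top-N per length per sample (5 for plasma-style, 10 for
#'   PBMC-style analyses).
#' @param lo,hi Analysis window.
#' @return Character vector of unique sequences.
#' @export
comparing_set <- function(samples, N = 5L, lo = 5L, hi = 40L) {
  stopifnot(length(samples) >= 2L)
  seqs <- unique(unlist(lapply(samples, function(s)
    top_n_species(s, N, lo, hi)$sequence), use.names = FALSE))
  seqs[order(nchar(seqs), seqs)]
}

#' Two-sample pooled-variance Student t-test
#'
#' Equal-variance two-sample t with `df = n_a + n_b - 2` and a two-tailed
#' p-value. Degenerate inputs are handled explicitly: when the pooled
#' variance is zero and the means are equal, `t = 0, p = 1`; when the
#' pooled variance is zero but the means differ, the difference is exact,
#' so `p = 0` with `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, and `degenerate`.
#' @examples
#' t_test_pooled(c(1, 2, 3), c(4, 5, 6))
#' @export
t_test_pooled <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  df <- na + nb - 2L
  sp2 <- (sum((values_a - ma)^2) + sum((values_b - mb)^2)) / df
  if (sp2 == 0) {
    if (ma == mb) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

# Vectorised pooled t over the rows of a frequency matrix.
# Returns a data.frame with means, sds, t, p per row.
.t_test_rows <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  A <- mat[, idx_a, drop = FALSE]; B <- mat[, idx_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(sp2 > 0, (ma - mb) / se,
              ifelse(ma == mb, 0, sign(ma - mb) * Inf))
  p <- ifelse(sp2 > 0, 2 * pt(-abs(t), df), ifelse(ma == mb, 1, 0))
  data.frame(mean_a = ma, sd_a = sqrt(ssa / (na - 1L)),
             mean_b = mb, sd_b = sqrt(ssb / (nb - 1L)),
             t = t, df = df, p = p,
             degenerate = sp2 == 0 & ma != mb)
}

#' Differential species abundance between two groups
#'
#' Builds the comparing-sequence set (per-length top-N union across
#' samples), computes each sequence's same-length frequency in every
#' sample (absent sequences impute 0), and tests each sequence for a group
#' difference with the two-tailed pooled-variance Student t-test. No
#' multiple-testing correction is applied by default, matching the raw
#' `P < alpha` convention; Benjamini-Hochberg adjustment is available via
#' `p_adjust = "BH"`.
#'
#' @param samples List of [sample_library()] objects covering both groups.
#' @param grouping Named character vector, sample id -> group label (two
#'   levels). The `case_group` level defines the direction labels.
#' @param N Top-N per length per sample (default 5).
#' @param alpha Significance level (default 0.05).
#' @param case_group Label of the case group (default: the second sorted
#'   level, so `"B"` for an A/B grouping).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param lo,hi Analysis window.
#' @return Data frame of class `sgrna_comparison` with one row per
#'   comparing sequence: `sequence`, `length`, group means and standard
#'   deviations (`mean_ref`, `sd_ref`, `mean_case`, `sd_case`), `t`, `p`,
#'   `direction` (`"more"`/`"less"` abundant in the case group),
#'   `significant`.
#' @export
significant_species <- function(samples, grouping, N = 5L, alpha = 0.05,
                                case_group = NULL, p_adjust = c("none", "BH"),
                                lo = 5L, hi = 40L) {
  p_adjust <- match.arg(p_adjust)
  ids <- vapply(samples, `[[`, "", "sample_id")
  stopifnot(all(ids %in% names(grouping)))
  g <- grouping[ids]
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("`grouping` must have exactly two levels")
  if (is.null(case_group)) case_group <- lev[2L]
  stopifnot(case_group %in% lev)
  ref_group <- setdiff(lev, case_group)
  if (sum(g == case_group) < 2L || sum(g == ref_group) < 2L)
    stop("each group needs at least 2 samples")

  seqs <- comparing_set(samples, N, lo, hi)
  mat <- species_frequency_table(samples, seqs, lo, hi)
  tt <- .t_test_rows(mat, which(g == ref_group), which(g == case_group))
  p_use <- if (p_adjust == "BH") stats::p.adjust(tt$p, "BH") else tt$p
  out <- data.frame(
    sequence = seqs, length = nchar(seqs),
    mean_ref = tt$mean_a, sd_ref = tt$sd_a,
    mean_case = tt$mean_b, sd_case = tt$sd_b,
    t = tt$t, p = tt$p, p_adj = p_use,
    direction = ifelse(tt$mean_b >= tt$mean_a, "more", "less"),
    degenerate = tt$degenerate,
    significant = p_use < alpha,
    row.names = NULL)
  out$direction[tt$mean_b == tt$mean_a] <- NA_character_
  structure(out, alpha = alpha, N = N,
            case_group = case_group, ref_group = ref_group,
            class = c("sgrna_comparison", "data.frame"))
}

#' @export
print.sgrna_comparison <- function(x, ...) {
  cat(sprintf(paste0("<sgrna_comparison> %d comparing sequences, %d ",
                     "significant at alpha = %g (case group %s)\n"),
              nrow(x), sum(x$significant), attr(x, "alpha"),
              attr(x, "case_group")))
  print.data.frame(head(x[order(x$p), ], 10L), digits = 4)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
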