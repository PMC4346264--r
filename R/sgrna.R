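# Structural identification of potential tRNase Z(L) small guide RNAs and
# prediction of guided cleavage sites.
#
# The search is combinatorial pattern matching over Watson-Crick and G:U
# wobble pairs, not thermodynamic folding: every reported structure is a
# set of explicit base pairs that can be verified base by base.

# Allowed pair alphabet: Watson-Crick plus G:U wobble.
.pairs_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Reverse complement of an RNA sequence
#'
#' @param sequence RNA string over `{A,C,G,U}`.
#' @return The reverse complement (A<->U, G<->C), as an RNA string.
#' @examples
#' reverse_complement_rna("GGCUGGUCC")
#' @export
reverse_complement_rna <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) ||
      grepl("[^ACGU]", toupper(sequence)))
    stop("`sequence` must be a single RNA string over {A,C,G,U}")
  paste(rev(strsplit(chartr("ACGU", "UGCA", toupper(sequence)), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# Enumerate all intramolecular stem-loops: 5' strand at i..i+s-1 pairs the
# 3' strand at j..j+s-1 antiparallel (i+k with j+s-1-k), loop = j-i-s nt.
# Restricted to stems whose 5' side starts at >= min_start and whose 3'
# side ends at <= max_end.
.find_stem_loops <- function(sv, stem_range, loop_range,
                             min_start = 1L, max_end = length(sv)) {
  n <- length(sv)
  out <- list()
  for (s in stem_range) for (L in loop_range) {
    i_max <- max_end - 2L * s - L + 1L
    if (i_max < min_start) next
    for (i in min_start:i_max) {
      j <- i + s + L
      k <- 0L
      while (k < s && .pairs_ok(sv[i + k], sv[j + s - 1L - k])) k <- k + 1L
      if (k == s)
        out[[length(out) + 1L]] <- c(stem_start5 = i, stem_start3 = j,
                                     stem_bp = s, loop_len = L)
    }
  }
  if (!length(out)) return(NULL)
  df <- as.data.frame(do.call(rbind, out))
  df[order(-df$stem_bp, df$stem_start5, df$loop_len), , drop = FALSE]
}

#' Fold a small RNA as a 5'-half-tRNA mimic
#'
#' Searches for an internal stem-loop (stem 3--7 bp over Watson-Crick and
#' G:U pairs, loop 3--11 nt) whose 5' strand begins at least `min_arm + 1`
#' positions from the 5' end, leaving a 5'-terminal unpaired segment of at
#' least `min_arm` nt -- the acceptor-arm mimic available for
#' intermolecular pairing with a target. Among qualifying folds the one
#' with the longest stem is returned, ties broken by the 5'-most stem.
#'
#' @param sequence RNA string, length >= 20.
#' @param stem_bp Integer vector of admissible stem lengths (default 3:7).
#' @param loop_nt Integer vector of admissible loop lengths (default 3:11).
#' @param min_arm Minimum unpaired 5'-arm length (default 7).
#' @return A list of class `half_trna_fold` with elements `acceptor_arm`
#'   (arm length), `stem_start5`, `stem_start3`, `stem_bp`, `loop_len`, or
#'   `NULL` if no qualifying fold exists.
#' @examples
#' fold_half_trna(y4_fragment_31nt)
#' @export
fold_half_trna <- function(sequence, stem_bp = 3:7, loop_nt = 3:11,
                           min_arm = 7L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 20L) stop("`sequence` must be at least 20 nt")
  sv <- strsplit(sequence, "", fixed = TRUE)[[1]]
  folds <- .find_stem_loops(sv, stem_bp, loop_nt, min_start = min_arm + 1L)
  if (is.null(folds)) return(NULL)
  best <- folds[1L, ]
  structure(list(sequence = sequence,
                 acceptor_arm = best$stem_start5 - 1L,
                 stem_start5 = best$stem_start5,
                 stem_start3 = best$stem_start3,
                 stem_bp = best$stem_bp,
                 loop_len = best$loop_len),
            class = "half_trna_fold")
}

#' @export
print.half_trna_fold <- function(x, ...) {
  cat(sprintf(paste0("<half_trna_fold> %d-nt 5' arm | %d-bp stem at ",
                     "%d..%d/%d..%d | %d-nt loop\n"),
              x$acceptor_arm, x$stem_bp,
              x$stem_start5, x$stem_start5 + x$stem_bp - 1L,
              x$stem_start3, x$stem_start3 + x$stem_bp - 1L, x$loop_len))
  invisible(x)
}

#' Classify a small RNA into sgRNA structural classes
#'
#' Assigns zero or more of the four tRNase Z(L) guide classes:
#' * `heptamer` -- length 5--8 nt;
#' * `linear14` -- length 12--16 nt with no internal stem-loop of >= 4 bp
#'   (loop 3--11 nt);
#' * `half_tRNA` -- length 26--40 nt folding as a 5'-half-tRNA mimic
#'   ([fold_half_trna()]);
#' * `hook` -- length 15--25 nt with a 3' stem-loop (>= 4 bp) preceded by
#'   an unpaired 5' guide segment of >= 7 nt.
#'
#' Classes may overlap and the empty set is allowed.
#'
#' @param sequence RNA string, 5--40 nt.
#' @return Character vector of assigned classes (possibly empty).
#' @examples
#' classify_sgrna("ACGUACG")
#' classify_sgrna(y4_fragment_31nt)
#' @export
classify_sgrna <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 5L || n > 40L) stop("`sequence` must be 5-40 nt")
  sv <- strsplit(sequence, "", fixed = TRUE)[[1]]
  classes <- character(0)
  if (n >= 5L && n <= 8L) classes <- c(classes, "heptamer")
  if (n >= 12L && n <= 16L &&
      is.null(.find_stem_loops(sv, 4:7, 3:11)))
    classes <- c(classes, "linear14")
  if (n >= 26L && n <= 40L && !is.null(fold_half_trna(sequence)))
    classes <- c(classes, "half_tRNA")
  if (n >= 15L && n <= 25L &&
      !is.null(.find_stem_loops(sv, 4:7, 3:11, min_start = 8L)))
    classes <- c(classes, "hook")
  classes
}

#' Scan a target RNA for pre-tRNA-like complex sites with a guide
#'
#' For a half-tRNA-type guide, finds every target position where a
#' pre-tRNA-like guide:target complex can form: (i) a contiguous
#' intermolecular duplex of at least `min_acceptor_bp` base pairs
#' (Watson-Crick + G:U) between the guide's 5' terminus and the target,
#' capped at the guide's unpaired 5'-arm length (positions 3' of the arm
#' are engaged in the guide's own D-arm-like stem); (ii) a T-arm-like
#' stem-loop on the target (stem >= `t_stem_bp` bp, loop 5--9 nt) within
#' `window_upstream` nt 5' of the duplex, with a bonus flag when a loop
#' contains the T-loop consensus `GGUUC`; (iii) at least one target
#' nucleotide 3' of the duplex -- the discriminator.
#'
#' Complexes are ranked by duplex length, then by the T-loop bonus.
#'
#' @param guide RNA string classifiable as `half_tRNA`.
#' @param target RNA string.
#' @param min_acceptor_bp Minimum acceptor-duplex length (default 7).
#' @param window_upstream Target window searched for the T-arm-like
#'   stem-loop, in nt 5' of the duplex (default 30).
#' @param t_stem_bp Minimum T-arm stem length (default 4).
#' @return A list of `pre_trna_complex` objects (possibly empty), ranked
#'   best first. Each complex records the guide/target pairing
#'   coordinates, the T-arm stem-loop, the discriminator position, and the
#'   predicted cleavage site.
#' @examples
#' cx <- find_target_sites(y4_fragment_31nt, rna_y_target)
#' cx[[1]]
#' @export
find_target_sites <- function(guide, target, min_acceptor_bp = 7L,
                              window_upstream = 30L, t_stem_bp = 4L) {
  guide <- toupper(guide); target <- toupper(target)
  fold <- fold_half_trna(guide)
  if (is.null(fold))
    stop("`guide` has no 5'-half-tRNA-like fold; see classify_sgrna()")
  gv <- strsplit(guide, "", fixed = TRUE)[[1]]
  tv <- strsplit(target, "", fixed = TRUE)[[1]]
  nt <- length(tv)
  arm <- fold$acceptor_arm
  out <- list()
  for (e in seq_len(nt)) {  # e = target position paired with guide[1]
    kmax <- min(arm, e)
    L <- 0L
    while (L < kmax && .pairs_ok(gv[L + 1L], tv[e - L])) L <- L + 1L
    if (L < min_acceptor_bp) next
    s <- e - L + 1L
    # T-arm-like stem-loop upstream of the duplex on the target
    stems <- .find_stem_loops(tv, t_stem_bp:7L, 5:9,
                              min_start = max(1L, s - window_upstream),
                              max_end = s - 1L)
    if (is.null(stems)) next
    loops <- apply(stems, 1L, function(r) {
      paste(tv[(r[["stem_start5"]] + r[["stem_bp"]]):(r[["stem_start3"]] - 1L)],
            collapse = "")
    })
    bonus <- grepl("GGUUC", loops, fixed = TRUE)
    pick <- if (any(bonus)) which(bonus)[1L] else 1L
    discriminator <- e + 1L
    if (discriminator > nt) next
    out[[length(out) + 1L]] <- structure(list(
      guide = guide, target = target,
      guide_positions = seq_len(L),
      target_positions = s:e,
      duplex_bp = L,
      t_arm = as.list(stems[pick, ]),
      t_loop_bonus = bonus[pick],
      discriminator = discriminator,
      cleavage_site = discriminator,  # bond 3' of the discriminator
      guide_fold = fold
    ), class = "pre_trna_complex")
  }
  if (length(out) > 1L) {
    key <- order(-vapply(out, `[[`, 0L, "duplex_bp"),
                 -vapply(out, function(x) as.integer(x$t_loop_bonus), 0L),
                 vapply(out, `[[`, 0L, "discriminator"))
    out <- out[key]
  }
  out
}

#' @export
print.pre_trna_complex <- function(x, ...) {
  cat(sprintf(paste0("<pre_trna_complex> %d-bp acceptor duplex ",
                     "guide[1..%d]:target[%d..%d] | discriminator %d (%s) | ",
                     "cleavage 3' of %d%s\n"),
              x$duplex_bp, x$duplex_bp,
              min(x$target_positions), max(x$target_positions),
              x$discriminator, substr(x$target, x$discriminator, x$discriminator),
              x$cleavage_site,
              if (x$t_loop_bonus) " | GGUUC T-loop" else ""))
  invisible(x)
}

#' Predict the tRNase Z(L) cleavage site of a complex
#'
#' tRNase Z(L) cleaves the phosphodiester bond immediately 3' of the
#' discriminator nucleotide of a pre-tRNA-like complex. The cut between
#' target positions `d` and `d + 1` yields a 5' product of `d` nt and a 3'
#' product of `length(target) - d` nt.
#'
#' @param complex A `pre_trna_complex` from [find_target_sites()].
#' @return A list with `position` (the 5' side of the cleaved bond, i.e.
#'   the discriminator position), `len5`, `len3`, and `terminal` (`TRUE`
#'   when the discriminator is the target's last nucleotide, leaving an
#'   empty 3' product).
#' @examples
#' cx <- find_target_sites(y4_fragment_31nt, rna_y_target)
#' predict_cleavage(cx[[1]])
#' @export
predict_cleavage <- function(complex) {
  stopifnot(inherits(complex, "pre_trna_complex"))
  d <- complex$discriminator
  n <- nchar(complex$target)
  list(position = d, len5 = d, len3 = n - d, terminal = (d == n))
}
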