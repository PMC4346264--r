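# Transcript-space annotation: assign each insert to its potential origin
# transcripts and to the ten RNA categories, with the rDNA two-mismatch
# pre-filter applied before any other transcript matching.
#
# Matching is full-insert contiguous (Hamming-distance) matching against a
# small reference transcript set -- a desk-scale, interchangeable stand-in
# for genome-scale alignment: downstream stages only consume the
# insert -> category multiset contract.

#' Precompiled annotation index over a reference set
#'
#' Bundles the reference transcripts as a `RNAStringSet` together with
#' their category labels and the strand policy, ready for repeated
#' matching.
#'
#' @param refs A `reference_set`.
#' @param strand `"sense"` (default; small-RNA libraries are stranded) or
#'   `"both"` to also match the reverse complement.
#' @return Object of class `annotation_index`.
#' @export
annotation_index <- function(refs, strand = c("sense", "both")) {
  strand <- match.arg(strand)
  subjects <- Biostrings::RNAStringSet(refs$sequence)
  names(subjects) <- refs$id
  structure(list(subjects = subjects, ids = refs$id,
                 categories = refs$category,
                 rdna_unit = attr(refs, "rdna_unit"), strand = strand),
            class = "annotation_index")
}

#' Find all mismatch-tolerant occurrences of a query in a subject
#'
#' All alignments of the full query as a contiguous substring of the
#' subject with Hamming distance at most `max_mm`; equivalent to a naive
#' scan over every subject position.
#'
#' @param query,subject RNA strings; `nchar(query) <= nchar(subject)`.
#' @param max_mm Maximum mismatches.
#' @return Data frame with columns `position` (1-based start) and
#'   `mismatches`.
#' @examples
#' match_with_mismatches("ACGU", "UUACGUUU", 0)
#' @export
match_with_mismatches <- function(query, subject, max_mm = 2L) {
  if (nchar(query) > nchar(subject))
    stop("`query` must not be longer than `subject`")
  m <- Biostrings::matchPattern(toupper(query),
                                Biostrings::RNAString(toupper(subject)),
                                max.mismatch = max_mm)
  pos <- Biostrings::start(m)
  if (!length(pos))
    return(data.frame(position = integer(0), mismatches = integer(0)))
  mm <- Biostrings::neditStartingAt(Biostrings::RNAString(toupper(query)),
                                    Biostrings::RNAString(toupper(subject)),
                                    starting.at = pos)
  data.frame(position = pos, mismatches = as.integer(mm))
}

# Does `insert` occur in `subject` within max_mm mismatches, honouring the
# strand policy?
.hits_subject <- function(insert, subject, max_mm, strand) {
  if (nchar(insert) > length(subject)) return(FALSE)
  n <- length(Biostrings::matchPattern(insert, subject,
                                       max.mismatch = max_mm))
  if (n > 0L) return(TRUE)
  if (strand == "both") {
    rc <- Biostrings::reverseComplement(Biostrings::RNAString(insert))
    return(length(Biostrings::matchPattern(rc, subject,
                                           max.mismatch = max_mm)) > 0L)
  }
  FALSE
}

#' rDNA repeating-unit pre-filter
#'
#' `TRUE` when the insert matches the designated rDNA repeating-unit
#' transcript within `max_mm` (default 2) mismatches. Matching reads are
#' annotated rRNA and excluded from further transcript matching.
#'
#' @param insert Canonicalized insert sequence.
#' @param index An [annotation_index()] whose reference designates an rDNA
#'   unit.
#' @param max_mm Mismatch allowance (default 2).
#' @return Logical.
#' @export
rdna_filter <- function(insert, index, max_mm = 2L) {
  stopifnot(inherits(index, "annotation_index"))
  if (is.na(index$rdna_unit))
    stop("the reference set designates no rDNA repeating unit")
  subject <- index$subjects[[match(index$rdna_unit, index$ids)]]
  .hits_subject(toupper(insert), subject, max_mm, index$strand)
}

#' Assign an insert to RNA categories
#'
#' The set of categories of all transcripts containing the insert as a
#' contiguous substring within `max_mm` mismatches. An empty set marks an
#' unidentified RNA fragment.
#'
#' @param insert Canonicalized insert sequence.
#' @param index An [annotation_index()].
#' @param max_mm Mismatch allowance (default 2, matching the rDNA rule;
#'   the genome-alignment settings behind the original category calls are
#'   not independently specified).
#' @param exclude Transcript ids to skip (used to keep the rDNA unit out
#'   of post-filter matching).
#' @return Character vector of categories (possibly empty).
#' @export
assign_categories <- function(insert, index, max_mm = 2L,
                              exclude = character(0)) {
  stopifnot(inherits(index, "annotation_index"))
  insert <- toupper(insert)
  use <- which(!(index$ids %in% exclude))
  hit <- vapply(use, function(i)
    .hits_subject(insert, index$subjects[[i]], max_mm, index$strand),
    logical(1))
  sort(unique(index$categories[use[hit]]))
}

#' Annotate a whole sample library
#'
#' Applies the rDNA pre-filter and category assignment to every distinct
#' insert of a sample. rDNA-filtered inserts are annotated rRNA and do not
#' reach transcript matching; all other inserts collect the categories of
#' their matching transcripts.
#'
#' @param sample A [sample_library()].
#' @param index An [annotation_index()].
#' @param max_mm Mismatch allowance (default 2).
#' @return Data frame with one row per distinct insert: `sequence`,
#'   `count`, `rdna_hit`, `categories` (comma-joined, `""` =
#'   unidentified), `n_categories`.
#' @export
annotate_library <- function(sample, index, max_mm = 2L) {
  stopifnot(inherits(sample, "sample_library"))
  seqs <- names(sample$counts)
  has_rdna <- !is.na(index$rdna_unit)
  rdna <- if (has_rdna)
    vapply(seqs, rdna_filter, logical(1), index = index, max_mm = max_mm)
  else rep(FALSE, length(seqs))
  cats <- character(length(seqs))
  for (i in seq_along(seqs)) {
    cats[i] <- if (rdna[i]) "rRNA" else
      paste(assign_categories(seqs[i], index, max_mm,
                              exclude = if (has_rdna) index$rdna_unit
                                        else character(0)),
            collapse = ",")
  }
  data.frame(sequence = seqs, count = as.integer(sample$counts),
             rdna_hit = rdna, categories = cats,
             n_categories = ifelse(nzchar(cats),
                                   lengths(strsplit(cats, ",", fixed = TRUE)),
                                   0L),
             row.names = NULL)
}

#' Relative category frequencies of a sample
#'
#' Per-category percentages over the annotated reads of a sample. A read
#' matching `k >= 1` categories contributes `1/k` to each (fractional
#' assignment), so the ten percentages always sum to 100 over annotated
#' reads; the unannotated fraction is reported separately. A
#' winner-takes-priority alternative (first category in the fixed order
#' wins) is selectable.
#'
#' @param annotations Data frame from [annotate_library()].
#' @param rule `"fractional"` (default) or `"priority"`.
#' @return Named numeric vector of class `category_profile` over
#'   [rna_categories] (percentages), with attributes `annotated_reads` and
#'   `unannotated_fraction`. Zero annotated reads yield an all-`NA`
#'   profile flagged by `attr(, "empty")`.
#' @export
category_profile <- function(annotations, rule = c("fractional", "priority")) {
  rule <- match.arg(rule)
  ann <- annotations[annotations$n_categories > 0L, , drop = FALSE]
  total_ann <- sum(ann$count)
  total <- sum(annotations$count)
  weights <- setNames(numeric(length(rna_categories)), rna_categories)
  if (total_ann == 0L) {
    return(structure(weights + NA_real_, annotated_reads = 0L,
                     unannotated_fraction = if (total > 0) 1 else NA_real_,
                     empty = TRUE, class = "category_profile"))
  }
  for (i in seq_len(nrow(ann))) {
    cats <- strsplit(ann$categories[i], ",", fixed = TRUE)[[1]]
    if (rule == "priority")
      cats <- rna_categories[min(match(cats, rna_categories))]
    weights[cats] <- weights[cats] + ann$count[i] / length(cats)
  }
  structure(100 * weights / total_ann,
            annotated_reads = total_ann,
            unannotated_fraction = 1 - total_ann / total,
            empty = FALSE, class = "category_profile")
}

#' Plot a category profile as a stacked bar
#'
#' @param x A `category_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.category_profile <- function(x, ...) {
  mat <- matrix(as.numeric(x), dimnames = list(rna_categories, NULL))
  graphics::barplot(mat, legend.text = rna_categories,
                    ylab = "relative frequency (%)", ...)
}

#' @export
print.category_profile <- function(x, ...) {
  cat(sprintf("<category_profile> %s annotated reads (%.1f%% unannotated)\n",
              attr(x, "annotated_reads"),
              100 * attr(x, "unannotated_fraction")))
  print(round(unclass(x), 2))
  invisible(x)
}
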