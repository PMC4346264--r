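# Per-sample length-frequency profiles, peak detection, and the species
# frequency statistic used by all downstream comparisons.

#' Length profile of a sample library
#'
#' Counts reads per insert length over the analysis window, zero-filled.
#'
#' @param sample A [sample_library()].
#' @param lo,hi Inclusive window bounds (defaults 5 and 40 nt).
#' @return Integer vector of class `length_profile`, named by length, with
#'   a `total` attribute.
#' @examples
#' s <- sample_library("S1", c(GGCUGGUCC = 3L, ACGUACGUACGUAC = 1L))
#' length_profile(s)
#' @export
length_profile <- function(sample, lo = 5L, hi = 40L) {
  stopifnot(inherits(sample, "sample_library"))
  lens <- lo:hi
  counts <- setNames(integer(length(lens)), lens)
  if (length(sample$counts)) {
    got <- tapply(sample$counts, nchar(names(sample$counts)), sum)
    got <- got[names(got) %in% as.character(lens)]
    counts[names(got)] <- as.integer(got)
  }
  structure(counts, total = sum(counts), class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %d reads over %s-%s nt\n",
              attr(x, "total"), names(x)[1], names(x)[length(x)]))
  print(unclass(x))
  invisible(x)
}

#' Plot a length profile
#'
#' @param x A `length_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.length_profile <- function(x, ...) {
  graphics::barplot(setNames(as.numeric(x), names(x)),
                    xlab = "insert length (nt)", ylab = "read count", ...)
}

#' Find peaks in a length profile
#'
#' A peak is a strict local maximum of the zero-filled profile; a plateau
#' of equal adjacent maxima reports all member lengths, and the window
#' endpoints are compared one-sided. A completely flat profile has no
#' peaks.
#'
#' @param profile A `length_profile` (or plain named count vector).
#' @return Integer vector of peak lengths.
#' @examples
#' s <- sample_library("S1", c(GGCUGGUCC = 5L, ACGUACGUAC = 9L,
#'                             ACGUACGUACG = 5L))
#' find_peaks(length_profile(s))
#' @export
find_peaks <- function(profile) {
  v <- as.numeric(profile)
  lens <- as.integer(names(profile))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 2L) return(integer(0))  # flat profile
  peaks <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- (i == 1L) || (r$values[i] > r$values[i - 1L])
    right_ok <- (i == k) || (r$values[i] > r$values[i + 1L])
    if (left_ok && right_ok)
      peaks <- c(peaks, lens[starts[i]:ends[i]])
  }
  peaks
}

# Per-length read totals of a sample, zero-filled over lo..hi.
.length_totals <- function(sample, lo = 5L, hi = 40L) {
  as.integer(length_profile(sample, lo, hi))
}

#' Frequency of one species in a sample
#'
#' The species frequency is the sequence's read count as a percentage of a
#' denominator: either all reads of the same length in the sample
#' (`"same_length"`, the default, used for species comparisons) or all
#' reads in the analysis window (`"all_5_40"`, used for overall-abundance
#' statements).
#'
#' @param sample A [sample_library()].
#' @param sequence Insert sequence (canonicalized RNA).
#' @param denominator `"same_length"` or `"all_5_40"`.
#' @param lo,hi Analysis window (defaults 5 and 40 nt).
#' @return Percentage in `[0, 100]`; 0 when the sequence is absent but the
#'   denominator is positive; `NA` when the denominator is 0 (undefined,
#'   reported as missing rather than 0).
#' @examples
#' s <- sample_library("S1", c(AAAAAAA = 3L, CCCCCCC = 1L))
#' species_frequency(s, "AAAAAAA")
#' @export
species_frequency <- function(sample, sequence,
                              denominator = c("same_length", "all_5_40"),
                              lo = 5L, hi = 40L) {
  denominator <- match.arg(denominator)
  len <- nchar(sequence)
  if (len < lo || len > hi)
    stop("`sequence` lies outside the analysis window")
  prof <- length_profile(sample, lo, hi)
  denom <- if (denominator == "same_length") {
    as.integer(prof[as.character(len)])
  } else {
    attr(prof, "total")
  }
  if (denom == 0L) return(NA_real_)
  cnt <- sample$counts[sequence]
  if (is.na(cnt)) cnt <- 0L
  100 * as.numeric(cnt) / denom
}

#' Species-by-sample frequency matrix
#'
#' Builds the frequency table underlying all group comparisons: for each
#' requested sequence and each sample, the read count as a percentage of
#' the sample's same-length reads. Sequences absent from a sample are 0;
#' if a sample has no reads of that length at all, the frequency is
#' likewise 0 (the species was not observed).
#'
#' @param samples List of [sample_library()] objects.
#' @param sequences Character vector of sequences within the window.
#' @param lo,hi Analysis window.
#' @return Numeric matrix, rows = sequences, columns = sample ids, with a
#'   `length` integer attribute giving each row's sequence length.
#' @export
species_frequency_table <- function(samples, sequences, lo = 5L, hi = 40L) {
  lens <- nchar(sequences)
  stopifnot(all(lens >= lo & lens <= hi))
  mat <- vapply(samples, function(s) {
    prof <- length_profile(s, lo, hi)
    denom <- as.numeric(prof[as.character(lens)])
    cnt <- s$counts[sequences]
    cnt[is.na(cnt)] <- 0L
    ifelse(denom > 0, 100 * as.numeric(cnt) / denom, 0)
  }, numeric(length(sequences)))
  mat <- matrix(mat, nrow = length(sequences),
                dimnames = list(sequences,
                                vapply(samples, `[[`, "", "sample_id")))
  attr(mat, "length") <- lens
  mat
}
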