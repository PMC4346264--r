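# Read preprocessing: canonicalization, demultiplexing, adapter trimming,
# adapter-artifact removal and the 5-40 nt analysis window.
#
# All operations are vectorised over reads; preprocess_reads() applies them
# to the unique read sequences of a run and re-expands counts, which makes
# whole-run preprocessing cheap even at 10^4-10^5 reads per library.

#' Canonicalize read sequences into RNA space
#'
#' Uppercases and maps T to U, so DNA-space sequencer output and RNA-space
#' analysis share one alphabet. Sequences containing characters outside
#' `{A,C,G,T,U}` (case-insensitive) are rejected and returned as `NA`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length, uppercase RNA alphabet;
#'   `NA` for rejected sequences.
#' @examples
#' canonicalize(c("acgt", "GGCUGGUCC", "ACGN"))
#' @export
canonicalize <- function(x) {
  out <- chartr("T", "U", toupper(x))
  bad <- is.na(out) | grepl("[^ACGU]", out) | !nzchar(out)
  out[bad] <- NA_character_
  out
}

#' Assign reads to samples by barcode
#'
#' Matches each observed 4-nt barcode field against a sample-to-barcode
#' table. A read is assigned to the unique sample whose barcode lies within
#' `max_bc_mismatch` Hamming distance; if no barcode or more than one
#' barcode is within tolerance the read is `"UNASSIGNED"` (ambiguous
#' matches are flagged in the `"ambiguous"` attribute).
#'
#' @param barcode_field Character vector of observed barcode fields
#'   (canonicalized RNA alphabet).
#' @param barcode_table Named character vector, sample id -> barcode. All
#'   barcodes must have equal length; pairwise Hamming distance >= 2 is
#'   recommended when `max_bc_mismatch > 0`.
#' @param max_bc_mismatch Maximum Hamming distance for a match (default 0).
#' @return Character vector of sample ids or `"UNASSIGNED"`, with a logical
#'   `"ambiguous"` attribute marking reads matched by several barcodes.
#' @examples
#' demultiplex(c("GAAA", "GCAA"), c(S1 = "GAAA", S5 = "CAAA"))
#' @export
demultiplex <- function(barcode_field, barcode_table, max_bc_mismatch = 0L) {
  stopifnot(length(barcode_table) >= 1L, !is.null(names(barcode_table)))
  bl <- unique(nchar(barcode_table))
  if (length(bl) != 1L)
    stop("all barcodes in `barcode_table` must have the same length")
  if (anyDuplicated(barcode_table))
    stop("barcodes must be pairwise distinct")
  n <- length(barcode_field)
  obs <- toupper(barcode_field)
  valid <- !is.na(obs) & nchar(obs) == bl
  # Hamming distance of every observed field to every table barcode.
  dmat <- matrix(NA_integer_, n, length(barcode_table))
  obs_split <- matrix(NA_character_, n, bl)
  obs_split[valid, ] <- matrix(unlist(strsplit(obs[valid], "", fixed = TRUE)),
                               ncol = bl, byrow = TRUE)
  for (j in seq_along(barcode_table)) {
    bc <- strsplit(barcode_table[[j]], "", fixed = TRUE)[[1]]
    dmat[, j] <- rowSums(obs_split != rep(bc, each = n))
  }
  hits <- dmat <= max_bc_mismatch
  hits[!valid, ] <- FALSE
  nhit <- rowSums(hits, na.rm = TRUE)
  out <- rep("UNASSIGNED", n)
  one <- which(nhit == 1L)
  out[one] <- names(barcode_table)[max.col(hits[one, , drop = FALSE])]
  structure(out, ambiguous = nhit > 1L)
}

#' Strip adapters from canonicalized reads
#'
#' Locates the leftmost occurrence of the first `seed_len` bases of the 3'
#' adapter (allowing up to `seed_mismatch` mismatches), removes it and
#' everything 3' of it, and strips the constant-length 5' remnant
#' (including the barcode). Reads without a 3'-adapter seed are rejected
#' with reason `"no_adapter"`; reads whose adapters abut (empty insert)
#' with reason `"adapter_dimer"`.
#'
#' @param reads Character vector of full-length canonicalized reads.
#' @param config Adapter configuration from [adapter_config()].
#' @return Character vector of insert sequences (`NA` where rejected), with
#'   a character attribute `"reason"` (`NA`, `"no_adapter"` or
#'   `"adapter_dimer"`).
#' @examples
#' cfg <- adapter_config()
#' read <- paste0(cfg$remnant, "GAAA", "GGCUGGU", cfg$adapter3)
#' trim_adapters(read, cfg)
#' @export
trim_adapters <- function(reads, config = adapter_config()) {
  seed <- substr(config$adapter3, 1L, config$seed_len)
  n <- length(reads)
  insert <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  ok <- !is.na(reads) & nchar(reads) >= config$seed_len
  reason[!ok] <- "no_adapter"
  if (any(ok)) {
    subj <- Biostrings::RNAStringSet(reads[ok])
    m <- Biostrings::vmatchPattern(seed, subj,
                                   max.mismatch = config$seed_mismatch)
    starts <- Biostrings::startIndex(m)
    left <- vapply(starts,
                   function(s) if (length(s)) min(s) else NA_integer_,
                   integer(1))
    idx <- which(ok)
    none <- is.na(left)
    reason[idx[none]] <- "no_adapter"
    dimer <- !none & left <= config$remnant_len + 1L
    reason[idx[dimer]] <- "adapter_dimer"
    keep <- !none & !dimer
    insert[idx[keep]] <- substr(reads[idx[keep]],
                                config$remnant_len + 1L,
                                left[keep] - 1L)
  }
  structure(insert, reason = reason)
}

# All k-mers of a string.
.kmers <- function(x, k) {
  L <- nchar(x)
  if (L < k) return(character(0))
  substring(x, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

# Generic diagonal scan: TRUE when `s` and `t` share a contiguous local
# alignment with >= M matching positions and <= mm mismatches.
.local_match_scan <- function(s, tsplit, M, mm) {
  L <- nchar(s)
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  for (tv in tsplit) {
    Lt <- length(tv)
    for (d in (1L - L):(Lt - 1L)) {   # s[i] aligned to t[i + d]
      i1 <- max(1L, 1L - d); i2 <- min(L, Lt - d)
      ov <- i2 - i1 + 1L
      if (ov < M) next
      v <- sv[i1:i2] == tv[(i1:i2) + d]
      cs <- cumsum(c(0L, v))
      for (len in M:min(M + mm, ov)) {
        w <- cs[(len + 1L):(ov + 1L)] - cs[1L:(ov - len + 1L)]
        if (any(w >= M)) return(TRUE)
      }
    }
  }
  FALSE
}

# Cached k-mer lookup sets for the fast artifact test. For mm <= 1 the
# local-match condition is exactly: the insert shares an exact M-mer with
# a target, or (mm = 1) an (M+1)-mer within one mismatch -- any longer
# qualifying alignment contains one of these windows.
.artifact_sets_env <- new.env(parent = emptyenv())
.artifact_sets <- function(targets, M, mm) {
  key <- paste(c(targets, M, mm), collapse = "|")
  hit <- get0(key, envir = .artifact_sets_env)
  if (!is.null(hit)) return(hit)
  exact_m <- unique(unlist(lapply(targets, .kmers, k = M)))
  nb <- NULL
  if (mm >= 1L) {
    w <- unique(unlist(lapply(targets, .kmers, k = M + 1L)))
    nb <- unique(unlist(lapply(w, function(s) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      c(s, unlist(lapply(seq_along(v), function(i)
        vapply(setdiff(c("A", "C", "G", "U"), v[i]), function(b) {
          v2 <- v; v2[i] <- b; paste(v2, collapse = "")
        }, "")), use.names = FALSE))
    })))
  }
  res <- list(exact_m = exact_m, nb = nb)
  assign(key, res, envir = .artifact_sets_env)
  res
}

# TRUE where the insert has a local match to a 5' adapter (or its reverse
# complement) with >= min_match matching positions and <= max_mm mismatches
# along one contiguous alignment diagonal.
.is_adapter_artifact <- function(inserts, config = adapter_config()) {
  targets <- c(config$adapters5,
               vapply(config$adapters5, reverse_complement_rna, ""))
  M <- config$artifact_min_match
  mm <- config$artifact_mismatch
  u <- unique(inserts[!is.na(inserts)])
  if (mm <= 1L) {
    sets <- .artifact_sets(targets, M, mm)
    flag_u <- vapply(u, function(s) {
      any(.kmers(s, M) %in% sets$exact_m) ||
        (mm == 1L && any(.kmers(s, M + 1L) %in% sets$nb))
    }, logical(1), USE.NAMES = FALSE)
  } else {
    tsplit <- lapply(targets, function(t) strsplit(t, "", fixed = TRUE)[[1]])
    flag_u <- vapply(u, function(s) {
      nchar(s) >= M && .local_match_scan(s, tsplit, M, mm)
    }, logical(1), USE.NAMES = FALSE)
  }
  out <- rep(FALSE, length(inserts))
  out[!is.na(inserts)] <- flag_u[match(inserts[!is.na(inserts)], u)]
  out
}

#' Flag adapter-derived artifact inserts
#'
#' An insert is dropped when it matches part of any 5' adapter (or its
#' reverse complement) over a contiguous local alignment with at least
#' `artifact_min_match` matching positions and at most `artifact_mismatch`
#' mismatches. Such sequences arise as library artifacts and would
#' otherwise contaminate the abundance profiles.
#'
#' @param insert Character vector of canonicalized inserts.
#' @param config Adapter configuration from [adapter_config()].
#' @return Character vector of `"KEEP"` / `"DROP"` decisions.
#' @examples
#' cfg <- adapter_config()
#' filter_artifacts(c(substr(cfg$adapters5[[1]], 3, 14), "GGCUGGUCC"), cfg)
#' @export
filter_artifacts <- function(insert, config = adapter_config()) {
  ifelse(.is_adapter_artifact(insert, config), "DROP", "KEEP")
}

#' Apply the analysis length window
#'
#' @param insert Character vector of inserts.
#' @param lo,hi Inclusive length bounds (defaults 5 and 40 nt).
#' @return Character vector of `"KEEP"` / `"DROP"` decisions.
#' @examples
#' length_select(c("ACGUA", "ACGU"))
#' @export
length_select <- function(insert, lo = 5L, hi = 40L) {
  if (lo > hi) stop("`lo` must not exceed `hi`")
  len <- nchar(insert)
  ifelse(!is.na(insert) & len >= lo & len <= hi, "KEEP", "DROP")
}

#' Construct a sample library
#'
#' A sample library is one sample's demultiplexed insert multiset, stored
#' as a named integer count vector, together with its group and source
#' labels.
#'
#' @param sample_id Sample identifier.
#' @param counts Named integer vector, insert sequence -> read count
#'   (counts >= 1).
#' @param group Group label (e.g. `"A"` / `"B"` or `"healthy"` /
#'   `"myeloma"`).
#' @param source Sample source (e.g. `"plasma"`, `"PBMC"`, `"cell line"`).
#' @return An object of class `sample_library`.
#' @export
sample_library <- function(sample_id, counts, group = NA_character_,
                           source = NA_character_) {
  if (!length(counts)) counts <- setNames(integer(0), character(0))
  if (is.null(names(counts)) || any(counts < 1L))
    stop("`counts` must be a named vector of positive counts")
  counts <- counts[order(names(counts))]
  storage.mode(counts) <- "integer"
  structure(list(sample_id = sample_id, group = group, source = source,
                 counts = counts),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat(sprintf("<sample_library> %s (group %s, %s): %d reads, %d species\n",
              x$sample_id, x$group, x$source,
              sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Preprocess a raw multiplexed read set
#'
#' Runs the full preprocessing chain on one sequencing run: canonicalize,
#' demultiplex by barcode, trim adapters, drop adapter artifacts, and apply
#' the analysis length window. Every read is accounted to exactly one fate,
#' so raw totals are conserved.
#'
#' @param reads Character vector of raw read sequences (DNA or RNA
#'   alphabet), optionally named by read id.
#' @param sample_sheet Data frame with columns `sample_id`, `barcode`, and
#'   optionally `group` and `source`.
#' @param config Adapter configuration from [adapter_config()].
#' @param lo,hi Analysis length window (defaults 5 and 40 nt).
#' @param artifact_filter Logical scalar, or named logical vector per
#'   sample id, switching the adapter-artifact filter (default `TRUE`
#'   everywhere).
#' @return An object of class `preprocessed_run`: a list with `samples`
#'   (named list of [sample_library()] objects) and `accounting` (data
#'   frame of per-sample read fates: kept, rejected_no_adapter,
#'   rejected_adapter_dimer, dropped_artifact, dropped_length, plus
#'   unassigned and alphabet-rejected reads).
#' @examples
#' cfg <- adapter_config()
#' sheet <- data.frame(sample_id = "S1", barcode = "GAAA")
#' reads <- paste0(chartr("U", "T", paste0(cfg$remnant, "GAAA")),
#'                 c("GGCTGGTCC", "ACGTACGTAGA"),
#'                 chartr("U", "T", cfg$adapter3))
#' pp <- preprocess_reads(reads, sheet, cfg)
#' pp$samples$S1
#' @export
preprocess_reads <- function(reads, sample_sheet, config = adapter_config(),
                             lo = 5L, hi = 40L, artifact_filter = TRUE) {
  stopifnot(all(c("sample_id", "barcode") %in% names(sample_sheet)))
  sheet <- sample_sheet
  sheet$barcode <- canonicalize(sheet$barcode)
  barcode_table <- setNames(sheet$barcode, sheet$sample_id)
  if (length(artifact_filter) == 1L)
    artifact_filter <- setNames(rep(artifact_filter, nrow(sheet)),
                                sheet$sample_id)

  tab <- table(reads)
  u <- names(tab)
  n_u <- as.integer(tab)

  canon <- canonicalize(u)
  fate <- rep(NA_character_, length(u))
  sample_of <- rep("UNASSIGNED", length(u))
  fate[is.na(canon)] <- "rejected_alphabet"

  live <- which(is.na(fate))
  bc <- substr(canon[live], config$barcode_start,
               config$barcode_start + config$barcode_len - 1L)
  sample_of[live] <- demultiplex(bc, barcode_table, config$max_bc_mismatch)
  fate[live][sample_of[live] == "UNASSIGNED"] <- "unassigned"

  live <- which(is.na(fate))
  insert <- rep(NA_character_, length(u))
  if (length(live)) {
    tr <- trim_adapters(canon[live], config)
    insert[live] <- as.character(tr)
    reason <- attr(tr, "reason")
    fate[live][!is.na(reason) & reason == "no_adapter"] <- "rejected_no_adapter"
    fate[live][!is.na(reason) & reason == "adapter_dimer"] <- "rejected_adapter_dimer"
  }

  live <- which(is.na(fate))
  if (length(live)) {
    filt_on <- artifact_filter[sample_of[live]]
    filt_on[is.na(filt_on)] <- TRUE
    art <- .is_adapter_artifact(insert[live], config) & filt_on
    fate[live][art] <- "dropped_artifact"
  }

  live <- which(is.na(fate))
  if (length(live)) {
    drop_len <- length_select(insert[live], lo, hi) == "DROP"
    fate[live][drop_len] <- "dropped_length"
  }
  fate[is.na(fate)] <- "kept"

  fates <- c("kept", "rejected_no_adapter", "rejected_adapter_dimer",
             "dropped_artifact", "dropped_length", "unassigned",
             "rejected_alphabet")
  groups <- c(sheet$sample_id, "UNASSIGNED")
  acct <- matrix(0L, nrow = length(groups), ncol = length(fates),
                 dimnames = list(groups, fates))
  agg_sample <- ifelse(sample_of == "UNASSIGNED", "UNASSIGNED", sample_of)
  for (k in seq_along(u))
    acct[agg_sample[k], fate[k]] <- acct[agg_sample[k], fate[k]] + n_u[k]
  accounting <- data.frame(sample_id = groups, acct,
                           total = as.integer(rowSums(acct)),
                           row.names = NULL)

  samples <- lapply(seq_len(nrow(sheet)), function(i) {
    sid <- sheet$sample_id[i]
    sel <- which(sample_of == sid & fate == "kept")
    cnt <- tapply(n_u[sel], insert[sel], sum)
    cnt <- setNames(as.integer(cnt), names(cnt))
    sample_library(sid, cnt,
                   group = if ("group" %in% names(sheet)) sheet$group[i] else NA,
                   source = if ("source" %in% names(sheet)) sheet$source[i] else NA)
  })
  names(samples) <- sheet$sample_id

  structure(list(samples = samples, accounting = accounting,
                 window = c(lo = lo, hi = hi), n_reads = length(reads)),
            class = "preprocessed_run")
}

#' @export
print.preprocessed_run <- function(x, ...) {
  cat(sprintf("<preprocessed_run> %d raw reads, %d samples, window %d-%d nt\n",
              x$n_reads, length(x$samples), x$window["lo"], x$window["hi"]))
  print(x$accounting)
  invisible(x)
}
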