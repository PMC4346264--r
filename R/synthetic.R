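# Seeded synthetic-data generation: category-annotated reference
# transcripts and six-sample barcoded read sets with planted ground truth.
#
# The generator is first-class, tested code: every downstream stage is
# validated against the truth tables it emits. Reference transcripts are
# screened so that no legitimate insert can collide with the adapter
# chemistry (no 3'-adapter seed occurrence within one mismatch, no local
# 5'-adapter artifact match), which makes noise-free preprocessing an
# exact round trip.

.default_length_peaks <- function() {
  data.frame(length = c(14L, 15L, 16L, 22L, 23L, 26L, 31L, 37L),
             weight = c(4, 5, 4, 6, 5, 5, 12, 4))
}

.default_category_mix <- function() {
  c(mRNA = 0.38, rRNA = 0.05, scRNA = 0.25, snRNA = 0.01, srpRNA = 0.01,
    miRNA = 0.15, lncRNA = 0.10, piRNA = 0.01, snoRNA = 0.01, tRNA = 0.03)
}

#' Specification of a synthetic small-RNA experiment
#'
#' Collects every knob of the synthetic-data generator: sample layout,
#' read depth, the planted insert-length peaks, the category mixture over
#' the ten RNA categories, the planted two-group differential species, the
#' adapter-artifact fraction, and the barcode table.
#'
#' The defaults emulate the published study conditions: six barcoded
#' libraries of 5--45 nt inserts, 3 vs 3 group assignment, length peaks at
#' 14/15/16, 22/23, 26, 31 (dominant) and 37 nt, four planted differential
#' species at fold change 20, and a 5% adapter-artifact fraction.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_samples Number of samples (default 6).
#' @param group_assignment Character vector of group labels per sample
#'   (default 3 x `"A"`, 3 x `"B"`).
#' @param reads_per_sample Reads per library (default 10000).
#' @param length_peaks Data frame `length`, `weight`: extra weight placed
#'   on peak lengths on top of a uniform baseline weight of 1 over
#'   5--45 nt.
#' @param category_mix Named proportions over the ten categories in
#'   [rna_categories] (must sum to 1).
#' @param n_planted_differential Number of planted differential species
#'   (default 4), placed in distinct peak strata, directions alternating
#'   more/less in group B.
#' @param differential_fold_change Within-stratum frequency fold change of
#'   planted species in group B (> 1, default 20).
#' @param artifact_fraction Fraction of adapter-derived artifact reads per
#'   library, in `[0, 1]` (default 0.05).
#' @param barcode_table Named character vector sample id -> 4-nt barcode
#'   (default: the six published barcodes).
#' @param error_rate Uniform per-base substitution rate on emitted reads
#'   (default 0; no error model is implied by the library chemistry).
#' @param count_model `"multinomial"` (default): read counts are sampled,
#'   so libraries carry sampling noise; `"expected"`: deterministic
#'   largest-remainder allocation of the expected counts -- the noise-free
#'   mode in which the only between-group differences are the planted
#'   ones.
#' @param species_per_length Species pool size per length stratum
#'   (default 8), with within-stratum abundances following a Zipf-like
#'   law so each stratum has clearly ranked top species.
#' @param source Source label for all samples (default `"plasma"`).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_samples = 6L,
                           group_assignment = rep(c("A", "B"),
                                                  each = n_samples %/% 2L),
                           reads_per_sample = 10000L,
                           length_peaks = .default_length_peaks(),
                           category_mix = .default_category_mix(),
                           n_planted_differential = 4L,
                           differential_fold_change = 20,
                           artifact_fraction = 0.05,
                           barcode_table = NULL,
                           error_rate = 0,
                           count_model = c("multinomial", "expected"),
                           species_per_length = 8L,
                           source = "plasma") {
  count_model <- match.arg(count_model)
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (length(group_assignment) != n_samples)
    stop("`group_assignment` must have one label per sample")
  if (!all(names(category_mix) %in% rna_categories))
    stop("`category_mix` names categories outside the fixed 10: ",
         paste(setdiff(names(category_mix), rna_categories), collapse = ", "))
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("`category_mix` proportions must sum to 1")
  if (any(category_mix < 0)) stop("`category_mix` proportions must be >= 0")
  if (any(length_peaks$length < 5L | length_peaks$length > 45L))
    stop("peak lengths must lie in [5, 45]")
  if (any(length_peaks$weight < 0)) stop("peak weights must be >= 0")
  if (differential_fold_change <= 1)
    stop("`differential_fold_change` must exceed 1")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("`artifact_fraction` must lie in [0, 1]")
  if (n_planted_differential > nrow(length_peaks))
    stop("cannot plant more differential species than peak strata")
  sample_ids <- paste0("S", seq_len(n_samples))
  if (is.null(barcode_table)) {
    bcs <- adapter_config()$barcodes
    if (n_samples > length(bcs))
      stop("default barcode table supports at most ", length(bcs), " samples")
    barcode_table <- setNames(bcs[seq_len(n_samples)], sample_ids)
  }
  if (anyDuplicated(barcode_table)) stop("barcodes must be pairwise distinct")
  names(group_assignment) <- sample_ids
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    sample_ids = sample_ids, group_assignment = group_assignment,
    reads_per_sample = as.integer(reads_per_sample),
    length_peaks = length_peaks, category_mix = category_mix,
    n_planted_differential = as.integer(n_planted_differential),
    differential_fold_change = differential_fold_change,
    artifact_fraction = artifact_fraction,
    barcode_table = barcode_table, error_rate = error_rate,
    count_model = count_model,
    species_per_length = as.integer(species_per_length),
    source = source), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> seed %d | %d samples (%s) | %d ",
                     "reads/sample | %d planted diff. species at fold %g | ",
                     "%s counts\n"),
              x$seed, x$n_samples,
              paste(table(x$group_assignment), collapse = " vs "),
              x$reads_per_sample, x$n_planted_differential,
              x$differential_fold_change, x$count_model))
  invisible(x)
}

# Random RNA string.
.random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# TRUE when `seq` contains an occurrence of the 3'-adapter seed within
# `mm` mismatches (which would confuse adapter trimming).
.contains_seed <- function(seq, config) {
  seed <- substr(config$adapter3, 1L, config$seed_len)
  length(Biostrings::matchPattern(seed, Biostrings::RNAString(seq),
                                  max.mismatch = config$seed_mismatch)) > 0L
}

# Draw a random transcript free of adapter-chemistry collisions.
.clean_transcript <- function(n, config, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- .random_rna(n)
    if (!.contains_seed(s, config) && !.is_adapter_artifact(s, config))
      return(s)
  }
  stop("failed to draw an adapter-clean transcript")  # nocov
}

#' Fabricate a category-annotated reference transcript set
#'
#' Generates at least one transcript per category with nonzero proportion
#' in the spec's category mixture. When the rRNA category is present, an
#' rDNA repeating-unit surrogate (600 nt, with the published 14-nt 5.8S
#' and 28S fragments embedded) is included and designated as the rDNA
#' pre-filter subject; when the scRNA category is present, a 94-nt Y4-RNA
#' surrogate whose 5' 31-mer is [y4_fragment_31nt] is included.
#' Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param transcripts_per_category Number of random transcripts per
#'   category in addition to the designated surrogates (default 2).
#' @param transcript_length Length of the random transcripts (default
#'   150 nt).
#' @return Object of class `reference_set`: a data frame with columns
#'   `id`, `category`, `sequence`, and an `rdna_unit` attribute naming the
#'   rDNA surrogate (or `NA` when rRNA has zero proportion).
#' @export
make_reference_set <- function(spec, transcripts_per_category = 2L,
                               transcript_length = 150L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  config <- adapter_config()
  cats <- names(spec$category_mix)[spec$category_mix > 0]
  with_seed(spec$seed, {
    rows <- list()
    for (cat in cats) {
      if (cat == "rRNA") {
        # The 28S 5'-end 14-mer is embedded so the rDNA pre-filter sees it;
        # the 5.8S 3'-end 14-mer is NOT embeddable: it carries an 11-nt
        # near-match (1 mismatch) to a 5'-adapter reverse complement and
        # would trip the artifact filter.
        repeat {
          # embedding the printed fragment can re-create adapter collisions
          # at the junctions, so the assembled unit is re-screened
          body <- .clean_transcript(586L, config)
          rdna <- paste0(substr(body, 1L, 300L), rrna_28s_fragment_14nt,
                         substr(body, 301L, 586L))
          if (!.contains_seed(rdna, config) &&
              !.is_adapter_artifact(rdna, config)) break
        }
        rows[[length(rows) + 1L]] <-
          data.frame(id = "rDNA_repeating_unit_synthetic",
                     category = "rRNA", sequence = rdna)
      }
      if (cat == "scRNA") {
        repeat {
          tail <- .random_rna(63L)
          y4 <- paste0(y4_fragment_31nt, tail)
          if (!.contains_seed(y4, config) && !.is_adapter_artifact(y4, config))
            break
        }
        rows[[length(rows) + 1L]] <-
          data.frame(id = "Y4_RNA_synthetic", category = "scRNA",
                     sequence = y4)
      }
      for (i in seq_len(transcripts_per_category)) {
        rows[[length(rows) + 1L]] <-
          data.frame(id = sprintf("%s_synthetic_%d", cat, i), category = cat,
                     sequence = .clean_transcript(transcript_length, config))
      }
    }
    refs <- do.call(rbind, rows)
    rownames(refs) <- NULL
    structure(refs,
              rdna_unit = if ("rRNA" %in% cats)
                "rDNA_repeating_unit_synthetic" else NA_character_,
              class = c("reference_set", "data.frame"))
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d transcripts, %d categories (rDNA unit: %s)\n",
              nrow(x), length(unique(x$category)), attr(x, "rdna_unit")))
  print(table(x$category))
  invisible(x)
}

#' Write / read a reference set as FASTA plus category table
#'
#' @param refs A `reference_set`.
#' @param fasta,tsv File paths for the transcript FASTA and the
#'   `transcript_id`/`category` table.
#' @return `write_reference_set()` returns the paths invisibly;
#'   `read_reference_set()` returns a `reference_set`.
#' @export
write_reference_set <- function(refs, fasta, tsv) {
  seqs <- Biostrings::RNAStringSet(refs$sequence)
  names(seqs) <- refs$id
  Biostrings::writeXStringSet(seqs, fasta)
  write.table(data.frame(transcript_id = refs$id, category = refs$category),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_reference_set
#' @param rdna_unit Transcript id of the rDNA repeating unit (default:
#'   taken from the ids when one matches `"rDNA"`).
#' @export
read_reference_set <- function(fasta, tsv, rdna_unit = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)
  ann <- read.delim(tsv, stringsAsFactors = FALSE)
  stopifnot(all(names(seqs) %in% ann$transcript_id))
  if (!all(ann$category %in% rna_categories))
    stop("annotation table names categories outside the fixed 10")
  refs <- data.frame(id = names(seqs),
                     category = ann$category[match(names(seqs),
                                                   ann$transcript_id)],
                     sequence = canonicalize(as.character(seqs)))
  if (is.null(rdna_unit)) {
    hit <- grep("rDNA", refs$id, value = TRUE)
    rdna_unit <- if (length(hit)) hit[1L] else NA_character_
  }
  structure(refs, rdna_unit = rdna_unit,
            class = c("reference_set", "data.frame"))
}

# Deterministic largest-remainder integer allocation of `n` over weights.
.largest_remainder <- function(n, w) {
  if (sum(w) == 0) stop("weights sum to zero")
  x <- n * w / sum(w)
  fl <- floor(x)
  rem <- n - sum(fl)
  if (rem > 0) {
    o <- order(-(x - fl), seq_along(x))
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# Build the per-length species pool with planted differential species and
# designated planted-null high-abundance controls. Uses the RNG.
.build_species_pool <- function(spec, refs, config) {
  lens <- 5:45
  lw <- rep(1, length(lens))
  lw[match(spec$length_peaks$length, lens)] <-
    lw[match(spec$length_peaks$length, lens)] + spec$length_peaks$weight
  K <- spec$species_per_length
  cats <- names(spec$category_mix)[spec$category_mix > 0]
  cat_p <- spec$category_mix[cats]
  barcodes <- spec$barcode_table
  prefix <- paste0(config$remnant, barcodes)

  seed_pat <- substr(config$adapter3, 1L, config$seed_len)
  pool <- list()
  for (L in lens) {
    acc_seq <- character(0); acc_cat <- character(0); acc_tr <- character(0)
    tries <- 0L
    while (length(acc_seq) < K) {
      tries <- tries + 1L
      if (tries > 50L) stop("could not draw clean species at length ", L)
      nb <- 2L * (K - length(acc_seq))
      cat_d <- sample(cats, nb, replace = TRUE, prob = cat_p)
      tr_d <- character(nb); seq_d <- character(nb)
      for (i in seq_len(nb)) {
        cand <- refs[refs$category == cat_d[i], , drop = FALSE]
        tr <- cand[sample.int(nrow(cand), 1L), ]
        start <- sample.int(nchar(tr$sequence) - L + 1L, 1L)
        tr_d[i] <- tr$id
        seq_d[i] <- substr(tr$sequence, start, start + L - 1L)
      }
      # guard the junctions: the trimming seed must resolve at the true
      # adapter position for every barcode
      reads <- paste0(rep(prefix, nb), rep(seq_d, each = length(prefix)),
                      config$adapter3)
      m <- Biostrings::vmatchPattern(seed_pat,
                                     Biostrings::RNAStringSet(reads),
                                     max.mismatch = config$seed_mismatch)
      left <- vapply(Biostrings::startIndex(m),
                     function(z) if (length(z)) min(z) else NA_integer_,
                     integer(1))
      clean_read <- !is.na(left) & left == config$remnant_len + L + 1L
      clean <- colSums(matrix(!clean_read, nrow = length(prefix))) == 0L
      for (i in which(clean)) {
        if (length(acc_seq) >= K) break
        if (seq_d[i] %in% acc_seq) next
        acc_seq <- c(acc_seq, seq_d[i])
        acc_cat <- c(acc_cat, cat_d[i])
        acc_tr <- c(acc_tr, tr_d[i])
      }
    }
    pool[[length(pool) + 1L]] <- data.frame(
      sequence = acc_seq, length = L, rank = seq_len(K),
      category = acc_cat, transcript = acc_tr, weight = seq_len(K)^-1.3)
  }
  pool <- do.call(rbind, pool)
  pool$length_weight <- lw[match(pool$length, lens)]

  # planted differential species: rank-2 species of the first
  # n_planted_differential peak strata, directions alternating more/less
  pool$direction <- NA_character_
  planted_lengths <- spec$length_peaks$length[
    seq_len(spec$n_planted_differential)]
  if (spec$n_planted_differential > 0) {
    dirs <- rep(c("more", "less"),
                length.out = spec$n_planted_differential)
    for (i in seq_along(planted_lengths)) {
      sel <- pool$length == planted_lengths[i] & pool$rank == 2L
      pool$direction[sel] <- dirs[i]
    }
  }
  # planted-null high-abundance controls: rank-1 species of the remaining
  # peak strata (frequencies identical in expectation across groups)
  null_lengths <- setdiff(spec$length_peaks$length, planted_lengths)
  pool$null_control <- pool$length %in% null_lengths & pool$rank == 1L
  list(pool = pool, length_weights = setNames(lw, lens), lengths = lens)
}

#' Simulate per-sample insert count tables with planted truth
#'
#' The count-level core of the generator: builds the seeded species pool
#' (per-length species drawn from the reference transcripts according to
#' the category mixture, with Zipf-like within-stratum abundances), plants
#' the differential species (group-B within-stratum weight multiplied or
#' divided by the fold change) and the null high-abundance controls, and
#' allocates each library's insert reads -- multinomially (default) or as
#' deterministic expected counts (`count_model = "expected"`).
#'
#' @param spec A [synthetic_spec()].
#' @param refs A `reference_set`; default [make_reference_set()] of the
#'   spec.
#' @return A list of class `simulated_counts` with `samples` (list of
#'   [sample_library()]), `truth` (list: `differential_species`,
#'   `null_species`, `per_sample_insert_counts` matrix, `n_artifacts` per
#'   sample), `pool`, and the `spec`.
#' @export
simulate_counts <- function(spec, refs = make_reference_set(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  config <- adapter_config()
  n_art <- as.integer(round(spec$artifact_fraction * spec$reads_per_sample))
  n_insert <- spec$reads_per_sample - n_art
  if (n_insert <= 0L && spec$n_planted_differential > 0L)
    stop("no insert reads available but planted differentials requested")
  with_seed(spec$seed + 1L, {
    ps <- .build_species_pool(spec, refs, config)
    pool <- ps$pool
    counts <- matrix(0L, nrow = nrow(pool), ncol = spec$n_samples,
                     dimnames = list(pool$sequence, spec$sample_ids))
    for (j in seq_len(spec$n_samples)) {
      grp <- spec$group_assignment[j]
      w <- pool$weight
      if (grp == "B" && spec$n_planted_differential > 0) {
        w <- ifelse(is.na(pool$direction), w,
                    ifelse(pool$direction == "more",
                           w * spec$differential_fold_change,
                           w / spec$differential_fold_change))
      }
      if (n_insert > 0L) {
        lw <- ps$length_weights
        len_alloc <- if (spec$count_model == "multinomial")
          as.integer(rmultinom(1L, n_insert, lw))
        else .largest_remainder(n_insert, lw)
        for (k in seq_along(ps$lengths)) {
          if (len_alloc[k] == 0L) next
          sel <- which(pool$length == ps$lengths[k])
          counts[sel, j] <- if (spec$count_model == "multinomial")
            as.integer(rmultinom(1L, len_alloc[k], w[sel]))
          else .largest_remainder(len_alloc[k], w[sel])
        }
      }
    }
    samples <- lapply(seq_len(spec$n_samples), function(j) {
      cnt <- counts[counts[, j] > 0L, j]
      sample_library(spec$sample_ids[j], cnt,
                     group = spec$group_assignment[[j]],
                     source = spec$source)
    })
    names(samples) <- spec$sample_ids
    truth <- list(
      differential_species = pool[!is.na(pool$direction),
                                  c("sequence", "length", "direction")],
      null_species = pool[pool$null_control,
                          c("sequence", "length", "category")],
      per_sample_insert_counts = counts,
      n_artifacts = setNames(rep(n_art, spec$n_samples), spec$sample_ids))
    structure(list(samples = samples, truth = truth, pool = pool,
                   spec = spec), class = "simulated_counts")
  })
}

# 5'-adapter fragment inserts used as trimmable artifact reads: substrings
# of the sample's 5' adapter that still trim cleanly (the artifact filter,
# not the trimmer, must catch them). Returns `n` fragments cycling over
# the admissible start positions.
.artifact_fragments <- function(adapter5, bc, n, config, frag_len = 14L) {
  if (n <= 0L) return(character(0))
  starts <- seq_len(nchar(adapter5) - frag_len + 1L)
  frags <- substr(rep(adapter5, length(starts)), starts,
                  starts + frag_len - 1L)
  reads <- paste0(config$remnant, bc, frags, config$adapter3)
  m <- Biostrings::vmatchPattern(substr(config$adapter3, 1L, config$seed_len),
                                 Biostrings::RNAStringSet(reads),
                                 max.mismatch = config$seed_mismatch)
  left <- vapply(Biostrings::startIndex(m),
                 function(z) if (length(z)) min(z) else NA_integer_,
                 integer(1))
  frags <- frags[!is.na(left) & left == config$remnant_len + frag_len + 1L]
  frags[(seq_len(n) - 1L) %% length(frags) + 1L]
}

#' Emit barcoded raw reads with planted truth
#'
#' Expands the count-level simulation into one multiplexed raw read set:
#' each read is `[9-nt 5'-adapter remnant incl. barcode][insert][25-nt 3'
#' adapter]`, except the artifact reads -- half adapter dimers (empty
#' insert), half 5'-adapter fragments (trimmed normally but caught by the
#' artifact filter). Reads are emitted in DNA space (T), canonicalized back
#' to RNA by preprocessing. With `error_rate > 0`, uniform per-base
#' substitutions are applied to the emitted copies (the truth table keeps
#' the planted counts).
#'
#' @param spec A [synthetic_spec()].
#' @param refs A `reference_set`; default [make_reference_set()] of the
#'   spec.
#' @param dir Optional output directory; when given, writes
#'   `reads.fasta`/`reads.fastq`, `sample_sheet.tsv`, `truth.tsv`,
#'   `reference.fasta` and `reference_categories.tsv`.
#' @param format `"fasta"` (default) or `"fastq"` (constant quality).
#' @return Object of class `simulated_run`: `reads` (named character
#'   vector, DNA space), `sample_sheet` (sample_id, barcode, group,
#'   source), `truth` (as in [simulate_counts()], plus `artifact_reads`,
#'   the artifact read ids), `counts` (the `simulated_counts` object), and
#'   `files` when `dir` was given.
#' @export
simulate_libraries <- function(spec, refs = make_reference_set(spec),
                               dir = NULL, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  config <- adapter_config()
  sim <- simulate_counts(spec, refs)
  reads <- character(0)
  ids <- character(0)
  artifact_ids <- character(0)
  with_seed(spec$seed + 2L, {
    for (j in seq_len(spec$n_samples)) {
      sid <- spec$sample_ids[j]
      bc <- spec$barcode_table[[sid]]
      adapter5 <- paste0(.adapter5_body, bc)
      cnt <- sim$truth$per_sample_insert_counts[, j]
      inserts <- rep(rownames(sim$truth$per_sample_insert_counts), cnt)
      n_art <- sim$truth$n_artifacts[[sid]]
      n_dimer <- ceiling(n_art / 2)
      n_frag <- n_art - n_dimer
      art <- c(rep("", n_dimer),
               .artifact_fragments(adapter5, bc, n_frag, config))
      all_ins <- c(inserts, art)
      rd <- paste0(config$remnant, bc, all_ins, config$adapter3)
      if (spec$error_rate > 0) {
        rd <- vapply(rd, function(s) {
          v <- strsplit(s, "", fixed = TRUE)[[1]]
          hit <- runif(length(v)) < spec$error_rate
          if (any(hit))
            v[hit] <- vapply(v[hit], function(b)
              sample(setdiff(c("A", "C", "G", "U"), b), 1L), "")
          paste(v, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      rid <- sprintf("%s_read%06d", sid, seq_along(rd))
      reads <- c(reads, chartr("U", "T", rd))
      ids <- c(ids, rid)
      if (n_art > 0)
        artifact_ids <- c(artifact_ids,
                          rid[(length(rd) - n_art + 1L):length(rd)])
    }
  })
  names(reads) <- ids
  sheet <- data.frame(sample_id = spec$sample_ids,
                      barcode = spec$barcode_table[spec$sample_ids],
                      group = spec$group_assignment[spec$sample_ids],
                      source = spec$source, row.names = NULL)
  truth <- c(sim$truth, list(artifact_reads = artifact_ids))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    reads_file <- file.path(dir, paste0("reads.", format))
    xs <- Biostrings::DNAStringSet(unname(reads))
    names(xs) <- names(reads)
    if (format == "fastq") {
      Biostrings::writeXStringSet(
        xs, reads_file, format = "fastq",
        qualities = Biostrings::BStringSet(
          vapply(Biostrings::width(xs),
                 function(w) strrep("I", w), "")))
    } else {
      Biostrings::writeXStringSet(xs, reads_file)
    }
    sheet_file <- file.path(dir, "sample_sheet.tsv")
    write.table(sheet, sheet_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cm <- sim$truth$per_sample_insert_counts
    truth_long <- data.frame(
      sequence = rep(rownames(cm), ncol(cm)),
      sample_id = rep(colnames(cm), each = nrow(cm)),
      count = as.integer(cm), row.names = NULL)
    truth_file <- file.path(dir, "truth.tsv")
    write.table(truth_long[truth_long$count > 0L, ], truth_file,
                sep = "\t", quote = FALSE, row.names = FALSE)
    rf <- write_reference_set(refs, file.path(dir, "reference.fasta"),
                              file.path(dir, "reference_categories.tsv"))
    files <- c(reads = reads_file, sample_sheet = sheet_file,
               truth = truth_file, rf)
  }
  structure(list(reads = reads, sample_sheet = sheet, truth = truth,
                 counts = sim, spec = spec, files = files),
            class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf(paste0("<simulated_run> %d reads, %d samples, %d planted ",
                     "differential species, %d artifact reads\n"),
              length(x$reads), x$spec$n_samples,
              nrow(x$truth$differential_species),
              length(x$truth$artifact_reads)))
  invisible(x)
}
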