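# End-to-end orchestration: simulate (optional) -> preprocess -> annotate
# -> profile -> differential -> segregation -> sgRNA scan, with versioned
# TSV/JSON outputs and a parameter log. Identical config + seed implies
# byte-identical outputs.

#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Either a
#' synthetic spec (`simulate`) or the three input paths (`reads`,
#' `sample_sheet`, `reference_fasta` + `reference_tsv`) must be provided.
#'
#' @param out_dir Output directory for the report bundle.
#' @param simulate Optional [synthetic_spec()]; when given, input data are
#'   generated rather than read.
#' @param reads Path to a FASTA/FASTQ file of raw multiplexed reads.
#' @param sample_sheet Path to a TSV with `sample_id`, `barcode`, `group`,
#'   `source` (or a data frame).
#' @param reference_fasta,reference_tsv Reference transcripts and their
#'   category table.
#' @param N Top-N species per length per sample (default 5).
#' @param alpha Significance level (default 0.05).
#' @param lo,hi Analysis length window (defaults 5, 40).
#' @param max_mm Mismatch allowance for annotation (default 2).
#' @param annotate Run the annotation stage (default `TRUE`; it is the
#'   most expensive stage on large references).
#' @param case_group Group label treated as the case side (default
#'   `"B"`).
#' @param sgrna_targets Named character vector of target RNAs scanned
#'   against half-tRNA-type candidate guides (default: the bundled model
#'   target [rna_y_target]).
#' @param adapter Adapter configuration (default [adapter_config()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            reads = NULL, sample_sheet = NULL,
                            reference_fasta = NULL, reference_tsv = NULL,
                            N = 5L, alpha = 0.05, lo = 5L, hi = 40L,
                            max_mm = 2L, annotate = TRUE,
                            case_group = "B",
                            sgrna_targets = c(RNA_Y = rna_y_target),
                            adapter = adapter_config()) {
  if (is.null(simulate)) {
    for (f in c(reads, reference_fasta, reference_tsv))
      if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
    if (is.null(reads) || is.null(sample_sheet) ||
        is.null(reference_fasta) || is.null(reference_tsv))
      stop("either `simulate` or all of reads/sample_sheet/reference_* ",
           "must be given")
  } else stopifnot(inherits(simulate, "synthetic_spec"))
  stopifnot(N >= 1L, alpha > 0, alpha < 1, lo <= hi)
  structure(list(out_dir = out_dir, simulate = simulate, reads = reads,
                 sample_sheet = sample_sheet,
                 reference_fasta = reference_fasta,
                 reference_tsv = reference_tsv, N = as.integer(N),
                 alpha = alpha, lo = as.integer(lo), hi = as.integer(hi),
                 max_mm = as.integer(max_mm), annotate = annotate,
                 case_group = case_group, sgrna_targets = sgrna_targets,
                 adapter = adapter),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage behind one call and writes the report bundle:
#' read-fate accounting, per-sample length profiles and peaks, category
#' profiles, the full comparison table, the segregation report (JSON), and
#' the sgRNA candidate/complex tables. Any stage failure aborts with the
#' stage name; the accounting snapshot conserves raw read totals.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result` (invisibly): all stage
#'   outputs plus the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- .stage("synthetic_data", {
      refs <- make_reference_set(config$simulate)
      simulate_libraries(config$simulate, refs, dir = file.path(out, "input"))
    })
    reads <- sim$reads
    sheet <- sim$sample_sheet
    refs <- make_reference_set(config$simulate)  # seeded: same set as sim
  } else {
    sim <- NULL
    reads <- .stage("preprocess", {
      fmt <- if (grepl("\\.(fastq|fq)$", config$reads)) "fastq" else "fasta"
      xs <- Biostrings::readDNAStringSet(config$reads, format = fmt)
      setNames(as.character(xs), names(xs))
    })
    sheet <- if (is.data.frame(config$sample_sheet)) config$sample_sheet
             else read.delim(config$sample_sheet, stringsAsFactors = FALSE)
    refs <- read_reference_set(config$reference_fasta, config$reference_tsv)
  }

  pp <- .stage("preprocess",
               preprocess_reads(reads, sheet, config$adapter,
                                config$lo, config$hi))
  .write_tsv(pp$accounting, file.path(out, "accounting.tsv"))

  profiles <- .stage("profiling", lapply(pp$samples, length_profile,
                                         lo = config$lo, hi = config$hi))
  prof_df <- data.frame(
    length = as.integer(names(profiles[[1]])),
    vapply(profiles, as.integer, integer(length(profiles[[1]]))))
  .write_tsv(prof_df, file.path(out, "length_profiles.tsv"))
  peaks <- lapply(profiles, find_peaks)
  .write_tsv(data.frame(sample_id = rep(names(peaks), lengths(peaks)),
                        peak_length = unlist(peaks, use.names = FALSE)),
             file.path(out, "length_peaks.tsv"))

  cat_profiles <- NULL
  if (config$annotate) {
    cat_profiles <- .stage("reference_annotation", {
      idx <- annotation_index(refs)
      lapply(pp$samples, function(s)
        category_profile(annotate_library(s, idx, config$max_mm)))
    })
    cp_df <- data.frame(category = rna_categories,
                        vapply(cat_profiles, as.numeric,
                               numeric(length(rna_categories))))
    .write_tsv(cp_df, file.path(out, "category_profiles.tsv"))
  }

  grouping <- setNames(sheet$group, sheet$sample_id)
  comparison <- .stage("differential_abundance",
                       significant_species(pp$samples, grouping,
                                           N = config$N,
                                           alpha = config$alpha,
                                           case_group = config$case_group,
                                           lo = config$lo, hi = config$hi))
  .write_tsv(as.data.frame(comparison), file.path(out, "comparisons.tsv"))

  seg <- .stage("segregation_stat", {
    seqs <- comparing_set(pp$samples, config$N, config$lo, config$hi)
    tab <- species_frequency_table(pp$samples, seqs, config$lo, config$hi)
    case_ids <- sheet$sample_id[sheet$group == config$case_group]
    other_ids <- setdiff(sheet$sample_id, case_ids)
    if (length(case_ids) != length(other_ids))
      stop("balanced bipartitions need equal group sizes")
    segregation_test(tab, list(side_a = other_ids, side_b = case_ids),
                     alpha = config$alpha)
  })
  jsonlite::write_json(
    list(counts = as.list(seg$counts), s_case = seg$s_case,
         s_other = seg$s_other, n = seg$n, B = seg$B,
         expected = seg$expected, p_point = seg$p_point,
         p_upper_tail = seg$p_upper_tail, case_rank = seg$case_rank),
    file.path(out, "segregation.json"), auto_unbox = TRUE, digits = NA)

  sgrna <- .stage("sgrna_structure", {
    sig <- comparison$sequence[comparison$significant]
    classes <- lapply(sig, classify_sgrna)
    cand <- data.frame(sequence = sig, length = nchar(sig),
                       classes = vapply(classes, paste, "", collapse = ","))
    cx_rows <- list()
    for (g in sig[vapply(classes, function(cl) "half_tRNA" %in% cl, TRUE)]) {
      for (tn in names(config$sgrna_targets)) {
        cxs <- find_target_sites(g, config$sgrna_targets[[tn]])
        if (length(cxs)) {
          cv <- predict_cleavage(cxs[[1]])
          cx_rows[[length(cx_rows) + 1L]] <- data.frame(
            guide = g, target = tn, duplex_bp = cxs[[1]]$duplex_bp,
            discriminator = cxs[[1]]$discriminator,
            cleavage_after = cv$position, len5 = cv$len5, len3 = cv$len3)
        }
      }
    }
    list(candidates = cand,
         complexes = if (length(cx_rows)) do.call(rbind, cx_rows)
                     else data.frame())
  })
  .write_tsv(sgrna$candidates, file.path(out, "sgrna_candidates.tsv"))
  .write_tsv(sgrna$complexes, file.path(out, "sgrna_complexes.tsv"))

  log_lines <- c(
    "sgrnaseg pipeline run",
    sprintf("N=%d alpha=%g window=%d-%d max_mm=%d case_group=%s",
            config$N, config$alpha, config$lo, config$hi, config$max_mm,
            config$case_group),
    if (!is.null(config$simulate))
      sprintf("synthetic seed=%d reads_per_sample=%d count_model=%s",
              config$simulate$seed, config$simulate$reads_per_sample,
              config$simulate$count_model),
    sprintf("raw_reads=%d kept=%d", pp$n_reads,
            sum(pp$accounting$kept)))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(structure(list(
    preprocessed = pp, profiles = profiles, peaks = peaks,
    category_profiles = cat_profiles, comparison = comparison,
    segregation = seg, sgrna = sgrna, simulated = sim,
    out_dir = out), class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  samples: %d | kept reads: %d\n",
              length(x$preprocessed$samples),
              sum(x$preprocessed$accounting$kept)))
  cat(sprintf("  comparing sequences: %d | significant: %d\n",
              nrow(x$comparison), sum(x$comparison$significant)))
  cat(sprintf("  segregation: S_case=%d E=%.4g P=%.3g (rank %d)\n",
              x$segregation$s_case, x$segregation$expected,
              x$segregation$p_point, x$segregation$case_rank))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
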