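# Synthetic-data generator: reference fabrication, planted truth, and
# determinism.

test_that("synthetic_spec validates its invariants", {
  expect_s3_class(synthetic_spec(seed = 1), "synthetic_spec")
  expect_error(synthetic_spec(seed = 1, category_mix = c(foo = 1)),
               "outside the fixed 10")
  bad_mix <- c(mRNA = 0.5, tRNA = 0.4)
  expect_error(synthetic_spec(seed = 1, category_mix = bad_mix), "sum to 1")
  expect_error(synthetic_spec(seed = 1, differential_fold_change = 1),
               "exceed 1")
  expect_error(synthetic_spec(seed = 1, artifact_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(seed = 1,
                              length_peaks = data.frame(length = 50,
                                                        weight = 1)),
               "\\[5, 45\\]")
  expect_error(synthetic_spec(seed = 1,
                              barcode_table = setNames(rep("GAAA", 6),
                                                       paste0("S", 1:6))),
               "distinct")
})

test_that("reference set covers the requested categories", {
  spec <- synthetic_spec(seed = 3)
  refs <- make_reference_set(spec)
  expect_setequal(unique(refs$category), rna_categories)
  expect_false(anyDuplicated(refs$id) > 0)
  expect_identical(attr(refs, "rdna_unit"), "rDNA_repeating_unit_synthetic")

  # degenerate mix: only tRNA transcripts
  spec_t <- synthetic_spec(seed = 3,
                           category_mix = c(tRNA = 1))
  refs_t <- make_reference_set(spec_t)
  expect_identical(unique(refs_t$category), "tRNA")
  expect_true(is.na(attr(refs_t, "rdna_unit")))
})

test_that("the Y4 surrogate starts with the printed 31-mer and the rDNA
           unit carries the 28S fragment", {
  refs <- make_reference_set(synthetic_spec(seed = 5))
  y4 <- refs$sequence[refs$id == "Y4_RNA_synthetic"]
  expect_identical(nchar(y4), 94L)
  expect_identical(substr(y4, 1, 31), y4_fragment_31nt)
  rdna <- refs$sequence[refs$id == "rDNA_repeating_unit_synthetic"]
  expect_true(grepl("CGCGACCUCAGAUC", rdna, fixed = TRUE))
})

test_that("fixed seed gives byte-identical outputs", {
  spec <- synthetic_spec(seed = 11, reads_per_sample = 500L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  refs <- make_reference_set(spec)
  r1 <- simulate_libraries(spec, refs, dir = d1)
  r2 <- simulate_libraries(spec, refs, dir = d2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  expect_identical(readLines(file.path(d1, "reads.fasta")),
                   readLines(file.path(d2, "reads.fasta")))
  expect_identical(make_reference_set(spec), refs)
})

test_that("truth counts account for every non-artifact read", {
  spec <- synthetic_spec(seed = 7, reads_per_sample = 2000L)
  run <- simulate_libraries(spec)
  n_art <- sum(run$truth$n_artifacts)
  expect_identical(sum(run$truth$per_sample_insert_counts) + n_art,
                   length(run$reads))
  expect_identical(length(run$truth$artifact_reads), n_art)
  expect_true(all(run$truth$artifact_reads %in% names(run$reads)))
  # every planted differential sequence occurs in at least one sample
  planted <- run$truth$differential_species$sequence
  expect_true(all(rowSums(
    run$truth$per_sample_insert_counts[planted, , drop = FALSE]) > 0))
})

test_that("expected-count model is deterministic and conserves depth", {
  spec <- synthetic_spec(seed = 9, count_model = "expected")
  sc <- simulate_counts(spec)
  cm <- sc$truth$per_sample_insert_counts
  n_art <- round(spec$artifact_fraction * spec$reads_per_sample)
  expect_true(all(colSums(cm) == spec$reads_per_sample - n_art))
  # samples in the same group receive identical allocations
  expect_identical(cm[, "S1"], cm[, "S2"])
  expect_identical(cm[, "S4"], cm[, "S5"])
  # planted 'more' species are boosted in group B
  more <- subset(sc$truth$differential_species, direction == "more")$sequence
  expect_true(all(cm[more, "S4"] > cm[more, "S1"]))
  less <- subset(sc$truth$differential_species, direction == "less")$sequence
  expect_true(all(cm[less, "S4"] < cm[less, "S1"]))
})

test_that("insert-length histogram matches the planted peak weights", {
  # chi-square goodness of fit at 1e5 inserts, alpha = 0.01
  spec <- synthetic_spec(seed = 13, reads_per_sample = 100000L,
                         n_samples = 1L, group_assignment = "A",
                         artifact_fraction = 0,
                         n_planted_differential = 0L)
  sc <- simulate_counts(spec)
  cm <- sc$truth$per_sample_insert_counts[, 1]
  lens <- nchar(names(cm))
  obs <- vapply(5:45, function(L) sum(cm[lens == L]), numeric(1))
  w <- rep(1, 41)
  pk <- spec$length_peaks
  w[match(pk$length, 5:45)] <- w[match(pk$length, 5:45)] + pk$weight
  expect_gt(chisq.test(obs, p = w / sum(w))$p.value, 0.01)
})

test_that("degenerate generator settings behave as specified", {
  # all-artifact library: preprocessing must drop 100%
  spec <- synthetic_spec(seed = 21, reads_per_sample = 400L,
                         artifact_fraction = 1,
                         n_planted_differential = 0L)
  run <- simulate_libraries(spec)
  pp <- preprocess_reads(run$reads, run$sample_sheet)
  expect_identical(sum(pp$accounting$kept), 0L)
  # planted differentials without insert reads is an error
  expect_error(simulate_counts(synthetic_spec(seed = 21,
                                              reads_per_sample = 100L,
                                              artifact_fraction = 1)),
               "planted differentials")
})
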