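# Preprocessing: canonicalization, demultiplexing, trimming, artifact
# removal, length window, and whole-run accounting.

cfg <- adapter_config()

test_that("canonicalize maps to uppercase RNA and rejects other alphabets", {
  expect_identical(canonicalize("acgt"), "ACGU")
  expect_identical(canonicalize("GGCUGGUCC"), "GGCUGGUCC")  # fixed point
  expect_identical(canonicalize(c("ACGN", "", "ACG-U")),
                   rep(NA_character_, 3))
})

test_that("demultiplex resolves unique matches and flags ambiguity", {
  table6 <- setNames(cfg$barcodes, paste0("S", 1:6))
  expect_identical(demultiplex("GAAA", table6)[1], "S1")
  expect_identical(demultiplex("GCAA", table6)[1], "UNASSIGNED")
  # one mismatch to both GAAA and CAAA: ambiguous, hence unassigned
  two <- c(S1 = "GAAA", S5 = "CAAA")
  d_ga <- sum(strsplit("AAAA", "")[[1]] != strsplit("GAAA", "")[[1]])
  d_ca <- sum(strsplit("AAAA", "")[[1]] != strsplit("CAAA", "")[[1]])
  expect_identical(c(d_ga, d_ca), c(1L, 1L))  # oracle: enumerate distances
  res <- demultiplex("AAAA", two, max_bc_mismatch = 1)
  expect_identical(res[1], "UNASSIGNED")
  expect_true(attr(res, "ambiguous")[1])
  # non-ambiguous 1-mismatch rescue works
  expect_identical(demultiplex("GAAC", two, max_bc_mismatch = 1)[1], "S1")
  expect_error(demultiplex("GAAA", c(S1 = "GAAA", S2 = "GAAA")), "distinct")
})

test_that("trim_adapters performs exact string surgery on constructed reads", {
  read <- paste0(cfg$remnant, "GAAA", "GGCUGGU", cfg$adapter3)
  expect_identical(as.character(trim_adapters(read, cfg)), "GGCUGGU")

  dimer <- paste0(cfg$remnant, "GAAA", cfg$adapter3)
  tr <- trim_adapters(dimer, cfg)
  expect_true(is.na(tr[1]))
  expect_identical(attr(tr, "reason")[1], "adapter_dimer")

  # two mismatches in the seed exceed the tolerance
  seed <- substr(cfg$adapter3, 1, cfg$seed_len)
  bad_seed <- paste0("GG", substr(seed, 3, cfg$seed_len),
                     substr(cfg$adapter3, cfg$seed_len + 1, 25))
  read2 <- paste0(cfg$remnant, "GAAA", "GGAUCCGAU", bad_seed)
  tr2 <- trim_adapters(read2, cfg)
  expect_identical(attr(tr2, "reason")[1], "no_adapter")

  # one mismatch in the seed is tolerated
  one_mm <- paste0("G", substr(cfg$adapter3, 2, 25))
  read3 <- paste0(cfg$remnant, "GAAA", "GGAUCCGAU", one_mm)
  expect_identical(as.character(trim_adapters(read3, cfg)), "GGAUCCGAU")
})

test_that("artifact filter drops 5'-adapter-derived inserts only", {
  expect_identical(filter_artifacts(substr(cfg$adapters5[[1]], 3, 14), cfg),
                   "DROP")  # 12-nt exact adapter substring
  expect_identical(filter_artifacts(y4_fragment_31nt, cfg), "KEEP")
  expect_identical(filter_artifacts("ACGUACG", cfg), "KEEP")  # below 10 nt
  # reverse-complement matches are caught too
  rc <- reverse_complement_rna(substr(cfg$adapters5[[2]], 5, 17))
  expect_identical(filter_artifacts(rc, cfg), "DROP")
})

test_that("fast artifact lookup agrees with the diagonal-scan oracle", {
  targets <- c(cfg$adapters5,
               vapply(cfg$adapters5, reverse_complement_rna, ""))
  tsplit <- lapply(targets, function(t) strsplit(t, "", fixed = TRUE)[[1]])
  set.seed(101)
  for (i in 1:300) {
    if (runif(1) < 0.4) {
      a <- sample(cfg$adapters5, 1)
      st <- sample(1:(nchar(a) - 13), 1)
      core <- substr(a, st, st + sample(9:14, 1))
      v <- strsplit(core, "", fixed = TRUE)[[1]]
      if (runif(1) < 0.5) {
        p <- sample(length(v), 1)
        v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1)
      }
      s <- paste0(random_rna(sample(0:5, 1)), paste(v, collapse = ""),
                  random_rna(sample(0:5, 1)))
    } else {
      s <- random_rna(sample(5:45, 1))
    }
    slow <- nchar(s) >= cfg$artifact_min_match &&
      sgrnaseg:::.local_match_scan(s, tsplit, cfg$artifact_min_match,
                                   cfg$artifact_mismatch)
    expect_identical(sgrnaseg:::.is_adapter_artifact(s, cfg), slow,
                     label = paste("insert", s))
  }
})

test_that("length window keeps 5-40 nt and honours custom bounds", {
  expect_identical(length_select(strrep("A", 31)), "KEEP")
  expect_identical(length_select(strrep("A", 4)), "DROP")
  expect_identical(length_select(strrep("A", 41)), "DROP")
  expect_identical(length_select(strrep("A", 7), lo = 7, hi = 7), "KEEP")
  expect_error(length_select("ACGUA", lo = 10, hi = 5), "lo")
})

test_that("noise-free preprocessing is an exact round trip with conserved
           accounting", {
  spec <- synthetic_spec(seed = 31, reads_per_sample = 3000L)
  run <- simulate_libraries(spec)
  pp <- preprocess_reads(run$reads, run$sample_sheet)

  # conservation: every raw read lands in exactly one fate
  acct <- pp$accounting
  fates <- c("kept", "rejected_no_adapter", "rejected_adapter_dimer",
             "dropped_artifact", "dropped_length", "unassigned",
             "rejected_alphabet")
  expect_identical(sum(acct[, fates]), length(run$reads))
  expect_identical(acct$total, as.integer(rowSums(acct[, fates])))

  # exact recovery of the planted insert multiset (within the window)
  cm <- run$truth$per_sample_insert_counts
  for (s in colnames(cm)) {
    planted <- cm[cm[, s] > 0L, s]
    planted <- planted[nchar(names(planted)) <= 40]
    got <- pp$samples[[s]]$counts
    expect_identical(sort(names(got)), sort(names(planted)))
    expect_true(all(got[names(planted)] == planted))
  }

  # artifact reads are dropped at exactly the planted fraction
  dropped <- acct$rejected_adapter_dimer + acct$dropped_artifact
  expect_identical(sum(dropped), sum(run$truth$n_artifacts))
})

test_that("the artifact filter can be switched off per sample", {
  spec <- synthetic_spec(seed = 33, reads_per_sample = 1000L)
  run <- simulate_libraries(spec)
  off <- setNames(rep(FALSE, 6), paste0("S", 1:6))
  pp <- preprocess_reads(run$reads, run$sample_sheet,
                         artifact_filter = off)
  expect_identical(sum(pp$accounting$dropped_artifact), 0L)
})
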