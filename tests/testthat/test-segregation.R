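# Balanced bipartitions, the expected count, and the exact binomial point
# probability.

test_that("bipartition enumeration gives C(2m, m)/2 canonical splits", {
  expect_length(enumerate_bipartitions(paste0("S", 1:6)), 10L)
  expect_length(enumerate_bipartitions(paste0("S", 1:4)), 3L)
  expect_length(enumerate_bipartitions(paste0("S", 1:2)), 1L)
  expect_error(enumerate_bipartitions(paste0("S", 1:5)), "even")
  bps <- enumerate_bipartitions(paste0("S", 1:6))
  # canonical: every side_a contains the first id; sides partition the set
  expect_true(all(vapply(bps, function(b) "S1" %in% b$side_a, TRUE)))
  for (b in bps) {
    expect_length(intersect(b$side_a, b$side_b), 0L)
    expect_setequal(c(b$side_a, b$side_b), paste0("S", 1:6))
  }
  # no duplicates up to side exchange
  keys <- vapply(bps, function(b)
    paste(sort(c(paste(sort(b$side_a), collapse = ","),
                 paste(sort(b$side_b), collapse = ","))), collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("expected count reproduces the published arithmetic", {
  expect_equal(expected_count(79, 54), 13.3)
  expect_equal(expected_count(109, 141), 25.0)
  expect_equal(expected_count(0, 0), 0)
  expect_error(expected_count(1, 1, B = 0), "positive")
  expect_error(expected_count(-1, 0), "nonnegative")
})

test_that("binomial point probability is exact in log space", {
  expect_equal(binomial_point_probability(1, 2, 0.5), 0.5)
  expect_equal(binomial_point_probability(0, 0, 0.1), 1)
  # published PBMC statistic: k = 109 of n = 250 at p = 1/10
  expect_equal(signif(binomial_point_probability(109, 250, 0.1), 2), 4.2e-43)
  # plasma recomputation: mantissa 2.4 but exponent -44
  expect_equal(signif(binomial_point_probability(79, 133, 0.1), 2), 2.4e-44)
  expect_error(binomial_point_probability(3, 2, 0.5), "\\[0, n\\]")
  expect_error(binomial_point_probability(1, 2, 1.5), "\\[0, 1\\]")
  # edge probabilities do not produce 0 * log(0)
  expect_equal(binomial_point_probability(0, 5, 0), 1)
  expect_equal(binomial_point_probability(5, 5, 1), 1)
})

test_that("log-space pmf agrees with exact rational arithmetic", {
  # full k sweep against the exact big-integer oracle at p = 1/10
  for (n in c(10L, 133L, 250L, 300L)) {
    got <- binomial_point_probability(0:n, n, 0.1)
    want <- vapply(0:n, exact_binom_tenth, numeric(1), n = n)
    expect_lt(max(abs(got - want) / want), 1e-10)
  }
  # random (k, n, p) against the interleaved-product oracle
  set.seed(404)
  for (i in 1:200) {
    n <- sample(1:300, 1); k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(binomial_point_probability(k, n, p),
                 interleaved_binom(k, n, p), tolerance = 1e-10)
  }
})

test_that("pmf sums to one", {
  for (n in c(1L, 10L, 100L, 250L, 500L)) {
    expect_equal(sum(binomial_point_probability(0:n, n, 0.1)), 1,
                 tolerance = 1e-12)
    expect_equal(sum(binomial_point_probability(0:n, n, 0.5)), 1,
                 tolerance = 1e-12)
  }
})

test_that("segregation test assembles counts, E, and both probabilities", {
  spec <- synthetic_spec(seed = 53, count_model = "expected")
  sc <- simulate_counts(spec)
  seqs <- comparing_set(sc$samples)
  tab <- species_frequency_table(sc$samples, seqs)
  seg <- segregation_test(tab, default_case_bipartition())
  expect_s3_class(seg, "segregation_test")
  expect_identical(seg$B, 10L)
  expect_identical(seg$n, seg$s_case + seg$s_other)
  expect_equal(seg$expected, seg$n / 10)
  expect_equal(seg$p_point,
               binomial_point_probability(seg$s_case, seg$n, 0.1))
  expect_gte(seg$p_upper_tail, seg$p_point)
  # strong planted case-aligned effects put the case bipartition first
  expect_identical(seg$case_rank, 1L)
  expect_gte(seg$s_case, nrow(sc$truth$differential_species))
  # E is invariant under relabelling of non-case bipartitions: it only
  # depends on the total count
  expect_equal(expected_count(seg$s_case, seg$s_other), seg$expected)
  # side order of the case bipartition does not matter
  seg2 <- segregation_test(tab, list(side_a = c("S5", "S6", "S4"),
                                     side_b = c("S3", "S1", "S2")))
  expect_identical(seg2$case_index, seg$case_index)
  expect_error(segregation_test(tab, list(side_a = c("S1", "S2"),
                                          side_b = c("S3", "S4", "S5",
                                                     "S6"))),
               "balanced")
})

test_that("all-identical samples give zero counts and unit probability", {
  counts <- c(AAAAAAA = 30L, CCCCCCC = 10L)
  libs <- lapply(paste0("S", 1:6), sample_library, counts = counts)
  tab <- species_frequency_table(libs, names(counts))
  seg <- segregation_test(tab, default_case_bipartition())
  expect_true(all(seg$counts == 0L))
  expect_equal(seg$expected, 0)
  expect_equal(seg$p_point, 1)
})

test_that("label-permuted data leave the case bipartition unremarkable", {
  # with no planted effects the case count should not be an outlier
  spec <- synthetic_spec(seed = 59, n_planted_differential = 0L,
                         reads_per_sample = 4000L)
  sc <- simulate_counts(spec)
  seqs <- comparing_set(sc$samples)
  tab <- species_frequency_table(sc$samples, seqs)
  seg <- segregation_test(tab, default_case_bipartition())
  expect_gte(seg$case_rank, 1L)
  expect_lte(seg$s_case, max(seg$counts))
  # the case count lies inside the span of the other nine
  others <- seg$counts[-seg$case_index]
  expect_lte(seg$s_case, max(others) + max(3, 3 * stats::sd(others)))
})
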