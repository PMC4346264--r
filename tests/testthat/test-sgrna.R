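# Structural guide-RNA analysis: reverse complement, class rules, the
# half-tRNA fold search, target-site scanning, and cleavage prediction.

test_that("reverse complement is correct and involutive", {
  expect_identical(reverse_complement_rna("A"), "U")
  # both strings appear as the printed acceptor pairing strands
  expect_identical(reverse_complement_rna("GGCUGGUCC"), "GGACCAGCC")
  set.seed(505)
  for (i in 1:50) {
    x <- random_rna(sample(5:40, 1))
    expect_identical(reverse_complement_rna(reverse_complement_rna(x)), x)
  }
  expect_error(reverse_complement_rna("ACGT"), "RNA")
})

test_that("class windows and fold requirements assign sgRNA classes", {
  expect_true("heptamer" %in% classify_sgrna("ACGUACG"))
  # the published 14-nt 28S fragment has no >= 4 bp hairpin: linear guide
  expect_true(is.null(enumerate_stem_loops("CGCGACCUCAGAUC", 4:7, 3:11)))
  expect_true("linear14" %in% classify_sgrna("CGCGACCUCAGAUC"))
  # a 14-mer with a strong hairpin is not a linear guide
  hp <- "GGCGCGAAAGCGCC"
  expect_false(is.null(enumerate_stem_loops(hp, 4:7, 3:11)))
  expect_false("linear14" %in% classify_sgrna(hp))
  # the printed Y4 31-mer folds as a 5'-half-tRNA mimic
  expect_true("half_tRNA" %in% classify_sgrna(y4_fragment_31nt))
  # hook: 3' stem-loop preceded by a >= 7 nt free 5' segment
  hook <- paste0("ACUGAUA", "GGCGC", "GAAA", "GCGCC")
  expect_identical(nchar(hook), 21L)
  expect_true("hook" %in% classify_sgrna(hook))
  expect_error(classify_sgrna("ACG"), "5-40")
})

test_that("fold search maximises the stem and honours the arm constraint", {
  expect_null(fold_half_trna(strrep("A", 25)))  # no pairing possible
  # constructed 27-mer: 8-nt arm + GCGC + GAAA loop + GCGC + 7-nt tail
  s <- paste0("AAAAAAAA", "GCGC", "GAAA", "GCGC", "AAAAAAA")
  f <- fold_half_trna(s)
  expect_identical(f$acceptor_arm, 8L)
  expect_identical(f$stem_bp, 4L)
  expect_identical(f$loop_len, 4L)
  # oracle: exhaustive enumeration confirms it is the longest stem with
  # the 5'-most start among qualifying folds
  all_folds <- enumerate_stem_loops(s, 3:7, 3:11, min_start = 8L)
  best <- all_folds[order(-all_folds[, "stem"], all_folds[, "i"]), ,
                    drop = FALSE][1, ]
  expect_identical(f$stem_bp, as.integer(best[["stem"]]))
  expect_identical(f$stem_start5, as.integer(best[["i"]]))

  # the printed Y4 31-mer: the best fold leaves the 5' arm GGCUGGUCC free
  fy <- fold_half_trna(y4_fragment_31nt)
  expect_identical(fy$acceptor_arm, 9L)
  expect_identical(substr(y4_fragment_31nt, 1, fy$acceptor_arm),
                   "GGCUGGUCC")
  ory <- enumerate_stem_loops(y4_fragment_31nt, 3:7, 3:11, min_start = 8L)
  ory <- ory[order(-ory[, "stem"], ory[, "i"]), , drop = FALSE]
  expect_identical(fy$stem_bp, as.integer(ory[1, "stem"]))
  expect_identical(fy$stem_start5, as.integer(ory[1, "i"]))
  expect_error(fold_half_trna("ACGUACGU"), "20")
})

test_that("the Y4 31-mer finds exactly one complex on RNA-Y", {
  cx <- find_target_sites(y4_fragment_31nt, rna_y_target)
  expect_length(cx, 1L)
  top <- cx[[1]]
  expect_identical(top$duplex_bp, 9L)
  expect_identical(top$guide_positions, 1:9)
  expect_identical(top$target_positions, 29:37)
  expect_identical(top$discriminator, 38L)
  # oracle: guide[1..9] must be the reverse complement of target[29..37]
  expect_identical(reverse_complement_rna(substr(rna_y_target, 29, 37)),
                   substr(y4_fragment_31nt, 1, 9))
  # every reported pairing is a legal AU/GC/GU pair
  gv <- strsplit(top$guide, "")[[1]]
  tv <- strsplit(top$target, "")[[1]]
  prs <- paste0(gv[top$guide_positions],
                rev(tv[top$target_positions]))
  expect_true(all(prs %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
  cv <- predict_cleavage(top)
  expect_identical(cv$position, 38L)
  expect_identical(cv$len5, 38L)
  expect_identical(cv$len3, 8L)
  expect_false(cv$terminal)
  expect_identical(cv$len5 + cv$len3, nchar(rna_y_target))
})

test_that("target scanning handles empty and boundary cases", {
  # no 7-bp complement anywhere
  expect_length(find_target_sites(y4_fragment_31nt, strrep("C", 40)), 0L)
  # complement only, no discriminator 3' of the duplex and no T-arm room
  bare <- reverse_complement_rna(substr(y4_fragment_31nt, 1, 9))
  expect_length(find_target_sites(y4_fragment_31nt, bare), 0L)
  # guide without a half-tRNA fold is rejected up front
  expect_error(find_target_sites(strrep("A", 31), rna_y_target), "fold")
})

test_that("cleavage position is covariant with duplex translation", {
  # prepending one nucleotide to the target shifts the site by exactly one
  cx0 <- find_target_sites(y4_fragment_31nt, rna_y_target)[[1]]
  shifted <- paste0("A", rna_y_target)
  cx1 <- find_target_sites(y4_fragment_31nt, shifted)[[1]]
  expect_identical(cx1$discriminator, cx0$discriminator + 1L)
  expect_identical(predict_cleavage(cx1)$position,
                   predict_cleavage(cx0)$position + 1L)
  expect_identical(predict_cleavage(cx1)$len3, predict_cleavage(cx0)$len3)
})

test_that("a terminal discriminator is flagged and products still sum", {
  # truncate RNA-Y right after the discriminator
  trunc <- substr(rna_y_target, 1, 38)
  cx <- find_target_sites(y4_fragment_31nt, trunc)
  expect_length(cx, 1L)
  cv <- predict_cleavage(cx[[1]])
  expect_true(cv$terminal)
  expect_identical(cv$len3, 0L)
  expect_identical(cv$len5 + cv$len3, nchar(trunc))
})

test_that("scanning is exhaustive against a brute-force position scan", {
  ok_pair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  set.seed(606)
  tried <- 0L
  while (tried < 25L) {
    g <- random_rna(sample(26:40, 1))
    f <- fold_half_trna(g)
    if (is.null(f)) next
    tried <- tried + 1L
    t_str <- if (tried %% 3 == 0) {
      # plant a binding site to exercise the positive path
      site <- reverse_complement_rna(substr(g, 1, min(f$acceptor_arm, 9)))
      paste0(random_rna(20), site, random_rna(5))
    } else random_rna(sample(30:60, 1))
    got <- find_target_sites(g, t_str)
    # brute force: at every end position count the maximal duplex
    gv <- strsplit(g, "")[[1]]; tv <- strsplit(t_str, "")[[1]]
    want_e <- integer(0)
    for (e in seq_along(tv)) {
      L <- 0L
      while (L < min(f$acceptor_arm, e) && ok_pair(gv[L + 1L], tv[e - L]))
        L <- L + 1L
      if (L < 7L || e + 1L > length(tv)) next
      s0 <- e - L + 1L
      stems <- enumerate_stem_loops(t_str, 4:7, 5:9,
                                    min_start = max(1L, s0 - 30L))
      if (!is.null(stems))
        stems <- stems[stems[, "j"] + stems[, "stem"] - 1L <= s0 - 1L, ,
                       drop = FALSE]
      if (is.null(stems) || nrow(stems) == 0L) next
      want_e <- c(want_e, e)
    }
    got_e <- vapply(got, function(x) max(x$target_positions), integer(1))
    expect_setequal(got_e, want_e)
  }
})
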