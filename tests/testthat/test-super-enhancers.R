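test_that("stitching bridges gaps up to the threshold, inclusive", {
  peaks <- iv("chr1", 1, 2, score = 1)[0, ]
  near <- iv("chr1", c(1000, 14400), c(2000, 15400))   # 12,400 bp gap
  expect_equal(nrow(stitch_and_rank(near, peaks, stitch_gap = 12500)), 1)
  far <- iv("chr1", c(1000, 14600), c(2000, 15600))    # 12,600 bp gap
  expect_equal(nrow(stitch_and_rank(far, peaks, stitch_gap = 12500)), 2)
})

test_that("constituents fully inside a TSS-exclusion window are dropped", {
  cres <- iv("chr1", c(1000, 8000), c(2000, 9000))
  excl <- iv("chr1", 500, 2500)
  out <- stitch_and_rank(cres, iv("chr1", 1, 2, score = 1)[0, ],
                         stitch_gap = 100, tss_exclusion = excl)
  expect_equal(out[, c("start", "end")], data.frame(start = 8000, end = 9000))
  # partial overlap with the window is not enough to drop
  excl2 <- iv("chr1", 1500, 2500)
  expect_equal(nrow(stitch_and_rank(cres, iv("chr1", 1, 2, score = 1)[0, ],
                                    stitch_gap = 100, tss_exclusion = excl2)), 2)
})

test_that("region signal equals the prorated signal-sum oracle", {
  set.seed(31)
  cres <- random_intervals(30, 32, max_pos = 50000, max_w = 600)
  peaks <- random_intervals(40, 33, max_pos = 50000, max_w = 900)
  peaks$score <- runif(40, 1, 100)
  out <- stitch_and_rank(cres, peaks, stitch_gap = 500)
  for (i in seq_len(nrow(out)))
    expect_equal(out$signal[i], oracle_region_signal(out[i, ], peaks),
                 tolerance = 1e-9)
  expect_error(stitch_and_rank(cres, transform(peaks, score = -score)),
               "non-negative")
})

test_that("se_cutoff finds the hockey-stick elbow", {
  hs <- make_hockey_stick(100, 8, seed = 4)
  cut <- se_cutoff(hs$signals)
  expect_equal(sum(cut$is_super), 8)
  expect_equal(se_cutoff(c(1, 1, 1, 1, 100))$is_super,
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(se_cutoff(c(1, 2)), "insufficient")
  expect_error(se_cutoff(c(3, 2, 1)), "ascending")
  expect_warning(cut <- se_cutoff(rep(2, 10)), "constant")
  expect_false(any(cut$is_super))
  # strictly linear curve: every gap is ~0, no super-enhancers
  expect_warning(cut <- se_cutoff(seq(0, 1, length.out = 20)), "degenerate")
  expect_false(any(cut$is_super))
})

test_that("se_cutoff is invariant to affine rescaling of the signals", {
  hs <- make_hockey_stick(80, 6, seed = 9)
  base <- se_cutoff(hs$signals)
  scaled <- se_cutoff(hs$signals * 37.5 + 1200)
  expect_equal(scaled$cutoff_index, base$cutoff_index)
  expect_equal(scaled$is_super, base$is_super)
})

test_that("se_cutoff argmax agrees with an exhaustive index scan", {
  for (seed in 1:10) {
    set.seed(seed)
    s <- sort(rexp(50, 1 / 10))
    cut <- se_cutoff(s)
    x <- (seq_along(s) - 1) / (length(s) - 1)
    y <- (s - min(s)) / (max(s) - min(s))
    d <- x - y
    expect_equal(cut$cutoff_index, max(which(d == max(d))))
  }
})

test_that("se_consensus applies the k-of-n rule with merge-then-count", {
  se <- iv("chr1", 1000, 5000)
  other <- iv("chr1", 50000, 60000)
  sets <- c(replicate(4, se, simplify = FALSE),
            replicate(2, other, simplify = FALSE))
  out <- se_consensus(sets, k = 4)
  expect_equal(out[, c("chrom", "start", "end")], se)      # 4 of 6 retained
  expect_equal(nrow(se_consensus(sets, k = 5)), 0)
  expect_error(se_consensus(list(), 1), "empty")
  # per-base oracle on random sets
  sets2 <- lapply(1:5, function(r) random_intervals(10, 40 + r,
                                                    max_pos = 9000, max_w = 700))
  expect_equal(bases_of(se_consensus(sets2, 3), 10000),
               oracle_support_bases(sets2, 3, 10000))
})

test_that("se_diff inherits the any-overlap diff contract", {
  d <- se_diff(iv("chr1", 1, 2)[0, ], iv("chr1", 1000, 2000))
  expect_equal(nrow(d$gained), 1)
  d <- se_diff(iv("chr1", 100, 200), iv("chr1", 199, 300))
  expect_equal(nrow(d$stable), 2)
  control <- random_intervals(100, 61, max_pos = 2e5, min_w = 500, max_w = 5000)
  treated <- random_intervals(100, 62, max_pos = 2e5, min_w = 500, max_w = 5000)
  d <- se_diff(control, treated)
  oracle <- oracle_diff_labels(control, treated)
  expect_equal(nrow(d$lost), sum(!oracle$control_stable))
  expect_equal(nrow(d$gained), sum(!oracle$treated_stable))
})

test_that("tissue specificity needs 70% single-SE coverage of the query SE", {
  tm <- iv("chr1", 0, 10000)
  almost <- list(s1 = iv("chr1", 0, 6990))            # 69.9% covered
  expect_equal(se_tissue_specificity(tm, almost)$n_samples, 0)
  enough <- list(s1 = iv("chr1", 0, 7000))            # exactly 70%
  expect_equal(se_tissue_specificity(tm, enough)$n_samples, 1)
  containing <- list(s1 = iv("chr1", -0 , 20000), s2 = iv("chr1", 50000, 60000))
  out <- se_tissue_specificity(tm, containing)
  expect_equal(out$n_samples, 1)
  expect_equal(out$fraction_samples, 0.5)
  # two 40% SEs in one sample only count when stacking is enabled
  split_cov <- list(s1 = iv("chr1", c(0, 5000), c(4000, 9000)))
  expect_equal(se_tissue_specificity(tm, split_cov)$n_samples, 0)
  expect_equal(se_tissue_specificity(tm, split_cov, stacked = TRUE)$n_samples, 1)
})
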