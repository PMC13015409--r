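test_that("consensus_peaks keeps regions supported by at least k replicates", {
  r1 <- iv("chr1", 100, 200)
  r2 <- iv("chr1", 5000, 5100)
  r3 <- iv("chr1", 5050, 5150)
  expect_equal(nrow(consensus_peaks(list(r1, r2, r3), k = 2)), 1)  # 1-of-3 excluded
  same <- iv("chr1", 100, 200)
  out <- consensus_peaks(list(same, same, same), k = 2)
  expect_equal(out[, c("chrom", "start", "end")], same)
  expect_equal(out$n_support, 3)
  expect_error(consensus_peaks(list(), 1), "empty")
  expect_error(consensus_peaks(list(r1), 2), "k must be")
})

test_that("consensus_peaks matches the per-base support oracle on staggered peaks", {
  for (seed in 1:5) {
    reps <- lapply(1:3, function(r) random_intervals(15, seed * 10 + r,
                                                     max_pos = 9000, max_w = 400))
    for (k in 1:3) {
      got <- consensus_peaks(reps, k)
      expect_equal(bases_of(got, 10000), oracle_support_bases(reps, k, 10000),
                   info = paste("seed", seed, "k", k))
    }
  }
})

test_that("consensus_peaks retained bases are monotone decreasing in k", {
  reps <- lapply(1:4, function(r) random_intervals(20, 99 + r, max_pos = 9000))
  prev <- bases_of(consensus_peaks(reps, 1), 10000)
  for (k in 2:4) {
    cur <- bases_of(consensus_peaks(reps, k), 10000)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("diff_peaks labels by 1 bp any-overlap and partitions each side", {
  d <- diff_peaks(iv("chr1", 100, 200), iv("chr1", 1000, 1100)[0, ])
  expect_equal(nrow(d$lost), 1)
  expect_equal(nrow(d$gained) + nrow(d$stable), 0)
  # 1 bp overlap at the boundary counts as stable
  d <- diff_peaks(iv("chr1", 100, 200), iv("chr1", 199, 300))
  expect_equal(nrow(d$stable), 2)
  expect_equal(nrow(d$gained) + nrow(d$lost), 0)
  # book-ended intervals do not overlap
  d <- diff_peaks(iv("chr1", 100, 200), iv("chr1", 200, 300))
  expect_equal(nrow(d$gained), 1)
  expect_equal(nrow(d$lost), 1)
})

test_that("diff_peaks agrees with the O(n*m) brute-force labeller", {
  control <- random_intervals(200, 301, max_pos = 80000)
  treated <- random_intervals(200, 302, max_pos = 80000)
  d <- diff_peaks(control, treated)
  oracle <- oracle_diff_labels(control, treated)
  expect_equal(nrow(d$lost), sum(!oracle$control_stable))
  expect_equal(nrow(d$gained), sum(!oracle$treated_stable))
  key <- function(x) paste(x$chrom, x$start, x$end)
  expect_setequal(key(d$lost), key(control)[!oracle$control_stable])
  expect_setequal(key(d$gained), key(treated)[!oracle$treated_stable])
  # per-side partition
  expect_equal(sum(d$stable$side == "control") + nrow(d$lost), nrow(control))
  expect_equal(sum(d$stable$side == "treated") + nrow(d$gained), nrow(treated))
})

test_that("epigenetic changes bin activating/repressive events by TSS distance", {
  genes <- toy_genes()
  de <- data.frame(gene_id = "gA")
  # gained H3K27ac 1 kb from gA's TSS -> activating in the first bin
  ac <- diff_peaks(iv("chr1", 1, 2)[0, ], iv("chr1", 20900, 21100))
  me3 <- diff_peaks(iv("chr1", 1, 2)[0, ], iv("chr1", 1, 2)[0, ])
  out <- classify_epigenetic_changes(ac, me3, genes, de)
  first <- out[out$distance_bin == "<=10kb", ]
  expect_equal(first$n_activating, 1L)
  expect_equal(sum(out$n_repressive), 0L)
  # gained H3K27me3 at 50 kb -> repressive in the 10-100 kb bin
  me3 <- diff_peaks(iv("chr1", 1, 2)[0, ], iv("chr1", 69900, 70100))
  out <- classify_epigenetic_changes(ac, me3, genes, de)
  mid <- out[out$distance_bin == "10kb-100kb", ]
  expect_equal(mid$n_repressive, 1L)
  expect_error(
    classify_epigenetic_changes(ac, me3, genes, data.frame(gene_id = "nope")),
    "absent")
})

test_that("epigenetic-change summaries match a brute-force distance-bin oracle", {
  set.seed(42)
  genes <- toy_genes()
  de <- data.frame(gene_id = genes$gene_id)
  bins <- c(1e4, 1e5, 1e6)
  mk_diff <- function(seed) {
    g <- random_intervals(25, seed, max_pos = 9e5, max_w = 300)
    l <- random_intervals(25, seed + 1, max_pos = 9e5, max_w = 300)
    diff_peaks(l, g)  # treated-only peaks in g become gained, etc.
  }
  ac <- mk_diff(7); me3 <- mk_diff(19)
  out <- classify_epigenetic_changes(ac, me3, genes, de, bins)
  labels <- c("<=10kb", "10kb-100kb", "100kb-1Mb")
  oracle_count <- function(gene, events) {
    counts <- stats::setNames(rep(0L, 3), labels)
    tss <- genes$tss[genes$gene_id == gene]
    for (i in seq_len(nrow(events))) {
      d <- abs(floor((events$start[i] + events$end[i]) / 2) - tss)
      b <- which(d <= bins)[1]
      if (!is.na(b)) counts[b] <- counts[b] + 1L
    }
    counts
  }
  for (gene in genes$gene_id) {
    act <- oracle_count(gene, rbind(ac$gained[, 1:3], me3$lost[, 1:3]))
    rep_ <- oracle_count(gene, rbind(me3$gained[, 1:3], ac$lost[, 1:3]))
    sub <- out[out$gene_id == gene, ]
    expect_equal(stats::setNames(sub$n_activating, sub$distance_bin),
                 act[sub$distance_bin])
    expect_equal(stats::setNames(sub$n_repressive, sub$distance_bin),
                 rep_[sub$distance_bin])
  }
})
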