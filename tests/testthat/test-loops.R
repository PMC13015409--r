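test_that("two-anchor matching tests both pairings with 1 bp overlap", {
  a <- loop_table("chr1", 100, 200, "chr1", 5000, 5100)
  b <- loop_table("chr1", 150, 250, "chr1", 5050, 5150)
  expect_true(loops_match(a, b))
  # swapped anchors in one record still match (canonicalization)
  b_swapped <- loop_table("chr1", 5050, 5150, "chr1", 150, 250)
  expect_true(loops_match(a, b_swapped))
  # one anchor matching is not enough
  c_ <- loop_table("chr1", 150, 250, "chr1", 9000, 9100)
  expect_false(loops_match(a, c_))
  # padding can bridge near-misses
  d <- loop_table("chr1", 210, 300, "chr1", 5050, 5150)
  expect_false(loops_match(a, d))
  expect_true(loops_match(a, d, padding = 20))
})

test_that("loops_match is reflexive, symmetric, and equals the 4-way oracle", {
  la <- random_loops(20, seed = 71)
  lb <- random_loops(10, seed = 72)
  for (i in seq_len(nrow(la))) {
    expect_true(loops_match(la[i, ], la[i, ]))
    for (j in seq_len(nrow(lb))) {
      got <- loops_match(la[i, ], lb[j, ])
      expect_equal(got, loops_match(lb[j, ], la[i, ]))
      expect_equal(got, oracle_loops_match(la[i, ], lb[j, ]),
                   info = paste(i, j))
    }
  }
})

test_that("loop_consensus keeps loops present in at least k samples", {
  l <- loop_table("chr1", 1000, 3000, "chr1", 50000, 52000, name = "shared")
  uniq <- loop_table("chr1", 200000, 202000, "chr1", 500000, 502000,
                     name = "private")
  out <- loop_consensus(list(s1 = l, s2 = l, s3 = uniq), k = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$name, "shared")
  expect_equal(out$samples[[1]], c("s1", "s2"))
  expect_equal(nrow(loop_consensus(list(s1 = l, s2 = uniq), k = 2)), 0)
})

test_that("loop_consensus clusters by transitive matching with union spans", {
  # chain: A matches B, B matches C, A does not match C directly
  a <- loop_table("chr1", 1000, 2000, "chr1", 50000, 51000)
  b <- loop_table("chr1", 1900, 2900, "chr1", 50900, 51900)
  c_ <- loop_table("chr1", 2800, 3800, "chr1", 51800, 52800)
  expect_false(loops_match(a, c_))
  out <- loop_consensus(list(s1 = a, s2 = b, s3 = c_), k = 3)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start1, out$end1, out$start2, out$end2),
               c(1000, 3800, 50000, 52800))  # anchor-wise union span
  # monotone in k
  samples <- lapply(1:4, function(s) random_loops(30, 80 + s, max_pos = 3e5))
  names(samples) <- paste0("s", 1:4)
  prev <- nrow(loop_consensus(samples, 1))
  for (k in 2:4) {
    cur <- nrow(loop_consensus(samples, k))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("loop_diff partitions into stable, gained and lost", {
  a <- random_loops(15, seed = 91)
  b <- random_loops(15, seed = 92, max_pos = 5e5)
  # identical sets: all stable
  d <- loop_diff(a, a)
  expect_equal(nrow(d$gained) + nrow(d$lost), 0)
  expect_equal(sum(d$stable$side == "control"), nrow(a))
  # disjoint sets (different chromosome): all lost + all gained, with a
  # warning naming the unshared chromosomes
  far <- loop_table("chr2", 100, 200, "chr2", 5000, 5100, name = "far")
  w <- testthat::capture_warnings(d2 <- loop_diff(a, far))
  expect_true(any(grepl("chr2", w)))
  expect_equal(nrow(d2$lost), nrow(a))
  expect_equal(nrow(d2$gained), 1)
  expect_equal(nrow(d2$stable), 0)
})

test_that("anchor annotation labels every overlapping feature", {
  loops <- loop_table("chr1", c(1000, 8000), c(2000, 9000),
                      "chr1", c(50000, 60000), c(51000, 61000),
                      name = c("lp1", "lp2"))
  genes <- toy_genes()  # gB promoter 59500-62000 overlaps lp2 anchor2
  ctcf <- iv("chr1", c(1200, 50100), c(1400, 50300))
  variants <- data.frame(rsid = "rs1", chrom = "chr1", pos = 8500)
  ann <- annotate_anchors(loops, genes, cres_by_class = NULL, ctcf = ctcf,
                          variants = variants)
  expect_equal(ann$summary$ctcf_feet, c(2L, 0L))
  f <- ann$features
  expect_true(any(f$loop_id == "lp2" & f$feature_type == "promoter" &
                    f$feature_id == "gB"))
  expect_true(any(f$loop_id == "lp2" & f$feature_type == "variant" &
                    f$feature_id == "rs1" & f$anchor == 1))
})

test_that("anchor with two overlapping promoters collects both gene ids", {
  loops <- loop_table("chr1", 1000, 2000, "chr1", 18000, 60000, name = "wide")
  ann <- annotate_anchors(loops, toy_genes())
  prom <- ann$features[ann$features$feature_type == "promoter", ]
  expect_setequal(prom$feature_id, c("gA", "gB"))
})

test_that("anchor annotation matches a triple-loop overlap oracle", {
  loops <- random_loops(40, seed = 95, max_pos = 2e5)
  feats <- random_intervals(30, 96, max_pos = 2e5, max_w = 3000)
  ids <- sprintf("f%02d", seq_len(nrow(feats)))
  feats2 <- feats
  feats2$gene_id <- ids  # reuse the promoter channel for generic features
  genes_like <- data.frame(gene_id = ids, chrom = feats$chrom,
                           promoter_start = feats$start,
                           promoter_end = feats$end)
  ann <- annotate_anchors(loops, genes_like)
  got <- ann$features[, c("loop_id", "anchor", "feature_id")]
  oracle <- oracle_anchor_labels(loops, feats, ids)
  oracle$loop_id <- loops$name[oracle$loop]
  expect_setequal(paste(got$loop_id, got$anchor, got$feature_id),
                  paste(oracle$loop_id, oracle$anchor, oracle$feature_id))
})

test_that("cross-tissue sharing counts are invariant to tissue order", {
  tm <- random_loops(10, seed = 97)
  t1 <- tm[1:4, ]; t2 <- tm[3:7, ]; t3 <- random_loops(5, seed = 98, max_pos = 5e5)
  cats <- list(a = t1, b = t2, c = t3)
  out <- cross_tissue_sharing(tm, cats)
  out_rev <- cross_tissue_sharing(tm, rev(cats))
  expect_equal(out$n_tissues, out_rev$n_tissues)
  expect_equal(out$n_tissues[1], sum(sapply(cats, function(cc)
    any(sapply(seq_len(nrow(cc)), function(j) oracle_loops_match(tm[1, ], cc[j, ]))))))
})

test_that("top loop-change genes use an inclusive-tie upper quantile", {
  mk_ann <- function(counts) {
    # one gained loop per change event, promoter feature on anchor 1
    rows <- do.call(rbind, lapply(seq_along(counts), function(g)
      if (counts[g] > 0) data.frame(
        loop_id = sprintf("g%d_l%d", g, seq_len(counts[g])),
        anchor = 1L, feature_type = "promoter",
        feature_id = sprintf("gene%03d", g), stringsAsFactors = FALSE)))
    list(features = rows)
  }
  mk_diff <- function(counts) {
    ids <- unlist(lapply(seq_along(counts), function(g)
      if (counts[g] > 0) sprintf("g%d_l%d", g, seq_len(counts[g]))))
    n <- length(ids)
    gained <- loop_table("chr1", seq(1, by = 10000, length.out = n),
                         seq(3001, by = 10000, length.out = n),
                         "chr1", seq(500001, by = 10000, length.out = n),
                         seq(503001, by = 10000, length.out = n), name = ids)
    list(stable = gained[0, ], gained = gained, lost = gained[0, ])
  }
  counts <- c(50, rep(1, 99))
  out <- top_loop_change_genes(mk_diff(counts), mk_ann(counts), quantile = 0.05)
  # independent type-7 quantile on the positive-count distribution
  thr <- stats::quantile(counts, 0.95, names = FALSE)
  expect_setequal(out$gene_id[out$selected],
                  sprintf("gene%03d", which(counts >= thr)))
  # a spread of counts: only the top tail (with ties) survives
  counts2 <- c(rep(1, 90), rep(2, 6), 5, 5, 9, 12)
  out2 <- top_loop_change_genes(mk_diff(counts2), mk_ann(counts2), 0.05)
  thr2 <- stats::quantile(counts2, 0.95, names = FALSE)
  expect_setequal(out2$gene_id[out2$selected],
                  sprintf("gene%03d", which(counts2 >= thr2)))
  # quantile = 1 returns every gene with at least one change
  out3 <- top_loop_change_genes(mk_diff(counts2), mk_ann(counts2), 1)
  expect_equal(sum(out3$selected), length(counts2))
  # no changes at all
  empty <- mk_diff(c(2, 1))
  empty$gained <- empty$gained[0, ]
  out4 <- top_loop_change_genes(empty, list(features = mk_ann(c(2, 1))$features),
                                0.05)
  expect_equal(nrow(out4), 0)
})
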