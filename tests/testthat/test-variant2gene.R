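make_leads <- function(rsid, chrom, pos, trait = "IOP") {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, trait = trait,
             lead_rsid = rsid, r2 = 1, is_lead = TRUE,
             stringsAsFactors = FALSE)
}

test_that("LD expansion filters by r2 and the 1 Mb window", {
  leads <- make_leads("rsL", "chr1", 5e6)
  prox <- function(rsid, pos, r2) data.frame(
    rsid = rsid, chrom = "chr1", pos = pos, trait = "IOP",
    lead_rsid = "rsL", r2 = r2, stringsAsFactors = FALSE)
  tab <- rbind(prox("p_low", 5.1e6, 0.79),   # below threshold
               prox("p_ok", 5.2e6, 0.80),    # boundary retained
               prox("p_far", 6.2e6, 0.95))   # 1.2 Mb away
  out <- expand_ld(leads, tab)
  expect_setequal(out$rsid, c("rsL", "p_ok"))
  expect_error(expand_ld(leads, prox("x", 5e6, 0.9) |>
                           transform(lead_rsid = "unknown")), "unknown lead")
  # row-filter oracle on random tables
  set.seed(23)
  tab2 <- data.frame(rsid = sprintf("p%03d", 1:200), chrom = "chr1",
                     pos = round(runif(200, 3e6, 7e6)), trait = "IOP",
                     lead_rsid = "rsL", r2 = runif(200))
  out2 <- expand_ld(leads, tab2, r2_min = 0.6)
  keep <- tab2$r2 >= 0.6 & abs(tab2$pos - 5e6) <= 1e6
  expect_setequal(out2$rsid, c("rsL", tab2$rsid[keep]))
})

test_that("loop targets need variant and promoter in opposite anchors", {
  genes <- toy_genes()
  # anchor2 covers gB promoter; variant inside anchor1
  loops <- loop_table("chr1", 1000, 3000, "chr1", 59000, 61000, name = "lp")
  v_in_a1 <- make_leads("rs1", "chr1", 2000)
  out <- loop_targets(v_in_a1, loops, genes, loop_set = "resource")
  expect_equal(out[, c("rsid", "gene_id", "evidence")],
               data.frame(rsid = "rs1", gene_id = "gB", evidence = "lp"))
  # variant and promoter in the SAME anchor only: no assignment
  v_in_a2 <- make_leads("rs2", "chr1", 60000)
  expect_equal(nrow(loop_targets(v_in_a2,
                                 loop_table("chr1", 59000, 61000,
                                            "chr1", 200000, 202000,
                                            name = "lp2"),
                                 genes)), 0)
  # assignment is invariant to the stored anchor order
  swapped <- loop_table("chr1", 59000, 61000, "chr1", 1000, 3000, name = "lp")
  expect_equal(loop_targets(v_in_a1, swapped, genes, loop_set = "resource"),
               out)
})

test_that("SE targets require variant and promoter inside the same SE", {
  genes <- toy_genes()
  se <- iv("chr1", c(15000, 40000), c(25000, 48000))
  v <- make_leads(c("rs_in", "rs_adjacent"), "chr1", c(24000, 41000))
  out <- se_targets(v, se, genes)
  # rs_in shares SE1 with gA's promoter; rs_adjacent's SE2 has no promoter
  expect_equal(out$rsid, "rs_in")
  expect_equal(out$gene_id, "gA")
  # brute-force triple loop
  set.seed(67)
  ses <- random_intervals(15, 68, max_pos = 2e5, min_w = 2000, max_w = 20000)
  vs <- make_leads(sprintf("rv%02d", 1:30), "chr1",
                   sort(sample.int(2e5, 30)))
  got <- se_targets(vs, ses, genes)
  expected <- list()
  for (i in seq_len(nrow(vs))) for (s in seq_len(nrow(ses)))
    for (g in seq_len(nrow(genes))) {
      v_in <- vs$pos[i] >= ses$start[s] && vs$pos[i] < ses$end[s]
      p_ov <- genes$promoter_start[g] < ses$end[s] &&
        ses$start[s] < genes$promoter_end[g]
      if (v_in && p_ov)
        expected[[length(expected) + 1]] <- paste(vs$rsid[i], genes$gene_id[g])
    }
  expect_setequal(paste(got$rsid, got$gene_id), unique(unlist(expected)))
})

test_that("closest genes report all minimum-distance ties", {
  genes <- toy_genes()
  inside <- make_leads("rs_in", "chr1", 25000)
  out <- closest_genes(inside, genes)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$distance, 0)
  # equidistant between gA end (30000) and gB start (50000):
  # gaps are pos - 30000 and 50000 - pos - 1, equal at pos 39999.5 -> use
  # a constructed pair with exact 500 bp gaps
  g2 <- genes
  g2$start[2] <- 30501 + 500
  tie <- make_leads("rs_tie", "chr1", 30500)
  g2$end[1] <- 30000
  d <- closest_genes(tie, g2)
  expect_equal(d$distance, c(500, 500))
  expect_setequal(d$gene_id, c("gA", "gB"))
  expect_warning(out2 <- closest_genes(make_leads("rs_no", "chrZ", 100), genes),
                 "without genes")
  expect_true(is.na(out2$gene_id))
})

test_that("closest genes agree with an exhaustive distance scan", {
  set.seed(29)
  genes <- toy_genes()
  vs <- make_leads(sprintf("rc%04d", 1:1000), "chr1",
                   sample.int(150000, 1000))
  got <- closest_genes(vs, genes)
  for (i in seq_len(nrow(vs))) {
    oracle <- oracle_closest("chr1", vs$pos[i], genes)
    sub <- got[got$rsid == vs$rsid[i], ]
    expect_setequal(sub$gene_id, oracle$gene_id)
    expect_true(all(sub$distance == oracle$distance))
  }
})

test_that("SNP-compartment overlap uses half-open window membership", {
  win <- iv("chr1", c(0, 5e4), c(5e4, 1e5))
  shifted <- cbind(win, shift = c("toward_B", "toward_A"))
  v <- make_leads(c("r1", "r2", "r3"), "chr1", c(100, 50000, 2e5))
  out <- snp_compartment_overlap(v, shifted)
  # pos 50000 equals window 1's exclusive end: belongs to window 2
  expect_equal(out$shift, c("toward_B", "toward_A", "none"))
})

test_that("peri-SNP counts match a brute-force window scan", {
  set.seed(83)
  gained <- random_intervals(50, 84, max_pos = 2e5, max_w = 400)
  lost <- random_intervals(50, 85, max_pos = 2e5, max_w = 400)
  diffs <- list(H3K27ac = list(gained = gained, lost = lost))
  class(diffs$H3K27ac) <- "diff_peaks"
  vs <- make_leads(sprintf("rp%02d", 1:40), "chr1", sample.int(2e5, 40))
  out <- peri_snp_peak_changes(vs, diffs, radius = 5000)
  for (i in seq_len(nrow(vs))) {
    row <- out[out$rsid == vs$rsid[i], ]
    expect_equal(row$n_gained,
                 oracle_peri_counts(vs$pos[i], "chr1", gained, 5000))
    expect_equal(row$n_lost,
                 oracle_peri_counts(vs$pos[i], "chr1", lost, 5000))
  }
  # boundary: peak 6 kb away is outside a 5 kb radius
  d2 <- list(ATAC = list(gained = iv("chr1", 16000, 16500),
                         lost = iv("chr1", 1, 2)[0, ]))
  class(d2$ATAC) <- "diff_peaks"
  near <- peri_snp_peak_changes(make_leads("rx", "chr1", 10000), d2, 5000)
  expect_equal(near$n_gained, 0L)
  d2$ATAC$gained <- iv("chr1", 14000, 14500)  # 4 kb away
  near2 <- peri_snp_peak_changes(make_leads("rx", "chr1", 10000), d2, 5000)
  expect_equal(near2$n_gained, 1L)
})
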