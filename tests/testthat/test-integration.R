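test_that("regulatory calls match the rule on exhaustive small counts", {
  grid <- expand.grid(ge = 0:3, le = 0:3, gr = 0:3, lr = 0:3)
  got <- regulatory_call(grid$ge, grid$le, grid$gr, grid$lr)
  for (i in seq_len(nrow(grid))) {
    act <- grid$ge[i] + grid$lr[i]
    rep_ <- grid$le[i] + grid$gr[i]
    want <- if (act > 0 && rep_ == 0) "activating"
            else if (rep_ > 0 && act == 0) "repressive"
            else if (act > 0 && rep_ > 0) "mixed" else "none"
    expect_equal(got[i], want)
  }
  expect_equal(regulatory_call(1, 0, 0, 0), "activating")
  expect_equal(regulatory_call(1, 0, 1, 0), "mixed")
})

test_that("per-gene regulatory changes count promoter-partner loops", {
  gained <- loop_table("chr1", c(1000, 8000), c(2000, 9000),
                       "chr1", c(50000, 60000), c(51000, 61000),
                       name = c("lgA", "lgB"))
  lost <- loop_table("chr1", 20000, 21000, "chr1", 70000, 71000, name = "llC")
  diff <- list(stable = gained[0, ], gained = gained, lost = lost)
  feats <- data.frame(
    loop_id = c("lgA", "lgA", "lgB", "lgB", "llC", "llC"),
    anchor = c(1L, 2L, 1L, 2L, 1L, 2L),
    feature_type = c("enhancer", "promoter", "repressor", "promoter",
                     "repressor", "promoter"),
    feature_id = c("e1", "gene1", "r1", "gene2", "r2", "gene3"),
    stringsAsFactors = FALSE)
  out <- classify_regulatory_changes(diff, list(features = feats))
  expect_equal(out$call[out$gene_id == "gene1"], "activating")
  expect_equal(out$call[out$gene_id == "gene2"], "repressive")
  expect_equal(out$call[out$gene_id == "gene3"], "activating")  # lost repressor
  # promoter and partner on the same anchor must not count
  feats_same <- feats
  feats_same$anchor <- 1L
  out2 <- classify_regulatory_changes(diff, list(features = feats_same))
  expect_equal(nrow(out2), 0)
})

test_that("the 16 gene sets assemble independently", {
  cs <- synthetic_case()
  res <- cs$result
  sets <- res$gene_sets
  expect_length(sets, 16)
  expect_setequal(sets$de_genes, cs$manifest$de_genes)
  # empty DE table empties set 1, leaves the other 15 unchanged
  empty_de <- data.frame(gene_id = character(), log2fc = numeric(),
                         fdr = numeric())
  sets2 <- build_gene_sets(
    res$genes, empty_de, res$compartment_shifts, res$diff_peaks$ATAC,
    res$se_diff, res$cre_diff, res$enhancers, res$diff_peaks,
    list(diff = res$loop_diff,
         annotations = annotate_anchors(
           rbind(res$loop_diff$gained, res$loop_diff$lost), res$genes,
           list(enhancer = res$cres$control, repressor = res$cres$control,
                super_enhancer = res$se_union))),
    res$top_loop_genes$gene_id[res$top_loop_genes$selected])
  expect_length(sets2$de_genes, 0)
  expect_equal(sets2$atac_diff, sets$atac_diff)
  expect_equal(sets2$se_diff, sets$se_diff)
  expect_error(build_gene_sets(res$genes, NULL, res$compartment_shifts,
                               res$diff_peaks$ATAC, res$se_diff, res$cre_diff,
                               res$enhancers, res$diff_peaks, list(), character(0)),
               "de_genes")
  # a gene overlapping a gained SE and a lost H3K27ac peak joins both sets
  both <- intersect(sets$se_diff, sets$h3k27ac_diff)
  expect_true(all(both %in% sets$se_diff) && all(both %in% sets$h3k27ac_diff))
})

test_that("planted mark perturbations land their genes in the intended sets", {
  cs <- synthetic_case()
  sets <- cs$result$gene_sets
  man <- cs$manifest
  genes <- cs$result$genes
  for (mk in c("H3K27ac", "H3K4me1", "CTCF")) {
    truth <- man$diff_peaks[[mk]]
    # genes whose slot hosts a gained/lost background peak block carry
    # in-gene copies of the changed peaks, so they must appear in the set
    changed <- rbind(truth$gained, truth$lost)
    spans <- data.frame(chrom = genes$chrom,
                        start = pmin(genes$start, genes$promoter_start),
                        end = pmax(genes$end, genes$promoter_end))
    # the changed-slot genes: find genes within 30 kb upstream of peaks
    near <- unlist(lapply(seq_len(nrow(changed)), function(i) {
      hit <- genes$chrom == changed$chrom[i] &
        genes$end <= changed$start[i] & genes$end > changed$start[i] - 30000
      genes$gene_id[hit]
    }))
    expect_true(all(unique(near) %in% sets[[paste0(tolower(mk), "_diff")]]))
  }
})

test_that("hypergeometric ORA matches exact combinatorics", {
  # all 5 draws hit a 5-gene term in a 20-gene universe: p = 1/C(20,5)
  universe <- sprintf("u%02d", 1:20)
  term <- list(T1 = universe[1:5])
  out <- hypergeom_ora(universe[1:5], term, universe)
  expect_equal(out$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(out$k, 5)
  # zero hits: p = 1
  out0 <- hypergeom_ora(universe[6:10], term, universe)
  expect_equal(out0$p_value, 1)
  expect_error(hypergeom_ora(universe[1:2], term, character(0)), "empty universe")
  # term with no universe genes is skipped
  out_skip <- hypergeom_ora(universe[1:5], list(T1 = universe[1:5], T0 = "zz"),
                            universe)
  expect_equal(out_skip$term, "T1")
})

test_that("ORA p-values match draw enumeration for N <= 30", {
  set.seed(19)
  for (rep_ in 1:5) {
    N <- sample(10:30, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:min(8, N - 1), 1)
    universe <- sprintf("g%02d", seq_len(N))
    term <- list(T = universe[seq_len(K)])
    gene_set <- sample(universe, n)
    out <- hypergeom_ora(gene_set, term, universe)
    expect_equal(out$p_value, oracle_hyper_tail(N, K, n, out$k),
                 tolerance = 1e-12, info = paste(N, K, n))
  }
})

test_that("ORA p-values are invariant to relabeling genes", {
  universe <- sprintf("g%02d", 1:25)
  term <- list(T = universe[1:8])
  gene_set <- universe[c(1:4, 20:22)]
  p1 <- hypergeom_ora(gene_set, term, universe)$p_value
  relabel <- stats::setNames(sample(universe), universe)
  p2 <- hypergeom_ora(unname(relabel[gene_set]),
                      list(T = unname(relabel[term$T])),
                      unname(relabel[universe]))$p_value
  expect_equal(p1, p2)
})

test_that("BH FDR is monotone in sorted p order and never below p", {
  set.seed(37)
  for (i in 1:10) {
    universe <- sprintf("g%03d", 1:60)
    ann <- lapply(stats::setNames(1:12, paste0("T", 1:12)), function(j)
      sample(universe, sample(5:20, 1)))
    out <- hypergeom_ora(sample(universe, 15), ann, universe)
    expect_true(all(out$fdr >= out$p_value))
    ord <- order(out$p_value)
    expect_true(all(diff(out$fdr[ord]) >= -1e-12))
    expect_equal(out$fdr, stats::p.adjust(out$p_value, "BH"))
  }
})

test_that("term-set matrix keeps terms enriched in at least min_sets sets", {
  mk_enr <- function(terms, fdr) data.frame(term = terms, fdr = fdr)
  enr <- list(
    s1 = mk_enr(c("A", "B"), c(0.01, 0.2)),
    s2 = mk_enr(c("A", "B"), c(0.02, 0.01)),
    s3 = mk_enr(c("A", "C"), c(0.03, 0.01)),
    s4 = mk_enr(c("A", "B"), c(0.04, 0.01)))
  m <- term_set_matrix(enr, fdr_max = 0.05, min_sets = 4)
  expect_equal(rownames(m), "A")   # B significant in only 3 sets
  expect_true(all(m["A", ]))
  m2 <- term_set_matrix(enr, fdr_max = 0.05, min_sets = 2)
  expect_equal(rownames(m2), c("A", "B"))  # ordered by descending row-sum
  # random tables vs direct row-sum filter
  set.seed(41)
  enr3 <- lapply(stats::setNames(1:6, paste0("s", 1:6)), function(i)
    mk_enr(paste0("T", 1:10), runif(10)))
  m3 <- term_set_matrix(enr3, fdr_max = 0.3, min_sets = 2)
  direct <- sapply(enr3, function(e) e$fdr <= 0.3)
  rownames(direct) <- paste0("T", 1:10)
  keep <- rowSums(direct) >= 2
  expect_setequal(rownames(m3), rownames(direct)[keep])
  expect_equal(m3[rownames(m3), ], direct[rownames(m3), ])
})
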