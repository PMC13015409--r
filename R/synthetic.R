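#' Configuration for the synthetic dataset generator
#'
#' Defaults define the study conditions the generator emulates: two
#' conditions (control, dex) with three replicates per mark, ~10% of
#' enhancers switching activation state after treatment, loop and SE
#' turnover fractions, negative-binomial counts with planted log2
#' fold-changes, GWAS leads planted on loop anchors / SEs / gene deserts,
#' and external SE and tissue-loop catalogs with planted tissue
#' specificity.
#'
#' The genome is laid out in fixed-width gene slots cycling through six
#' roles (enhancer cluster, eRNA locus, filter decoys, super-enhancer,
#' loop-distal anchors, background), which keeps every planted feature
#' geometrically isolated from the others so that planted truth is exactly
#' recoverable in the noiseless setting.
#'
#' @param seed master seed; all layer seeds derive from it.
#' @param n_chroms,chrom_length genome shape (default 2 x 10 Mb).
#' @param n_genes total genes (default 300; must be divisible by
#'   `n_chroms`).
#' @param n_replicates replicates per condition per mark (default 3).
#' @param enhancer_switch_rate probability an enhancer element switches
#'   between active and non-active after treatment (default 0.10).
#' @param frac_loops_gained,frac_loops_lost loop turnover fractions
#'   (default 0.15 each).
#' @param frac_se_gained,frac_se_lost plain-SE turnover fractions
#'   (default 0.2 each; their sum emulates the reported ~38% SE turnover).
#' @param n_noise_loops_per_sample sample-private loops removed by
#'   consensus (default 40).
#' @param n_flips_per_chrom compartment windows flipping sign after
#'   treatment (default 8).
#' @param frac_de fraction of genes differentially expressed (default
#'   0.15).
#' @param log2fc_mean,log2fc_sd planted |log2FC| distribution for DE
#'   genes.
#' @param nb_dispersion negative-binomial dispersion of counts (default
#'   0.1).
#' @param n_loop_snps,n_se_snps,n_closest_snps,n_peri_snps,n_compartment_snps,n_decoy_snps
#'   planted lead-variant counts per mechanism/role.
#' @param n_proxies_per_lead LD proxies drawn per lead (default 4).
#' @param n_catalog_samples external SE-catalog samples (default 40).
#' @param n_tissue_catalogs external tissue loop catalogs (default 10).
#' @param replicate_jitter_sd replicate peak-boundary jitter sd in bp
#'   (default 25).
#' @param replicate_dropout per-replicate peak dropout probability
#'   (default 0.10).
#' @param loop_anchor_jitter_sd per-sample loop-anchor jitter sd in bp
#'   (default 30).
#' @param noise FALSE zeroes all three noise knobs (noiseless placement).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_chroms = 2, chrom_length = 1e7,
                             n_genes = 300, n_replicates = 3,
                             enhancer_switch_rate = 0.10,
                             frac_loops_gained = 0.15, frac_loops_lost = 0.15,
                             frac_se_gained = 0.2, frac_se_lost = 0.2,
                             n_noise_loops_per_sample = 40,
                             n_flips_per_chrom = 8,
                             frac_de = 0.15, log2fc_mean = 2, log2fc_sd = 0.5,
                             nb_dispersion = 0.1,
                             n_loop_snps = 10, n_se_snps = 8,
                             n_closest_snps = 8, n_peri_snps = 6,
                             n_compartment_snps = 8, n_decoy_snps = 5,
                             n_proxies_per_lead = 4,
                             n_catalog_samples = 40, n_tissue_catalogs = 10,
                             replicate_jitter_sd = 25,
                             replicate_dropout = 0.10,
                             loop_anchor_jitter_sd = 30,
                             noise = TRUE) {
  cfg <- as.list(environment())
  if (!noise) {
    cfg$replicate_jitter_sd <- 0
    cfg$replicate_dropout <- 0
    cfg$loop_anchor_jitter_sd <- 0
  }
  stopifnot(n_genes %% n_chroms == 0,
            enhancer_switch_rate >= 0, enhancer_switch_rate <= 1,
            frac_loops_gained + frac_loops_lost <= 1,
            frac_se_gained + frac_se_lost <= 1)
  structure(cfg, class = "synthetic_config")
}

ALL_MARKS <- c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me2", "H3K4me3",
               "H3K36me3", "H3K9me3", "CTCF", "ATAC")
SLOT_MIN <- 66000
COMP_WINDOW <- 50000

#' Generate the complete synthetic dataset with ground-truth manifest
#'
#' Writes, under `out_dir`: a gene-model GTF; per-mark per-condition
#' per-replicate narrowPeak files; chromatin-state segment BEDs (promoter
#' and enhancer labels) and repressor-segment BEDs per condition;
#' per-sample loop BEDPEs for both conditions; external tissue loop
#' catalogs; compartment score bedGraphs, a window table with external
#' significance flags, and a per-window per-mark signal-delta table; gene
#' counts, a DE table and eRNA counts; lead and LD-proxy variant tables;
#' an external SE catalog; ChromHMM-style emission matrices with a known
#' selection plateau; a toy GMT; and `truth_manifest.json` recording every
#' planted truth. Fully deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the truth manifest, invisibly (also written as JSON).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  n_per_chrom <- config$n_genes / config$n_chroms
  slot <- floor(config$chrom_length / n_per_chrom)
  if (slot < SLOT_MIN)
    stop("chrom_length too small to place requested features: need >= ",
         SLOT_MIN * n_per_chrom, " bp per chromosome for ", n_per_chrom,
         " genes")
  set.seed(config$seed)
  seeds <- sample.int(2^30, 14)

  chroms <- paste0("chr", seq_len(config$n_chroms))
  layout <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    idx <- seq_len(n_per_chrom) - 1
    data.frame(chrom = chroms[ci], slot_idx = idx, base = idx * slot,
               role = idx %% 6, stringsAsFactors = FALSE)
  }))

  # ---- genes -------------------------------------------------------------
  set.seed(seeds[1])
  gw <- round(runif(nrow(layout), 4000, 12000))
  strand <- sample(c("+", "-"), nrow(layout), replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(nrow(layout))),
    gene_name = sprintf("GENE%04d", seq_len(nrow(layout))),
    chrom = layout$chrom, strand = strand,
    start = layout$base + 5000, end = layout$base + 5000 + gw,
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end - 1)
  genes$promoter_start <- pmax(0, ifelse(strand == "+", genes$tss - 2000,
                                         genes$tss - 500 + 1))
  genes$promoter_end <- ifelse(strand == "+", genes$tss + 500,
                               genes$tss + 2000 + 1)
  layout$gene_id <- genes$gene_id

  truth_peaks <- empty_truth_peaks(config)
  add_peak <- function(mark, conditions, chrom, start, end, signal) {
    for (cond in conditions)
      truth_peaks[[mark]][[cond]] <<- rbind(
        truth_peaks[[mark]][[cond]],
        data.frame(chrom = chrom, start = start, end = end, score = signal,
                   stringsAsFactors = FALSE))
  }
  # promoter-associated peaks at every TSS, both conditions
  add_peak("H3K4me3", c("control", "dex"), genes$chrom,
           genes$tss - 300, genes$tss + 500, runif(nrow(genes), 5, 15))
  add_peak("ATAC", c("control", "dex"), genes$chrom,
           genes$tss - 400, genes$tss + 400, runif(nrow(genes), 5, 15))

  segments <- list(control = NULL, dex = NULL)  # promoter/enhancer segments
  add_segment <- function(cond, chrom, start, end, label) {
    segments[[cond]] <<- rbind(segments[[cond]],
      data.frame(chrom = chrom, start = start, end = end, label = label,
                 stringsAsFactors = FALSE))
  }
  for (cond in c("control", "dex"))
    add_segment(cond, genes$chrom, genes$promoter_start, genes$promoter_end,
                "promoter")

  # ---- enhancer elements with states and switches ------------------------
  set.seed(seeds[2])
  enh_rows <- layout[layout$role == 0, , drop = FALSE]
  elements <- do.call(rbind, lapply(seq_len(nrow(enh_rows)), function(i) {
    b <- enh_rows$base[i]
    data.frame(chrom = enh_rows$chrom[i], start = b + c(24000, 34000, 44000),
               end = b + c(24000, 34000, 44000) + 600,
               kind = "element", stringsAsFactors = FALSE)
  }))
  st_ctrl <- sample(c("active", "primed", "poised", "inactive"),
                    nrow(elements), replace = TRUE,
                    prob = c(0.45, 0.25, 0.15, 0.15))
  switches <- runif(nrow(elements)) < config$enhancer_switch_rate
  st_dex <- st_ctrl
  nonactive <- c("primed", "poised", "inactive")
  for (i in which(switches))
    st_dex[i] <- if (st_ctrl[i] == "active")
      sample(nonactive, 1) else "active"
  elements$state_control <- st_ctrl
  elements$state_treated <- st_dex
  keep <- !(st_ctrl == "inactive" & st_dex == "inactive")
  elements <- elements[keep, , drop = FALSE]
  rownames(elements) <- NULL

  state_marks <- function(state) switch(state,
    active = c("H3K27ac", "H3K4me1"), primed = "H3K4me1",
    poised = c("H3K4me1", "H3K27me3"), inactive = character(0))
  plant_element <- function(chrom, start, end, sc, sd_) {
    for (cond in c("control", "dex")) {
      st <- if (cond == "control") sc else sd_
      if (st == "inactive") next
      add_segment(cond, chrom, start, end, "enhancer")
      for (mk in state_marks(st))
        add_peak(mk, cond, chrom, start - 100, end + 100,
                 if (mk == "H3K27ac") runif(1, 2, 6) else runif(1, 3, 8))
    }
  }
  for (i in seq_len(nrow(elements)))
    plant_element(elements$chrom[i], elements$start[i], elements$end[i],
                  elements$state_control[i], elements$state_treated[i])

  # ---- eRNA loci and filter decoys ---------------------------------------
  set.seed(seeds[3])
  erna_rows <- layout[layout$role == 1, , drop = FALSE]
  erna <- list(); decoys <- list()
  for (i in seq_len(nrow(erna_rows))) {
    b <- erna_rows$base[i]; ch <- erna_rows$chrom[i]
    first <- erna_rows$slot_idx[i] == min(erna_rows$slot_idx[erna_rows$chrom == ch])
    erna[[length(erna) + 1]] <- data.frame(
      chrom = ch, start = b + 24000, end = b + 24500,
      expressed = TRUE, merged_id = NA, stringsAsFactors = FALSE)
    erna[[length(erna) + 1]] <- data.frame(
      chrom = ch, start = b + 34000, end = b + 34500,
      expressed = FALSE, merged_id = NA, stringsAsFactors = FALSE)
    if (first) {
      # deliberate 30 bp gap pair: merges into one expressed locus
      erna[[length(erna) + 1]] <- data.frame(
        chrom = ch, start = b + 44000, end = b + 44480,
        expressed = TRUE, merged_id = paste0(ch, ":", b + 44000, "-", b + 44990),
        stringsAsFactors = FALSE)
      erna[[length(erna) + 1]] <- data.frame(
        chrom = ch, start = b + 44510, end = b + 44990,
        expressed = TRUE, merged_id = paste0(ch, ":", b + 44000, "-", b + 44990),
        stringsAsFactors = FALSE)
    }
  }
  erna <- do.call(rbind, erna)
  erna$merged_id <- ifelse(is.na(erna$merged_id), interval_id(erna),
                           erna$merged_id)
  for (i in seq_len(nrow(erna))) {
    for (cond in c("control", "dex")) {
      add_segment(cond, erna$chrom[i], erna$start[i], erna$end[i], "enhancer")
      add_peak("H3K4me1", cond, erna$chrom[i], erna$start[i] - 100,
               erna$end[i] + 100, runif(1, 3, 8))
      if (erna$expressed[i])
        add_peak("H3K27ac", cond, erna$chrom[i], erna$start[i] - 100,
                 erna$end[i] + 100, runif(1, 2, 6))
    }
  }
  decoy_rows <- layout[layout$role == 2, , drop = FALSE]
  for (i in seq_len(nrow(decoy_rows))) {
    b <- decoy_rows$base[i]; ch <- decoy_rows$chrom[i]
    g <- genes[genes$gene_id == decoy_rows$gene_id[i], ]
    body_decoy <- c(g$start + 500, g$start + 900)
    tss_decoy <- if (g$strand == "+") c(g$tss - 2000, g$tss - 1600)
                 else c(g$tss + 1601, g$tss + 2001)
    k4_decoy <- c(b + 44000, b + 44400)
    decoys[[length(decoys) + 1]] <- data.frame(
      chrom = ch,
      start = c(body_decoy[1], tss_decoy[1], k4_decoy[1]),
      end = c(body_decoy[2], tss_decoy[2], k4_decoy[2]),
      fails = c("gene_body", "tss_distance", "h3k4me3_distance"),
      stringsAsFactors = FALSE)
    add_peak("H3K4me3", c("control", "dex"), ch, b + 45500, b + 46200,
             runif(1, 5, 12))
  }
  decoys <- do.call(rbind, decoys)
  for (i in seq_len(nrow(decoys)))
    for (cond in c("control", "dex")) {
      add_segment(cond, decoys$chrom[i], decoys$start[i], decoys$end[i],
                  "enhancer")
      add_peak("H3K4me1", cond, decoys$chrom[i], decoys$start[i] - 100,
               decoys$end[i] + 100, runif(1, 3, 8))
    }

  # ---- super-enhancers ---------------------------------------------------
  set.seed(seeds[4])
  se_rows <- layout[layout$role == 3, , drop = FALSE]
  n_se_prom_per_chrom <- ceiling(config$n_se_snps / config$n_chroms)
  ses <- list()
  for (ch in chroms) {
    rows <- se_rows[se_rows$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      b <- rows$base[j]
      if (j <= n_se_prom_per_chrom) {
        g <- genes[genes$gene_id == rows$gene_id[j], ]
        cst <- g$tss + c(-4500, 3500, 15000)
        ses[[length(ses) + 1]] <- data.frame(
          chrom = ch, start = g$tss - 4500, end = g$tss + 16000,
          c1 = cst[1], c2 = cst[2], c3 = cst[3], width = 1000,
          type = "se_promoter", label = "stable", gene_id = g$gene_id,
          specificity = "tm_specific", stringsAsFactors = FALSE)
      } else {
        u <- runif(1)
        lab <- if (u < config$frac_se_gained) "gained"
               else if (u < config$frac_se_gained + config$frac_se_lost) "lost"
               else "stable"
        ses[[length(ses) + 1]] <- data.frame(
          chrom = ch, start = b + 22000, end = b + 43000,
          c1 = b + 22000, c2 = b + 32000, c3 = b + 42000, width = 1000,
          type = "plain", label = lab, gene_id = NA_character_,
          specificity = "tm_specific", stringsAsFactors = FALSE)
      }
    }
  }
  ses <- do.call(rbind, ses)
  ses$se_id <- sprintf("SE%03d", seq_len(nrow(ses)))
  # first stable plain SEs per chromosome are catalog-ubiquitous
  for (ch in chroms) {
    cand <- which(ses$chrom == ch & ses$type == "plain" & ses$label == "stable")
    ses$specificity[utils::head(cand, 3)] <- "ubiquitous"
  }
  for (i in seq_len(nrow(ses))) {
    conds <- switch(ses$label[i], stable = c("control", "dex"),
                    gained = "dex", lost = "control")
    for (cond in conds)
      for (cs in c(ses$c1[i], ses$c2[i], ses$c3[i])) {
        add_segment(cond, ses$chrom[i], cs, cs + ses$width[i], "enhancer")
        add_peak("H3K27ac", cond, ses$chrom[i], cs - 100,
                 cs + ses$width[i] + 100, runif(1, 300, 400))
        add_peak("H3K4me1", cond, ses$chrom[i], cs - 100,
                 cs + ses$width[i] + 100, runif(1, 3, 8))
      }
  }

  # ---- repressor elements and loops --------------------------------------
  set.seed(seeds[5])
  distal_rows <- layout[layout$role == 4, , drop = FALSE]
  repressors <- data.frame(chrom = distal_rows$chrom,
                           start = distal_rows$base + 40000,
                           end = distal_rows$base + 41000,
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(repressors)))
    for (cond in c("control", "dex")) {
      add_peak("H3K27me3", cond, repressors$chrom[i], repressors$start[i] - 100,
               repressors$end[i] + 100, runif(1, 3, 8))
      add_peak("H3K9me3", cond, repressors$chrom[i], repressors$start[i] - 100,
               repressors$end[i] + 100, runif(1, 3, 8))
    }

  # per-chromosome target pools: a loop and its target gene share a chromosome
  target_pool <- lapply(stats::setNames(chroms, chroms), function(ch)
    sample(layout$gene_id[layout$role != 3 & layout$chrom == ch]))
  pool_i <- stats::setNames(rep(0, length(chroms)), chroms)
  next_gene <- function(ch) {
    pool_i[ch] <<- pool_i[ch] + 1
    if (pool_i[ch] > length(target_pool[[ch]]))
      stop("gene target pool exhausted on ", ch)
    target_pool[[ch]][pool_i[ch]]
  }
  loops <- list()
  add_loop <- function(chrom, a1s, a1e, category, gene_id = next_gene(chrom)) {
    g <- genes[genes$gene_id == gene_id, ]
    loops[[length(loops) + 1]] <<- data.frame(
      chrom = chrom, a1s = a1s, a1e = a1e,
      a2s = g$tss - 2500, a2e = g$tss + 1500,
      gene_id = gene_id, category = category, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(distal_rows))) {
    b <- distal_rows$base[i]; ch <- distal_rows$chrom[i]
    add_loop(ch, b + 20000, b + 23000, "enhancer")
    for (cond in c("control", "dex")) {
      add_segment(cond, ch, b + 21000, b + 21600, "enhancer")
      add_peak("H3K27ac", cond, ch, b + 20900, b + 21700, runif(1, 2, 6))
      add_peak("H3K4me1", cond, ch, b + 20900, b + 21700, runif(1, 3, 8))
    }
    add_loop(ch, b + 24000, b + 27000, "plain")
    add_loop(ch, b + 39500, b + 42500, "repressor")
  }
  se_anchor_rows <- which(ses$type == "plain")
  for (i in utils::head(se_anchor_rows, 8 * config$n_chroms)) {
    b <- ses$start[i] - 22000  # slot base for plain SEs
    add_loop(ses$chrom[i], b + 29000, b + 32000, "super_enhancer")
  }
  loops <- do.call(rbind, loops)
  loops$loop_id <- sprintf("L%04d", seq_len(nrow(loops)))
  u <- runif(nrow(loops))
  loops$label <- ifelse(u < config$frac_loops_gained, "gained",
                        ifelse(u < config$frac_loops_gained +
                                 config$frac_loops_lost, "lost", "stable"))
  loops$ctcf_feet <- sample(0:2, nrow(loops), replace = TRUE,
                            prob = c(0.3, 0.4, 0.3))
  for (i in seq_len(nrow(loops))) {
    if (loops$ctcf_feet[i] >= 1)
      add_peak("CTCF", c("control", "dex"), loops$chrom[i],
               loops$a1s[i] + 1400, loops$a1s[i] + 1800, runif(1, 5, 12))
    if (loops$ctcf_feet[i] == 2)
      add_peak("CTCF", c("control", "dex"), loops$chrom[i],
               loops$a2s[i] + 1400, loops$a2s[i] + 1800, runif(1, 5, 12))
  }
  stable_idx <- which(loops$label == "stable")
  loops$shared_tissue <- FALSE
  loops$shared_tissue[sample(stable_idx, round(0.4 * length(stable_idx)))] <- TRUE
  # per-sample presence: loops present in 2 or 3 of the replicates
  n_rep <- config$n_replicates
  pres <- lapply(seq_len(nrow(loops)), function(i)
    sort(sample(n_rep, sample(2:n_rep, 1))))
  loops$present_reps <- vapply(pres, paste, character(1), collapse = ",")

  # ---- decoy loops (non-promoter anchor2) for variant specificity --------
  set.seed(seeds[6])
  decoy_loops <- NULL
  n_nonprom <- min(3, config$n_decoy_snps)
  if (n_nonprom > 0) {
    dist1 <- distal_rows[distal_rows$chrom == chroms[1], , drop = FALSE]
    dd <- dist1[seq_len(n_nonprom), , drop = FALSE]
    other <- dist1[rev(seq_len(nrow(dist1)))[seq_len(n_nonprom)], , drop = FALSE]
    decoy_loops <- data.frame(
      chrom = dd$chrom, a1s = dd$base + 44000, a1e = dd$base + 47000,
      a2s = other$base + 50000, a2e = other$base + 53000,
      loop_id = sprintf("LD%02d", seq_len(n_nonprom)),
      stringsAsFactors = FALSE)
  }

  # ---- background differential peaks -------------------------------------
  set.seed(seeds[7])
  bg_rows <- layout[layout$role == 5, , drop = FALSE]
  bg_rows$diff_class <- c("stable", "stable", "stable", "lost", "gained")[
    (bg_rows$slot_idx %% 5) + 1]
  for (i in seq_len(nrow(bg_rows))) {
    b <- bg_rows$base[i]; ch <- bg_rows$chrom[i]
    conds <- switch(bg_rows$diff_class[i], stable = c("control", "dex"),
                    gained = "dex", lost = "control")
    g <- genes[genes$gene_id == bg_rows$gene_id[i], ]
    for (mi in seq_along(ALL_MARKS)) {
      add_peak(ALL_MARKS[mi], conds, ch, b + 20000 + (mi - 1) * 1000,
               b + 20000 + (mi - 1) * 1000 + 700, runif(1, 2, 8))
      if (bg_rows$diff_class[i] != "stable")
        add_peak(ALL_MARKS[mi], conds, ch, g$start + 1000 + (mi - 1) * 300,
                 g$start + 1000 + (mi - 1) * 300 + 200, runif(1, 2, 8))
    }
  }

  # ---- compartments ------------------------------------------------------
  set.seed(seeds[8])
  nw <- floor(config$chrom_length / COMP_WINDOW)
  comp <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- seq_len(nw) - 1
    sign_block <- ifelse((idx %/% 10) %% 2 == 0, 1, -1)
    data.frame(chrom = ch, start = idx * COMP_WINDOW,
               end = (idx + 1) * COMP_WINDOW,
               score_control = sign_block * runif(nw, 0.5, 0.9),
               stringsAsFactors = FALSE)
  }))
  comp$score_treated <- comp$score_control
  comp$flipped <- FALSE
  for (ch in chroms) {
    rows <- which(comp$chrom == ch)
    flip <- rows[seq(5, by = floor(nw / config$n_flips_per_chrom),
                     length.out = config$n_flips_per_chrom)]
    comp$flipped[flip] <- TRUE
  }
  comp$score_treated[comp$flipped] <- -comp$score_control[comp$flipped] *
    runif(sum(comp$flipped), 0.9, 1.1)
  comp$shift <- ifelse(!comp$flipped, "none",
                       ifelse(comp$score_treated > comp$score_control,
                              "toward_A", "toward_B"))
  # per-window per-mark signal deltas: shifted windows move with direction
  delta_marks <- c("H3K27ac", "H3K4me1", "ATAC")
  deltas <- do.call(rbind, lapply(delta_marks, function(mk) {
    mu <- ifelse(comp$shift == "toward_A", 0.6,
                 ifelse(comp$shift == "toward_B", -0.6, 0))
    data.frame(chrom = comp$chrom, start = comp$start, end = comp$end,
               mark = mk, delta = rnorm(nrow(comp), mu, 0.2),
               stringsAsFactors = FALSE)
  }))

  # ---- variants ----------------------------------------------------------
  set.seed(seeds[9])
  avoid <- rbind(
    data.frame(chrom = loops$chrom, start = loops$a1s - 500,
               end = loops$a1e + 500),
    data.frame(chrom = loops$chrom, start = loops$a2s - 500,
               end = loops$a2e + 500),
    if (!is.null(decoy_loops)) rbind(
      data.frame(chrom = decoy_loops$chrom, start = decoy_loops$a1s - 500,
                 end = decoy_loops$a1e + 500),
      data.frame(chrom = decoy_loops$chrom, start = decoy_loops$a2s - 500,
                 end = decoy_loops$a2e + 500)),
    data.frame(chrom = ses$chrom, start = ses$start - 500,
               end = ses$end + 500))
  in_avoid <- function(chrom, pos) {
    any(avoid$chrom == chrom & avoid$start <= pos & pos < avoid$end)
  }
  free_pos <- function(chrom, pos, lo, hi) {
    while (in_avoid(chrom, pos) && pos + 1500 < hi) pos <- pos + 1500
    if (in_avoid(chrom, pos)) stop("could not place variant outside features")
    pos
  }
  variants <- list(); v2g_truth <- list()
  vid <- 0
  add_variant <- function(chrom, pos, role, extra = list()) {
    vid <<- vid + 1
    variants[[vid]] <<- c(list(
      rsid = sprintf("rs%05d", vid), chrom = chrom, pos = pos,
      trait = if (vid %% 2 == 0) "IOP" else "POAG", role = role), extra)
    variants[[vid]]$rsid
  }
  loop_snp_loops <- utils::head(which(loops$category == "plain" &
                                        loops$label == "stable"),
                                config$n_loop_snps)
  for (i in loop_snp_loops) {
    rs <- add_variant(loops$chrom[i], (loops$a1s[i] + loops$a1e[i]) %/% 2,
                      "loop", list(gene_id = loops$gene_id[i],
                                   loop_id = loops$loop_id[i]))
    v2g_truth[[length(v2g_truth) + 1]] <- data.frame(
      rsid = rs, gene_id = loops$gene_id[i], mechanism = "loop",
      stringsAsFactors = FALSE)
  }
  se_prom <- ses[ses$type == "se_promoter", , drop = FALSE]
  for (i in seq_len(min(nrow(se_prom), config$n_se_snps))) {
    g <- genes[genes$gene_id == se_prom$gene_id[i], ]
    rs <- add_variant(se_prom$chrom[i], g$tss + 10000, "super_enhancer",
                      list(gene_id = se_prom$gene_id[i],
                           se_id = se_prom$se_id[i]))
    v2g_truth[[length(v2g_truth) + 1]] <- data.frame(
      rsid = rs, gene_id = se_prom$gene_id[i], mechanism = "super_enhancer",
      stringsAsFactors = FALSE)
  }
  closest_truth <- list()
  bg_per_chrom <- split(bg_rows, bg_rows$chrom)
  for (ci in seq_along(chroms)) {
    rows <- bg_per_chrom[[chroms[ci]]]
    n_cl <- config$n_closest_snps / config$n_chroms
    for (j in seq_len(n_cl)) {
      r <- rows[j, ]
      g <- genes[genes$gene_id == r$gene_id, ]
      pos <- r$base + 19000
      rs <- add_variant(r$chrom, pos, "closest")
      closest_truth[[length(closest_truth) + 1]] <- data.frame(
        rsid = rs, gene_id = g$gene_id, distance = pos - g$end,
        stringsAsFactors = FALSE)
    }
  }
  peri_truth <- list()
  for (ci in seq_along(chroms)) {
    rows <- bg_per_chrom[[chroms[ci]]]
    n_peri <- config$n_peri_snps / config$n_chroms
    for (j in seq_len(n_peri)) {
      r <- rows[nrow(rows) - j + 1, ]
      pos <- r$base + 35000
      rs <- add_variant(r$chrom, pos, "peri_snp")
      add_peak("H3K27ac", "dex", r$chrom, pos + 3000, pos + 3600,
               runif(1, 2, 6))
      add_peak("ATAC", "control", r$chrom, pos - 4500, pos - 3900,
               runif(1, 2, 6))
      add_peak("H3K4me1", "dex", r$chrom, pos + 6000, pos + 6600,
               runif(1, 2, 6))  # outside the 5 kb window
      peri_truth[[length(peri_truth) + 1]] <- data.frame(
        rsid = rs, mark = c("H3K27ac", "ATAC"),
        n_gained = c(1L, 0L), n_lost = c(0L, 1L), stringsAsFactors = FALSE)
    }
  }
  comp_truth <- list()
  flips <- comp[comp$flipped, , drop = FALSE]
  for (j in seq_len(min(config$n_compartment_snps, nrow(flips)))) {
    w <- flips[j, ]
    pos <- free_pos(w$chrom, w$start + 25000, w$start, w$end)
    rs <- add_variant(w$chrom, pos, "compartment")
    comp_truth[[length(comp_truth) + 1]] <- data.frame(
      rsid = rs, shift = w$shift, stringsAsFactors = FALSE)
  }
  if (!is.null(decoy_loops))
    for (i in seq_len(nrow(decoy_loops)))
      add_variant(decoy_loops$chrom[i],
                  (decoy_loops$a1s[i] + decoy_loops$a1e[i]) %/% 2,
                  "decoy_nonpromoter_loop")
  same_anchor <- utils::tail(which(loops$category == "plain" &
                                     loops$label == "stable"), 2)
  for (i in same_anchor) {
    g <- genes[genes$gene_id == loops$gene_id[i], ]
    add_variant(loops$chrom[i], g$tss + 1200, "decoy_same_anchor")
  }
  variants <- do.call(rbind, lapply(variants, function(v)
    data.frame(rsid = v$rsid, chrom = v$chrom, pos = v$pos, trait = v$trait,
               role = v$role, stringsAsFactors = FALSE)))
  # LD proxies: mostly retained, plus planted sub-threshold and too-far rows
  proxies <- list()
  for (i in seq_len(nrow(variants))) {
    lead <- variants[i, ]
    offs <- round(runif(config$n_proxies_per_lead, 8000, 60000)) *
      sample(c(-1, 1), config$n_proxies_per_lead, replace = TRUE)
    r2 <- c(runif(config$n_proxies_per_lead - 1, 0.82, 0.99), runif(1, 0.3, 0.7))
    for (k in seq_len(config$n_proxies_per_lead)) {
      pos <- lead$pos + offs[k]
      if (pos < 0 || pos >= config$chrom_length) next
      tries <- 0
      while (in_avoid(lead$chrom, pos) && tries < 50) {
        pos <- pos + 777; tries <- tries + 1
      }
      if (in_avoid(lead$chrom, pos)) next
      proxies[[length(proxies) + 1]] <- data.frame(
        rsid = sprintf("rs%05d_p%d", i, k), chrom = lead$chrom, pos = pos,
        trait = lead$trait, lead_rsid = lead$rsid, r2 = r2[k],
        stringsAsFactors = FALSE)
    }
    if (i <= 2 && lead$pos + 1.2e6 < config$chrom_length)
      proxies[[length(proxies) + 1]] <- data.frame(
        rsid = sprintf("rs%05d_far", i), chrom = lead$chrom,
        pos = lead$pos + 1.2e6, trait = lead$trait, lead_rsid = lead$rsid,
        r2 = 0.95, stringsAsFactors = FALSE)
  }
  proxies <- do.call(rbind, proxies)

  # ---- counts and DE table -----------------------------------------------
  set.seed(seeds[10])
  n_genes <- nrow(genes)
  base_mu <- exp(rnorm(n_genes, log(200), 1))
  is_de <- runif(n_genes) < config$frac_de
  lfc <- ifelse(is_de, sample(c(-1, 1), n_genes, replace = TRUE) *
                  pmax(1, rnorm(n_genes, config$log2fc_mean, config$log2fc_sd)),
                0)
  size <- 1 / config$nb_dispersion
  counts <- cbind(
    matrix(rnbinom(n_genes * 3, mu = base_mu, size = size), ncol = 3),
    matrix(rnbinom(n_genes * 3, mu = base_mu * 2^lfc, size = size), ncol = 3))
  dimnames(counts) <- list(genes$gene_id,
                           c(paste0("control_", 1:3), paste0("dex_", 1:3)))
  de_table <- data.frame(
    gene_id = genes$gene_id, log2fc = lfc,
    fdr = ifelse(is_de, 10^-runif(n_genes, 3, 8), runif(n_genes, 0.2, 1)),
    stringsAsFactors = FALSE)

  # ---- eRNA counts (library sizes fixed at 1e6 so counts == CPM) ---------
  set.seed(seeds[11])
  all_enh_control <- segments$control[segments$control$label == "enhancer",
                                      c("chrom", "start", "end")]
  merged_enh <- merge_intervals(all_enh_control, gap = 50)
  merged_ids <- interval_id(merged_enh)
  n_samp <- 6
  erna_counts <- matrix(0, length(merged_ids), n_samp,
                        dimnames = list(merged_ids,
                                        c(paste0("ctrl_rna_", 1:3),
                                          paste0("dex_rna_", 1:3))))
  expr_ids <- unique(erna$merged_id[erna$expressed])
  expr_ids <- intersect(expr_ids, merged_ids)
  erna_counts[expr_ids, ] <- matrix(
    round(runif(length(expr_ids) * n_samp, 3, 50)),
    ncol = n_samp)
  unexpr_ids <- intersect(unique(erna$merged_id[!erna$expressed]), merged_ids)
  for (id in unexpr_ids)
    erna_counts[id, sample(n_samp, 1)] <- 1  # CPM 1, not > 1
  filler <- pmax(0, 1e6 - colSums(erna_counts))
  erna_counts <- rbind(erna_counts,
                       matrix(filler, 1, n_samp,
                              dimnames = list("background", NULL)))

  # ---- emission matrices with a planted plateau --------------------------
  emissions <- make_emission_models(seed = seeds[12])

  # ---- GMT ---------------------------------------------------------------
  set.seed(seeds[13])
  de_up <- de_table$gene_id[de_table$log2fc > 0 & de_table$fdr <= 0.05]
  de_dn <- de_table$gene_id[de_table$log2fc < 0 & de_table$fdr <= 0.05]
  gmt <- list(
    PLANTED_DE_UP = utils::head(de_up, 40),
    PLANTED_DE_DOWN = utils::head(de_dn, 40),
    PLANTED_LOOP_TARGETS = unique(loops$gene_id[loops$label != "stable"]),
    RANDOM_A = sample(genes$gene_id, 30),
    RANDOM_B = sample(genes$gene_id, 30),
    RANDOM_C = sample(genes$gene_id, 30))
  gmt <- gmt[vapply(gmt, length, integer(1)) > 0]

  # ---- emit files --------------------------------------------------------
  set.seed(seeds[14])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "segments", "loops", "tissue_loops", "compartments",
              "expression", "variants", "se_catalog", "annotation",
              "emissions"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  write_gene_models(genes, file.path(out_dir, "genes.gtf"))

  jit <- function(x, sd_) if (sd_ > 0) round(x + rnorm(length(x), 0, sd_)) else x
  for (mk in ALL_MARKS)
    for (cond in c("control", "dex")) {
      tp <- truth_peaks[[mk]][[cond]]
      for (r in seq_len(config$n_replicates)) {
        keep <- runif(nrow(tp)) >= config$replicate_dropout
        rp <- tp[keep, , drop = FALSE]
        if (nrow(rp)) {
          rp$start <- pmax(0, jit(rp$start, config$replicate_jitter_sd))
          rp$end <- pmax(rp$start + 1, jit(rp$end, config$replicate_jitter_sd))
          rp$score <- rp$score * runif(nrow(rp), 0.9, 1.1)
          rp$name <- sprintf("%s_%s_r%d_%d", mk, cond, r, seq_len(nrow(rp)))
        }
        write_intervals(sort_intervals(rp),
                        file.path(out_dir, "peaks",
                                  sprintf("%s_%s_rep%d.narrowPeak", mk, cond, r)),
                        dialect = "narrowPeak")
      }
    }

  for (cond in c("control", "dex")) {
    seg <- sort_intervals(segments[[cond]])
    utils::write.table(seg[, c("chrom", "start", "end", "label")],
                       file.path(out_dir, "segments",
                                 paste0("cre_segments_", cond, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_intervals(repressors,
                    file.path(out_dir, "segments",
                              paste0("repressor_", cond, ".bed")),
                    dialect = "bed3")
  }

  noise_window <- function(s_global) 44000 + (s_global - 1) * 3500
  sample_names <- c(paste0("control_", 1:3), paste0("dex_", 1:3))
  for (si in seq_along(sample_names)) {
    smp <- sample_names[si]
    cond <- if (si <= 3) "control" else "dex"
    rep_no <- ((si - 1) %% 3) + 1
    present <- loops[
      (loops$label == "stable" |
         (loops$label == "gained" & cond == "dex") |
         (loops$label == "lost" & cond == "control")) &
        vapply(strsplit(loops$present_reps, ","), function(p)
          as.character(rep_no) %in% p, logical(1)), , drop = FALSE]
    ldf <- data.frame(
      chrom1 = present$chrom,
      start1 = pmax(0, jit(present$a1s, config$loop_anchor_jitter_sd)),
      end1 = jit(present$a1e, config$loop_anchor_jitter_sd),
      chrom2 = present$chrom,
      start2 = pmax(0, jit(present$a2s, config$loop_anchor_jitter_sd)),
      end2 = jit(present$a2e, config$loop_anchor_jitter_sd),
      name = present$loop_id, score = runif(nrow(present), 5, 15),
      stringsAsFactors = FALSE)
    if (!is.null(decoy_loops)) {
      ldf <- rbind(ldf, data.frame(
        chrom1 = decoy_loops$chrom, start1 = decoy_loops$a1s,
        end1 = decoy_loops$a1e, chrom2 = decoy_loops$chrom,
        start2 = decoy_loops$a2s, end2 = decoy_loops$a2e,
        name = decoy_loops$loop_id,
        score = runif(nrow(decoy_loops), 5, 15), stringsAsFactors = FALSE))
    }
    # sample-private noise loops in per-sample disjoint windows
    bgc <- split(bg_rows, bg_rows$chrom)
    for (k in seq_len(config$n_noise_loops_per_sample)) {
      ch <- chroms[(k %% config$n_chroms) + 1]
      rows <- bgc[[ch]]
      pick <- rows[sample(nrow(rows), 2), ]
      w0 <- noise_window(si)
      ldf <- rbind(ldf, data.frame(
        chrom1 = ch, start1 = pick$base[1] + w0, end1 = pick$base[1] + w0 + 3000,
        chrom2 = ch, start2 = pick$base[2] + w0, end2 = pick$base[2] + w0 + 3000,
        name = sprintf("noise_%s_%03d", smp, k), score = runif(1, 5, 15),
        stringsAsFactors = FALSE))
    }
    write_loops(canonicalize_loops(ldf),
                file.path(out_dir, "loops", paste0(smp, ".bedpe")))
  }

  shared <- loops[loops$shared_tissue, , drop = FALSE]
  for (t in seq_len(config$n_tissue_catalogs)) {
    tdf <- data.frame(chrom1 = shared$chrom, start1 = shared$a1s,
                      end1 = shared$a1e, chrom2 = shared$chrom,
                      start2 = shared$a2s, end2 = shared$a2e,
                      name = paste0("t", t, "_", shared$loop_id),
                      score = runif(nrow(shared), 5, 15),
                      stringsAsFactors = FALSE)
    bgc <- split(bg_rows, bg_rows$chrom)
    for (k in 1:30) {
      ch <- chroms[(k %% config$n_chroms) + 1]
      rows <- bgc[[ch]]
      pick <- rows[sample(nrow(rows), 2), ]
      tdf <- rbind(tdf, data.frame(
        chrom1 = ch, start1 = pick$base[1] + 30000, end1 = pick$base[1] + 33000,
        chrom2 = ch, start2 = pick$base[2] + 37000, end2 = pick$base[2] + 40000,
        name = sprintf("tnoise_%d_%03d", t, k), score = runif(1, 5, 15),
        stringsAsFactors = FALSE))
    }
    write_loops(canonicalize_loops(tdf),
                file.path(out_dir, "tissue_loops", sprintf("tissue%02d.bedpe", t)))
  }

  for (cond in c("control", "dex")) {
    sc <- if (cond == "control") comp$score_control else comp$score_treated
    write_intervals(data.frame(chrom = comp$chrom, start = comp$start,
                               end = comp$end, score = round(sc, 4)),
                    file.path(out_dir, "compartments",
                              paste0("score_", cond, ".bedgraph")),
                    dialect = "bedgraph")
  }
  write_tsv_table(data.frame(chrom = comp$chrom, start = comp$start,
                             end = comp$end,
                             score_control = round(comp$score_control, 4),
                             score_treated = round(comp$score_treated, 4),
                             significant = comp$flipped),
                  file.path(out_dir, "compartments", "windows.tsv"))
  deltas$delta <- round(deltas$delta, 4)
  write_tsv_table(deltas, file.path(out_dir, "compartments", "signal_deltas.tsv"))

  write_count_matrix(counts, file.path(out_dir, "expression", "counts.tsv"),
                     id_col = "gene_id")
  write_tsv_table(de_table, file.path(out_dir, "expression", "de_table.tsv"))
  write_count_matrix(erna_counts,
                     file.path(out_dir, "expression", "erna_counts.tsv"))

  leads_out <- data.frame(rsid = variants$rsid, chrom = variants$chrom,
                          pos = variants$pos + 1,  # emit 1-based
                          trait = variants$trait, lead_rsid = variants$rsid,
                          r2 = 1, stringsAsFactors = FALSE)
  write_tsv_table(leads_out, file.path(out_dir, "variants", "leads.tsv"))
  proxies_out <- proxies
  proxies_out$pos <- proxies_out$pos + 1
  write_tsv_table(proxies_out, file.path(out_dir, "variants", "proxies.tsv"))

  # external SE catalog: ubiquitous SEs in all but 2 samples, TM-specific
  # in exactly one, plus private noise SEs per sample
  decoy_bases <- layout$base[layout$role == 2]
  decoy_chroms <- layout$chrom[layout$role == 2]
  for (s in seq_len(config$n_catalog_samples)) {
    cat_se <- NULL
    ubi <- ses[ses$specificity == "ubiquitous", , drop = FALSE]
    if (s <= config$n_catalog_samples - 2 && nrow(ubi))
      cat_se <- data.frame(chrom = ubi$chrom, start = ubi$start - 1000,
                           end = ubi$end + 1000, stringsAsFactors = FALSE)
    if (s == 1) {
      spec <- ses[ses$specificity == "tm_specific", , drop = FALSE]
      cat_se <- rbind(cat_se,
                      data.frame(chrom = spec$chrom, start = spec$start - 500,
                                 end = spec$end + 500, stringsAsFactors = FALSE))
    }
    j <- ((s - 1) %% length(decoy_bases)) + 1
    cat_se <- rbind(cat_se, data.frame(chrom = decoy_chroms[j],
                                       start = decoy_bases[j] + 50000,
                                       end = decoy_bases[j] + 55000,
                                       stringsAsFactors = FALSE))
    write_intervals(sort_intervals(cat_se),
                    file.path(out_dir, "se_catalog",
                              sprintf("sample%02d.bed", s)),
                    dialect = "bed3")
  }

  write_gmt(gmt, file.path(out_dir, "annotation", "genesets.gmt"))
  for (i in seq_along(emissions$models)) {
    m <- emissions$models[[i]]
    write_tsv_table(data.frame(state = seq_len(nrow(m)), m),
                    file.path(out_dir, "emissions",
                              sprintf("model_%02d.tsv", nrow(m))))
  }

  # ---- truth manifest ----------------------------------------------------
  se_by_cond <- function(cond) {
    lab <- if (cond == "control") c("stable", "lost") else c("stable", "gained")
    ses[ses$label %in% lab, c("se_id", "chrom", "start", "end", "label",
                              "type", "specificity"), drop = FALSE]
  }
  manifest <- list(
    config = unclass(config),
    genes = genes,
    enhancers = {
      el <- elements
      el$switch <- switch_label(el$state_control, el$state_treated)
      el[, c("chrom", "start", "end", "state_control", "state_treated",
             "switch")]
    },
    super_enhancers = ses[, c("se_id", "chrom", "start", "end", "label",
                              "type", "gene_id", "specificity")],
    se_control = se_by_cond("control"),
    se_dex = se_by_cond("dex"),
    loops = loops[, c("loop_id", "chrom", "a1s", "a1e", "a2s", "a2e",
                      "gene_id", "category", "label", "ctcf_feet",
                      "shared_tissue")],
    decoy_loops = decoy_loops,
    compartment_windows = comp[, c("chrom", "start", "end", "flipped",
                                   "shift")],
    de_genes = de_table$gene_id[de_table$fdr <= 0.05],
    erna = list(
      expressed_ids = sort(unique(erna$merged_id[erna$expressed])),
      unexpressed_ids = sort(unique(erna$merged_id[!erna$expressed])),
      decoys = decoys),
    variants = variants,
    v2g = do.call(rbind, v2g_truth),
    closest = do.call(rbind, closest_truth),
    peri_snp = do.call(rbind, peri_truth),
    snp_compartment = do.call(rbind, comp_truth),
    ld = list(r2_min = 0.8,
              expected_retained = local({
                li <- match(proxies$lead_rsid, variants$rsid)
                proxies$rsid[proxies$r2 >= 0.8 &
                               abs(proxies$pos - variants$pos[li]) <= 1e6]
              })),
    diff_peaks = lapply(stats::setNames(ALL_MARKS, ALL_MARKS), function(mk) {
      lab_of <- function(cls) {
        r <- bg_rows[bg_rows$diff_class == cls, , drop = FALSE]
        if (nrow(r) == 0) return(NULL)
        data.frame(chrom = r$chrom,
                   start = r$base + 20000 +
                     (match(mk, ALL_MARKS) - 1) * 1000,
                   end = r$base + 20000 + (match(mk, ALL_MARKS) - 1) * 1000 + 700,
                   stringsAsFactors = FALSE)
      }
      list(gained = lab_of("gained"), lost = lab_of("lost"))
    }),
    emission_plateau = emissions$plateau,
    tissue_sharing = list(shared_ids = loops$loop_id[loops$shared_tissue],
                          specific_ids = loops$loop_id[!loops$shared_tissue],
                          n_tissues = config$n_tissue_catalogs))
  jsonlite::write_json(manifest, file.path(out_dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Hockey-stick ranked-signal fixture with a known breakpoint
#'
#' Generates a monotone non-decreasing signal vector whose last `n_super`
#' points rise sharply (slope > 1 after 0-1 scaling of both axes) above a
#' shallow background (slope < 1), the geometry the super-enhancer elbow
#' cutoff detects. The true breakpoint index is `n_points - n_super`: the
#' last background rank, below which no point is super.
#'
#' @param n_points total number of ranked regions.
#' @param n_super number of super points in the steep tail
#'   (`n_super < n_points`).
#' @param seed integer seed.
#' @return list with `signals` (sorted ascending) and `breakpoint`
#'   (= `n_points - n_super`).
#' @export
make_hockey_stick <- function(n_points, n_super, seed = 1) {
  if (n_super >= n_points) stop("n_super must be smaller than n_points")
  set.seed(seed)
  b <- n_points - n_super
  if (n_super == 0) {
    # flat-ish background only: no super regime, breakpoint = n_points
    return(list(signals = sort(runif(n_points, 0, 0.2)), breakpoint = n_points))
  }
  background <- sort(runif(b, 0, 0.2))
  tail_ <- sort(0.35 + 0.65 * runif(n_super))
  list(signals = c(background, tail_), breakpoint = b)
}

empty_truth_peaks <- function(config) {
  one <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    score = numeric(), stringsAsFactors = FALSE)
  lapply(stats::setNames(ALL_MARKS, ALL_MARKS), function(mk)
    list(control = one, dex = one))
}

#' Fabricate nested emission matrices with a known selection plateau
#'
#' Builds ChromHMM-style emission matrices for 5 to 16 states over the
#' nine assayed marks by nested merging of a 13-state base model: models
#' below 13 states merge pairs of base states into group means, models at
#' or above 13 states append duplicate states. Consecutive-model
#' best-match correlation therefore reaches exactly 1 at 13 states, and
#' the construction is checked (and re-drawn from derived sub-seeds if
#' needed) so that every pre-plateau score gain is at least 0.012.
#'
#' @param seed integer seed.
#' @param k_min,k_max model range (default 5..16).
#' @param k_true plateau state count (default 13).
#' @return list with `models` (list of matrices) and `plateau` (= `k_true`).
#' @export
make_emission_models <- function(seed = 1, k_min = 5, k_max = 16, k_true = 13) {
  marks <- ALL_MARKS
  d <- length(marks)
  # rescale a real vector affinely into (0.05, 0.95); affine maps preserve
  # Pearson correlation, so the designed correlations survive
  to_unit <- function(v) 0.5 + 0.45 * v / max(abs(v), 1e-9)
  # vector with exact sample correlation rho to v
  cor_vec <- function(v, rho) {
    z1 <- as.numeric(base::scale(v))
    h <- stats::rnorm(d)
    z2 <- stats::residuals(stats::lm(h ~ z1))
    z2 <- as.numeric(base::scale(z2))
    rho * z1 + sqrt(1 - rho^2) * z2
  }
  score_curve <- function(models) {
    vapply(seq_len(length(models) - 1), function(k) {
      a <- models[[k]]; b <- models[[k + 1]]
      mean(vapply(seq_len(nrow(a)), function(i)
        max(vapply(seq_len(nrow(b)), function(j) {
          if (stats::sd(a[i, ]) == 0 || stats::sd(b[j, ]) == 0) 0
          else stats::cor(a[i, ], b[j, ])
        }, numeric(1))), numeric(1)))
    }, numeric(1))
  }
  # designed score curve: rises by 0.015 per model, exact 1 from k_true on
  rho <- seq(0.85, by = 0.015, length.out = k_true - k_min)
  for (attempt in seq_len(80)) {
    set.seed(seed %% 2^20 + attempt)
    models <- vector("list", k_max - k_min + 1)
    cur <- t(replicate(k_min, to_unit(stats::rnorm(d))))
    models[[1]] <- cur
    for (k in (k_min + 1):k_max) {
      if (k <= k_true) {
        r <- rho[k - k_min]
        nxt <- t(apply(cur, 1, function(v) to_unit(cor_vec(v, r))))
        nxt <- rbind(nxt, to_unit(stats::rnorm(d)))
      } else {
        nxt <- rbind(cur[seq_len(k_true), , drop = FALSE],
                     cur[seq_len(k - k_true), , drop = FALSE])
      }
      models[[k - k_min + 1]] <- nxt
      cur <- nxt
    }
    models <- lapply(models, function(m) {
      dimnames(m) <- list(NULL, marks)
      round(m, 6)
    })
    s <- score_curve(models)
    gains <- diff(s)
    n_pre <- k_true - k_min  # gains up to the plateau score
    if (all(gains[seq_len(n_pre)] >= 0.012) &&
        all(abs(gains[-seq_len(n_pre)]) < 1e-9))
      return(list(models = models, plateau = k_true, scores = s))
  }
  stop("could not construct emission models with the requested plateau")
}
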