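#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the integrated
#' analysis. `data_dir` must follow the layout emitted by
#' [generate_dataset()] (peaks/, segments/, loops/, tissue_loops/,
#' compartments/, expression/, variants/, se_catalog/, annotation/,
#' genes.gtf). Defaults equal the values used throughout the module
#' documentation (consensus k = 2, ROSE stitch gap 12.5 kb and TSS
#' exclusion +/- 2.5 kb, r2 >= 0.8, peri-SNP radius 5 kb, top 5% loop
#' changes, FDR 0.05, terms in >= 4 sets).
#'
#' @param data_dir input directory.
#' @param out_dir output directory (tables, config echo, summary).
#' @param k_peaks,k_loops,k_se replicate/sample consensus thresholds.
#' @param stitch_gap,tss_exclusion_radius ROSE stitching parameters (bp).
#' @param promoter_up,promoter_down promoter window around the TSS (bp).
#' @param erna_merge_gap,erna_exclusion_radius eRNA cascade parameters (bp).
#' @param min_cpm,min_samples eRNA expression retention rule.
#' @param r2_min LD proxy threshold.
#' @param peri_radius peri-SNP window half-width (bp).
#' @param top_quantile top loop-change gene quantile.
#' @param fdr_max,min_sets enrichment-matrix thresholds.
#' @param shift_method compartment shift detection mode.
#' @param shift_delta threshold for `delta_threshold` mode.
#' @param seed seed echoed into the run manifest (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, out_dir = NULL,
                            k_peaks = 2, k_loops = 2, k_se = 2,
                            stitch_gap = 12500, tss_exclusion_radius = 2500,
                            promoter_up = 2000, promoter_down = 500,
                            erna_merge_gap = 50, erna_exclusion_radius = 3000,
                            min_cpm = 1, min_samples = 2,
                            r2_min = 0.8, peri_radius = 5000,
                            top_quantile = 0.05, fdr_max = 0.05, min_sets = 4,
                            shift_method = "external_flags", shift_delta = 0.3,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

read_labeled_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "label"))
  validate_intervals(df, path)
  sort_intervals(df)
}

read_replicate_peaks <- function(dir, mark, condition) {
  reps <- list()
  r <- 1
  repeat {
    f <- file.path(dir, sprintf("%s_%s_rep%d.narrowPeak", mark, condition, r))
    if (!file.exists(f)) break
    reps[[r]] <- read_intervals(f, "narrowPeak")
    r <- r + 1
  }
  if (length(reps) == 0)
    stop("no replicate peak files for ", mark, " ", condition, " under ", dir)
  reps
}

#' Run the full integrated pipeline
#'
#' Executes every stage against a data directory: replicate-consensus
#' peaks and condition diffs for all marks; enhancer-state classification
#' and switches; CRE assembly and diff; per-replicate super-enhancer
#' calling, consensus, diff, and catalog tissue specificity; the eRNA
#' filter cascade with CPM retention; loop consensus per condition plus a
#' pooled resource set, two-anchor loop diff, anchor annotation,
#' cross-tissue sharing and top loop-change genes; compartment shift
#' detection and per-mark signal t-tests; LD expansion and all
#' variant-to-gene integrations; and the 16-gene-set enrichment matrix.
#'
#' Deterministic given the inputs; a summary of per-stage counts is
#' returned and, when `config$out_dir` is set, written together with the
#' config echo and the main result tables.
#'
#' @param config a [pipeline_config()].
#' @return a named list with every stage's result and a `summary` count
#'   list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dd <- config$data_dir
  need <- c("genes.gtf", "peaks", "segments", "loops", "compartments",
            "expression", "variants")
  for (f in need)
    if (!file.exists(file.path(dd, f)))
      stop("missing input path: ", file.path(dd, f))
  res <- list(config = config)

  genes <- read_gene_models(file.path(dd, "genes.gtf"),
                            config$promoter_up, config$promoter_down)
  res$genes <- genes

  # ---- peaks -------------------------------------------------------------
  cons <- list(); diffs <- list()
  for (mk in ALL_MARKS) {
    cons[[mk]] <- list()
    for (cond in c("control", "dex"))
      cons[[mk]][[cond]] <- consensus_peaks(
        read_replicate_peaks(file.path(dd, "peaks"), mk, cond), config$k_peaks)
    diffs[[mk]] <- diff_peaks(cons[[mk]]$control, cons[[mk]]$dex, mk)
  }
  res$consensus_peaks <- cons
  res$diff_peaks <- diffs

  # ---- chromatin states and CREs -----------------------------------------
  segments <- list(
    control = read_labeled_bed(file.path(dd, "segments", "cre_segments_control.bed")),
    dex = read_labeled_bed(file.path(dd, "segments", "cre_segments_dex.bed")))
  repressors <- read_intervals(file.path(dd, "segments", "repressor_control.bed"),
                               "bed3")
  enh_union <- merge_intervals(rbind(
    segments$control[segments$control$label == "enhancer", c("chrom", "start", "end")],
    segments$dex[segments$dex$label == "enhancer", c("chrom", "start", "end")]))
  mark_peaks <- function(cond) list(H3K27ac = cons$H3K27ac[[cond]],
                                    H3K4me1 = cons$H3K4me1[[cond]],
                                    H3K27me3 = cons$H3K27me3[[cond]])
  res$enhancers <- classify_enhancers(enh_union, mark_peaks("control"),
                                      mark_peaks("dex"))
  cres <- lapply(segments, assemble_cres)
  res$cres <- cres
  res$cre_diff <- diff_peaks(cres$control, cres$dex, "CRE")

  # ---- super-enhancers ---------------------------------------------------
  tss_excl <- data.frame(chrom = genes$chrom,
                         start = pmax(0, genes$tss - config$tss_exclusion_radius),
                         end = genes$tss + config$tss_exclusion_radius + 1,
                         stringsAsFactors = FALSE)
  se_cons <- list()
  for (cond in c("control", "dex")) {
    reps <- read_replicate_peaks(file.path(dd, "peaks"), "H3K27ac", cond)
    sets <- lapply(reps, function(p) {
      called <- call_super_enhancers(cres[[cond]], p, config$stitch_gap, tss_excl)
      called[called$is_super, c("chrom", "start", "end"), drop = FALSE]
    })
    se_cons[[cond]] <- se_consensus(sets, config$k_se)
  }
  res$se_consensus <- se_cons
  res$se_diff <- se_diff(se_cons$control, se_cons$dex)
  se_union <- merge_intervals(rbind(
    se_cons$control[, c("chrom", "start", "end")],
    se_cons$dex[, c("chrom", "start", "end")]))
  res$se_union <- se_union
  cat_dir <- file.path(dd, "se_catalog")
  if (dir.exists(cat_dir)) {
    files <- list.files(cat_dir, full.names = TRUE)
    catalog <- lapply(files, read_intervals, dialect = "bed3")
    names(catalog) <- basename(files)
    res$se_specificity <- se_tissue_specificity(se_cons$control, catalog)
  }

  # ---- eRNAs -------------------------------------------------------------
  enh_control <- segments$control[segments$control$label == "enhancer",
                                  c("chrom", "start", "end"), drop = FALSE]
  cands <- call_erna_candidates(enh_control, genes, cons$H3K4me3$control,
                                config$erna_merge_gap,
                                config$erna_exclusion_radius)
  erna_counts <- read_count_matrix(file.path(dd, "expression", "erna_counts.tsv"))
  res$ernas <- filter_expressed(cands, erna_counts, config$min_cpm,
                                config$min_samples)

  # ---- loops -------------------------------------------------------------
  loop_files <- list.files(file.path(dd, "loops"), pattern = "\\.bedpe$",
                           full.names = TRUE)
  sample_loops <- lapply(loop_files, function(f)
    suppressWarnings(read_loops(f, sub("\\.bedpe$", "", basename(f)))))
  names(sample_loops) <- sub("\\.bedpe$", "", basename(loop_files))
  is_ctrl <- grepl("^control", names(sample_loops))
  loop_sets <- list(
    control = loop_consensus(sample_loops[is_ctrl], config$k_loops),
    dex = loop_consensus(sample_loops[!is_ctrl], config$k_loops),
    resource = loop_consensus(sample_loops, config$k_loops))
  res$loop_consensus <- loop_sets
  ldiff <- loop_diff(loop_sets$control, loop_sets$dex)
  res$loop_diff <- ldiff
  changed <- rbind(ldiff$gained, ldiff$lost)
  variants_leads <- read_variants(file.path(dd, "variants", "leads.tsv"))
  cres_by_class <- list(enhancer = enh_union, repressor = repressors,
                        super_enhancer = se_union)
  ctcf_union <- merge_intervals(rbind(
    cons$CTCF$control[, c("chrom", "start", "end")],
    cons$CTCF$dex[, c("chrom", "start", "end")]))
  res$anchor_annotation <- annotate_anchors(loop_sets$resource, genes,
                                            cres_by_class, ctcf_union,
                                            variants_leads)
  ann_changed <- annotate_anchors(changed, genes, cres_by_class, ctcf_union,
                                  variants_leads)
  res$top_loop_genes <- top_loop_change_genes(ldiff, ann_changed,
                                              config$top_quantile)
  tissue_dir <- file.path(dd, "tissue_loops")
  if (dir.exists(tissue_dir)) {
    tf <- list.files(tissue_dir, full.names = TRUE)
    catalogs <- lapply(tf, function(f)
      suppressWarnings(read_loops(f, sub("\\.bedpe$", "", basename(f)))))
    names(catalogs) <- sub("\\.bedpe$", "", basename(tf))
    res$tissue_sharing <- cross_tissue_sharing(loop_sets$resource, catalogs)
  }

  # ---- compartments ------------------------------------------------------
  tr_c <- read_intervals(file.path(dd, "compartments", "score_control.bedgraph"),
                         "bedgraph")
  tr_d <- read_intervals(file.path(dd, "compartments", "score_dex.bedgraph"),
                         "bedgraph")
  flags <- NULL
  wt_path <- file.path(dd, "compartments", "windows.tsv")
  if (config$shift_method == "external_flags") {
    wt <- read_tsv_table(wt_path)
    wt <- wt[order(wt$chrom, wt$start), , drop = FALSE]
    flags <- as.logical(wt$significant)
  }
  shifted <- detect_shifts(tr_c, tr_d, method = config$shift_method,
                           flags = flags, delta = config$shift_delta)
  res$compartment_shifts <- shifted
  dt_path <- file.path(dd, "compartments", "signal_deltas.tsv")
  if (file.exists(dt_path))
    res$signal_shift_tests <- signal_shift_tests(read_tsv_table(dt_path), shifted)

  # ---- variants ----------------------------------------------------------
  proxies <- read_variants(file.path(dd, "variants", "proxies.tsv"))
  ld_variants <- expand_ld(variants_leads, proxies, config$r2_min)
  res$ld_variants <- ld_variants
  res$loop_targets <- do.call(rbind, lapply(names(loop_sets), function(ls)
    loop_targets(ld_variants, loop_sets[[ls]], genes, loop_set = ls)))
  res$se_targets <- se_targets(ld_variants, se_union, genes)
  res$closest_genes <- suppressWarnings(closest_genes(variants_leads, genes))
  res$snp_compartments <- snp_compartment_overlap(variants_leads, shifted)
  res$peri_snp <- peri_snp_peak_changes(variants_leads, diffs,
                                        config$peri_radius)

  # ---- integration -------------------------------------------------------
  res$regulatory_changes <- classify_regulatory_changes(ldiff, ann_changed)
  de_table <- read_tsv_table(file.path(dd, "expression", "de_table.tsv"))
  sets16 <- build_gene_sets(
    genes, de_table, shifted, diffs$ATAC, res$se_diff, res$cre_diff,
    res$enhancers, diffs,
    list(diff = ldiff, annotations = ann_changed),
    res$top_loop_genes$gene_id[res$top_loop_genes$selected],
    config$fdr_max)
  res$gene_sets <- sets16
  gmt_path <- file.path(dd, "annotation", "genesets.gmt")
  if (file.exists(gmt_path)) {
    annotation <- read_gmt(gmt_path)
    res$enrichments <- lapply(stats::setNames(names(sets16), names(sets16)),
                              function(s)
      hypergeom_ora(sets16[[s]], annotation, genes$gene_id, set_name = s))
    res$term_matrix <- term_set_matrix(res$enrichments, config$fdr_max,
                                       config$min_sets)
  }

  res$summary <- list(
    n_genes = nrow(genes),
    n_consensus_peaks = vapply(cons, function(x)
      nrow(x$control) + nrow(x$dex), numeric(1)),
    n_enhancers = nrow(res$enhancers),
    enhancer_switch_fraction = mean(res$enhancers$switch %in%
                                      c("activated", "deactivated")),
    n_cres = vapply(cres, nrow, numeric(1)),
    n_super_enhancers = vapply(se_cons, nrow, numeric(1)),
    se_diff = vapply(res$se_diff[c("gained", "lost")], nrow, numeric(1)),
    n_erna_candidates = sum(res$ernas$candidate),
    n_erna_expressed = sum(res$ernas$expressed),
    n_loops = vapply(loop_sets, nrow, numeric(1)),
    loop_diff = c(stable = length(unique(ldiff$stable$name)),
                  gained = nrow(ldiff$gained), lost = nrow(ldiff$lost)),
    n_shifted_windows = sum(shifted$shift != "none"),
    n_ld_variants = nrow(ld_variants),
    n_loop_targets = nrow(res$loop_targets),
    n_se_targets = nrow(res$se_targets),
    term_matrix_dim = if (!is.null(res$term_matrix)) dim(res$term_matrix)
                      else c(0L, 0L))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(config$out_dir, "config_echo.yaml"))
    jsonlite::write_json(res$summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv_table(res$ernas, file.path(config$out_dir, "erna_candidates.tsv"))
    write_tsv_table(res$loop_targets, file.path(config$out_dir, "loop_targets.tsv"))
    write_tsv_table(res$se_targets, file.path(config$out_dir, "se_targets.tsv"))
    write_tsv_table(res$regulatory_changes,
                    file.path(config$out_dir, "regulatory_changes.tsv"))
    write_tsv_table(res$compartment_shifts,
                    file.path(config$out_dir, "compartment_windows.tsv"))
  }
  res
}
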