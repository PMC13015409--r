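#' Replicate-consensus peaks
#'
#' Candidate regions are the union-merge of all replicate peaks; a
#' candidate is retained when at least `k` replicates have >= 1 bp overlap
#' with it (the merge-then-count idiom of bedtools-style replicate
#' filtering, "observed in at least two samples").
#'
#' @param replicate_sets list of interval data.frames, one per replicate
#'   (same mark and condition).
#' @param k minimum supporting replicates, `1 <= k <= length(replicate_sets)`.
#' @return merged interval data.frame with an `n_support` column.
#' @export
consensus_peaks <- function(replicate_sets, k) {
  if (length(replicate_sets) == 0) stop("empty replicate list")
  if (k < 1 || k > length(replicate_sets))
    stop("k must be between 1 and the number of replicates (",
         length(replicate_sets), ")")
  for (df in replicate_sets) validate_intervals(df)
  pooled <- do.call(rbind, lapply(replicate_sets, function(d)
    d[, c("chrom", "start", "end"), drop = FALSE]))
  cand <- merge_intervals(pooled)
  if (nrow(cand) == 0) {
    cand$n_support <- integer(0)
    return(cand)
  }
  support <- Reduce(`+`, lapply(replicate_sets, function(d)
    as.integer(overlaps_any(cand, d))))
  cand$n_support <- support
  out <- cand[support >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Condition-level peak gain/loss by any-overlap
#'
#' A control peak with >= 1 bp overlap to any treated peak is stable (and
#' vice versa); control-only peaks are lost, treated-only peaks gained.
#'
#' @param control,treated interval data.frames (typically consensus sets).
#' @param mark optional mark label carried on the result.
#' @return an object of class `diff_peaks`: list with `mark`, `gained`,
#'   `lost` and `stable` (the stable table carries a `side` column so the
#'   per-side partition is recoverable).
#' @export
diff_peaks <- function(control, treated, mark = NA_character_) {
  validate_intervals(control, "control")
  validate_intervals(treated, "treated")
  ol_c <- overlaps_any(control, treated)
  ol_t <- overlaps_any(treated, control)
  tag <- function(df, side) {
    df$side <- rep(side, nrow(df))
    df
  }
  stable <- rbind(tag(control[ol_c, , drop = FALSE], "control"),
                  tag(treated[ol_t, , drop = FALSE], "treated"))
  lost <- control[!ol_c, , drop = FALSE]
  gained <- treated[!ol_t, , drop = FALSE]
  rownames(stable) <- rownames(lost) <- rownames(gained) <- NULL
  structure(list(mark = mark, gained = gained, lost = lost, stable = stable),
            class = "diff_peaks")
}

changed_peaks <- function(diff) {
  rbind(diff$gained[, c("chrom", "start", "end"), drop = FALSE],
        diff$lost[, c("chrom", "start", "end"), drop = FALSE])
}

#' Activating/repressive epigenetic changes near differentially expressed genes
#'
#' Gain of H3K27ac or loss of H3K27me3 near a gene is an activating event;
#' gain of H3K27me3 or loss of H3K27ac is repressive. Events are binned by
#' the distance from the peak midpoint to the gene TSS; peaks beyond the
#' last cutoff are ignored.
#'
#' @param diff_h3k27ac,diff_h3k27me3 [diff_peaks()] results for the two
#'   marks.
#' @param genes gene-model table.
#' @param de_table data.frame with a `gene_id` column naming the
#'   differentially expressed genes to summarize.
#' @param bins strictly increasing distance cutoffs in bp
#'   (default 10 kb, 100 kb, 1 Mb).
#' @return data.frame `gene_id`, `distance_bin`, `n_activating`,
#'   `n_repressive` (complete grid, zero counts included).
#' @export
classify_epigenetic_changes <- function(diff_h3k27ac, diff_h3k27me3, genes,
                                        de_table,
                                        bins = c(1e4, 1e5, 1e6)) {
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  de_genes <- unique(de_table$gene_id)
  missing <- setdiff(de_genes, genes$gene_id)
  if (length(missing))
    stop("gene(s) absent from gene models: ", paste(missing, collapse = ", "))
  gm <- genes[match(de_genes, genes$gene_id), , drop = FALSE]
  ev <- function(df, cls) {
    if (nrow(df) == 0) return(NULL)
    cbind(df[, c("chrom", "start", "end")], class = cls)
  }
  events <- rbind(ev(diff_h3k27ac$gained, "activating"),
                  ev(diff_h3k27me3$lost, "activating"),
                  ev(diff_h3k27me3$gained, "repressive"),
                  ev(diff_h3k27ac$lost, "repressive"))
  if (is.null(events))
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), class = character())
  bin_labels <- c(paste0("<=", format_bp(bins[1])),
                  if (length(bins) > 1)
                    paste0(format_bp(bins[-length(bins)]), "-", format_bp(bins[-1])))
  grid <- expand.grid(gene_id = de_genes, distance_bin = bin_labels,
                      stringsAsFactors = FALSE)
  grid$n_activating <- 0L
  grid$n_repressive <- 0L
  if (nrow(events)) {
    mid <- floor((events$start + events$end) / 2)
    for (gi in seq_len(nrow(gm))) {
      on_chrom <- events$chrom == gm$chrom[gi]
      if (!any(on_chrom)) next
      d <- abs(mid[on_chrom] - gm$tss[gi])
      bin_idx <- vapply(d, function(x) {
        w <- which(x <= bins)
        if (length(w)) w[1] else NA_integer_
      }, integer(1))
      cls <- events$class[on_chrom]
      for (ev in which(!is.na(bin_idx))) {
        row <- grid$gene_id == gm$gene_id[gi] &
          grid$distance_bin == bin_labels[bin_idx[ev]]
        if (cls[ev] == "activating")
          grid$n_activating[row] <- grid$n_activating[row] + 1L
        else
          grid$n_repressive[row] <- grid$n_repressive[row] + 1L
      }
    }
  }
  grid
}

format_bp <- function(x) {
  vapply(x, function(v) {
    if (v >= 1e6 && v %% 1e6 == 0) paste0(v / 1e6, "Mb")
    else if (v >= 1e3 && v %% 1e3 == 0) paste0(v / 1e3, "kb")
    else paste0(v, "bp")
  }, character(1))
}
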