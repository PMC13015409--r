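#' Read a GWAS variant table
#'
#' TSV columns: `rsid`, `chrom`, `pos` (1-based, dbSNP convention —
#' converted to 0-based on read), `trait`, `lead_rsid`, `r2`. A variant is
#' a lead when `rsid == lead_rsid`.
#'
#' @param path TSV file.
#' @return data.frame with 0-based `pos` and an `is_lead` column.
#' @export
read_variants <- function(path) {
  df <- read_tsv_table(path)
  need <- c("rsid", "chrom", "pos", "trait", "lead_rsid", "r2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE)) stop("r2 outside [0,1]")
  df$pos <- df$pos - 1  # to 0-based
  df$is_lead <- df$rsid == df$lead_rsid
  df
}

#' Expand lead variants with LD proxies
#'
#' Retains proxies with `r2 >= r2_min` lying within 1 Mb of their lead on
#' the same chromosome; leads are always retained (r2 = 1 to themselves).
#'
#' @param leads lead variant data.frame (0-based `pos`).
#' @param proxy_table proxy variant data.frame referencing leads via
#'   `lead_rsid`.
#' @param r2_min LD threshold (default 0.8).
#' @param max_distance lead-to-proxy distance cap in bp (default 1e6).
#' @return combined variant data.frame (leads + retained proxies).
#' @export
expand_ld <- function(leads, proxy_table, r2_min = 0.8, max_distance = 1e6) {
  unknown <- setdiff(unique(proxy_table$lead_rsid), leads$rsid)
  if (length(unknown))
    stop("prox(ies) referencing unknown lead(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  li <- match(proxy_table$lead_rsid, leads$rsid)
  keep <- proxy_table$r2 >= r2_min &
    proxy_table$chrom == leads$chrom[li] &
    abs(proxy_table$pos - leads$pos[li]) <= max_distance
  out <- rbind(leads[, c("rsid", "chrom", "pos", "trait", "lead_rsid", "r2")],
               proxy_table[keep, c("rsid", "chrom", "pos", "trait",
                                   "lead_rsid", "r2"), drop = FALSE])
  out$is_lead <- out$rsid == out$lead_rsid
  rownames(out) <- NULL
  out
}

variant_intervals <- function(variants) {
  data.frame(chrom = variants$chrom, start = variants$pos,
             end = variants$pos + 1, stringsAsFactors = FALSE)
}

#' Variant-to-gene assignment through chromatin loops
#'
#' Emits one assignment for every loop with the variant in one anchor and
#' at least 1 bp of a gene promoter in the other anchor (both anchor
#' orderings are tested; a variant overlapping both anchors collects genes
#' from either side). Identical (variant, gene, loop) triples are
#' deduplicated.
#'
#' @param variants variant data.frame (0-based `pos`).
#' @param loops loop data.frame.
#' @param genes gene-model table.
#' @param loop_set optional label recording which loop set was used
#'   (e.g. `resource`, `control`, `dex`).
#' @return data.frame `rsid`, `trait`, `gene_id`, `mechanism` (`loop`),
#'   `evidence` (loop id), `loop_set`.
#' @export
loop_targets <- function(variants, loops, genes, loop_set = NA_character_) {
  empty <- data.frame(rsid = character(), trait = character(),
                      gene_id = character(), mechanism = character(),
                      evidence = character(), loop_set = character(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0 || nrow(loops) == 0 || nrow(genes) == 0) return(empty)
  ids <- loop_ids(loops)
  v_iv <- variant_intervals(variants)
  prom <- promoters_of(genes)
  va <- list(overlap_pairs(v_iv, anchor1_of(loops)),
             overlap_pairs(v_iv, anchor2_of(loops)))
  pa <- list(overlap_pairs(prom, anchor1_of(loops)),
             overlap_pairs(prom, anchor2_of(loops)))
  out <- list()
  for (cfg in list(c(1, 2), c(2, 1))) {   # (variant anchor, promoter anchor)
    v <- va[[cfg[1]]]; p <- pa[[cfg[2]]]
    if (nrow(v) == 0 || nrow(p) == 0) next
    j <- merge(v, p, by = "subject")      # join on loop index
    if (nrow(j) == 0) next
    out[[length(out) + 1]] <- data.frame(
      rsid = variants$rsid[j$query.x], trait = variants$trait[j$query.x],
      gene_id = genes$gene_id[j$query.y], mechanism = "loop",
      evidence = ids[j$subject], loop_set = loop_set,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Variant-to-gene assignment through shared super-enhancers
#'
#' One assignment per (variant, gene) pair whose variant position and
#' gene promoter (>= 1 bp) both fall inside the same SE interval.
#'
#' @param variants variant data.frame.
#' @param super_enhancers SE interval data.frame.
#' @param genes gene-model table.
#' @return data.frame `rsid`, `trait`, `gene_id`, `mechanism`
#'   (`super_enhancer`), `evidence` (SE id).
#' @export
se_targets <- function(variants, super_enhancers, genes) {
  empty <- data.frame(rsid = character(), trait = character(),
                      gene_id = character(), mechanism = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0 || nrow(super_enhancers) == 0 || nrow(genes) == 0)
    return(empty)
  se_ids <- interval_id(super_enhancers)
  v_hits <- overlap_pairs(variant_intervals(variants), super_enhancers)
  p_hits <- overlap_pairs(promoters_of(genes), super_enhancers)
  j <- merge(v_hits, p_hits, by = "subject")
  if (nrow(j) == 0) return(empty)
  res <- unique(data.frame(
    rsid = variants$rsid[j$query.x], trait = variants$trait[j$query.x],
    gene_id = genes$gene_id[j$query.y], mechanism = "super_enhancer",
    evidence = se_ids[j$subject], stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Closest gene(s) to each variant
#'
#' Nearest gene by edge-to-edge distance to the gene body (0 when the
#' variant lies inside a gene); all genes tied at the minimum distance are
#' reported. A variant on a chromosome without genes yields an NA gene
#' with a warning.
#'
#' @param variants variant data.frame.
#' @param genes gene-model table.
#' @return data.frame `rsid`, `trait`, `gene_id`, `mechanism` (`closest`),
#'   `distance`.
#' @export
closest_genes <- function(variants, genes) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    g <- genes[genes$chrom == variants$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      warning("variant ", variants$rsid[i], " on chromosome without genes: ",
              variants$chrom[i], call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        rsid = variants$rsid[i], trait = variants$trait[i],
        gene_id = NA_character_, mechanism = "closest",
        distance = NA_real_, stringsAsFactors = FALSE)
      next
    }
    pos <- variants$pos[i]
    # edge-to-edge gap to [start, end); 0 if pos inside
    d <- ifelse(pos < g$start, g$start - pos - 1,
                ifelse(pos >= g$end, pos - g$end, 0))
    d <- pmax(d, 0)
    hits <- which(d == min(d))
    out[[length(out) + 1]] <- data.frame(
      rsid = variants$rsid[i], trait = variants$trait[i],
      gene_id = g$gene_id[hits], mechanism = "closest",
      distance = d[hits], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compartment-shift label of the window containing each variant
#'
#' Variants are assigned the shift direction of the half-open window
#' containing their position (a position equal to a window end belongs to
#' the next window), else `none`.
#'
#' @param variants variant data.frame.
#' @param shifted [detect_shifts()] output.
#' @return data.frame `rsid`, `trait`, `shift`.
#' @export
snp_compartment_overlap <- function(variants, shifted) {
  lab <- rep("none", nrow(variants))
  p <- overlap_pairs(variant_intervals(variants), shifted)
  lab[p$query] <- shifted$shift[p$subject]
  data.frame(rsid = variants$rsid, trait = variants$trait, shift = lab,
             stringsAsFactors = FALSE)
}

#' Peri-SNP peak-change counts
#'
#' For each variant, counts gained and lost peaks per mark with >= 1 bp
#' overlap of the window `[pos - radius, pos + radius + 1)` (clipped at
#' 0).
#'
#' @param variants variant data.frame.
#' @param diff_peaks_by_mark named list of [diff_peaks()] results.
#' @param radius window half-width in bp (default 5000).
#' @return data.frame `rsid`, `trait`, `mark`, `n_gained`, `n_lost`
#'   (complete variant x mark grid).
#' @export
peri_snp_peak_changes <- function(variants, diff_peaks_by_mark, radius = 5000) {
  stopifnot(radius > 0)
  win <- data.frame(chrom = variants$chrom,
                    start = pmax(0, variants$pos - radius),
                    end = variants$pos + radius + 1,
                    stringsAsFactors = FALSE)
  out <- list()
  for (mk in names(diff_peaks_by_mark)) {
    d <- diff_peaks_by_mark[[mk]]
    ng <- if (nrow(d$gained)) GenomicRanges::countOverlaps(gr_of(win), gr_of(d$gained))
          else integer(nrow(win))
    nl <- if (nrow(d$lost)) GenomicRanges::countOverlaps(gr_of(win), gr_of(d$lost))
          else integer(nrow(win))
    out[[mk]] <- data.frame(rsid = variants$rsid, trait = variants$trait,
                            mark = mk, n_gained = as.integer(ng),
                            n_lost = as.integer(nl), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
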