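#' Derive enhancer-RNA candidates by the geometric filter cascade
#'
#' Enhancer regions are merged within `merge_gap` bp, then a merged region
#' survives only if it (1) has no >= 1 bp gene-body overlap, (2) lies at
#' least `exclusion_radius` bp from every TSS, and (3) lies at least
#' `exclusion_radius` bp from every H3K4me3 peak. Distances are
#' edge-to-edge gaps (0 when overlapping); "within" is strict
#' (`distance < exclusion_radius` rejects).
#'
#' @param enhancers enhancer interval data.frame (chromatin-state
#'   enhancer segments).
#' @param genes gene-model table (bodies and TSSs).
#' @param h3k4me3_peaks H3K4me3 consensus peak table.
#' @param merge_gap merge gap in bp (default 50).
#' @param exclusion_radius TSS / H3K4me3 exclusion distance in bp
#'   (default 3000).
#' @return data.frame of merged regions with `id`, per-filter pass
#'   columns (`pass_gene_body`, `pass_tss_distance`,
#'   `pass_h3k4me3_distance`) and the conjunction `candidate`.
#' @export
call_erna_candidates <- function(enhancers, genes, h3k4me3_peaks,
                                 merge_gap = 50, exclusion_radius = 3000) {
  merged <- merge_intervals(enhancers, gap = merge_gap)
  if (nrow(merged) == 0) {
    merged$id <- character(0)
    merged$pass_gene_body <- merged$pass_tss_distance <-
      merged$pass_h3k4me3_distance <- merged$candidate <- logical(0)
    return(merged)
  }
  merged$id <- interval_id(merged)
  tss <- data.frame(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1, stringsAsFactors = FALSE)
  merged$pass_gene_body <- !overlaps_any(merged, bodies_of(genes))
  merged$pass_tss_distance <- nearest_distance(merged, tss) >= exclusion_radius
  merged$pass_h3k4me3_distance <-
    nearest_distance(merged, h3k4me3_peaks) >= exclusion_radius
  merged$candidate <- merged$pass_gene_body & merged$pass_tss_distance &
    merged$pass_h3k4me3_distance
  merged
}

#' Counts-per-million normalization
#'
#' `cpm[g, s] = counts[g, s] / colsum(s) * 1e6`; every column of the
#' result sums to 1e6.
#'
#' @param counts non-negative feature-by-sample matrix.
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("zero library size in sample(s): ",
                           paste(colnames(counts)[libs <= 0], collapse = ", "))
  sweep(counts, 2, libs, "/") * 1e6
}

#' Retain candidates expressed above a CPM threshold
#'
#' A candidate is retained iff its CPM exceeds `min_cpm` (strictly) in at
#' least `min_samples` samples — the ">1 CPM in at least 2 samples" rule.
#'
#' @param candidates [call_erna_candidates()] output (rows with
#'   `candidate == TRUE` are evaluated; others are marked not expressed).
#' @param counts feature-by-sample count matrix whose row names cover the
#'   candidate `id`s.
#' @param min_cpm strict CPM threshold (default 1).
#' @param min_samples minimum qualifying samples (default 2).
#' @return `candidates` with an `expressed` logical column.
#' @export
filter_expressed <- function(candidates, counts, min_cpm = 1, min_samples = 2) {
  geom <- candidates$candidate
  ids <- candidates$id[geom]
  missing <- setdiff(ids, rownames(counts))
  if (length(missing))
    stop("candidate(s) missing from counts: ",
         paste(utils::head(missing, 10), collapse = ", "))
  cpm_m <- cpm(counts)
  n_over <- rowSums(cpm_m[ids, , drop = FALSE] > min_cpm)
  candidates$expressed <- FALSE
  candidates$expressed[geom] <- n_over >= min_samples
  candidates
}
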