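#' Stitch CREs and rank by H3K27ac signal (ROSE-style)
#'
#' Constituent CREs fully inside a TSS-exclusion window are dropped, the
#' remainder stitched when separated by at most `stitch_gap` bp
#' (inclusive), and each stitched region scored as the sum of overlapping
#' H3K27ac peak signals prorated by overlap fraction. Regions are returned
#' ranked ascending by signal.
#'
#' @param cres CRE interval data.frame.
#' @param h3k27ac_peaks interval data.frame with a non-negative `score`
#'   column (signal).
#' @param stitch_gap maximum stitched gap in bp (default 12,500, the
#'   canonical ROSE value).
#' @param tss_exclusion interval data.frame of TSS windows (constituents
#'   fully within one are discarded before stitching), or NULL.
#' @return data.frame `chrom`, `start`, `end`, `constituent_count`,
#'   `signal`, `rank` (ascending by signal).
#' @export
stitch_and_rank <- function(cres, h3k27ac_peaks, stitch_gap = 12500,
                            tss_exclusion = NULL) {
  stopifnot(stitch_gap >= 0)
  validate_intervals(cres, "cres")
  validate_intervals(h3k27ac_peaks, "h3k27ac_peaks")
  if (is.null(h3k27ac_peaks$score) || any(is.na(h3k27ac_peaks$score)) ||
      any(h3k27ac_peaks$score < 0))
    stop("h3k27ac_peaks must carry non-negative signal in 'score'")
  kept <- cres
  if (!is.null(tss_exclusion) && nrow(tss_exclusion) && nrow(cres)) {
    inside <- GenomicRanges::countOverlaps(gr_of(cres), gr_of(tss_exclusion),
                                           type = "within") > 0
    kept <- cres[!inside, , drop = FALSE]
  }
  if (nrow(kept) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      constituent_count = integer(), signal = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  stitched <- merge_intervals(kept, gap = stitch_gap)
  stitched$constituent_count <-
    GenomicRanges::countOverlaps(gr_of(stitched), gr_of(kept))
  sg <- gr_of(stitched); pg <- gr_of(h3k27ac_peaks)
  h <- GenomicRanges::findOverlaps(sg, pg)
  signal <- numeric(nrow(stitched))
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(sg[qi], pg[si]))
    contrib <- h3k27ac_peaks$score[si] * ow / GenomicRanges::width(pg)[si]
    agg <- tapply(contrib, qi, sum)
    signal[as.integer(names(agg))] <- as.numeric(agg)
  }
  stitched$signal <- signal
  stitched <- stitched[order(stitched$signal), , drop = FALSE]
  stitched$rank <- seq_len(nrow(stitched))
  rownames(stitched) <- NULL
  stitched
}

#' Geometric super-enhancer cutoff on a ranked signal curve
#'
#' Rank and signal are each scaled to \[0, 1\]; the cutoff index is the
#' argmax of (scaled rank - scaled signal), i.e. the slope-1 tangent point
#' of the convex hockey stick. Regions with signal strictly greater than
#' the cutoff signal are super; ties at the maximum gap break toward the
#' larger index (fewer super-enhancers). A constant or effectively linear
#' curve (maximum gap below `tol`) yields zero super-enhancers with a
#' warning.
#'
#' @param signals non-decreasing numeric vector of stitched-region
#'   signals, length >= 3.
#' @param tol degeneracy tolerance on the maximum scaled gap.
#' @return list with `cutoff_index`, `is_super` (logical vector) and
#'   `gap` (the scaled rank-minus-signal curve).
#' @export
se_cutoff <- function(signals, tol = 1e-9) {
  n <- length(signals)
  if (n < 3) stop("insufficient regions: need at least 3 ranked signals")
  if (is.unsorted(signals)) stop("signals must be sorted ascending")
  rng <- max(signals) - min(signals)
  x <- (seq_len(n) - 1) / (n - 1)
  if (rng == 0) {
    warning("constant signal: no super-enhancers called", call. = FALSE)
    return(list(cutoff_index = n, is_super = rep(FALSE, n), gap = x * 0))
  }
  y <- (signals - min(signals)) / rng
  d <- x - y
  if (max(d) <= tol) {
    warning("degenerate (linear) signal curve: no super-enhancers called",
            call. = FALSE)
    return(list(cutoff_index = n, is_super = rep(FALSE, n), gap = d))
  }
  i_star <- max(which(d == max(d)))
  list(cutoff_index = i_star,
       is_super = signals > signals[i_star],
       gap = d)
}

#' Call super-enhancers: stitch, rank and apply the elbow cutoff
#'
#' Convenience wrapper chaining [stitch_and_rank()] and [se_cutoff()].
#'
#' @inheritParams stitch_and_rank
#' @param ... passed to [se_cutoff()].
#' @return the [stitch_and_rank()] table with an `is_super` column.
#' @export
call_super_enhancers <- function(cres, h3k27ac_peaks, stitch_gap = 12500,
                                 tss_exclusion = NULL, ...) {
  ranked <- stitch_and_rank(cres, h3k27ac_peaks, stitch_gap, tss_exclusion)
  if (nrow(ranked) < 3) {
    ranked$is_super <- rep(FALSE, nrow(ranked))
    return(ranked)
  }
  cut <- se_cutoff(ranked$signal, ...)
  ranked$is_super <- cut$is_super
  ranked
}

#' Multi-set consensus super-enhancers
#'
#' Same merge-then-count semantics as [consensus_peaks()]: union-merge all
#' SE sets, retain merged regions with >= 1 bp overlap support from at
#' least `k` input sets.
#'
#' @param se_sets list of SE interval data.frames.
#' @param k minimum supporting sets.
#' @return merged interval data.frame with `n_support`.
#' @export
se_consensus <- function(se_sets, k) {
  if (length(se_sets) == 0) stop("empty SE set list")
  consensus_peaks(se_sets, k)
}

#' Gained/lost/stable super-enhancers between conditions
#'
#' Identical contract to [diff_peaks()].
#'
#' @param control,treated SE interval data.frames.
#' @return a `diff_peaks` object.
#' @export
se_diff <- function(control, treated) diff_peaks(control, treated, mark = "SE")

#' Tissue specificity of SEs against an external catalog
#'
#' A catalog sample counts for a query SE when one of its SEs covers at
#' least `min_coverage` of the query SE's length (single-SE coverage by
#' default; `stacked = TRUE` instead unions all of the sample's
#' overlapping SEs).
#'
#' @param tm_ses query SE interval data.frame.
#' @param catalog named list mapping catalog sample id to an SE interval
#'   data.frame.
#' @param min_coverage covered fraction threshold (default 0.7).
#' @param stacked union coverage across a sample's SEs instead of
#'   single-SE coverage (default FALSE).
#' @return `tm_ses` with `n_samples`, `fraction_samples` columns.
#' @export
se_tissue_specificity <- function(tm_ses, catalog, min_coverage = 0.7,
                                  stacked = FALSE) {
  if (length(catalog) == 0) stop("empty catalog")
  validate_intervals(tm_ses, "tm_ses")
  qg <- gr_of(tm_ses)
  qw <- GenomicRanges::width(qg)
  counts <- integer(nrow(tm_ses))
  for (s in seq_along(catalog)) {
    cg <- gr_of(catalog[[s]])
    h <- GenomicRanges::findOverlaps(qg, cg)
    if (length(h) == 0) next
    qi <- S4Vectors::queryHits(h)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
      qg[qi], cg[S4Vectors::subjectHits(h)]))
    if (stacked) {
      # union of the sample's SEs restricted to each query SE
      cov <- vapply(unique(qi), function(q) {
        sub <- GenomicRanges::reduce(GenomicRanges::pintersect(
          qg[rep(q, sum(qi == q))], cg[S4Vectors::subjectHits(h)[qi == q]]))
        sum(GenomicRanges::width(sub))
      }, numeric(1))
      frac <- cov / qw[unique(qi)]
      hit <- unique(qi)[frac >= min_coverage]
    } else {
      frac <- ow / qw[qi]
      hit <- unique(qi[frac >= min_coverage])
    }
    counts[hit] <- counts[hit] + 1L
  }
  out <- tm_ses
  out$n_samples <- counts
  out$fraction_samples <- counts / length(catalog)
  out
}
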