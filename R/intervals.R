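#' Build a genomic-interval table
#'
#' The atom of all overlap algebra in the package: a data.frame with columns
#' `chrom`, `start`, `end` (0-based half-open) and optional `name`/`score`.
#'
#' @param chrom character vector of chromosome names (exact string match is
#'   used everywhere; no "chr" aliasing).
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param name,score optional per-interval annotation.
#' @return a sorted interval data.frame.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(),
                      name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  sort_intervals(df)
}

validate_intervals <- function(df, ctx = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(ctx, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(ctx, ": empty chromosome name")
  if (any(df$start < 0)) stop(ctx, ": negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(ctx, ": start >= end at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(df)
}

#' Sort an interval table by (chrom, start, end)
#' @param df interval data.frame.
#' @return the sorted data.frame, row names dropped.
#' @export
sort_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 0-based half-open data.frame -> GRanges (1-based closed) and back.
# These two helpers are the only place the convention shift happens.
gr_of <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

df_of <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Union-merge intervals, optionally bridging gaps
#'
#' Overlapping and book-ended intervals are always merged; `gap > 0`
#' additionally merges intervals separated by at most `gap` bases
#' (inclusive), the semantics used for enhancer merging (50 bp) and
#' super-enhancer stitching (12,500 bp).
#'
#' @param df interval data.frame.
#' @param gap maximum separation (bp) bridged by the merge; default 0
#'   (book-ended intervals still merge).
#' @return merged, sorted interval data.frame.
#' @export
merge_intervals <- function(df, gap = 0) {
  validate_intervals(df)
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  r <- GenomicRanges::reduce(gr_of(df), min.gapwidth = gap + 1)
  sort_intervals(df_of(r))
}

# chromosome naming is exact-match only; sets with no chromosome in common
# yield zero overlaps plus a warning naming the unshared chromosomes
check_shared_chroms <- function(query, subject) {
  if (nrow(query) && nrow(subject) &&
      !any(unique(query$chrom) %in% unique(subject$chrom)))
    warn_unshared_chroms(query, subject)
}

# index pairs (query, subject) of >=1 bp overlaps between two interval tables
overlap_pairs <- function(query, subject) {
  check_shared_chroms(query, subject)
  h <- suppressWarnings(GenomicRanges::findOverlaps(gr_of(query), gr_of(subject)))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

# logical: does each query interval overlap any subject interval (>=1 bp)?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  check_shared_chroms(query, subject)
  suppressWarnings(GenomicRanges::countOverlaps(gr_of(query), gr_of(subject))) > 0
}

# edge-to-edge gap distance (0 if overlapping or book-ended) from each query
# interval to its nearest subject interval on the same chromosome; Inf when
# the chromosome carries no subject feature.
nearest_distance <- function(query, subject) {
  if (nrow(query) == 0) return(numeric(0))
  out <- rep(Inf, nrow(query))
  if (nrow(subject) == 0) return(out)
  qg <- gr_of(query)
  sg <- gr_of(subject)
  h <- GenomicRanges::distanceToNearest(qg, sg)
  out[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
  out
}

interval_id <- function(df) paste0(df$chrom, ":", df$start, "-", df$end)

# warn once about chromosome names present on only one side of an overlap
warn_unshared_chroms <- function(a, b, what = "overlap") {
  ca <- unique(a$chrom); cb <- unique(b$chrom)
  only <- c(setdiff(ca, cb), setdiff(cb, ca))
  if (length(only))
    warning(what, ": chromosome names present on one side only: ",
            paste(sort(unique(only)), collapse = ", "), call. = FALSE)
  invisible(NULL)
}
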