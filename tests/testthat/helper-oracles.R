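# Independent brute-force oracles. Each works position-by-position or by
# exhaustive enumeration and never calls the package's interval machinery.

# per-base replicate support on a small chromosome; returns the set of
# 0-based positions covered by >= k replicates (restricted to one chrom)
oracle_support_bases <- function(replicate_sets, k, chrom_len) {
  cover <- matrix(0L, length(replicate_sets), chrom_len)
  for (r in seq_along(replicate_sets)) {
    df <- replicate_sets[[r]]
    for (i in seq_len(nrow(df)))
      cover[r, (df$start[i] + 1):df$end[i]] <- 1L
  }
  # merge-then-count: a candidate region is a maximal covered run; it is
  # retained iff >= k replicates overlap it anywhere
  any_cover <- colSums(cover) > 0
  runs <- rle(any_cover)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  kept <- logical(chrom_len)
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    span <- starts[j]:ends[j]
    support <- sum(vapply(seq_along(replicate_sets), function(r)
      any(cover[r, span] > 0), logical(1)))
    if (support >= k) kept[span] <- TRUE
  }
  which(kept) - 1L
}

# base set covered by an interval data.frame on one chromosome
bases_of <- function(df, chrom_len) {
  kept <- logical(chrom_len)
  for (i in seq_len(nrow(df))) kept[(df$start[i] + 1):df$end[i]] <- TRUE
  which(kept) - 1L
}

# O(n*m) any-overlap diff labels
oracle_diff_labels <- function(control, treated) {
  ov <- function(a, b, i, j) a$chrom[i] == b$chrom[j] &&
    a$start[i] < b$end[j] && b$start[j] < a$end[i]
  c_stable <- vapply(seq_len(nrow(control)), function(i)
    any(vapply(seq_len(nrow(treated)), function(j)
      ov(control, treated, i, j), logical(1))), logical(1))
  t_stable <- vapply(seq_len(nrow(treated)), function(j)
    any(vapply(seq_len(nrow(control)), function(i)
      ov(control, treated, i, j), logical(1))), logical(1))
  list(control_stable = c_stable, treated_stable = t_stable)
}

# direct four-way overlap evaluation of the two-anchor loop match
oracle_loops_match <- function(a, b) {
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  straight <- ov(a$chrom1, a$start1, a$end1, b$chrom1, b$start1, b$end1) &&
    ov(a$chrom2, a$start2, a$end2, b$chrom2, b$start2, b$end2)
  crossed <- ov(a$chrom1, a$start1, a$end1, b$chrom2, b$start2, b$end2) &&
    ov(a$chrom2, a$start2, a$end2, b$chrom1, b$start1, b$end1)
  straight || crossed
}

# exhaustive closest-gene scan (edge-to-edge gap to the gene body)
oracle_closest <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  d <- vapply(seq_len(nrow(g)), function(i) {
    if (pos >= g$start[i] && pos < g$end[i]) return(0)
    if (pos < g$start[i]) return(g$start[i] - pos - 1)
    pos - g$end[i]
  }, numeric(1))
  list(gene_id = g$gene_id[d == min(d)], distance = min(d))
}

# window-scan peri-SNP counter
oracle_peri_counts <- function(pos, chrom, peaks, radius) {
  lo <- max(0, pos - radius); hi <- pos + radius + 1
  sum(vapply(seq_len(nrow(peaks)), function(i)
    peaks$chrom[i] == chrom && peaks$start[i] < hi && lo < peaks$end[i],
    logical(1)))
}

# triple-loop anchor annotation: for every (loop, anchor, feature), test
# the overlap directly
oracle_anchor_labels <- function(loops, features, feature_ids) {
  out <- list()
  for (li in seq_len(nrow(loops)))
    for (anchor in 1:2) {
      as_ <- if (anchor == 1) loops$start1[li] else loops$start2[li]
      ae <- if (anchor == 1) loops$end1[li] else loops$end2[li]
      ac <- if (anchor == 1) loops$chrom1[li] else loops$chrom2[li]
      for (fi in seq_len(nrow(features)))
        if (ac == features$chrom[fi] && as_ < features$end[fi] &&
            features$start[fi] < ae)
          out[[length(out) + 1]] <- data.frame(
            loop = li, anchor = anchor, feature_id = feature_ids[fi],
            stringsAsFactors = FALSE)
    }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(loop = integer(), anchor = integer(), feature_id = character())
}

# hypergeometric upper tail by enumeration of all n-draws from N
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements are "successes"
  mean(hits >= k)
}

# all-pairs Pearson best-match score between two emission matrices
oracle_model_score <- function(a, b) {
  mean(vapply(seq_len(nrow(a)), function(i)
    max(vapply(seq_len(nrow(b)), function(j) {
      if (stats::sd(a[i, ]) == 0 || stats::sd(b[j, ]) == 0) 0
      else stats::cor(a[i, ], b[j, ])
    }, numeric(1))), numeric(1)))
}

# prorated signal sum for one region over peaks
oracle_region_signal <- function(region, peaks) {
  s <- 0
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != region$chrom) next
    ov <- min(region$end, peaks$end[i]) - max(region$start, peaks$start[i])
    if (ov > 0) s <- s + peaks$score[i] * ov / (peaks$end[i] - peaks$start[i])
  }
  s
}
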