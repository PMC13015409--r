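#' Construct a loop table
#'
#' Loops are ordered pairs of intra-chromosomal anchor intervals with an
#' optional score and a `samples` list-column recording which samples the
#' loop was called in. Anchors are kept in canonical order (anchor1 before
#' anchor2 lexicographically by chrom, start, end).
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 anchor coordinates
#'   (0-based half-open).
#' @param name,score optional loop id / score.
#' @param samples optional list of character vectors (one per loop).
#' @return a canonical loop data.frame.
#' @export
loop_table <- function(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                       chrom2 = character(), start2 = numeric(), end2 = numeric(),
                       name = NULL, score = NULL, samples = NULL) {
  n <- length(chrom1)
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.numeric(start1),
                   end1 = as.numeric(end1), chrom2 = as.character(chrom2),
                   start2 = as.numeric(start2), end2 = as.numeric(end2),
                   stringsAsFactors = FALSE)
  df$name <- if (is.null(name)) rep(".", n) else as.character(name)
  df$score <- if (is.null(score)) rep(NA_real_, n) else as.numeric(score)
  df <- canonicalize_loops(df)
  df$samples <- if (is.null(samples)) replicate(n, character(0), simplify = FALSE) else samples
  df
}

#' Normalize loop anchor order
#'
#' Swaps anchors so that (chrom1, start1, end1) <= (chrom2, start2, end2)
#' lexicographically.
#'
#' @param loops loop data.frame.
#' @return the canonicalized data.frame.
#' @export
canonicalize_loops <- function(loops) {
  if (nrow(loops) == 0) return(loops)
  swap <- (loops$chrom2 < loops$chrom1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 < loops$start1) |
    (loops$chrom2 == loops$chrom1 & loops$start2 == loops$start1 &
       loops$end2 < loops$end1)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  rownames(loops) <- NULL
  loops
}

anchor1_of <- function(loops) data.frame(chrom = loops$chrom1, start = loops$start1,
                                         end = loops$end1, stringsAsFactors = FALSE)
anchor2_of <- function(loops) data.frame(chrom = loops$chrom2, start = loops$start2,
                                         end = loops$end2, stringsAsFactors = FALSE)

pad_anchor <- function(a, padding) {
  if (padding > 0) {
    a$start <- pmax(0, a$start - padding)
    a$end <- a$end + padding
  }
  a
}

#' Index pairs of two-anchor-matching loops between two loop tables
#'
#' Two loops match when both anchors overlap (>= 1 bp, optionally after
#' symmetric padding), testing both anchor pairings.
#'
#' @param a,b loop data.frames.
#' @param padding symmetric anchor padding in bp (default 0).
#' @return data.frame with columns `i` (row in `a`) and `j` (row in `b`).
#' @export
loop_match_pairs <- function(a, b, padding = 0) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(i = integer(), j = integer()))
  a1 <- pad_anchor(anchor1_of(a), padding); a2 <- pad_anchor(anchor2_of(a), padding)
  b1 <- pad_anchor(anchor1_of(b), padding); b2 <- pad_anchor(anchor2_of(b), padding)
  key <- function(p) paste(p$query, p$subject)
  p11 <- overlap_pairs(a1, b1); p22 <- overlap_pairs(a2, b2)
  straight <- p11[key(p11) %in% key(p22), , drop = FALSE]
  p12 <- overlap_pairs(a1, b2); p21 <- overlap_pairs(a2, b1)
  crossed <- p12[key(p12) %in% key(p21), , drop = FALSE]
  out <- unique(rbind(straight, crossed))
  data.frame(i = out$query, j = out$subject)
}

#' Do two loops match by two-anchor overlap?
#'
#' @param a,b single-row loop data.frames.
#' @param padding symmetric anchor padding in bp.
#' @return logical scalar.
#' @export
loops_match <- function(a, b, padding = 0) {
  nrow(loop_match_pairs(a[1, , drop = FALSE], b[1, , drop = FALSE], padding)) > 0
}

# minimal union-find for transitive loop clustering
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs$i[r]); rj <- find(pairs$j[r])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

#' Replicate-consensus loops across samples
#'
#' Pools loops from all samples, clusters them by transitive two-anchor
#' matching (single linkage), and retains clusters supported by at least
#' `k` distinct samples. The cluster representative is the anchor-wise
#' union span; its `samples` field is the supporting sample set and its
#' `name` the sorted unique member names.
#'
#' @param sample_loops named list mapping sample id to a loop data.frame.
#' @param k minimum number of distinct supporting samples (default 2).
#' @param padding anchor padding passed to the matcher.
#' @return consensus loop data.frame with an `n_samples` column.
#' @export
loop_consensus <- function(sample_loops, k = 2, padding = 0) {
  stopifnot(k >= 1)
  if (is.null(names(sample_loops)) || any(!nzchar(names(sample_loops))))
    stop("sample_loops must be a named list")
  pool <- do.call(rbind, lapply(names(sample_loops), function(s) {
    df <- sample_loops[[s]]
    if (nrow(df) == 0) return(NULL)
    df$.sample <- s
    df[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", ".sample")]
  }))
  if (is.null(pool) || nrow(pool) == 0) return(loop_table())
  pool <- canonicalize_loops(pool)
  pairs <- loop_match_pairs(pool, pool, padding)
  comp <- uf_components(nrow(pool), pairs)
  reps <- lapply(split(seq_len(nrow(pool)), comp), function(idx) {
    members <- pool[idx, , drop = FALSE]
    smp <- sort(unique(members$.sample))
    if (length(smp) < k) return(NULL)
    nm <- sort(unique(members$name[members$name != "."]))
    data.frame(chrom1 = members$chrom1[1], start1 = min(members$start1),
               end1 = max(members$end1), chrom2 = members$chrom2[1],
               start2 = min(members$start2), end2 = max(members$end2),
               name = if (length(nm)) paste(nm, collapse = ";") else ".",
               score = NA_real_, n_samples = length(smp),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(reps, is.null, logical(1))
  smp_sets <- lapply(split(seq_len(nrow(pool)), comp), function(idx)
    sort(unique(pool$.sample[idx])))[keep]
  out <- do.call(rbind, reps[keep])
  if (is.null(out)) return(loop_table())
  out <- canonicalize_loops(out)
  ord <- order(out$chrom1, out$start1, out$start2)
  out <- out[ord, , drop = FALSE]
  out$samples <- smp_sets[ord]
  rownames(out) <- NULL
  out
}

#' Classify loops as stable, gained or lost between conditions
#'
#' A control loop matching any treated loop by two-anchor overlap is
#' stable (both representatives are recorded, tagged by `side`); unmatched
#' control loops are lost and unmatched treated loops gained.
#'
#' @param control,treated consensus loop data.frames.
#' @param padding anchor padding passed to the matcher.
#' @return an object of class `loop_diff`: list with `stable`, `gained`,
#'   `lost` loop data.frames.
#' @export
loop_diff <- function(control, treated, padding = 0) {
  pairs <- loop_match_pairs(control, treated, padding)
  c_st <- sort(unique(pairs$i)); t_st <- sort(unique(pairs$j))
  tag <- function(df, side) {
    if (nrow(df)) df$side <- side else df$side <- character(0)
    df
  }
  stable <- rbind(tag(control[c_st, , drop = FALSE], "control"),
                  tag(treated[t_st, , drop = FALSE], "treated"))
  rownames(stable) <- NULL
  lost <- control[setdiff(seq_len(nrow(control)), c_st), , drop = FALSE]
  gained <- treated[setdiff(seq_len(nrow(treated)), t_st), , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  structure(list(stable = stable, gained = gained, lost = lost),
            class = "loop_diff")
}

loop_ids <- function(loops) {
  if (!is.null(loops$name) && !anyDuplicated(loops$name) && all(loops$name != "."))
    loops$name
  else
    paste0("loop_", seq_len(nrow(loops)))
}

#' Annotate loop anchors with regulatory features
#'
#' Every anchor receives every label whose feature interval overlaps it
#' by at least 1 bp: gene promoters (carrying `gene_id`), CRE classes (enhancer /
#' repressor / super_enhancer), CTCF peaks, and variants (carrying rsid).
#'
#' @param loops loop data.frame.
#' @param genes gene-model table (promoter labels), or NULL.
#' @param cres_by_class named list of interval tables; names become the
#'   feature labels (e.g. `enhancer`, `repressor`, `super_enhancer`).
#' @param ctcf CTCF consensus peak table, or NULL.
#' @param variants variant table (`rsid`, `chrom`, `pos` 0-based), or NULL.
#' @return list with `features` (long data.frame: `loop_id`, `anchor`,
#'   `feature_type`, `feature_id`) and `summary` (per-loop `ctcf_feet`).
#' @export
annotate_anchors <- function(loops, genes = NULL, cres_by_class = NULL,
                             ctcf = NULL, variants = NULL) {
  ids <- loop_ids(loops)
  anchors <- list(`1` = anchor1_of(loops), `2` = anchor2_of(loops))
  rows <- list()
  add_hits <- function(feature_df, type, feature_ids) {
    for (a in c("1", "2")) {
      p <- overlap_pairs(anchors[[a]], feature_df)
      if (nrow(p))
        rows[[length(rows) + 1]] <<- data.frame(
          loop_id = ids[p$query], anchor = as.integer(a),
          feature_type = type, feature_id = feature_ids[p$subject],
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(genes) && nrow(genes))
    add_hits(promoters_of(genes), "promoter", genes$gene_id)
  if (!is.null(cres_by_class))
    for (cls in names(cres_by_class)) {
      df <- cres_by_class[[cls]]
      if (!is.null(df) && nrow(df)) add_hits(df, cls, interval_id(df))
    }
  if (!is.null(ctcf) && nrow(ctcf))
    add_hits(ctcf, "CTCF", rep(NA_character_, nrow(ctcf)))
  if (!is.null(variants) && nrow(variants)) {
    vdf <- data.frame(chrom = variants$chrom, start = variants$pos,
                      end = variants$pos + 1, stringsAsFactors = FALSE)
    add_hits(vdf, "variant", variants$rsid)
  }
  features <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(loop_id = character(), anchor = integer(),
               feature_type = character(), feature_id = character(),
               stringsAsFactors = FALSE)
  ctcf_anchors <- unique(features[features$feature_type == "CTCF",
                                  c("loop_id", "anchor")])
  feet <- table(factor(ctcf_anchors$loop_id, levels = ids))
  summary <- data.frame(loop_id = ids, ctcf_feet = as.integer(feet[ids]),
                        stringsAsFactors = FALSE)
  list(features = features, summary = summary)
}

#' Count tissues sharing each loop
#'
#' For each query loop, counts how many external tissue loop catalogs
#' contain at least one two-anchor-matching loop.
#'
#' @param tm_loops loop data.frame (e.g. the tissue-of-interest consensus).
#' @param tissue_catalogs named list mapping tissue id to a loop data.frame.
#' @param padding anchor padding passed to the matcher.
#' @return data.frame with `loop_id`, `n_tissues` and a comma-separated
#'   `tissues` column.
#' @export
cross_tissue_sharing <- function(tm_loops, tissue_catalogs, padding = 0) {
  ids <- loop_ids(tm_loops)
  hit <- matrix(FALSE, nrow(tm_loops), length(tissue_catalogs))
  for (t in seq_along(tissue_catalogs)) {
    p <- loop_match_pairs(tm_loops, tissue_catalogs[[t]], padding)
    hit[unique(p$i), t] <- TRUE
  }
  tn <- names(tissue_catalogs)
  data.frame(loop_id = ids, n_tissues = rowSums(hit),
             tissues = apply(hit, 1, function(h) paste(tn[h], collapse = ",")),
             stringsAsFactors = FALSE)
}

#' Genes with the greatest number of loop changes
#'
#' Counts gained plus lost loops carrying each gene's promoter label on
#' either anchor, and returns genes at or above the upper `quantile` of the
#' positive-count distribution (ties at the threshold included; genes with
#' zero changes are excluded from the distribution).
#'
#' @param diff a [loop_diff()] result.
#' @param annotations an [annotate_anchors()] result computed on the
#'   gained and lost loops of `diff`.
#' @param quantile upper tail fraction (default 0.05 = top 5%).
#' @return data.frame with `gene_id`, `n_changes`, `selected`.
#' @export
top_loop_change_genes <- function(diff, annotations, quantile = 0.05) {
  stopifnot(quantile > 0, quantile <= 1)
  changed_ids <- c(loop_ids(diff$gained), loop_ids(diff$lost))
  f <- annotations$features
  f <- f[f$feature_type == "promoter" & f$loop_id %in% changed_ids, , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(gene_id = character(), n_changes = integer(),
                      selected = logical(), stringsAsFactors = FALSE))
  # one change per (gene, loop), regardless of how many anchors hit
  f <- unique(f[, c("loop_id", "feature_id")])
  counts <- table(f$feature_id)
  thr <- stats::quantile(as.numeric(counts), 1 - quantile, names = FALSE)
  out <- data.frame(gene_id = names(counts), n_changes = as.integer(counts),
                    selected = as.numeric(counts) >= thr,
                    stringsAsFactors = FALSE)
  out[order(-out$n_changes, out$gene_id), , drop = FALSE]
}
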