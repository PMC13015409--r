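#' Activating/repressive call from promoter-loop change counts
#'
#' Activating iff (gained enhancer loops + lost repressor loops) > 0 and
#' (lost enhancer loops + gained repressor loops) = 0; repressive is the
#' mirror; both positive is mixed; all zero is none.
#'
#' @param gained_enhancer,lost_enhancer,gained_repressor,lost_repressor
#'   non-negative integer vectors (recycled).
#' @return character vector over `activating`/`repressive`/`mixed`/`none`.
#' @export
regulatory_call <- function(gained_enhancer, lost_enhancer,
                            gained_repressor, lost_repressor) {
  act <- gained_enhancer + lost_repressor
  rep_ <- lost_enhancer + gained_repressor
  ifelse(act > 0 & rep_ == 0, "activating",
         ifelse(rep_ > 0 & act == 0, "repressive",
                ifelse(act > 0 & rep_ > 0, "mixed", "none")))
}

#' Classify per-gene regulatory change from differential promoter loops
#'
#' A gained/lost loop counts for a gene when one anchor carries that
#' gene's promoter label and the other anchor carries the enhancer
#' (respectively repressor) label; counts feed [regulatory_call()].
#'
#' @param diff a [loop_diff()] result.
#' @param annotations [annotate_anchors()] output for the gained and lost
#'   loops of `diff` (with `promoter`, `enhancer`, `repressor` features).
#' @return data.frame per gene: the four loop-change counts and `call`.
#' @export
classify_regulatory_changes <- function(diff, annotations) {
  gained_ids <- loop_ids(diff$gained)
  lost_ids <- loop_ids(diff$lost)
  f <- annotations$features
  pairs_for <- function(partner_type) {
    p <- f[f$feature_type == "promoter", , drop = FALSE]
    q <- f[f$feature_type == partner_type, , drop = FALSE]
    if (nrow(p) == 0 || nrow(q) == 0)
      return(data.frame(loop_id = character(), gene_id = character()))
    j <- merge(p, q, by = "loop_id")
    j <- j[j$anchor.x != j$anchor.y, , drop = FALSE]  # opposite anchors only
    unique(data.frame(loop_id = j$loop_id, gene_id = j$feature_id.x,
                      stringsAsFactors = FALSE))
  }
  enh <- pairs_for("enhancer")
  rep_ <- pairs_for("repressor")
  genes <- sort(unique(c(enh$gene_id, rep_$gene_id)))
  count_in <- function(tab, ids) {
    vapply(genes, function(g)
      sum(tab$gene_id == g & tab$loop_id %in% ids), integer(1))
  }
  out <- data.frame(
    gene_id = genes,
    gained_enhancer_loops = count_in(enh, gained_ids),
    lost_enhancer_loops = count_in(enh, lost_ids),
    gained_repressor_loops = count_in(rep_, gained_ids),
    lost_repressor_loops = count_in(rep_, lost_ids),
    stringsAsFactors = FALSE)
  out$call <- regulatory_call(out$gained_enhancer_loops,
                              out$lost_enhancer_loops,
                              out$gained_repressor_loops,
                              out$lost_repressor_loops)
  rownames(out) <- NULL
  out
}

# genes whose body-union-promoter span overlaps any feature interval
genes_overlapping <- function(features, genes) {
  if (is.null(features) || nrow(features) == 0) return(character(0))
  span <- data.frame(chrom = genes$chrom,
                     start = pmin(genes$start, genes$promoter_start),
                     end = pmax(genes$end, genes$promoter_end),
                     stringsAsFactors = FALSE)
  sort(unique(genes$gene_id[overlaps_any(span, features)]))
}

# genes with gained or lost promoter-X loops, from annotated diff loops
loop_partner_genes <- function(diff, annotations, partner_type) {
  changed <- c(loop_ids(diff$gained), loop_ids(diff$lost))
  f <- annotations$features
  p <- f[f$feature_type == "promoter" & f$loop_id %in% changed, , drop = FALSE]
  q <- f[f$feature_type == partner_type & f$loop_id %in% changed, , drop = FALSE]
  if (nrow(p) == 0 || nrow(q) == 0) return(character(0))
  j <- merge(p, q, by = "loop_id")
  j <- j[j$anchor.x != j$anchor.y, , drop = FALSE]
  sort(unique(j$feature_id.x))
}

#' Build the 16 integrated gene sets
#'
#' One named gene set per layer of regulatory change: differential
#' expression; compartment shifts; differential ATAC, SEs, CREs; enhancer
#' activation switches; differential peaks for six marks; top loop-change
#' genes; and genes with gained/lost promoter-enhancer, promoter-repressor
#' and promoter-SE loops. Gene-feature overlap uses the gene body union
#' promoter span (>= 1 bp).
#'
#' @param genes gene-model table.
#' @param de_table data.frame `gene_id`, `log2fc`, `fdr`.
#' @param shifted [detect_shifts()] output.
#' @param diff_atac,diff_se,diff_cre [diff_peaks()] results.
#' @param enhancer_switches [classify_enhancers()] output.
#' @param diff_peaks_by_mark named list of [diff_peaks()] results for
#'   H3K27ac, H3K27me3, H3K4me1, H3K4me3, H3K36me3, CTCF.
#' @param loop_diff_annotated list with elements `diff` ([loop_diff()])
#'   and `annotations` ([annotate_anchors()] on the changed loops).
#' @param top_genes character vector from [top_loop_change_genes()]
#'   (selected genes).
#' @param fdr_max FDR threshold defining differential expression.
#' @return named list of 16 character vectors.
#' @export
build_gene_sets <- function(genes, de_table, shifted, diff_atac, diff_se,
                            diff_cre, enhancer_switches, diff_peaks_by_mark,
                            loop_diff_annotated, top_genes, fdr_max = 0.05) {
  marks <- c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me3", "H3K36me3", "CTCF")
  inputs <- list(de_genes = de_table, compartment_shift = shifted,
                 atac_diff = diff_atac, se_diff = diff_se, cre_diff = diff_cre,
                 enhancer_switch = enhancer_switches,
                 loop_changes = loop_diff_annotated, top_loop_change = top_genes)
  for (nm in names(inputs))
    if (is.null(inputs[[nm]]))
      stop("missing upstream input blocks gene set '", nm, "'")
  for (mk in marks)
    if (is.null(diff_peaks_by_mark[[mk]]))
      stop("missing diff peaks for mark ", mk,
           " block gene set '", tolower(mk), "_diff'")
  sets <- list()
  sets$de_genes <- sort(unique(de_table$gene_id[de_table$fdr <= fdr_max]))
  sets$compartment_shift <- genes_overlapping(
    shifted[shifted$shift != "none", , drop = FALSE], genes)
  sets$atac_diff <- genes_overlapping(changed_peaks(diff_atac), genes)
  sets$se_diff <- genes_overlapping(changed_peaks(diff_se), genes)
  sets$cre_diff <- genes_overlapping(changed_peaks(diff_cre), genes)
  sets$enhancer_switch <- genes_overlapping(
    enhancer_switches[enhancer_switches$switch %in% c("activated", "deactivated"),
                      c("chrom", "start", "end"), drop = FALSE], genes)
  for (mk in marks)
    sets[[paste0(tolower(mk), "_diff")]] <-
      genes_overlapping(changed_peaks(diff_peaks_by_mark[[mk]]), genes)
  sets$top_loop_change <- sort(unique(top_genes))
  d <- loop_diff_annotated$diff
  a <- loop_diff_annotated$annotations
  sets$loop_enhancer_diff <- loop_partner_genes(d, a, "enhancer")
  sets$loop_repressor_diff <- loop_partner_genes(d, a, "repressor")
  sets$loop_se_diff <- loop_partner_genes(d, a, "super_enhancer")
  stopifnot(length(sets) == 16)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric test per annotation term:
#' `p = P(X >= k)` under `Hypergeometric(N, K, n)` with `N` the universe
#' size, `K` the term size within the universe, `n` the query set size
#' and `k` the overlap; Benjamini-Hochberg FDR across all tested terms.
#' Terms with no universe genes are skipped.
#'
#' @param gene_set character vector of query genes (intersected with the
#'   universe).
#' @param annotation named list mapping term to gene vector.
#' @param universe character vector of background genes.
#' @param set_name optional label carried on every row.
#' @return data.frame `term`, `set_name`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fdr`.
#' @export
hypergeom_ora <- function(gene_set, annotation, universe,
                          set_name = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe)
  n <- length(gene_set)
  rows <- list()
  for (term in names(annotation)) {
    term_genes <- intersect(unique(annotation[[term]]), universe)
    K <- length(term_genes)
    if (K == 0) next
    k <- length(intersect(gene_set, term_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      term = term, set_name = set_name, k = k, n = n, K = K, N = N,
      p_value = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(term = character(), set_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Term-by-set enrichment matrix
#'
#' Boolean matrix with a TRUE cell where a term's FDR is at most
#' `fdr_max` in that set; terms enriched in fewer than `min_sets` sets
#' are dropped; rows ordered by descending row-sum then term name.
#'
#' @param enrichments named list of [hypergeom_ora()] results, one per
#'   gene set.
#' @param fdr_max enrichment FDR threshold (default 0.05).
#' @param min_sets minimum number of sets a retained term must be
#'   enriched in (default 4).
#' @return logical matrix (terms x sets).
#' @export
term_set_matrix <- function(enrichments, fdr_max = 0.05, min_sets = 4) {
  sets <- names(enrichments)
  terms <- sort(unique(unlist(lapply(enrichments, function(e) e$term))))
  m <- matrix(FALSE, length(terms), length(sets),
              dimnames = list(terms, sets))
  for (s in sets) {
    e <- enrichments[[s]]
    sig <- e$term[e$fdr <= fdr_max]
    m[match(sig, terms), s] <- TRUE
  }
  m <- m[rowSums(m) >= min_sets, , drop = FALSE]
  m[order(-rowSums(m), rownames(m)), , drop = FALSE]
}
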