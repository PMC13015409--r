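#' Read genomic intervals from BED-family files
#'
#' Strict tab-separated parsing with coordinate validation. `track`,
#' `browser` and `#` comment lines are tolerated and skipped. All
#' coordinates are returned 0-based half-open, exactly as stored in the
#' file.
#'
#' Dialects:
#' \describe{
#'   \item{bed3}{chrom, start, end}
#'   \item{bed6}{+ name, score, strand}
#'   \item{narrowPeak}{BED6 + signalValue, pValue, qValue, peak; the
#'     returned `score` column carries `signalValue` (the quantity used for
#'     super-enhancer signal), with the original column 5 kept as
#'     `display_score`}
#'   \item{bedgraph}{chrom, start, end, score}
#' }
#'
#' @param path file path.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"bedgraph"`.
#' @return sorted interval data.frame.
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed6", "narrowPeak", "bedgraph")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  ncol_need <- c(bed3 = 3, bed6 = 6, narrowPeak = 10, bedgraph = 4)[[dialect]]
  if (length(lines) == 0) return(intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_need)
  if (length(bad))
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": expected >= ", ncol_need, " fields, got ", nf[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_need)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": start >= end")
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (dialect == "bed6") {
    df$name <- m[, 4]
    df$score <- suppressWarnings(as.numeric(m[, 5]))
    df$strand <- m[, 6]
  } else if (dialect == "narrowPeak") {
    df$name <- m[, 4]
    df$display_score <- suppressWarnings(as.numeric(m[, 5]))
    df$strand <- m[, 6]
    df$score <- suppressWarnings(as.numeric(m[, 7]))  # signalValue
    df$p_value <- suppressWarnings(as.numeric(m[, 8]))
    df$q_value <- suppressWarnings(as.numeric(m[, 9]))
    df$peak <- suppressWarnings(as.numeric(m[, 10]))
  } else if (dialect == "bedgraph") {
    df$score <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(df$score))
      stop("malformed bedgraph line ", lineno[which(is.na(df$score))[1]],
           " in ", path, ": non-numeric score")
  }
  validate_intervals(df, path)
  sort_intervals(df)
}

#' Write genomic intervals to a BED-family file
#'
#' Emits tab-separated, newline-terminated records with no trailing
#' whitespace; the inverse of [read_intervals()] for each dialect.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @param dialect see [read_intervals()].
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path, dialect = c("bed3", "bed6", "narrowPeak", "bedgraph")) {
  dialect <- match.arg(dialect)
  validate_intervals(df)
  col_or <- function(col, default) if (!is.null(df[[col]])) df[[col]] else rep(default, nrow(df))
  out <- switch(dialect,
    bed3 = df[, c("chrom", "start", "end")],
    bed6 = data.frame(df$chrom, df$start, df$end, col_or("name", "."),
                      col_or("score", 0), col_or("strand", ".")),
    narrowPeak = data.frame(df$chrom, df$start, df$end, col_or("name", "."),
                            col_or("display_score", 0), col_or("strand", "."),
                            col_or("score", 0), col_or("p_value", -1),
                            col_or("q_value", -1), col_or("peak", -1)),
    bedgraph = data.frame(df$chrom, df$start, df$end, col_or("score", 0)))
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Anchors are normalized to canonical order (anchor1 <= anchor2
#' lexicographically by chrom then start). Inter-chromosomal records are
#' skipped with a warning; the skip count is attached as attribute
#' `n_interchrom_skipped`.
#'
#' @param path BEDPE file (chrom1, start1, end1, chrom2, start2, end2
#'   \[, name, score\]).
#' @param sample_id identifier recorded in the `samples` list-column.
#' @return a loop data.frame (columns `chrom1..end2`, `name`, `score`,
#'   `samples`).
#' @export
read_loops <- function(path, sample_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(loop_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6)
  if (length(bad))
    stop("malformed BEDPE line ", lineno[bad[1]], " in ", path)
  get <- function(i, default = NA) vapply(fields, function(f)
    if (length(f) >= i) f[i] else as.character(default), character(1))
  df <- data.frame(chrom1 = get(1), start1 = as.numeric(get(2)), end1 = as.numeric(get(3)),
                   chrom2 = get(4), start2 = as.numeric(get(5)), end2 = as.numeric(get(6)),
                   name = get(7, "."), score = suppressWarnings(as.numeric(get(8, NA))),
                   stringsAsFactors = FALSE)
  inter <- df$chrom1 != df$chrom2
  if (any(inter))
    warning("skipped ", sum(inter), " inter-chromosomal record(s) in ", path,
            call. = FALSE)
  df <- df[!inter, , drop = FALSE]
  df <- canonicalize_loops(df)
  df$samples <- replicate(nrow(df), sample_id, simplify = FALSE)
  attr(df, "n_interchrom_skipped") <- sum(inter)
  df
}

#' Write chromatin loops to a BEDPE file
#' @param loops loop data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  out <- data.frame(loops$chrom1, loops$start1, loops$end1,
                    loops$chrom2, loops$start2, loops$end2,
                    if (!is.null(loops$name)) loops$name else ".",
                    if (!is.null(loops$score)) loops$score else 0)
  if (nrow(out) == 0)
    out <- out[0, , drop = FALSE]
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Consumes `gene` features (1-based inclusive, converted to 0-based
#' half-open) and derives the strand-aware TSS and promoter window: the
#' promoter contains the TSS with `promoter_up` bases on the 5' side of
#' transcription and `promoter_down` bases on the 3' side, clipped at 0.
#'
#' @param path GTF file with gene features carrying `gene_id` (and
#'   optionally `gene_name`) attributes.
#' @param promoter_up,promoter_down promoter extent in bp upstream /
#'   downstream of the TSS (defaults 2000 / 500).
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `tss` (0-based position), `start`, `end` (gene body),
#'   `promoter_start`, `promoter_end`.
#' @export
read_gene_models <- function(path, promoter_up = 2000, promoter_down = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (promoter_up + promoter_down <= 0)
    stop("empty promoter window: promoter_up + promoter_down must be > 0")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stop("no gene features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene(s) without strand in ", path, ": ",
         paste(utils::head(gr$gene_id[!strand %in% c("+", "-")], 5), collapse = ", "))
  ids <- gr$gene_id
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body_start <- GenomicRanges::start(gr) - 1  # to 0-based half-open
  body_end <- GenomicRanges::end(gr)
  tss <- ifelse(strand == "+", body_start, body_end - 1)
  prom_start <- ifelse(strand == "+", tss - promoter_up, tss - promoter_down + 1)
  prom_end <- ifelse(strand == "+", tss + promoter_down, tss + promoter_up + 1)
  gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else ids
  data.frame(gene_id = ids,
             gene_name = ifelse(is.na(gene_name), ids, gene_name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, tss = tss,
             start = body_start, end = body_end,
             promoter_start = pmax(0, prom_start),
             promoter_end = prom_end,
             stringsAsFactors = FALSE)
}

#' Write gene models as a minimal GTF
#' @param genes gene-model data.frame (as from [read_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- sprintf(
    "%s\ttmregulome\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, as.integer(genes$start + 1), as.integer(genes$end),
    genes$strand, genes$gene_id, genes$gene_name)
  writeLines(lines, path)
  invisible(path)
}

# promoter / gene-body interval views of a gene-model table
promoters_of <- function(genes) {
  data.frame(chrom = genes$chrom, start = genes$promoter_start,
             end = genes$promoter_end, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

bodies_of <- function(genes) {
  data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Lines are `term <tab> description <tab> gene1 <tab> gene2 ...`.
#' Duplicate genes within a term are deduplicated; terms with zero genes
#' are skipped with a warning.
#'
#' @param path GMT file.
#' @return named list mapping term to character vector of genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("GMT term with no genes skipped: ", f[1], call. = FALSE)
      next
    }
    out[[f[1]]] <- genes
  }
  out
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(term)
    paste(c(term, term, sets[[term]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#' @param path TSV with a first column of gene/feature ids and one column
#'   per sample.
#' @return numeric matrix with feature row names.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative counts in ", path)
  m
}

write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
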