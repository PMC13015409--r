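# Shared fixture builders. Random fixtures always take an explicit seed.

iv <- function(chrom, start, end, ...) {
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, seed, chrom = "chr1", max_pos = 1e5,
                             min_w = 50, max_w = 500) {
  set.seed(seed)
  s <- sort(sample.int(max_pos, n))
  w <- sample(min_w:max_w, n, replace = TRUE)
  iv(chrom, s, s + w)
}

random_loops <- function(n, seed, chrom = "chr1", max_pos = 1e6, w = 2000) {
  set.seed(seed)
  a1 <- sample.int(max_pos, n)
  a2 <- sample.int(max_pos, n)
  loop_table(chrom, a1, a1 + w, chrom, a2, a2 + w,
             name = sprintf("lp%03d", seq_len(n)))
}

toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    gene_name = c("gA", "gB", "gC"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss = c(20000, 59999, 100000),
    start = c(20000, 50000, 100000), end = c(30000, 60000, 110000),
    promoter_start = c(18000, 59500, 98000),
    promoter_end = c(20500, 62000, 100500),
    stringsAsFactors = FALSE)
}

# one cached noiseless synthetic dataset + pipeline run per test session
synthetic_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "tmregulome_ds")
      cfg <- synthetic_config(seed = 1, noise = FALSE)
      man <- generate_dataset(cfg, dir)
      res <- suppressWarnings(run_pipeline(pipeline_config(dir)))
      cache <<- list(dir = dir, config = cfg, manifest = man, result = res)
    }
    cache
  }
})
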