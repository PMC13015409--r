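#' Classify compartment windows as A or B from a score track
#'
#' A window with positive score is A, negative is B; a score of exactly 0
#' takes the majority class of its flanking windows on the same
#' chromosome, defaulting to B (with a warning). Windows must be uniform
#' width and non-overlapping.
#'
#' @param track interval data.frame with a `score` column (bedGraph
#'   semantics, e.g. 50 kb eigenvector windows).
#' @return `track` sorted, with a `class` column over `A`/`B`.
#' @export
classify_windows <- function(track) {
  validate_intervals(track, "score track")
  if (is.null(track$score)) stop("score track needs a 'score' column")
  track <- sort_intervals(track)
  if (nrow(track) > 1) {
    w <- track$end - track$start
    if (length(unique(w)) != 1) stop("track windows must be uniform width")
    same <- track$chrom[-1] == track$chrom[-nrow(track)]
    if (any(same & track$start[-1] < track$end[-nrow(track)]))
      stop("overlapping track records")
  }
  cls <- ifelse(track$score > 0, "A", ifelse(track$score < 0, "B", NA))
  zeros <- which(is.na(cls))
  if (length(zeros)) {
    warning("score exactly 0 in ", length(zeros),
            " window(s); resolved by neighbor majority (default B)",
            call. = FALSE)
    for (i in zeros) {
      nb <- c(if (i > 1 && track$chrom[i - 1] == track$chrom[i]) cls[i - 1],
              if (i < nrow(track) && track$chrom[i + 1] == track$chrom[i]) cls[i + 1])
      nb <- nb[!is.na(nb)]
      cls[i] <- if (sum(nb == "A") > sum(nb == "B")) "A" else "B"
    }
  }
  track$class <- cls
  track
}

#' Detect compartment shifts between conditions
#'
#' Window sets must be identical across conditions. In `external_flags`
#' mode a per-window significance flag (emulating an upstream differential
#' compartment caller) selects shifted windows, with direction from the
#' sign of the score change. In `delta_threshold` mode windows with
#' |delta score| >= `delta` (after optional per-track z-scaling) are
#' flagged.
#'
#' @param control,treated classified score tracks ([classify_windows()]
#'   output, or raw tracks — classification is applied if missing).
#' @param method `"external_flags"` or `"delta_threshold"`.
#' @param flags logical vector (window order of the sorted control track)
#'   for `external_flags` mode.
#' @param delta threshold on the (scaled) score change (default 0.3).
#' @param scale z-scale each track before thresholding (default TRUE;
#'   `delta_threshold` mode only).
#' @return data.frame of windows with `score_control`, `score_treated`,
#'   `class_control`, `class_treated` and `shift` in
#'   `toward_A` / `toward_B` / `none`.
#' @export
detect_shifts <- function(control, treated,
                          method = c("external_flags", "delta_threshold"),
                          flags = NULL, delta = 0.3, scale = TRUE) {
  method <- match.arg(method)
  if (is.null(control$class)) control <- classify_windows(control)
  if (is.null(treated$class)) treated <- classify_windows(treated)
  control <- sort_intervals(control)
  treated <- sort_intervals(treated)
  if (!identical(control[, c("chrom", "start", "end")],
                 treated[, c("chrom", "start", "end")]))
    stop("window sets differ between conditions")
  d_raw <- treated$score - control$score
  if (method == "external_flags") {
    if (is.null(flags) || length(flags) != nrow(control))
      stop("external_flags mode needs one logical flag per window")
    sig <- as.logical(flags)
  } else {
    ds <- if (scale) as.numeric(base::scale(treated$score)) -
      as.numeric(base::scale(control$score)) else d_raw
    sig <- abs(ds) >= delta
  }
  shift <- rep("none", nrow(control))
  shift[sig & d_raw > 0] <- "toward_A"
  shift[sig & d_raw < 0] <- "toward_B"
  data.frame(chrom = control$chrom, start = control$start, end = control$end,
             score_control = control$score, score_treated = treated$score,
             class_control = control$class, class_treated = treated$class,
             shift = shift, stringsAsFactors = FALSE)
}

#' One-sample t-test of per-window signal changes against zero
#'
#' Tests whether the mean per-window signal change within shifted windows
#' differs from zero: `t = mean / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom, two-sided.
#'
#' @param deltas numeric vector of per-window signal changes (n >= 2).
#' @param mark,direction labels carried onto the result row.
#' @return one-row data.frame `mark`, `direction`, `n_windows`,
#'   `mean_delta`, `t_statistic`, `p_value`, `df`.
#' @export
signal_shift_test <- function(deltas, mark = NA_character_,
                              direction = NA_character_) {
  n <- length(deltas)
  if (n < 2) stop("need at least 2 windows")
  if (stats::sd(deltas) == 0) stop("degenerate variance: deltas are constant")
  tt <- stats::t.test(deltas, mu = 0)
  data.frame(mark = mark, direction = direction, n_windows = n,
             mean_delta = mean(deltas),
             t_statistic = unname(tt$statistic),
             p_value = tt$p.value, df = unname(tt$parameter),
             stringsAsFactors = FALSE)
}

#' Signal-shift t-tests per mark and shift direction
#'
#' Joins a per-window per-mark delta table to shifted windows and runs
#' [signal_shift_test()] for every mark within each shift direction.
#'
#' @param delta_table data.frame `chrom`, `start`, `end`, `mark`, `delta`.
#' @param shifted [detect_shifts()] output.
#' @return data.frame of test results (one row per mark x direction with
#'   at least 2 windows).
#' @export
signal_shift_tests <- function(delta_table, shifted) {
  key <- function(df) paste(df$chrom, df$start, df$end)
  out <- list()
  for (dir in c("toward_A", "toward_B")) {
    wk <- key(shifted[shifted$shift == dir, , drop = FALSE])
    sub <- delta_table[key(delta_table) %in% wk, , drop = FALSE]
    for (mk in unique(sub$mark)) {
      d <- sub$delta[sub$mark == mk]
      if (length(d) >= 2 && stats::sd(d) > 0)
        out[[length(out) + 1]] <- signal_shift_test(d, mk, dir)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mark = character(), direction = character(),
               n_windows = integer(), mean_delta = numeric(),
               t_statistic = numeric(), p_value = numeric(), df = numeric(),
               stringsAsFactors = FALSE)
}
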