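ENHANCER_MARKS <- c("H3K27ac", "H3K4me1", "H3K27me3")

#' Classify an enhancer's chromatin state from its marks
#'
#' poised: H3K4me1 and H3K27me3 both present; active: H3K27ac present
#' without H3K27me3; primed: H3K4me1 alone (no H3K27ac, no H3K27me3);
#' otherwise inactive. Precedence poised > active > primed > inactive
#' resolves conflicts, so H3K4me1 + H3K27me3 is poised even with H3K27ac.
#'
#' @param marks_present character vector, subset of
#'   `c("H3K27ac", "H3K4me1", "H3K27me3")`.
#' @return one of `"active"`, `"primed"`, `"poised"`, `"inactive"`.
#' @export
classify_enhancer_state <- function(marks_present) {
  unknown <- setdiff(marks_present, ENHANCER_MARKS)
  if (length(unknown))
    stop("unknown mark name(s): ", paste(unknown, collapse = ", "))
  ac <- "H3K27ac" %in% marks_present
  me1 <- "H3K4me1" %in% marks_present
  me3 <- "H3K27me3" %in% marks_present
  if (me1 && me3) return("poised")
  if (ac && !me3) return("active")
  if (me1 && !ac && !me3) return("primed")
  "inactive"
}

switch_label <- function(state_control, state_treated) {
  ca <- state_control == "active"
  ta <- state_treated == "active"
  ifelse(ca & ta, "stays_active",
         ifelse(!ca & ta, "activated",
                ifelse(ca & !ta, "deactivated", "stays_nonactive")))
}

#' Classify enhancer elements per condition and call activation switches
#'
#' Per condition, `marks_present` for each element is the set of marks
#' with a >= 1 bp consensus-peak overlap; states follow
#' [classify_enhancer_state()] and the switch label compares the two
#' conditions (activated = non-active to active; deactivated = the
#' reverse).
#'
#' @param enhancers interval data.frame of enhancer elements.
#' @param control_peaks,treated_peaks named lists of consensus peak tables
#'   for (a subset of) H3K27ac, H3K4me1, H3K27me3.
#' @return `enhancers` with `state_control`, `state_treated`, `switch`
#'   columns.
#' @export
classify_enhancers <- function(enhancers, control_peaks, treated_peaks) {
  validate_intervals(enhancers, "enhancers")
  marks_matrix <- function(peaks) {
    sapply(ENHANCER_MARKS, function(mk) {
      df <- peaks[[mk]]
      if (is.null(df) || nrow(df) == 0) rep(FALSE, nrow(enhancers))
      else overlaps_any(enhancers, df)
    })
  }
  state_of <- function(m) {
    if (nrow(enhancers) == 0) return(character(0))
    apply(m, 1, function(row) classify_enhancer_state(ENHANCER_MARKS[row]))
  }
  sc <- state_of(matrix(marks_matrix(control_peaks), ncol = 3))
  st <- state_of(matrix(marks_matrix(treated_peaks), ncol = 3))
  out <- enhancers
  out$state_control <- sc
  out$state_treated <- st
  out$switch <- switch_label(sc, st)
  out
}

#' Assemble cis-regulatory elements from state-annotated segments
#'
#' Union-merges all promoter- and enhancer-labeled chromatin-state
#' segments; book-ended segments merge.
#'
#' @param segments interval data.frame with a `label` column over
#'   `promoter` / `enhancer`.
#' @return merged CRE interval data.frame.
#' @export
assemble_cres <- function(segments) {
  validate_intervals(segments, "segments")
  if (is.null(segments$label)) stop("segments need a 'label' column")
  bad <- setdiff(unique(segments$label), c("promoter", "enhancer"))
  if (length(bad))
    stop("unexpected segment label(s): ", paste(bad, collapse = ", "))
  merge_intervals(segments, gap = 0)
}

# Pearson correlation with the zero-variance rule: any constant vector
# yields correlation 0 (with a warning raised once per call chain).
safe_cor <- function(x, y, warn_env = NULL) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (!is.null(warn_env) && !warn_env$warned) {
      warning("constant emission row: correlation defined as 0", call. = FALSE)
      warn_env$warned <- TRUE
    }
    return(0)
  }
  stats::cor(x, y)
}

#' Chromatin-state-count selection curve over nested models
#'
#' For each model (except the largest), every state's emission row is
#' correlated against all state rows of the next-larger model and the
#' maximum taken; the model's score is the mean of those maxima. The
#' selected state count is the number of states of the last model before
#' the first score gain below `epsilon` (the plateau point of the curve).
#'
#' @param models list of emission matrices (states x marks, values in
#'   \[0,1\]) ordered by strictly increasing state count; identical mark
#'   ordering assumed.
#' @param epsilon plateau gain threshold (default 0.01).
#' @return list with `scores` (data.frame `n_states`, `score`) and
#'   `selected_n_states`.
#' @export
model_selection_curve <- function(models, epsilon = 0.01) {
  ns <- vapply(models, nrow, integer(1))
  if (length(models) < 2) stop("need at least two models")
  if (is.unsorted(ns, strictly = TRUE))
    stop("models must have strictly increasing state counts")
  nm <- vapply(models, ncol, integer(1))
  if (length(unique(nm)) != 1) stop("models must share the mark set")
  warn_env <- new.env()
  warn_env$warned <- FALSE
  scores <- vapply(seq_len(length(models) - 1), function(k) {
    a <- models[[k]]; b <- models[[k + 1]]
    best <- vapply(seq_len(nrow(a)), function(i)
      max(vapply(seq_len(nrow(b)), function(j)
        safe_cor(a[i, ], b[j, ], warn_env), numeric(1))), numeric(1))
    mean(best)
  }, numeric(1))
  gains <- diff(scores)
  below <- which(gains < epsilon)
  sel_idx <- if (length(below)) below[1] else length(scores)
  list(scores = data.frame(n_states = ns[seq_along(scores)], score = scores),
       selected_n_states = ns[sel_idx])
}
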