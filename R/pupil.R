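#' Extract baseline-corrected pupil responses
#'
#' The baseline is the mean pupil size 400-900 ms after fixation
#' acquisition; the response is the baseline-subtracted mean over the 1 s
#' immediately after cue offset (entirely within the delay period).
#' Incomplete trials are skipped.
#'
#' @param pupil Long-format pupil samples (`trial_id`, `t_ms` relative to
#'   fixation onset, `pupil_size`).
#' @param trials Trial schedule (provides the per-trial cue-offset time).
#' @param baseline_window Window after fixation acquisition, ms.
#' @param response_dur_ms Length of the post-cue-offset window, ms.
#' @param sampling_rate_hz Expected sampling rate; a window with missing
#'   samples raises a coverage error.
#' @return A data.frame with `trial_id`, `baseline`, `response`.
#' @export
extract_pupil_responses <- function(pupil, trials,
                                    baseline_window = c(400, 900),
                                    response_dur_ms = 1000,
                                    sampling_rate_hz = 500) {
  step <- 1000 / sampling_rate_hz
  trials <- trials[trials$completed, ]
  sp <- split(pupil[, c("t_ms", "pupil_size")], pupil$trial_id)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    tr <- sp[[id]]
    if (is.null(tr)) stop("coverage error: no pupil samples for trial ", id)
    off_rel <- trials$t_cue_off_ms[i] - trials$t_fixation_on_ms[i]
    wmean <- function(w) {
      sel <- tr$t_ms >= w[1] & tr$t_ms < w[2]
      if (sum(sel) < floor(diff(w) / step))
        stop("coverage error: missing pupil samples in [", w[1], ", ",
             w[2], ") of trial ", id)
      mean(tr$pupil_size[sel])
    }
    b <- wmean(baseline_window)
    r <- wmean(c(off_rel, off_rel + response_dur_ms)) - b
    out[[i]] <- data.frame(trial_id = id, baseline = b, response = r,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Regress pupil response on reward value (single-cue trials)
#'
#' Ordinary least squares `response = b0 + b1 * V` over completed
#' single-cue trials, V in drops of juice, with a two-sided test of the
#' slope.
#'
#' @param responses Output of [extract_pupil_responses()] joined with the
#'   trial's cue value: needs columns `response` and `value`.
#' @return List with `b0`, `b1`, `p_b0`, `p_b1`, `n`, and the `lm` fit.
#' @export
regress_pupil_on_value <- function(responses) {
  if (length(unique(responses$value)) < 2L)
    stop("rank deficiency: need at least 2 distinct values")
  fit <- stats::lm(response ~ value, data = responses)
  cf <- summary(fit)$coefficients
  list(b0 = cf[1, 1], b1 = cf[2, 1], p_b0 = cf[1, 4], p_b1 = cf[2, 4],
       n = nrow(responses), fit = fit)
}

#' Compare single- and double-cue pupil responses
#'
#' Double-cue trials are grouped by the higher of the two cue values and
#' compared with the single-cue trials of the same value by a two-way
#' ANOVA (factors: reward size, number of cues), followed by Tukey HSD on
#' the size-by-count cells.  The comparisons of primary interest — single
#' vs double at the same reward size — are returned separately (one per
#' value level).
#'
#' @param responses Data.frame with `response`, `value_group` (the higher
#'   value), and `n_cues` (1 or 2).
#' @return List with `anova` (the two-way table), `tukey` (all pairwise
#'   cell comparisons) and `same_value` (single-vs-double rows).
#' @export
compare_single_vs_double <- function(responses) {
  responses$value_group <- factor(responses$value_group)
  responses$n_cues <- factor(responses$n_cues)
  cells <- table(responses$value_group, responses$n_cues)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("grouping error: empty cell(s) ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = "x", collapse = ", "))
  }
  fit <- stats::aov(response ~ value_group + n_cues, data = responses)
  tab <- summary(fit)[[1]]
  responses$cell <- interaction(responses$value_group, responses$n_cues,
                                sep = ":")
  tuk <- stats::TukeyHSD(stats::aov(response ~ cell, data = responses))$cell
  lv <- levels(responses$value_group)
  want <- paste0(lv, ":2-", lv, ":1")
  same <- tuk[rownames(tuk) %in% want, , drop = FALSE]
  list(anova = tab,
       p_value_factor = tab["value_group", "Pr(>F)"],
       p_ncues_factor = tab["n_cues", "Pr(>F)"],
       tukey = tuk, same_value = same)
}
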