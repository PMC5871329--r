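#' Firing rate in a half-open window
#'
#' Spike count in `[start, end)` divided by the window length; a spike
#' exactly at the window end is excluded.
#'
#' @param spike_times Numeric vector of spike times, ms.
#' @param window `c(start, end)` in ms.
#' @return Rate in spikes/s.
#' @export
windowed_rate <- function(spike_times, window) {
  if (diff(window) <= 0) stop("empty window")
  sum(spike_times >= window[1] & spike_times < window[2]) /
    (diff(window) / 1000)
}

#' Trial-wise windowed firing rates
#'
#' Rates for every (neuron, completed trial) pair, including zeros for
#' trials without spikes in the window.  Spike times are interpreted in
#' ms relative to cue onset, as stored in `spikes.csv`.
#'
#' @param spikes Long-format spike table (`neuron_id`, `trial_id`, `t_ms`).
#' @param trials Trial schedule.
#' @param window `c(start, end)` in ms relative to cue onset.
#' @param neuron_ids Neurons to include (default: all in `spikes`).
#' @return Data.frame with `neuron_id`, `trial_id`, `rate`.
#' @export
windowed_rates <- function(spikes, trials, window,
                           neuron_ids = unique(spikes$neuron_id)) {
  if (diff(window) <= 0) stop("empty window")
  trials <- trials[trials$completed, ]
  sel <- spikes$t_ms >= window[1] & spikes$t_ms < window[2] &
    spikes$neuron_id %in% neuron_ids & spikes$trial_id %in% trials$trial_id
  cnt <- table(factor(spikes$neuron_id[sel], levels = neuron_ids),
               factor(spikes$trial_id[sel], levels = trials$trial_id))
  data.frame(neuron_id = rep(neuron_ids, times = nrow(trials)),
             trial_id = rep(trials$trial_id, each = length(neuron_ids)),
             rate = as.vector(cnt) / (diff(window) / 1000),
             stringsAsFactors = FALSE)
}

#' Test visual responsiveness of one neuron
#'
#' Paired two-tailed t-test, across completed trials, of the firing rate
#' between fixation onset and cue onset against the rate between cue
#' onset and cue offset.  (An unpaired Welch variant is available via
#' `paired = FALSE`.)
#'
#' @param rate_pre,rate_cue Trial-wise rates in the two epochs (aligned).
#' @param alpha Significance level.
#' @param paired Use the paired test (default) or an unpaired one.
#' @return List with `responsive` flag and `p`.
#' @export
test_visual_responsiveness <- function(rate_pre, rate_cue, alpha = 0.05,
                                       paired = TRUE) {
  if (length(rate_pre) < 2L || length(rate_pre) != length(rate_cue))
    stop("insufficient data: need >= 2 paired trials")
  d <- rate_cue - rate_pre
  if (paired && stats::sd(d) == 0) {
    # degenerate: constant difference (typically all zeros)
    p <- if (all(d == 0)) 1 else 0
  } else {
    p <- stats::t.test(rate_cue, rate_pre, paired = paired)$p.value
  }
  list(responsive = p < alpha, p = p)
}

#' Test value selectivity of one neuron
#'
#' One-way ANOVA of cue-period firing rates (150-550 ms after cue onset)
#' across the five reward levels of the completed single-cue trials.
#'
#' @param rate Trial-wise rates in the selectivity window.
#' @param value Reward value of the shown cue for each trial.
#' @param required_values Values that must all be represented.
#' @param alpha Significance level.
#' @return List with `selective` flag and `p`.
#' @export
test_value_selectivity <- function(rate, value,
                                   required_values = c(0, 1, 2, 4, 8),
                                   alpha = 0.05) {
  miss <- setdiff(required_values, unique(value))
  if (length(miss))
    stop("grouping error: missing value level(s) ",
         paste(miss, collapse = ", "))
  if (stats::sd(rate) == 0) return(list(selective = FALSE, p = 1))
  p <- summary(stats::aov(rate ~ factor(value)))[[1]][1, "Pr(>F)"]
  list(selective = p < alpha, p = p)
}

#' Classify a neuron's value tuning
#'
#' OLS of single-cue rates on the cue value (`FR = b0 + b1 * V`,
#' V in 0/1/2/4/8); the sign of `b1` assigns the neuron to the positively
#' or negatively tuned group, and the regression p-value is recorded.
#'
#' @param rate,value As in [test_value_selectivity()].
#' @param alpha Significance level recorded alongside the slope.
#' @return List with `tuning` ("positive"/"negative"), `b0`, `b1`, `p`,
#'   `significant`, and `preferred_value` (the highest value for positive
#'   tuning, the lowest for negative).
#' @export
classify_tuning <- function(rate, value, alpha = 0.05) {
  fit <- stats::lm(rate ~ value)
  cf <- summary(fit)$coefficients
  b1 <- cf[2, 1]
  p <- cf[2, 4]
  tuning <- if (b1 >= 0) "positive" else "negative"
  preferred <- if (tuning == "positive") max(value) else min(value)
  list(tuning = tuning, b0 = cf[1, 1], b1 = b1, p = p,
       significant = is.finite(p) && p < alpha,
       preferred_value = preferred)
}

#' Screen a neuron population
#'
#' Runs the classification cascade on every neuron: visual
#' responsiveness (pre-cue vs cue-period rates, paired t-test), then — for
#' responsive neurons — value selectivity (one-way ANOVA on 150-550 ms
#' single-cue rates), then tuning sign (OLS slope on value).  Neurons
#' failing a stage carry NA for the downstream fields, mirroring the
#' recorded-population accounting (selective = positive + negative;
#' selective neurons are a subset of the responsive ones).
#'
#' @param session An `ofc_session` (or a list with `spikes`, `trials`,
#'   `conditions`).
#' @param alpha Significance level for every stage.
#' @param selectivity_window Window for the selectivity/tuning rates, ms.
#' @param neuron_ids Neurons to screen (default: all with spikes).
#' @return Data.frame, one row per neuron: flags, p-values, slope,
#'   preferred value.
#' @export
screen_neurons <- function(session, alpha = 0.05,
                           selectivity_window = c(150, 550),
                           neuron_ids = NULL) {
  trials <- session$trials[session$trials$completed, ]
  feats <- condition_features(session$conditions)
  if (is.null(neuron_ids))
    neuron_ids <- if (!is.null(session$neurons))
      session$neurons$neuron_id else unique(session$spikes$neuron_id)
  cue_on <- 0
  pre <- windowed_rates(session$spikes, trials, c(-2000, cue_on), neuron_ids)
  cue <- windowed_rates(session$spikes, trials, c(cue_on, 1000), neuron_ids)
  selw <- windowed_rates(session$spikes, trials, selectivity_window,
                         neuron_ids)
  v_single <- feats$v_single[match(trials$condition_id, feats$condition_id)]
  single_ids <- trials$trial_id[!is.na(v_single)]
  single_val <- v_single[!is.na(v_single)]
  out <- vector("list", length(neuron_ids))
  for (k in seq_along(neuron_ids)) {
    id <- neuron_ids[k]
    rp <- pre$rate[pre$neuron_id == id]
    rc <- cue$rate[cue$neuron_id == id]
    vis <- test_visual_responsiveness(rp, rc, alpha)
    row <- data.frame(neuron_id = id, visually_responsive = vis$responsive,
                      p_visual = vis$p, value_selective = NA,
                      p_selectivity = NA_real_, tuning = NA_character_,
                      b1 = NA_real_, p_tuning = NA_real_,
                      preferred_value = NA_real_, stringsAsFactors = FALSE)
    if (vis$responsive) {
      rs <- selw[selw$neuron_id == id, ]
      rsel <- rs$rate[match(single_ids, rs$trial_id)]
      sel <- test_value_selectivity(rsel, single_val, alpha = alpha)
      row$value_selective <- sel$selective
      row$p_selectivity <- sel$p
      if (sel$selective) {
        tun <- classify_tuning(rsel, single_val, alpha)
        row$tuning <- tun$tuning
        row$b1 <- tun$b1
        row$p_tuning <- tun$p
        row$preferred_value <- tun$preferred_value
      }
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' Baseline-corrected, normalized condition means of one neuron
#'
#' Each condition's mean rate (in `window`) has the neuron's baseline
#' (mean rate in the 200 ms before cue onset) subtracted and is divided
#' by the baseline-subtracted mean response to the neuron's preferred
#' single-cue condition (8 drops for positive tuning, 0 for negative;
#' left/right presentations pooled), so the preferred condition maps to 1.
#'
#' @param session An `ofc_session`.
#' @param neuron_id Neuron to normalize.
#' @param preferred_value Preferred single-cue value from screening.
#' @param window Response window, ms relative to cue onset.
#' @param baseline_window Baseline window, ms.
#' @param min_divisor Minimum absolute divisor (spikes/s); below this the
#'   normalization is degenerate and an error is raised.
#' @param trial_ids Optional subset of trials (e.g. one split half).
#' @return Data.frame `condition_id`, `normalized_mean`, `n_trials`, with
#'   attributes `baseline` and `divisor`; plus a `trial_norm` attribute
#'   holding trial-wise normalized rates.
#' @export
normalize_responses <- function(session, neuron_id, preferred_value,
                                window = c(150, 550),
                                baseline_window = c(-200, 0),
                                min_divisor = 0.1, trial_ids = NULL) {
  trials <- session$trials[session$trials$completed, ]
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  feats <- condition_features(session$conditions)
  rr <- windowed_rates(session$spikes, trials, window, neuron_id)
  rb <- windowed_rates(session$spikes, trials, baseline_window, neuron_id)
  baseline <- mean(rb$rate)
  tf <- feats[match(trials$condition_id, feats$condition_id), ]
  pref <- !is.na(tf$v_single) & tf$v_single == preferred_value
  if (!any(pref)) stop("grouping error: no preferred single-cue trials")
  divisor <- mean(rr$rate[pref]) - baseline
  if (abs(divisor) < min_divisor)
    stop("degenerate normalization: divisor ", signif(divisor, 3),
         " spikes/s for neuron ", neuron_id)
  norm <- (rr$rate - baseline) / divisor
  agg <- stats::aggregate(norm, list(condition_id = trials$condition_id),
                          mean)
  n <- stats::aggregate(norm, list(condition_id = trials$condition_id),
                        length)
  out <- data.frame(condition_id = agg$condition_id,
                    normalized_mean = agg$x, n_trials = n$x,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "divisor") <- divisor
  attr(out, "trial_norm") <- data.frame(trial_id = trials$trial_id,
                                        condition_id = trials$condition_id,
                                        rate_norm = norm,
                                        stringsAsFactors = FALSE)
  out
}

#' Winner-take-all check on unperturbed responses
#'
#' Two analyses on trial-wise (or neuron-wise) responses to unperturbed
#' conditions: (i) a two-way ANOVA comparing single-cue responses with
#' double-cue responses grouped by the higher value (factors: value,
#' number of cues); (ii) an OLS of the double-cue responses on the higher
#' and the lower value jointly.  Under winner-take-all coding the
#' cue-count factor and the lower-value coefficient are both null.
#'
#' @param df Data.frame with columns `resp`, `n_cues` (1/2), `v_high`
#'   (the single-cue value for single-cue rows) and `v_low` (NA for
#'   single-cue rows).
#' @return List with the ANOVA table and p-values, and the higher/lower
#'   regression coefficient table.
#' @export
analyze_double_cue <- function(df) {
  if (!all(c("resp", "n_cues", "v_high", "v_low") %in% names(df)))
    stop("grouping error: need resp, n_cues, v_high, v_low")
  cells <- table(df$v_high, df$n_cues)
  if (any(cells == 0L))
    stop("grouping error: empty value x cue-count cell")
  fit <- stats::aov(resp ~ factor(v_high) + factor(n_cues), data = df)
  tab <- summary(fit)[[1]]
  dd <- df[df$n_cues == 2L, ]
  reg <- stats::lm(resp ~ v_high + v_low, data = dd)
  cf <- summary(reg)$coefficients
  list(anova = tab,
       p_value_factor = tab["factor(v_high)", "Pr(>F)"],
       p_ncues_factor = tab["factor(n_cues)", "Pr(>F)"],
       coef_high = cf["v_high", 1], p_high = cf["v_high", 4],
       coef_low = cf["v_low", 1], p_low = cf["v_low", 4])
}
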