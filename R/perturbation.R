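#' Trial-by-bin sliding-window rate matrix
#'
#' Rates computed in a 50 ms window slid in `step` ms increments; entry
#' (i, j) is trial i's rate in the window centred on bin j.
#'
#' @param spikes Spike table already restricted to one neuron.
#' @param trial_ids Trials forming the rows.
#' @param bin_centers Bin centres in ms relative to cue onset.
#' @param window_ms Sliding-window length.
#' @return Numeric matrix (trials x bins) of rates in spikes/s.
#' @export
psth_trial_matrix <- function(spikes, trial_ids,
                              bin_centers = seq(-200, 1000, by = 10),
                              window_ms = 50) {
  half <- window_ms / 2
  m <- matrix(0, nrow = length(trial_ids), ncol = length(bin_centers),
              dimnames = list(trial_ids, bin_centers))
  sp <- split(spikes$t_ms, factor(spikes$trial_id, levels = trial_ids))
  lo <- bin_centers - half
  hi <- bin_centers + half
  for (i in seq_along(trial_ids)) {
    st <- sort(sp[[i]])
    if (length(st))
      m[i, ] <- (findInterval(hi, st, left.open = TRUE) -
                   findInterval(lo, st, left.open = TRUE))
  }
  m / (window_ms / 1000)
}

#' Peri-stimulus time histogram of a trial group
#'
#' Mean sliding-window rate across all completed trials of a group, with
#' the neuron's baseline (mean rate in the 200 ms before cue onset over
#' the same trials) subtracted, optionally normalized to the neuron's
#' peak response to its preferred condition.
#'
#' @param session An `ofc_session`.
#' @param neuron_id Neuron.
#' @param trial_ids Trials forming the group (completed trials only are
#'   used).
#' @param bin_centers,window_ms Sliding-window geometry.
#' @param normalize_peak Optional positive scalar: the neuron's peak
#'   preferred-condition response used as the divisor.
#' @return Data.frame with `bin_ms` and `rate` (spikes/s, baseline
#'   subtracted; dimensionless when normalized), with the trial matrix in
#'   the `trial_matrix` attribute.
#' @export
compute_psth <- function(session, neuron_id, trial_ids,
                         bin_centers = seq(-200, 1000, by = 10),
                         window_ms = 50, normalize_peak = NULL) {
  trial_ids <- intersect(trial_ids,
                         session$trials$trial_id[session$trials$completed])
  if (length(trial_ids) == 0L) stop("empty trial group")
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  m <- psth_trial_matrix(sp, trial_ids, bin_centers, window_ms)
  rb <- windowed_rates(sp, session$trials[
    session$trials$trial_id %in% trial_ids, ], c(-200, 0), neuron_id)
  baseline <- mean(rb$rate)
  rate <- colMeans(m) - baseline
  if (!is.null(normalize_peak)) rate <- rate / normalize_peak
  out <- data.frame(bin_ms = bin_centers, rate = rate)
  attr(out, "trial_matrix") <- m
  attr(out, "baseline") <- baseline
  out
}

#' Pointwise t-tests between two perturbation groups
#'
#' Two-tailed t-test at every bin on the trial-wise sliding-window rates
#' of the higher-rotated vs the lower-rotated group.  Bins where both
#' groups have zero variance get p = 1 and are flagged.
#'
#' @param mat_h,mat_l Trial-by-bin matrices from [psth_trial_matrix()]
#'   with identical bin columns.
#' @return Numeric vector of p-values (one per bin) with a logical
#'   `degenerate` attribute.
#' @export
pointwise_rotation_test <- function(mat_h, mat_l) {
  if (ncol(mat_h) != ncol(mat_l)) stop("bin mismatch between groups")
  if (nrow(mat_h) == 0L || nrow(mat_l) == 0L) stop("empty trial group")
  p <- numeric(ncol(mat_h))
  degen <- logical(ncol(mat_h))
  for (j in seq_len(ncol(mat_h))) {
    x <- mat_h[, j]; y <- mat_l[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p[j] <- 1; degen[j] <- TRUE
    } else {
      p[j] <- stats::t.test(x, y)$p.value
    }
  }
  names(p) <- colnames(mat_h)
  attr(p, "degenerate") <- degen
  p
}

#' Benjamini-Hochberg rejection mask
#'
#' Standard step-up procedure controlling the false discovery rate at
#' level `q`, applied jointly over all supplied p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection mask of the same length.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Locate a neuron's modulation window
#'
#' The longest contiguous run of bins with uncorrected p < `alpha`, lying
#' within the period from rotation onset to cue offset (200-1000 ms after
#' cue onset) and spanning at least `min_duration_ms` (run duration is
#' counted as bins x step).  Ties go to the earliest run.
#'
#' @param p P-value series from [pointwise_rotation_test()].
#' @param bin_centers Bin centres matching `p`.
#' @param alpha Pointwise threshold.
#' @param min_duration_ms Minimum qualifying duration.
#' @param period Restriction window, ms after cue onset.
#' @return `c(start, end)` in ms (end = last bin centre + step), or NULL
#'   when no run qualifies.
#' @export
find_modulation_window <- function(p, bin_centers, alpha = 0.05,
                                   min_duration_ms = 200,
                                   period = c(200, 1000)) {
  keep <- bin_centers >= period[1] & bin_centers <= period[2]
  p <- p[keep]; bc <- bin_centers[keep]
  if (length(bc) < 2L) return(NULL)
  step <- bc[2] - bc[1]
  r <- rle(as.vector(p) < alpha)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths * step >= min_duration_ms)
  if (!length(ok)) return(NULL)
  best <- ok[which.max(r$lengths[ok])]  # which.max takes the earliest tie
  c(start = bc[starts[best]], end = min(bc[ends[best]] + step, period[2]))
}

#' Attentional modulation index
#'
#' `MI = (FRh - FRl) / (FRh + FRl)`, where `FRh` and `FRl` are the
#' neuron's responses when the higher- and the lower-value cue was
#' rotated.  Lies in `[-1, 1]` for nonnegative rates.
#'
#' @param frh,frl Mean firing rates of the two rotation groups.
#' @return The modulation index.
#' @export
modulation_index <- function(frh, frl) {
  if (any(frh + frl == 0)) stop("undefined MI: FRh + FRl = 0")
  (frh - frl) / (frh + frl)
}

#' Z-scored rotation-group responses
#'
#' Trial-wise rates of both rotation groups are pooled to define the
#' reference mean and SD; each group's mean rate is then standardized
#' against them.
#'
#' @param rates_h,rates_l Trial-wise rates of the higher- and
#'   lower-rotated groups in the evaluation window.
#' @return List with `z_high` and `z_low`.
#' @export
zscore_modulation <- function(rates_h, rates_l) {
  pooled <- c(rates_h, rates_l)
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) stop("degenerate z-score: zero pooled SD")
  m <- mean(pooled)
  list(z_high = (mean(rates_h) - m) / s, z_low = (mean(rates_l) - m) / s)
}

#' Consistency of the attentional modulation
#'
#' A modulated neuron is "consistent" when its responses to the
#' perturbed double-cue conditions moved toward its single-cue response
#' to the perturbed cue, relative to the unperturbed double-cue
#' response.
#'
#' @param r_pert Responses under the perturbed conditions (one per
#'   condition, any common scale).
#' @param r_unpert Responses under the matching unperturbed conditions.
#' @param r_single Single-cue responses to the perturbed cue.
#' @return "consistent" or "inconsistent".
#' @export
classify_consistency <- function(r_pert, r_unpert, r_single) {
  if (mean(abs(r_pert - r_single)) < mean(abs(r_unpert - r_single)))
    "consistent" else "inconsistent"
}

#' First-trials control subset
#'
#' Keeps the first `n_first` completed trials of every block (guarding
#' against perturbation-schedule prediction late in a block), then
#' randomly removes trials from the larger perturbation variant of each
#' cue combination so that, within every combination, each cue is
#' perturbed equally often.
#'
#' @param trials Trial schedule.
#' @param conditions Condition table.
#' @param n_first Number of leading completed trials kept per block.
#' @param seed Optional seed for the balancing subsample.
#' @return The retained subset of `trials`.
#' @export
first_block_control <- function(trials, conditions, n_first = 50,
                                seed = NULL) {
  tr <- trials[trials$completed, ]
  tr <- do.call(rbind, lapply(split(tr, tr$block_index),
                              function(b) utils::head(b, n_first)))
  feats <- condition_features(conditions)
  tf <- feats[match(tr$condition_id, feats$condition_id), ]
  pair <- paste(tf$left_cue_id, tf$right_cue_id)
  with_seed(seed, {
    resample <- function(x, k) x[sample.int(length(x))][seq_len(k)]
    drop <- character(0)
    for (pr in unique(pair[tf$n_cues == 2])) {
      il <- which(pair == pr & tf$perturbed_side == "left")
      ir <- which(pair == pr & tf$perturbed_side == "right")
      n <- min(length(il), length(ir))
      if (length(il) > n)
        drop <- c(drop, tr$trial_id[resample(il, length(il) - n)])
      if (length(ir) > n)
        drop <- c(drop, tr$trial_id[resample(ir, length(ir) - n)])
    }
    out <- tr[!tr$trial_id %in% drop, ]
    rownames(out) <- NULL
    out
  })
}

# Trials of one neuron's higher- and lower-rotated groups (equal-value
# pairs excluded) and the matching unperturbed double-cue trials.
rotation_groups <- function(trials, conditions) {
  feats <- condition_features(conditions)
  tf <- feats[match(trials$condition_id, feats$condition_id), ]
  keep <- trials$completed
  list(
    higher = trials$trial_id[keep & !is.na(tf$perturbed_rank) &
                               tf$perturbed_rank == "higher"],
    lower = trials$trial_id[keep & !is.na(tf$perturbed_rank) &
                              tf$perturbed_rank == "lower"],
    none = trials$trial_id[keep & tf$n_cues == 2 &
                             tf$perturbed_side == "none" &
                             tf$v_high != tf$v_low])
}

#' Perturbation-driven modulation of a neuron population
#'
#' For every value-selective neuron: sliding-window PSTH contrast of the
#' higher- vs lower-rotated trial groups, pointwise t-tests, modulation
#' window (longest run of at least 200 ms with p < 0.05 between rotation
#' onset and cue offset), Z-scored group responses and the modulation
#' index in that window (or in the full 200-1000 ms period for
#' unmodulated neurons), and the consistency classification.
#'
#' @param session An `ofc_session`.
#' @param screening Output of [screen_neurons()].
#' @param trials Optional trial subset (e.g. from
#'   [first_block_control()]); defaults to all trials.
#' @param bin_step_ms Sliding-window step.
#' @param window_ms Sliding-window length.
#' @param uniform_window Optional fixed evaluation window, e.g.
#'   `c(450, 750)`, overriding per-neuron modulation windows.
#' @param alpha Pointwise significance level.
#' @return Data.frame with one row per analyzed neuron: `modulated`,
#'   `window_start_ms`, `window_end_ms`, `z_high`, `z_low`, `mi`,
#'   `consistency`.
#' @export
analyze_perturbation <- function(session, screening, trials = NULL,
                                 bin_step_ms = 10, window_ms = 50,
                                 uniform_window = NULL, alpha = 0.05) {
  if (is.null(trials)) trials <- session$trials
  sel <- screening[!is.na(screening$value_selective) &
                     screening$value_selective, ]
  bins <- seq(-200, 1000, by = bin_step_ms)
  out <- vector("list", nrow(sel))
  for (k in seq_len(nrow(sel))) {
    id <- sel$neuron_id[k]
    grp <- rotation_groups(trials, session$conditions)
    sp <- session$spikes[session$spikes$neuron_id == id, ]
    mh <- psth_trial_matrix(sp, grp$higher, bins, window_ms)
    ml <- psth_trial_matrix(sp, grp$lower, bins, window_ms)
    p <- pointwise_rotation_test(mh, ml)
    win <- find_modulation_window(p, bins, alpha)
    modulated <- !is.null(win)
    eval_win <- if (!is.null(uniform_window)) uniform_window
    else if (modulated) unname(win) else c(200, 1000)
    rh <- apply_window_rates(sp, grp$higher, eval_win)
    rl <- apply_window_rates(sp, grp$lower, eval_win)
    z <- zscore_modulation(rh, rl)
    mi <- if (mean(rh) + mean(rl) > 0) modulation_index(mean(rh), mean(rl))
    else NA_real_
    consistency <- NA_character_
    if (modulated && !is.na(sel$tuning[k])) {
      nr <- normalize_responses(session, id, sel$preferred_value[k],
                                window = c(200, 1000),
                                trial_ids = trials$trial_id[trials$completed])
      consistency <- consistency_from_norm(nr, session$conditions)
    }
    out[[k]] <- data.frame(
      neuron_id = id, modulated = modulated,
      window_start_ms = if (modulated) win[1] else NA_real_,
      window_end_ms = if (modulated) win[2] else NA_real_,
      z_high = z$z_high, z_low = z$z_low, mi = mi,
      consistency = consistency, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# mean rates of a set of trials in an arbitrary window
apply_window_rates <- function(sp, trial_ids, window) {
  sel <- sp$t_ms >= window[1] & sp$t_ms < window[2]
  cnt <- table(factor(sp$trial_id[sel], levels = trial_ids))
  as.vector(cnt) / (diff(window) / 1000)
}

# consistency from a neuron's normalized condition means: compare the
# lower-perturbed conditions against the matching unperturbed pair and
# the perturbed (lower) cue's single-cue response
consistency_from_norm <- function(norm, conditions) {
  feats <- condition_features(conditions)
  nm <- merge(norm, feats, by = "condition_id")
  singles <- nm[nm$n_cues == 1, ]
  s_by_v <- tapply(singles$normalized_mean, singles$v_single, mean)
  low <- nm[!is.na(nm$perturbed_rank) & nm$perturbed_rank == "lower", ]
  if (nrow(low) == 0L) return(NA_character_)
  unpert_id <- condition_id(low$left_cue_id, low$right_cue_id, "none")
  r_unpert <- nm$normalized_mean[match(unpert_id, nm$condition_id)]
  r_single <- s_by_v[as.character(low$v_low)]
  ok <- !is.na(r_unpert) & !is.na(r_single)
  if (!any(ok)) return(NA_character_)
  classify_consistency(low$normalized_mean[ok], r_unpert[ok], r_single[ok])
}

#' Population contrasts between rotation conditions
#'
#' Per-neuron normalized mean responses (200-1000 ms, normalized to the
#' preferred single-cue response) in the higher-rotated, lower-rotated
#' and unperturbed double-cue groups, with population-level paired
#' t-tests of higher vs lower (the attentional modulation) and higher vs
#' no perturbation (expected null: perturbing the already-attended cue
#' changes nothing).
#'
#' @param session An `ofc_session`.
#' @param screening Output of [screen_neurons()].
#' @param window Evaluation window, ms.
#' @param neuron_ids Optional subset (default: all tuned neurons).
#' @return List with the per-neuron data.frame and the two paired tests.
#' @export
compare_rotation_conditions <- function(session, screening,
                                        window = c(200, 1000),
                                        neuron_ids = NULL) {
  sel <- screening[!is.na(screening$tuning), ]
  if (!is.null(neuron_ids)) sel <- sel[sel$neuron_id %in% neuron_ids, ]
  grp <- rotation_groups(session$trials, session$conditions)
  out <- vector("list", nrow(sel))
  for (k in seq_len(nrow(sel))) {
    id <- sel$neuron_id[k]
    nr <- normalize_responses(session, id, sel$preferred_value[k],
                              window = window)
    tn <- attr(nr, "trial_norm")
    gm <- function(ids) mean(tn$rate_norm[tn$trial_id %in% ids])
    out[[k]] <- data.frame(neuron_id = id, tuning = sel$tuning[k],
                           resp_higher = gm(grp$higher),
                           resp_lower = gm(grp$lower),
                           resp_none = gm(grp$none),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  t_hl <- stats::t.test(df$resp_higher, df$resp_lower, paired = TRUE)
  t_hn <- stats::t.test(df$resp_higher, df$resp_none, paired = TRUE)
  list(neurons = df,
       mean_diff_higher_lower = mean(df$resp_higher - df$resp_lower),
       p_higher_lower = t_hl$p.value,
       mean_diff_higher_none = mean(df$resp_higher - df$resp_none),
       p_higher_none = t_hn$p.value)
}
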