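# Self-contained simulation experiments used by the validation suite and
# by scripts/acceptance.R.  Each one regenerates its data from scratch,
# reproducibly from a single seed.

sub_seed <- function(seed, i) (abs(seed) + 99991L * i) %% 2147483547L

#' Parameter-recovery experiment
#'
#' Simulates value-tuned neurons from the winner-take-all generator
#' (each with its own attention parameters b, c, d), runs the full
#' normalization-model fit on each neuron's complete recording, and
#' compares fitted with generative parameters.  The number of blocks
#' defaults to 4 (340 trials, the scale of a typical recorded neuron).
#'
#' @param n_neurons Number of simulated neurons.
#' @param n_blocks Blocks per neuron.
#' @param seed Master seed.
#' @param ranges Generator parameter ranges.
#' @return Data.frame of true and fitted parameters, with the Spearman
#'   rank correlation of d in the `spearman_d` attribute.
#' @export
experiment_parameter_recovery <- function(n_neurons = 200L, n_blocks = 4L,
                                          seed = 1L,
                                          ranges = default_neuron_ranges()) {
  conditions <- enumerate_block_conditions(cue_set())
  trials <- build_trial_schedule(conditions, n_blocks,
                                 seed = sub_seed(seed, 0L))
  out <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    nr <- make_ground_truth_neurons(1L, 0L, 0L, 0L, ranges = ranges,
                                    seed = sub_seed(seed, i))
    s <- with_seed(sub_seed(seed, i) + 1L, {
      spikes <- simulate_neuron_spikes(nr[1, ], trials, conditions)
      structure(list(conditions = conditions, trials = trials,
                     spikes = spikes), class = "ofc_session")
    })
    cm <- condition_means(s, nr$neuron_id[1], 8)
    ff <- fit_full(cm, seed = sub_seed(seed, i) + 2L)
    out[[i]] <- data.frame(b_true = nr$att_b, c_true = nr$att_c,
                           d_true = nr$att_d, b_fit = ff$b, c_fit = ff$c,
                           d_fit = ff$d, rss = ff$rss)
  }
  res <- do.call(rbind, out)
  attr(res, "spearman_d") <- stats::cor(res$d_true, res$d_fit,
                                        method = "spearman")
  res
}

#' Noise-free identifiability check
#'
#' Builds exact condition means from the full model at the given
#' parameters (single-cue responses on the standard 5-value grid) and
#' refits; with no noise the optimizer must drive the residual to zero
#' and return the generating parameters.
#'
#' @param b,c,d Generating parameters.
#' @param seed Seed for the optimizer's starting points.
#' @return The [fit_full()] result.
#' @export
experiment_zero_noise_recovery <- function(b = 0.05, c = 8, d = 1.2,
                                           seed = 1L) {
  vals <- c(0, 1, 2, 4, 8)
  g <- expand.grid(h = vals, l = vals)
  g <- g[g$h >= g$l, ]
  resp <- function(v) 0.15 + 0.85 * v / 8  # monotone single-cue profile
  cm <- data.frame(condition_id = paste0("p", seq_len(nrow(g))),
                   v_high = g$h, v_low = g$l,
                   Rh = resp(g$h), Rl = resp(g$l),
                   R_obs = NA_real_, n_trials = 4L, pert = "lower",
                   stringsAsFactors = FALSE)
  cm$R_obs <- predict_full(cm$Rh, cm$Rl, b, c, d, cm$pert)
  fit_full(cm, seed = seed)
}

#' Model-selection contrast experiment
#'
#' One synthetic population per generator arm: either attention weights
#' that depend on the value difference (the sigmoid generator, c = 3,
#' d spread over 1.7-2) or constant per-neuron weights.  High-gain
#' neurons and long recordings (30 blocks) are used so that per-neuron
#' AICc selection is resolvable above the parsimony penalty; all three
#' models are fitted split-half and compared on the test halves.
#'
#' @param mode "sigmoid" or "constant".
#' @param n_neurons Population size.
#' @param n_blocks Blocks recorded.
#' @param seed Master seed.
#' @return The [compare_models()] result.
#' @export
experiment_model_selection <- function(mode = c("sigmoid", "constant"),
                                       n_neurons = 20L, n_blocks = 30L,
                                       seed = 1L) {
  mode <- match.arg(mode)
  rg <- default_neuron_ranges()
  rg$value_gain <- c(25, 35)
  rg$baseline_positive <- c(8, 12)
  nr <- make_ground_truth_neurons(n_neurons, 0L, 0L, 0L, ranges = rg,
                                  seed = sub_seed(seed, 1L))
  if (mode == "sigmoid") {
    nr$att_c <- 3
    nr$att_d <- seq(1.7, 2, length.out = n_neurons)
  } else {
    nr$attention_mode <- "constant"
  }
  s <- simulate_session(list(n_blocks = n_blocks, n_positive = n_neurons,
                             n_negative = 0L, n_untuned = 0L,
                             n_nonvisual = 0L, include_pupil = FALSE),
                        seed = sub_seed(seed, 2L), neurons = nr)
  scr <- data.frame(neuron_id = nr$neuron_id, tuning = "positive",
                    preferred_value = 8, stringsAsFactors = FALSE)
  fits <- fit_attention_models(s, scr, seed = sub_seed(seed, 3L),
                               n_starts = 10L)
  compare_models(fits)
}

#' One simulated experiment of the winner-take-all signature
#'
#' Simulates a population of positively tuned neurons, screens it, and
#' evaluates the three-part signature of winner-take-all value coding:
#' (i) responses differ between higher- and lower-value-cue rotations
#' (p < 0.05, paired across neurons); (ii) rotating the higher-value
#' (already attended) cue leaves responses unchanged relative to no
#' perturbation (p > 0.01); (iii) the lower value carries no weight in
#' the unperturbed double-cue population regression (p > 0.01).
#'
#' @param seed Seed for this experiment.
#' @param integration Generator mode passed to the simulator.
#' @param n_positive,n_blocks Population and session size.
#' @return Named logical vector with the three components and `signature`
#'   (their conjunction), or NULL when fewer than 3 neurons survive
#'   screening.
#' @export
experiment_wta_signature <- function(seed, integration = "winner_take_all",
                                     n_positive = 12L, n_blocks = 4L) {
  s <- simulate_session(list(n_blocks = n_blocks, n_positive = n_positive,
                             n_negative = 0L, n_untuned = 0L,
                             n_nonvisual = 0L, include_pupil = FALSE,
                             integration = integration), seed = seed)
  scr <- screen_neurons(s)
  scr <- scr[!is.na(scr$tuning) & scr$tuning == "positive", ]
  if (nrow(scr) < 3L) return(NULL)
  rc <- compare_rotation_conditions(s, scr)
  feats <- condition_features(s$conditions)
  pop <- Reduce(`+`, lapply(seq_len(nrow(scr)), function(k) {
    x <- normalize_responses(s, scr$neuron_id[k], scr$preferred_value[k],
                             window = c(200, 1000))
    x$normalized_mean[match(feats$condition_id, x$condition_id)]
  })) / nrow(scr)
  dd <- feats$n_cues == 2 & feats$perturbed_side == "none"
  reg <- summary(stats::lm(pop[dd] ~ feats$v_high[dd] + feats$v_low[dd]))
  p_low <- reg$coefficients[3, 4]
  parts <- c(rotation_contrast = rc$p_higher_lower < 0.05,
             higher_vs_none_null = rc$p_higher_none > 0.01,
             lower_value_null = p_low > 0.01)
  c(parts, signature = all(parts))
}

#' Screening-calibration experiment
#'
#' Simulates neurons on single-cue trials only and measures the fraction
#' flagged value-selective by the one-way ANOVA screen: value-blind
#' (zero-gain, visually responsive) neurons estimate the false-positive
#' rate, which should sit at the nominal alpha; strongly tuned neurons
#' estimate power.
#'
#' @param n_neurons Number of neurons.
#' @param tuned Simulate strongly value-tuned neurons (TRUE) or
#'   zero-gain neurons (FALSE).
#' @param n_blocks Blocks (single-cue trials only are simulated).
#' @param seed Master seed.
#' @param alpha Screening level.
#' @return Fraction flagged selective.
#' @export
experiment_screening_calibration <- function(n_neurons = 1000L,
                                             tuned = FALSE, n_blocks = 4L,
                                             seed = 1L, alpha = 0.05) {
  conditions <- enumerate_block_conditions(cue_set())
  feats <- condition_features(conditions)
  trials <- build_trial_schedule(conditions, n_blocks,
                                 seed = sub_seed(seed, 0L))
  v <- feats$v_single[match(trials$condition_id, feats$condition_id)]
  trials <- trials[!is.na(v), ]
  v <- v[!is.na(v)]
  rg <- default_neuron_ranges()
  if (tuned) rg$value_gain <- c(12, 15)
  hits <- logical(n_neurons)
  for (i in seq_len(n_neurons)) {
    nr <- if (tuned)
      make_ground_truth_neurons(1L, 0L, 0L, 0L, ranges = rg,
                                seed = sub_seed(seed, i))
    else make_ground_truth_neurons(0L, 0L, 1L, 0L, ranges = rg,
                                   seed = sub_seed(seed, i))
    sp <- with_seed(sub_seed(seed, i) + 1L,
                    simulate_neuron_spikes(nr[1, ], trials, conditions,
                                           t_range = c(-300, 700)))
    r <- windowed_rates(sp, trials, c(150, 550), nr$neuron_id[1])
    rate <- r$rate[match(trials$trial_id, r$trial_id)]
    hits[i] <- test_value_selectivity(rate, v, alpha = alpha)$selective
  }
  mean(hits)
}
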