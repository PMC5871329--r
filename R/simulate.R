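#' Ground-truth neuron parameter table
#'
#' Draws simulator parameters for a population of neurons.  Four classes
#' are supported:
#' \describe{
#'   \item{positive}{value-tuned, firing rate increases with the attended
#'     cue's value;}
#'   \item{negative}{value-tuned, rate decreases with attended value (the
#'     visual drive is larger than the value drive so the preferred,
#'     0-drop response stays well above baseline);}
#'   \item{untuned}{visually responsive but value-blind;}
#'   \item{nonvisual}{baseline firing only.}
#' }
#' Each neuron carries its own attention parameters `att_b`, `att_c`,
#' `att_d`: on trials in which the lower-value cue is perturbed, attention
#' switches to that cue with probability
#' `a = d / (1 + exp(c * |dV| / vmax))`, where `|dV|` is the value
#' difference of the pair.  The defaults place the mean switch
#' probability near 0.43, the average weight recovered by the reduced
#' constant-weight model in the experiment the simulator emulates.
#'
#' @param n_positive,n_negative,n_untuned,n_nonvisual Class sizes.
#' @param ranges Named list of `c(min, max)` ranges; see
#'   [default_neuron_ranges()].
#' @param seed Optional integer seed.
#' @return A data.frame, one row per neuron (`neurons_truth` schema).
#' @export
make_ground_truth_neurons <- function(n_positive = 5L, n_negative = 3L,
                                      n_untuned = 3L, n_nonvisual = 4L,
                                      ranges = default_neuron_ranges(),
                                      seed = NULL) {
  with_seed(seed, {
    tuning <- rep(c("positive", "negative", "untuned", "nonvisual"),
                  c(n_positive, n_negative, n_untuned, n_nonvisual))
    n <- length(tuning)
    if (n == 0L) stop("invalid config field: zero neurons requested")
    ru <- function(rg, m) stats::runif(m, rg[1], rg[2])
    out <- data.frame(
      neuron_id = sprintf("n%03d", seq_len(n)),
      tuning = tuning,
      baseline_rate = numeric(n), value_gain = numeric(n),
      visual_gain = numeric(n),
      visual_latency_ms = round(ru(ranges$visual_latency_ms, n)),
      transient_scale = ranges$transient_scale,
      att_b = ru(ranges$att_b, n),
      att_c = ru(ranges$att_c, n),
      att_d = ru(ranges$att_d, n),
      attention_shift_latency_ms = ranges$attention_shift_latency_ms,
      attention_mode = "sigmoid",
      att_a_const = ru(ranges$att_a_const, n),
      stringsAsFactors = FALSE)
    for (cls in unique(tuning)) {
      i <- tuning == cls
      m <- sum(i)
      out$baseline_rate[i] <- ru(ranges[[paste0("baseline_", cls)]], m)
      out$value_gain[i] <- switch(cls,
        positive = ,
        negative = ru(ranges$value_gain, m),
        0)
      out$visual_gain[i] <- switch(cls,
        positive = ru(ranges$visual_gain_positive, m),
        negative = ru(ranges$visual_gain_negative, m),
        untuned = ru(ranges$visual_gain_untuned, m),
        nonvisual = 0)
    }
    # keep the negative neurons' rate non-negative at the highest value
    i <- out$tuning == "negative"
    out$visual_gain[i] <- pmax(out$visual_gain[i], out$value_gain[i])
    out
  })
}

#' Default parameter ranges for the neuron generator
#'
#' Rates are in spikes/s; `value_gain` is the sustained drive at the
#' maximum (8-drop) value.  Attention steepness `att_c` and ceiling
#' `att_d` default to ranges centred on c = 2, d = 1.2.
#'
#' @return Named list of ranges and scalars.
#' @export
default_neuron_ranges <- function() {
  list(
    baseline_positive = c(5, 15), baseline_negative = c(15, 25),
    baseline_untuned = c(5, 15), baseline_nonvisual = c(5, 20),
    value_gain = c(8, 15),
    visual_gain_positive = c(1, 3),
    visual_gain_negative = c(0, 4),   # added on top of value_gain floor
    visual_gain_untuned = c(6, 12),
    visual_latency_ms = c(130, 170),
    transient_scale = 1.5,
    att_b = c(0, 0.1), att_c = c(1, 4), att_d = c(0.4, 2),
    att_a_const = c(0.3, 0.6),
    attention_shift_latency_ms = 100)
}

#' Attentional switch probability
#'
#' The sigmoid of the normalization model: the probability (equivalently,
#' time-averaged weight) that attention ends up on the lower-value cue
#' when it is perturbed, `a = d / (1 + exp(c * dv))`, with `dv >= 0` the
#' (normalized) difference between the two competing drives.
#'
#' @param dv Nonnegative difference (normalized value or response units).
#' @param c Sigmoid steepness, `0 <= c <= 100`.
#' @param d Sigmoid ceiling scale, `0 <= d <= 2`.
#' @return Weight in `[0, 1]`.
#' @export
attention_weight <- function(dv, c, d) {
  if (any(c < 0 | c > 100)) stop("parameter out of bounds: c")
  if (any(d < 0 | d > 2)) stop("parameter out of bounds: d")
  d / (1 + exp(c * abs(dv)))
}

#' Draw the attention trace of one trial
#'
#' Attention is winner-take-all at every instant.  Single-cue trials:
#' the shown cue is attended throughout.  Double-cue trials: the
#' higher-value cue is attended (ties broken at random).  A perturbation
#' of the higher-value cue changes nothing; a perturbation of the
#' lower-value (or equal-value) cue switches attention to the perturbed
#' cue, with probability given by [attention_weight()], from
#' perturbation onset + shift latency until cue offset.
#'
#' @param condition One-row condition data.frame (with or without the
#'   [condition_features()] columns).
#' @param att List with `c`, `d`, optionally `mode` ("sigmoid" or
#'   "constant") and `a_const` (used when `mode = "constant"`).
#' @param shift_latency_ms Latency from perturbation onset to the switch.
#' @param pert_onset_ms,cue_off_ms Perturbation onset and cue offset
#'   relative to cue onset.
#' @param vmax Value used to normalize value differences.
#' @return A data.frame with columns `t_start`, `t_end`, `value`, `side`
#'   partitioning the cue period `[0, cue_off_ms]`.
#' @export
draw_attention_trace <- function(condition, att, shift_latency_ms = 100,
                                 pert_onset_ms = 200, cue_off_ms = 1000,
                                 vmax = 8) {
  lv <- condition$left_value; rv <- condition$right_value
  seg <- function(s, e, v, side) data.frame(
    t_start = s, t_end = e, value = v, side = side,
    stringsAsFactors = FALSE)
  if (is.na(lv) || is.na(rv)) {  # single cue
    side <- if (is.na(rv)) "left" else "right"
    v <- if (is.na(rv)) lv else rv
    return(seg(0, cue_off_ms, v, side))
  }
  if (lv > rv) hi <- "left" else if (rv > lv) hi <- "right"
  else hi <- if (stats::runif(1) < 0.5) "left" else "right"
  v_hi <- max(lv, rv); v_lo <- min(lv, rv)
  ps <- condition$perturbed_side
  if (is.null(ps) || is.na(ps) || ps == "none" || ps == hi)
    return(seg(0, cue_off_ms, v_hi, hi))
  # perturbation on the non-attended (lower or equal value) cue
  mode <- if (is.null(att$mode)) "sigmoid" else att$mode
  a <- if (mode == "constant") att$a_const
       else attention_weight((v_hi - v_lo) / vmax, att$c, att$d)
  t_shift <- pert_onset_ms + shift_latency_ms
  if (stats::runif(1) < a && t_shift < cue_off_ms) {
    pv <- if (ps == "left") lv else rv
    rbind(seg(0, t_shift, v_hi, hi), seg(t_shift, cue_off_ms, pv, ps))
  } else {
    seg(0, cue_off_ms, v_hi, hi)
  }
}

# Piecewise-linear firing-rate envelope shared by all simulated neurons:
# 0 before the visual latency, a 50 ms ramp to the transient peak, decay
# to the sustained level by 500 ms, sustained until cue offset, back to
# 0 over 200 ms.  Returns knot positions and values.
rate_envelope_knots <- function(latency_ms, transient_scale = 1.5,
                                ramp_ms = 50, peak_end_ms = 400,
                                sustain_start_ms = 500, cue_off_ms = 1000,
                                decay_ms = 200) {
  x <- c(latency_ms, latency_ms + ramp_ms, peak_end_ms, sustain_start_ms,
         cue_off_ms, cue_off_ms + decay_ms)
  y <- c(0, transient_scale, transient_scale, 1, 1, 0)
  list(x = x, y = y)
}

# Instantaneous firing rate (spikes/s) of a neuron at times t (ms relative
# to cue onset) on a given trial, given its attention trace.
neuron_rate_at <- function(t, neuron, attention, is_double) {
  env <- rate_envelope_knots(neuron$visual_latency_ms,
                             neuron$transient_scale)
  e <- stats::approx(c(min(t, env$x[1]) - 1, env$x, max(t, env$x[6]) + 1),
                     c(0, env$y, 0), xout = t, rule = 2)$y
  sign <- switch(neuron$tuning, positive = 1, negative = -1, 0)
  # attended value as a step function of time (constant before cue onset
  # and after cue offset; envelope is 0 there so the value is irrelevant)
  idx <- findInterval(pmin(pmax(t, attention$t_start[1]),
                           max(attention$t_end) - 1e-9),
                      attention$t_start)
  v_att <- attention$value[pmax(idx, 1L)]
  gain_total <- switch(neuron$tuning,
                       positive = neuron$visual_gain + neuron$value_gain,
                       negative = neuron$visual_gain,
                       neuron$visual_gain)
  drive <- neuron$visual_gain + sign * neuron$value_gain * v_att / 8 +
    if (is_double) neuron$att_b * gain_total else 0
  pmax(neuron$baseline_rate + e * drive, 0)
}

#' Simulate one spike train
#'
#' Inhomogeneous-Poisson sampling (by thinning) from a rate function that
#' is baseline before cue onset + visual latency and thereafter baseline
#' plus a value drive of the currently attended cue, signed by the
#' neuron's tuning, under a transient-then-sustained envelope; rates are
#' rectified at zero.
#'
#' @param neuron One-row ground-truth neuron data.frame.
#' @param condition One-row condition data.frame.
#' @param attention Attention trace from [draw_attention_trace()].
#' @param t_range Simulated interval in ms relative to cue onset.
#' @return Sorted numeric vector of spike times (ms relative to cue onset).
#' @export
simulate_spike_train <- function(neuron, condition, attention,
                                 t_range = c(-2000, 1200)) {
  if (diff(t_range) < 0) stop("negative requested duration")
  is_double <- !is.na(condition$left_value) && !is.na(condition$right_value)
  drive_max <- neuron$visual_gain +
    (neuron$tuning == "positive") * neuron$value_gain +
    abs(neuron$att_b) * (neuron$visual_gain + neuron$value_gain)
  rmax <- neuron$baseline_rate + neuron$transient_scale * drive_max
  if (rmax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rmax * diff(t_range) / 1000)
  if (n_cand == 0L) return(numeric(0))
  tt <- stats::runif(n_cand, t_range[1], t_range[2])
  r <- neuron_rate_at(tt, neuron, attention, is_double)
  sort(tt[stats::runif(n_cand) * rmax < r])
}

#' Simulate all trials of one neuron
#'
#' Convenience wrapper used by [simulate_session()] and by large
#' calibration runs: draws an attention trace and a spike train for every
#' completed trial in `trials`.
#'
#' @param neuron One-row ground-truth neuron data.frame.
#' @param trials Trial schedule.
#' @param conditions Condition table.
#' @param t_range Simulated interval (ms relative to cue onset).
#' @param integration "winner_take_all" (the attention trace drives the
#'   value input) or "average" (a contrast generator: double-cue trials
#'   drive the neuron with the mean of the two values, attention playing
#'   no role).
#' @return A data.frame with columns `neuron_id`, `trial_id`, `t_ms`.
#' @export
simulate_neuron_spikes <- function(neuron, trials, conditions,
                                   t_range = c(-2000, 1200),
                                   integration = c("winner_take_all",
                                                   "average")) {
  integration <- match.arg(integration)
  idx <- match(trials$condition_id, conditions$condition_id)
  keep <- which(trials$completed)
  lv <- conditions$left_value[idx][keep]
  rv <- conditions$right_value[idx][keep]
  ps <- conditions$perturbed_side[idx][keep]
  n <- length(keep)

  # per-trial attended-value path: value v1 until t_shift, v2 after
  # (vectorized version of draw_attention_trace, same generative law)
  is_double <- !is.na(lv) & !is.na(rv)
  vhi <- pmax(lv, rv, na.rm = TRUE)
  vlo <- pmin(lv, rv, na.rm = TRUE)
  pv <- ifelse(ps == "left", lv, ifelse(ps == "right", rv, NA))
  ov <- ifelse(ps == "left", rv, ifelse(ps == "right", lv, NA))
  # perturbation on the non-attended cue (ties: attended side is random)
  eligible <- is_double & !is.na(pv) &
    (pv < ov | (pv == ov & stats::runif(n) < 0.5))
  a <- if (neuron$attention_mode == "constant")
    rep(neuron$att_a_const, n)
  else neuron$att_d / (1 + exp(neuron$att_c * (vhi - vlo) / 8))
  shift <- eligible & stats::runif(n) < a
  v1 <- vhi
  v2 <- ifelse(shift, pv, vhi)
  t_shift <- ifelse(shift, 200 + neuron$attention_shift_latency_ms, Inf)
  if (integration == "average") {
    v1 <- ifelse(is_double, (lv + rv) / 2, v1)
    v2 <- v1
    t_shift <- rep(Inf, n)
  }

  sgn <- switch(neuron$tuning, positive = 1, negative = -1, 0)
  gain_total <- if (neuron$tuning == "negative") neuron$visual_gain
  else neuron$visual_gain + neuron$value_gain
  bterm <- neuron$att_b * gain_total
  drive_max <- neuron$visual_gain +
    (neuron$tuning == "positive") * neuron$value_gain +
    abs(neuron$att_b) * (neuron$visual_gain + neuron$value_gain)
  rmax <- neuron$baseline_rate + neuron$transient_scale * drive_max
  empty <- data.frame(neuron_id = character(0), trial_id = character(0),
                      t_ms = numeric(0), stringsAsFactors = FALSE)
  if (rmax <= 0 || n == 0L) return(empty)

  env <- rate_envelope_knots(neuron$visual_latency_ms,
                             neuron$transient_scale)
  ex <- c(t_range[1] - 1, env$x, t_range[2] + 1)
  ey <- c(0, env$y, 0)
  n_cand <- stats::rpois(n, rmax * diff(t_range) / 1000)
  tot <- sum(n_cand)
  if (tot == 0L) return(empty)
  tt <- stats::runif(tot, t_range[1], t_range[2])
  ti <- rep.int(seq_len(n), n_cand)
  e <- stats::approx(ex, ey, xout = tt, rule = 2)$y
  v_att <- ifelse(tt < t_shift[ti], v1[ti], v2[ti])
  drive <- neuron$visual_gain + sgn * neuron$value_gain * v_att / 8 +
    bterm * is_double[ti]
  rate <- pmax(neuron$baseline_rate + e * drive, 0)
  acc <- stats::runif(tot) * rmax < rate
  o <- order(ti[acc], tt[acc])
  data.frame(neuron_id = neuron$neuron_id,
             trial_id = trials$trial_id[keep][ti[acc]][o],
             t_ms = tt[acc][o],
             stringsAsFactors = FALSE)
}

#' Default pupil ground truth
#'
#' The pupil trace is sampled at 500 Hz from fixation onset to reward.
#' It is a baseline (with per-trial drift) plus a slow kernel time-locked
#' to the cue whose amplitude increases linearly with the attended cue's
#' value: the kernel ramps from 0 at cue onset to 1 at cue offset and
#' stays at 1 through the delay, so the mean over the 1 s after cue
#' offset equals `amp_per_drop * value` exactly when noise is zero.
#' In double-cue trials only the higher-value (attended) cue drives the
#' trace.
#'
#' @return Named list of pupil parameters (arbitrary tracker units).
#' @export
default_pupil_gt <- function() {
  list(baseline_level = 1000, amp_per_drop = 5,
       baseline_drift_sd = 30, response_sd = 8, sample_noise_sd = 15,
       sampling_rate_hz = 500)
}

#' Simulate the pupil trace of one trial
#'
#' @param condition One-row condition data.frame.
#' @param pupil_gt Parameter list, see [default_pupil_gt()].
#' @param fix_dur_ms,cue_dur_ms,delay_ms Epoch durations.
#' @return A data.frame with `t_ms` (relative to fixation onset) and
#'   `pupil_size`.
#' @export
simulate_pupil_trace <- function(condition, pupil_gt = default_pupil_gt(),
                                 fix_dur_ms = 2000, cue_dur_ms = 1000,
                                 delay_ms = 1500) {
  step <- 1000 / pupil_gt$sampling_rate_hz
  t <- seq(0, fix_dur_ms + cue_dur_ms + delay_ms - step, by = step)
  v_att <- max(condition$left_value, condition$right_value, na.rm = TRUE)
  kernel <- pmin(pmax((t - fix_dur_ms) / cue_dur_ms, 0), 1)
  amp <- pupil_gt$amp_per_drop * v_att +
    stats::rnorm(1, 0, pupil_gt$response_sd)
  base <- pupil_gt$baseline_level +
    stats::rnorm(1, 0, pupil_gt$baseline_drift_sd)
  ps <- base + amp * kernel +
    stats::rnorm(length(t), 0, pupil_gt$sample_noise_sd)
  data.frame(t_ms = t, pupil_size = ps)
}

#' Default session configuration
#'
#' Nine 85-condition blocks (about 800 trials, matching a typical
#' recording day) and a 15-neuron population.
#'
#' @return Named list accepted by [simulate_session()].
#' @export
default_session_config <- function() {
  list(cues = cue_set(), n_blocks = 9L,
       n_positive = 5L, n_negative = 3L, n_untuned = 3L, n_nonvisual = 4L,
       neuron_ranges = default_neuron_ranges(),
       p_incomplete = 0, include_pupil = TRUE,
       integration = "winner_take_all",
       pupil = default_pupil_gt())
}

validate_session_config <- function(config) {
  defaults <- default_session_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("invalid config field: ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  for (f in c("n_blocks", "n_positive", "n_negative", "n_untuned",
              "n_nonvisual"))
    if (!is.numeric(config[[f]]) || config[[f]] < 0 ||
        config[[f]] != round(config[[f]]))
      stop("invalid config field: ", f)
  if (!is.numeric(config$p_incomplete) || config$p_incomplete < 0 ||
      config$p_incomplete >= 1)
    stop("invalid config field: p_incomplete")
  if (!config$integration %in% c("winner_take_all", "average"))
    stop("invalid config field: integration")
  config
}

#' Simulate a complete session
#'
#' Generates the trial schedule, the ground-truth neuron population, every
#' neuron's spike trains and (optionally) the pupil traces, fully
#' reproducibly from one seed.
#'
#' @param config Configuration list; missing entries fall back to
#'   [default_session_config()].
#' @param seed Integer seed.
#' @param neurons Optional pre-built ground-truth neuron table (overrides
#'   the class counts in `config`).
#' @return An object of class `ofc_session`: a list with `conditions`,
#'   `trials`, `spikes`, `pupil`, `neurons` and `config`.
#' @export
simulate_session <- function(config = list(), seed = 1L, neurons = NULL) {
  config <- validate_session_config(config)
  with_seed(seed, {
    conditions <- enumerate_block_conditions(config$cues)
    trials <- build_trial_schedule(conditions, config$n_blocks,
                                   p_incomplete = config$p_incomplete)
    if (is.null(neurons))
      neurons <- make_ground_truth_neurons(
        config$n_positive, config$n_negative, config$n_untuned,
        config$n_nonvisual, config$neuron_ranges)
    spikes <- vector("list", nrow(neurons))
    for (k in seq_len(nrow(neurons)))
      spikes[[k]] <- simulate_neuron_spikes(neurons[k, ], trials, conditions,
                                            integration = config$integration)
    spikes <- do.call(rbind, spikes)
    pupil <- NULL
    if (isTRUE(config$include_pupil)) {
      cond <- conditions[match(trials$condition_id,
                               conditions$condition_id), ]
      keep <- which(trials$completed)
      pl <- vector("list", length(keep))
      for (j in seq_along(keep)) {
        i <- keep[j]
        tr <- simulate_pupil_trace(cond[i, ], config$pupil)
        tr$trial_id <- trials$trial_id[i]
        pl[[j]] <- tr
      }
      pupil <- do.call(rbind, pl)[, c("trial_id", "t_ms", "pupil_size")]
    }
    structure(list(conditions = conditions, trials = trials,
                   spikes = spikes, pupil = pupil, neurons = neurons,
                   config = config, seed = seed),
              class = "ofc_session")
  })
}

#' @export
print.ofc_session <- function(x, ...) {
  cat("ofc_session:",
      nrow(x$trials), "trials in",
      max(x$trials$block_index), "blocks;",
      nrow(x$neurons), "neurons;",
      nrow(x$spikes), "spikes",
      if (!is.null(x$pupil)) paste0("; pupil traces for ",
                                    length(unique(x$pupil$trial_id)),
                                    " trials") else "", "\n")
  invisible(x)
}

#' Write / read a session bundle as plain CSV files
#'
#' Files written: `conditions.csv`, `trials.csv`, `spikes.csv`,
#' `pupil.csv` (if present) and `neurons_truth.csv`.
#'
#' @param session An `ofc_session`.
#' @param dir Directory (created if needed).
#' @return `write_session` returns `dir` invisibly; `read_session`
#'   returns an `ofc_session` (without config or ground truth when the
#'   corresponding files are absent).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(session$conditions, "conditions.csv")
  w(session$trials, "trials.csv")
  w(session$spikes, "spikes.csv")
  if (!is.null(session$pupil)) w(session$pupil, "pupil.csv")
  w(session$neurons, "neurons_truth.csv")
  invisible(dir)
}

session_schemas <- function() {
  list(
    conditions.csv = c("condition_id", "left_cue_id", "left_value",
                       "right_cue_id", "right_value", "perturbed_side"),
    trials.csv = c("trial_id", "block_index", "condition_id", "completed",
                   "rewarded_side", "reward_drops", "t_fixation_on_ms",
                   "t_cue_on_ms", "t_cue_off_ms", "t_reward_ms"),
    spikes.csv = c("neuron_id", "trial_id", "t_ms"),
    pupil.csv = c("trial_id", "t_ms", "pupil_size"),
    neurons_truth.csv = c("neuron_id", "tuning"))
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  schemas <- session_schemas()
  rd <- function(f, required = TRUE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      if (required) stop("missing session file: ", f)
      return(NULL)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(schemas[[f]], names(df))
    if (length(miss))
      stop("format error in ", f, ": missing column ",
           paste(miss, collapse = ", "))
    df
  }
  structure(list(conditions = rd("conditions.csv"),
                 trials = rd("trials.csv"),
                 spikes = rd("spikes.csv"),
                 pupil = rd("pupil.csv", required = FALSE),
                 neurons = rd("neurons_truth.csv", required = FALSE),
                 config = NULL),
            class = "ofc_session")
}
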