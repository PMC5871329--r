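test_that("windowed rates use half-open intervals", {
  expect_equal(windowed_rate(c(100, 200, 300, 350), c(100, 500)), 10)
  expect_equal(windowed_rate(numeric(0), c(0, 1000)), 0)
  expect_equal(windowed_rate(c(500), c(100, 500)), 0)  # end excluded
  expect_equal(windowed_rate(c(100), c(100, 500)), 2.5)  # start included
  expect_error(windowed_rate(1, c(5, 5)), "empty window")
})

test_that("visual responsiveness handles degenerate and clear cases", {
  expect_error(test_visual_responsiveness(1, c(1, 2)), "insufficient")
  r <- test_visual_responsiveness(rep(5, 10), rep(5, 10))
  expect_false(r$responsive)
  expect_equal(r$p, 1)
  set.seed(1)
  r2 <- test_visual_responsiveness(rnorm(40, 10), rnorm(40, 14))
  expect_true(r2$responsive)
})

test_that("value selectivity and tuning classification on exact inputs", {
  v <- rep(c(0, 1, 2, 4, 8), each = 6)
  expect_false(test_value_selectivity(rep(3, 30), v)$selective)
  expect_error(test_value_selectivity(rnorm(24), rep(c(0, 1, 2, 4), 6)),
               "missing value level")
  up <- classify_tuning(2 + 0.5 * v, v)
  expect_equal(up$tuning, "positive")
  expect_equal(up$b1, 0.5)
  expect_equal(up$preferred_value, 8)
  dn <- classify_tuning(10 - 0.5 * v, v)
  expect_equal(dn$tuning, "negative")
  expect_equal(dn$preferred_value, 0)
})

test_that("the screening cascade recovers the ground-truth classes", {
  s <- power_session()
  scr <- screen_neurons(s)
  truth <- s$neurons$tuning[match(scr$neuron_id, s$neurons$neuron_id)]
  # value-tuned neurons classified with the right sign
  expect_true(all(scr$tuning[truth == "positive"] == "positive"))
  expect_true(all(scr$tuning[truth == "negative"] == "negative"))
  # value-blind neurons are excluded from the tuned groups
  expect_true(all(is.na(scr$tuning[truth %in% c("untuned", "nonvisual")])))
  expect_false(any(scr$value_selective[truth == "untuned"]))
  # population accounting: selective = positive + negative, and
  # selective neurons are a subset of the visually responsive ones
  expect_equal(sum(scr$value_selective, na.rm = TRUE),
               sum(scr$tuning == "positive", na.rm = TRUE) +
                 sum(scr$tuning == "negative", na.rm = TRUE))
  expect_true(all(scr$visually_responsive[
    !is.na(scr$value_selective) & scr$value_selective]))
})

test_that("selectivity power increases with value gain and trial count", {
  power_at <- function(gain, blocks, seed) {
    rg <- default_neuron_ranges()
    rg$value_gain <- gain
    cond <- enumerate_block_conditions(cue_set())
    f <- condition_features(cond)
    tr <- build_trial_schedule(cond, blocks, seed = seed)
    v <- f$v_single[match(tr$condition_id, f$condition_id)]
    tr <- tr[!is.na(v), ]; v <- v[!is.na(v)]
    hits <- vapply(1:60, function(i) {
      nr <- make_ground_truth_neurons(1L, 0L, 0L, 0L, ranges = rg,
                                      seed = seed + i)
      sp <- ofcattn:::with_seed(seed + 10000L + i,
        simulate_neuron_spikes(nr[1, ], tr, cond, t_range = c(-300, 700)))
      r <- windowed_rates(sp, tr, c(150, 550), nr$neuron_id[1])
      test_value_selectivity(r$rate[match(tr$trial_id, r$trial_id)],
                             v)$selective
    }, logical(1))
    mean(hits)
  }
  p_weak_small <- power_at(c(2, 3), 2L, 1000L)
  p_weak_large <- power_at(c(2, 3), 6L, 2000L)
  p_strong_small <- power_at(c(12, 15), 2L, 3000L)
  expect_gte(p_weak_large, p_weak_small)
  expect_gte(p_strong_small, p_weak_small)
})

test_that("screening is invariant to trial order", {
  s <- power_session()
  scr <- screen_neurons(s)
  s2 <- s
  set.seed(8)
  s2$trials <- s2$trials[sample(nrow(s2$trials)), ]
  s2$spikes <- s2$spikes[sample(nrow(s2$spikes)), ]
  scr2 <- screen_neurons(s2)
  scr2 <- scr2[match(scr$neuron_id, scr2$neuron_id), ]
  rownames(scr2) <- NULL
  expect_equal(scr2, scr)
})

test_that("normalization maps the preferred condition to one", {
  s <- power_session()
  scr <- screen_neurons(s)
  pos <- scr$neuron_id[!is.na(scr$tuning) & scr$tuning == "positive"][1]
  nr <- normalize_responses(s, pos, preferred_value = 8)
  f <- condition_features(s$conditions)
  pref <- f$condition_id[f$n_cues == 1 & !is.na(f$v_single) &
                           f$v_single == 8]
  rows <- nr[nr$condition_id %in% pref, ]
  expect_equal(sum(rows$normalized_mean * rows$n_trials) /
                 sum(rows$n_trials), 1)
  # a silent neuron has no cue response and cannot be normalized
  expect_error(normalize_responses(s, "ghost", preferred_value = 8),
               "degenerate normalization")
})

test_that("unperturbed double-cue responses follow the higher value only", {
  s <- power_session()
  scr <- screen_neurons(s)
  pos <- scr[!is.na(scr$tuning) & scr$tuning == "positive", ][1, ]
  nr <- normalize_responses(s, pos$neuron_id, pos$preferred_value,
                            window = c(150, 550))
  tn <- attr(nr, "trial_norm")
  f <- condition_features(s$conditions)
  tf <- f[match(tn$condition_id, f$condition_id), ]
  keep <- tf$perturbed_side == "none"
  df <- data.frame(resp = tn$rate_norm[keep], n_cues = tf$n_cues[keep],
                   v_high = tf$v_high[keep],
                   v_low = ifelse(tf$n_cues[keep] == 2, tf$v_low[keep], NA))
  out <- analyze_double_cue(df)
  expect_lt(out$p_high, 1e-6)
  expect_gt(out$p_low, 0.05)       # winner-take-all: lower value is null
  expect_gt(out$p_ncues_factor, 0.01)
  # the equal-weight averaging generator breaks winner-take-all coding
  nr_avg <- make_ground_truth_neurons(1L, 0L, 0L, 0L, seed = 31L)
  nr_avg$value_gain <- 20
  sa <- simulate_session(list(n_blocks = 9L, n_positive = 1L,
                              n_negative = 0L, n_untuned = 0L,
                              n_nonvisual = 0L, include_pupil = FALSE,
                              integration = "average"),
                         seed = 32L, neurons = nr_avg)
  na_ <- normalize_responses(sa, nr_avg$neuron_id[1], 8,
                             window = c(150, 550))
  tna <- attr(na_, "trial_norm")
  tfa <- f[match(tna$condition_id, f$condition_id), ]
  keep <- tfa$perturbed_side == "none"
  dfa <- data.frame(resp = tna$rate_norm[keep], n_cues = tfa$n_cues[keep],
                    v_high = tfa$v_high[keep],
                    v_low = ifelse(tfa$n_cues[keep] == 2,
                                   tfa$v_low[keep], NA))
  outa <- analyze_double_cue(dfa)
  expect_lt(outa$p_low, 0.01)      # both values now carry weight
})
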