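lower_pert_condition <- function(v_high = 2, v_low = 0) {
  f <- condition_features(enumerate_block_conditions(cue_set()))
  f[!is.na(f$perturbed_rank) & f$perturbed_rank == "lower" &
      f$v_high == v_high & f$v_low == v_low, ][1, ]
}

test_that("attention traces follow the winner-take-all rules", {
  cond <- condition_features(enumerate_block_conditions(cue_set()))
  single <- cond[cond$n_cues == 1 & cond$v_single == 4, ][1, ]
  tr <- draw_attention_trace(single, list(c = 2, d = 1.2))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$value, 4)
  # unperturbed double: higher value attended throughout
  d82 <- cond[cond$n_cues == 2 & cond$perturbed_side == "none" &
                cond$v_high == 8 & cond$v_low == 2, ][1, ]
  expect_equal(draw_attention_trace(d82, list(c = 2, d = 1.2))$value, 8)
  # perturbation on the higher-value cue never shifts
  hi <- cond[!is.na(cond$perturbed_rank) &
               cond$perturbed_rank == "higher", ][1, ]
  set.seed(1)
  expect_true(all(replicate(100,
    nrow(draw_attention_trace(hi, list(c = 0, d = 2)))) == 1L))
})

test_that("shift probability is the sigmoid of the value difference", {
  lp <- lower_pert_condition(2, 0)
  set.seed(2)
  # d = 0: never shifts
  expect_true(all(replicate(100,
    nrow(draw_attention_trace(lp, list(c = 5, d = 0)))) == 1L))
  # c = 0, d = 2: always shifts, at perturbation onset + latency
  tr <- draw_attention_trace(lp, list(c = 0, d = 2))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$t_start[2], 300)
  expect_equal(tr$value[2], 0)
  # c = 0, d = 1: shift fraction one half
  set.seed(3)
  frac <- mean(replicate(4000,
    nrow(draw_attention_trace(lp, list(c = 0, d = 1))) == 2L))
  expect_true(abs(frac - 0.5) < 0.03)
  # and the sigmoid shape across value pairs
  set.seed(4)
  for (pair in list(c(1, 0), c(4, 2), c(8, 0))) {
    cnd <- lower_pert_condition(pair[1], pair[2])
    f <- mean(replicate(1500,
      nrow(draw_attention_trace(cnd, list(c = 2, d = 1.2))) == 2L))
    a <- attention_weight((pair[1] - pair[2]) / 8, 2, 1.2)
    expect_true(abs(f - a) < 4 * sqrt(a * (1 - a) / 1500))
  }
})

test_that("spike trains are inhomogeneous Poisson with the programmed rate", {
  cond <- enumerate_block_conditions(cue_set())
  nr <- make_ground_truth_neurons(0L, 0L, 0L, 1L, seed = 1)  # baseline only
  nr$baseline_rate <- 10
  tr <- data.frame(trial_id = sprintf("t%04d", 1:3000), block_index = 1L,
                   condition_id = cond$condition_id[1], completed = TRUE)
  set.seed(10)
  sp <- simulate_neuron_spikes(nr[1, ], tr, cond, t_range = c(0, 1000))
  counts <- table(factor(sp$trial_id, levels = tr$trial_id))
  expect_true(abs(mean(counts) - 10) < 0.2)  # 3+ SEs of Poisson(10)
  # variance consistent with Poisson
  expect_true(abs(var(as.vector(counts)) / 10 - 1) < 0.15)
  # zero rate produces no spikes
  nr0 <- nr; nr0$baseline_rate <- 0
  expect_equal(nrow(simulate_neuron_spikes(nr0[1, ], tr[1:50, ], cond)), 0L)
  expect_error(simulate_spike_train(nr[1, ], cond[1, ],
                                    data.frame(t_start = 0, t_end = 1000,
                                               value = 0, side = "left"),
                                    t_range = c(100, 0)), "duration")
})

test_that("the empirical PSTH converges to the programmed rate profile", {
  cond <- enumerate_block_conditions(cue_set())
  f <- condition_features(cond)
  cid <- f$condition_id[f$n_cues == 1 & f$v_single == 8][1]
  nr <- make_ground_truth_neurons(1L, 0L, 0L, 0L, seed = 7)
  tr <- data.frame(trial_id = sprintf("t%04d", 1:3000), block_index = 1L,
                   condition_id = cid, completed = TRUE)
  set.seed(11)
  sp <- simulate_neuron_spikes(nr[1, ], tr, cond)
  bins <- seq(-150, 1000, by = 25)
  m <- psth_trial_matrix(sp, tr$trial_id, bins, window_ms = 50)
  att <- data.frame(t_start = 0, t_end = 1000, value = 8, side = "left")
  expected <- vapply(bins, function(b)
    mean(ofcattn:::neuron_rate_at(seq(b - 25, b + 25, by = 0.5),
                                  nr[1, ], att, FALSE)), numeric(1))
  expect_lt(max(abs(colMeans(m) - expected)), 2)  # spikes/s, sup-norm
})

test_that("pupil traces implement the value-scaled kernel exactly", {
  gt <- default_pupil_gt()
  gt$baseline_drift_sd <- 0; gt$response_sd <- 0; gt$sample_noise_sd <- 0
  cond <- condition_features(enumerate_block_conditions(cue_set()))
  tr <- build_trial_schedule(cond, 1L, seed = 2)
  make_pupil <- function(ids) do.call(rbind, lapply(ids, function(id) {
    cr <- cond[cond$condition_id == tr$condition_id[tr$trial_id == id], ]
    p <- simulate_pupil_trace(cr, gt)
    p$trial_id <- id
    p
  }))
  s8 <- tr$trial_id[tr$condition_id %in%
                      cond$condition_id[cond$n_cues == 1 &
                                          cond$v_single == 8]][1]
  s0 <- tr$trial_id[tr$condition_id %in%
                      cond$condition_id[cond$n_cues == 1 &
                                          cond$v_single == 0]][1]
  d82 <- tr$trial_id[tr$condition_id %in%
                       cond$condition_id[cond$n_cues == 2 &
                                           cond$perturbed_side == "none" &
                                           cond$v_high == 8 &
                                           cond$v_low == 2]][1]
  pupil <- make_pupil(c(s8, s0, d82))
  resp <- extract_pupil_responses(pupil, tr[tr$trial_id %in%
                                              c(s8, s0, d82), ])
  r <- setNames(resp$response, resp$trial_id)
  # single cue: response is exactly value x amplitude-per-drop
  expect_equal(unname(r[s8]), 8 * gt$amp_per_drop)
  expect_equal(unname(r[s0]), 0)
  # winner-take-all: double 8 vs 2 is indistinguishable from single 8
  expect_equal(unname(r[d82]), unname(r[s8]))
})

test_that("sessions are reproducible and validate their configuration", {
  s <- tiny_session()
  expect_equal(sum(s$trials$completed), 170L)
  expect_equal(max(s$trials$block_index), 2L)
  # identical seed, byte-identical file bundle
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(make_fixture("tiny"), d1)
  write_session(make_fixture("tiny"), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # round trip preserves ground truth and spikes
  back <- read_session(d1)
  expect_equal(back$neurons$att_d, s$neurons$att_d)
  expect_equal(nrow(back$spikes), nrow(s$spikes))
  expect_error(simulate_session(list(n_bogus = 3)), "n_bogus")
  expect_error(simulate_session(list(p_incomplete = 2)), "p_incomplete")
})
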