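test_that("BH rejection equals the brute-force step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(benjamini_hochberg(rep(0.001, 10))))
  expect_equal(benjamini_hochberg(numeric(0)), logical(0))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:300) {
    m <- sample(1:60, 1)
    p <- if (runif(1) < 0.5) runif(m) else runif(m)^3  # mix of regimes
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(benjamini_hochberg(p, q), bh_oracle(p, q))
  }
})

test_that("sliding-window rate matrices count spikes correctly", {
  sp <- data.frame(neuron_id = "n1", trial_id = "t1", t_ms = 500)
  bins <- seq(-200, 1000, by = 10)
  m <- psth_trial_matrix(sp, "t1", bins, window_ms = 50)
  hit <- bins > 475 & bins <= 525  # windows [c-25, c+25) containing 500
  expect_true(all(m[1, hit] == 20))
  expect_true(all(m[1, !hit] == 0))
  # non-overlapping bins conserve the total spike count
  set.seed(1)
  sp2 <- data.frame(neuron_id = "n1", trial_id = "t1",
                    t_ms = runif(200, 0, 1000))
  bins50 <- seq(25, 975, by = 50)
  m2 <- psth_trial_matrix(sp2, "t1", bins50, window_ms = 50)
  expect_equal(sum(m2) * 0.05, 200)
})

test_that("pointwise rotation tests are symmetric and flag degeneracy", {
  set.seed(2)
  mh <- matrix(rpois(200, 5), nrow = 20)
  ml <- matrix(rpois(200, 5), nrow = 20)
  p1 <- pointwise_rotation_test(mh, ml)
  p2 <- pointwise_rotation_test(ml, mh)
  expect_equal(unname(p1), unname(p2))
  z <- matrix(3, nrow = 5, ncol = 2)
  pz <- pointwise_rotation_test(z, z)
  expect_equal(unname(as.vector(pz)), c(1, 1))
  expect_true(all(attr(pz, "degenerate")))
})

test_that("modulation windows require 200 ms of contiguous significance", {
  bins <- seq(200, 1000, by = 10)
  p <- rep(0.5, length(bins))
  p[bins >= 400 & bins < 650] <- 0.01            # one 250 ms run
  w <- find_modulation_window(p, bins)
  expect_equal(unname(w), c(400, 650))
  p2 <- rep(0.5, length(bins)); p2[bins >= 400 & bins < 550] <- 0.01
  expect_null(find_modulation_window(p2, bins))  # 150 ms only
  p3 <- rep(0.5, length(bins))
  p3[bins >= 250 & bins < 550] <- 0.01           # 300 ms
  p3[bins >= 700 & bins < 920] <- 0.01           # 220 ms
  expect_equal(unname(find_modulation_window(p3, bins)), c(250, 550))
  # significance outside the rotation-to-offset period is ignored
  bins_full <- seq(-200, 1000, by = 10)
  p4 <- rep(0.01, length(bins_full))
  p4[bins_full >= 200] <- 0.5
  expect_null(find_modulation_window(p4, bins_full))
})

test_that("modulation index and Z-scores behave as defined", {
  expect_equal(modulation_index(1, 1), 0)
  expect_equal(modulation_index(3, 1), 0.5)
  expect_equal(modulation_index(1, 3), -0.5)
  expect_error(modulation_index(0, 0), "undefined MI")
  z <- zscore_modulation(c(4, 6), c(4, 6))
  expect_equal(z$z_high, z$z_low)
  set.seed(3)
  a <- rnorm(30, 10); b <- rnorm(30, 12)
  z1 <- zscore_modulation(a, b)
  z2 <- zscore_modulation(a + 5, b + 5)
  expect_equal(z1$z_high, z2$z_high)
  expect_equal(z1$z_low, z2$z_low)
  expect_error(zscore_modulation(rep(1, 5), rep(1, 5)), "zero pooled SD")
})

test_that("consistency compares perturbed responses to the single-cue level", {
  expect_equal(classify_consistency(r_pert = 0.3, r_unpert = 1,
                                    r_single = 0.3), "consistent")
  expect_equal(classify_consistency(r_pert = 1.4, r_unpert = 1,
                                    r_single = 0.3), "inconsistent")
})

test_that("the first-trials control balances perturbation counts", {
  s <- tiny_session()
  sub <- first_block_control(s$trials, s$conditions, n_first = 50,
                             seed = 5)
  expect_true(all(table(sub$block_index) <= 50))
  # within every cue combination the two perturbed variants are even
  f <- condition_features(s$conditions)
  tf <- f[match(sub$condition_id, f$condition_id), ]
  pairs <- paste(tf$left_cue_id, tf$right_cue_id)
  for (pr in unique(pairs[tf$n_cues == 2])) {
    nl <- sum(pairs == pr & tf$perturbed_side == "left")
    nr_ <- sum(pairs == pr & tf$perturbed_side == "right")
    expect_equal(nl, nr_)
  }
  expect_identical(sub$trial_id,
                   first_block_control(s$trials, s$conditions, 50,
                                       seed = 5)$trial_id)
  # blocks shorter than the cutoff pass through before balancing
  sub85 <- first_block_control(s$trials, s$conditions, n_first = 85,
                               seed = 5)
  expect_true(all(table(s$trials$block_index[s$trials$completed]) ==
                    85))
  expect_true(nrow(sub85) <= sum(s$trials$completed))
})

test_that("strong attention shifts are detected, scored and classified", {
  s <- strong_mod_session()
  scr <- screen_neurons(s)
  expect_true(all(scr$value_selective))
  mod <- analyze_perturbation(s, scr)
  truth <- s$neurons$tuning[match(mod$neuron_id, s$neurons$neuron_id)]
  expect_true(all(mod$modulated))
  expect_true(all(mod$window_start_ms >= 200 & mod$window_end_ms <= 1000))
  expect_true(all(mod$window_end_ms - mod$window_start_ms >= 200))
  # the sign of the modulation follows the tuning
  expect_true(all(mod$z_high[truth == "positive"] >
                    mod$z_low[truth == "positive"]))
  expect_true(all(mod$mi[truth == "positive"] > 0))
  expect_true(all(mod$mi[truth == "negative"] < 0))
  expect_true(all(mod$mi >= -1 & mod$mi <= 1))
  expect_true(all(mod$consistency == "consistent"))
  # population contrast within the positively tuned group: higher vs
  # lower rotation differs, higher vs no perturbation does not
  pos <- scr$neuron_id[scr$tuning == "positive"]
  rc <- compare_rotation_conditions(s, scr, neuron_ids = pos)
  expect_lt(rc$p_higher_lower, 0.05)
  expect_gt(rc$p_higher_none, 0.05)
})

test_that("the modulation index grows with the shift ceiling d", {
  cond <- enumerate_block_conditions(cue_set())
  tr <- build_trial_schedule(cond, 4L, seed = 14)
  grp <- ofcattn:::rotation_groups(tr, cond)
  set.seed(15)
  mi_of <- function(d, seed) {
    nr <- make_ground_truth_neurons(1L, 0L, 0L, 0L, seed = seed)
    nr$att_c <- 1; nr$att_d <- d; nr$value_gain <- 25
    sp <- simulate_neuron_spikes(nr[1, ], tr, cond)
    frh <- mean(ofcattn:::apply_window_rates(sp, grp$higher, c(200, 1000)))
    frl <- mean(ofcattn:::apply_window_rates(sp, grp$lower, c(200, 1000)))
    modulation_index(frh, frl)
  }
  ds <- rep(c(0.2, 0.8, 1.4, 2), each = 3)
  mi <- mapply(mi_of, ds, seed = 500 + seq_along(ds))
  expect_gt(cor(ds, mi, method = "spearman"), 0)
  # and the sign flips for negatively tuned neurons
  nr <- make_ground_truth_neurons(0L, 1L, 0L, 0L, seed = 600)
  nr$att_c <- 0; nr$att_d <- 2; nr$value_gain <- 25
  nr$visual_gain <- 25
  sp <- simulate_neuron_spikes(nr[1, ], tr, cond)
  frh <- mean(ofcattn:::apply_window_rates(sp, grp$higher, c(200, 1000)))
  frl <- mean(ofcattn:::apply_window_rates(sp, grp$lower, c(200, 1000)))
  expect_lt(modulation_index(frh, frl), 0)
})

test_that("modulation-window detection stays calibrated under the null", {
  s <- power_session()
  id <- s$neurons$neuron_id[s$neurons$tuning == "positive"][1]
  sp <- s$spikes[s$spikes$neuron_id == id, ]
  f <- condition_features(s$conditions)
  tf <- f[match(s$trials$condition_id, f$condition_id), ]
  pool <- s$trials$trial_id[tf$n_cues == 2 & tf$perturbed_side == "none"]
  bins <- seq(-200, 1000, by = 10)
  set.seed(12)
  hits <- replicate(50, {
    g <- sample(pool)
    h <- g[seq_len(length(g) / 2)]
    l <- setdiff(g, h)
    p <- pointwise_rotation_test(psth_trial_matrix(sp, h, bins),
                                 psth_trial_matrix(sp, l, bins))
    !is.null(find_modulation_window(p, bins))
  })
  expect_lte(mean(hits), 0.2)  # anticonservative rule, bounded FPR
})
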