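# Shared fixtures, built once per test run and cached.

.session_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .session_cache, inherits = FALSE))
    assign(name, expr, envir = .session_cache)
  get(name, envir = .session_cache, inherits = FALSE)
}

# the deterministic miniature session from the pipeline module
tiny_session <- function() cached("tiny", make_fixture("tiny"))

# a 9-block session with enough trials per condition to classify tuning
power_session <- function() cached("power", simulate_session(
  list(n_blocks = 9L, n_positive = 4L, n_negative = 2L, n_untuned = 1L,
       n_nonvisual = 1L, include_pupil = FALSE), seed = 4242L))

# strongly modulated neurons: every lower-cue perturbation shifts
# attention (c = 0, d = 2) and the value drive is large, so per-neuron
# window detection operates well above threshold
strong_mod_session <- function() cached("strongmod", {
  nr <- make_ground_truth_neurons(4L, 2L, 0L, 0L, seed = 99L)
  nr$att_c <- 0
  nr$att_d <- 2
  nr$att_b <- 0
  nr$value_gain <- 40
  nr$visual_gain[nr$tuning == "positive"] <- 2
  nr$visual_gain[nr$tuning == "negative"] <- 40
  nr$baseline_rate[nr$tuning == "positive"] <- 10
  nr$baseline_rate[nr$tuning == "negative"] <- 15
  simulate_session(list(n_blocks = 9L, n_positive = 4L, n_negative = 2L,
                        n_untuned = 0L, n_nonvisual = 0L,
                        include_pupil = FALSE), seed = 77L, neurons = nr)
})

# exact condition means generated from the full normalization model on
# the standard value grid, optionally with Gaussian observation noise
make_cm <- function(b, c, d, noise_sd = 0, seed = 1) {
  vals <- c(0, 1, 2, 4, 8)
  g <- expand.grid(h = vals, l = vals)
  g <- g[g$h >= g$l, ]
  resp <- function(v) 0.15 + 0.85 * v / 8
  cm <- data.frame(condition_id = paste0("p", seq_len(nrow(g))),
                   v_high = g$h, v_low = g$l,
                   Rh = resp(g$h), Rl = resp(g$l), R_obs = NA_real_,
                   n_trials = 4L, pert = "lower", stringsAsFactors = FALSE)
  cm$R_obs <- predict_full(cm$Rh, cm$Rl, b, c, d, cm$pert)
  if (noise_sd > 0)
    cm$R_obs <- cm$R_obs + ofcattn:::with_seed(seed,
                                               rnorm(nrow(cm), 0, noise_sd))
  cm
}

# independent brute-force step-up implementation of the BH procedure
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  if (length(k) == 0L) return(rep(FALSE, m))
  p <= ps[max(k)]
}

# dense grid-search oracle for the full-model least squares; b is
# profiled on its own grid so the search is an honest 3-D grid
grid_search_full <- function(cm, n_grid = 50L, b_bounds = c(-2, 2)) {
  dat <- cm[cm$pert == "lower", ]
  cs <- seq(0, 100, length.out = n_grid)
  ds <- seq(0, 2, length.out = n_grid)
  bs <- seq(b_bounds[1], b_bounds[2], length.out = n_grid)
  best <- Inf
  x <- abs(dat$Rh - dat$Rl)
  for (ci in cs) {
    w <- 1 / (1 + exp(ci * x))
    for (di in ds) {
      res0 <- dat$R_obs - ((1 - di * w) * dat$Rh + di * w * dat$Rl)
      s1 <- sum(res0); s2 <- sum(res0^2); n <- length(res0)
      rss_b <- s2 - 2 * bs * s1 + n * bs^2
      m <- min(rss_b)
      if (m < best) best <- m
    }
  }
  best
}
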