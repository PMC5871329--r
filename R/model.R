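#' Full normalization-model prediction
#'
#' The response to a perturbed double-cue condition is a weighted average
#' of the single-cue responses plus an offset,
#' `R = (1 - a) * Rh + a * Rl + b`.  When the lower-value cue is
#' perturbed, the weight shifted to it is a sigmoid of the response
#' difference, `a = d / (1 + exp(c * |Rh - Rl|))`; when the higher-value
#' (already attended) cue is perturbed the weight stays at `a = 0`.
#'
#' @param Rh,Rl Normalized single-cue responses of the higher- and the
#'   lower-value cue of each pair.
#' @param b Offset (normalized units).
#' @param c Sigmoid steepness, `0 <= c <= 100`.
#' @param d Sigmoid ceiling scale, `0 <= d <= 2`.
#' @param pert "lower" (default; includes equal-value pairs) or "higher".
#' @return Predicted normalized responses.
#' @export
predict_full <- function(Rh, Rl, b, c, d, pert = "lower") {
  a <- ifelse(pert == "higher", 0, attention_weight(Rh - Rl, c, d))
  (1 - a) * Rh + a * Rl + b
}

#' Reduced-model predictions (constant weight)
#'
#' Both reduced models use a weight that does not depend on the value
#' difference: `R = (1 - a) * Rh + a * Rl + b`.  In Model 1 the weight
#' `a` is shared by all neurons of a tuning group (each keeping its own
#' offset `b`); in Model 2 each neuron has its own `a`.  The prediction
#' equation is identical, so both are served by one function.
#'
#' @param Rh,Rl Normalized single-cue responses.
#' @param a Attention weight, `0 <= a <= 1`.
#' @param b Offset.
#' @return Predicted normalized responses.
#' @export
predict_constant <- function(Rh, Rl, a, b) {
  if (any(a < 0 | a > 1)) stop("parameter out of bounds: a")
  (1 - a) * Rh + a * Rl + b
}

#' @rdname predict_constant
#' @export
predict_model1 <- predict_constant

#' @rdname predict_constant
#' @export
predict_model2 <- predict_constant

#' Stratified split-half partition of trials
#'
#' Completed trials are split into two halves within every condition, so
#' each condition contributes to both the training and the test half.  A
#' condition with a single trial goes to the training half (with a
#' warning).
#'
#' @param trials Trial schedule.
#' @param seed Optional seed; the partition is reproducible.
#' @return Data.frame with `trial_id` and `split` ("train"/"test").
#' @export
split_half <- function(trials, seed = NULL) {
  tr <- trials[trials$completed, ]
  with_seed(seed, {
    parts <- lapply(split(tr$trial_id, tr$condition_id), function(ids) {
      n <- length(ids)
      if (n == 1L) {
        warning("condition with a single trial assigned to train")
        return(data.frame(trial_id = ids, split = "train",
                          stringsAsFactors = FALSE))
      }
      test <- sample(ids, floor(n / 2))
      data.frame(trial_id = ids,
                 split = ifelse(ids %in% test, "test", "train"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Per-pair condition means for model fitting
#'
#' For one neuron and one trial subset (typically a split half): the
#' normalized single-cue responses `Rh`, `Rl` of every double-cue pair
#' and the observed normalized mean `R_obs` of each perturbed double-cue
#' condition, computed in the 200-1000 ms window after cue onset.
#' Conditions with the lower-value (or equal-value) cue perturbed enter
#' the least-squares objective; higher-perturbed conditions are predicted
#' with a = 0.
#'
#' @param session An `ofc_session`.
#' @param neuron_id Neuron.
#' @param preferred_value Preferred single-cue value from screening.
#' @param trial_ids Trial subset (e.g. one split half); default all.
#' @param window Response window, ms.
#' @return Data.frame with `condition_id`, `v_high`, `v_low`, `Rh`, `Rl`,
#'   `R_obs`, `n_trials`, `pert` ("lower"/"higher"; equal-value pairs are
#'   labelled "lower").
#' @export
condition_means <- function(session, neuron_id, preferred_value,
                            trial_ids = NULL, window = c(200, 1000)) {
  nr <- normalize_responses(session, neuron_id, preferred_value,
                            window = window, trial_ids = trial_ids)
  feats <- condition_features(session$conditions)
  nm <- merge(nr, feats, by = "condition_id")
  singles <- nm[nm$n_cues == 1, ]
  s_by_v <- tapply(singles$normalized_mean, singles$v_single, mean)
  pert <- nm[nm$perturbed_side != "none", ]
  if (nrow(pert) == 0L) stop("no perturbed conditions in this subset")
  out <- data.frame(
    condition_id = pert$condition_id,
    v_high = pert$v_high, v_low = pert$v_low,
    Rh = as.vector(s_by_v[as.character(pert$v_high)]),
    Rl = as.vector(s_by_v[as.character(pert$v_low)]),
    R_obs = pert$normalized_mean, n_trials = pert$n_trials,
    pert = ifelse(pert$perturbed_rank == "higher", "higher", "lower"),
    stringsAsFactors = FALSE)
  out[stats::complete.cases(out), ]
}

#' Fit the full normalization model to one neuron
#'
#' Bounded least squares over the lower-perturbed condition means, with
#' multi-start local optimization (Latin-hypercube starting points over
#' the parameter box) because the sigmoid makes the objective non-convex
#' in `c`.
#'
#' @param cm Condition means from [condition_means()].
#' @param n_starts Number of Latin-hypercube starts.
#' @param b_bounds Bounds for the offset.
#' @param include_higher Also include higher-perturbed conditions (with
#'   a = 0) in the objective.
#' @param seed Optional seed for the starting points.
#' @return List with `b`, `c`, `d`, `rss`, `n`, and `identifiable`
#'   (FALSE when all pairs share one `|Rh - Rl|`, leaving `c` free).
#' @export
fit_full <- function(cm, n_starts = 16L, b_bounds = c(-2, 2),
                     include_higher = FALSE, seed = NULL) {
  fitrows <- cm[cm$pert == "lower", ]
  if (!include_higher) dat <- fitrows else dat <- cm
  if (nrow(fitrows) < 4L)
    stop("insufficient data: need >= 4 lower-perturbed conditions")
  identifiable <- length(unique(round(abs(fitrows$Rh - fitrows$Rl), 10))) > 1L
  lower <- c(b_bounds[1], 0, 0)
  upper <- c(b_bounds[2], 100, 2)
  obj <- function(par) {
    # finite-difference gradient probes can poke just outside the box
    par <- pmin(pmax(par, lower), upper)
    sum((dat$R_obs - predict_full(dat$Rh, dat$Rl, par[1], par[2], par[3],
                                  dat$pert))^2)
  }
  starts <- with_seed(seed, lhs::randomLHS(n_starts, 3))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  starts <- rbind(starts, c(0, 2, 1))  # deterministic mid-range start
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e4, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(b = best$par[1], c = best$par[2], d = best$par[3],
       rss = best$value, n = nrow(dat), identifiable = identifiable)
}

#' Fit Model 2 (per-neuron constant weight)
#'
#' Least squares in `(a, b)` over the lower-perturbed condition means;
#' `b` is profiled out in closed form and `a` found by 1-D bounded
#' search.
#'
#' @param cm Condition means from [condition_means()].
#' @return List with `a`, `b`, `rss`, `n`.
#' @export
fit_model2 <- function(cm) {
  dat <- cm[cm$pert == "lower", ]
  if (nrow(dat) < 2L) stop("insufficient data")
  prof <- function(a) {
    res <- dat$R_obs - ((1 - a) * dat$Rh + a * dat$Rl)
    sum((res - mean(res))^2)
  }
  op <- stats::optimize(prof, c(0, 1), tol = 1e-10)
  a <- op$minimum
  # guard the interval endpoints, where optimize() does not look
  for (ae in c(0, 1)) if (prof(ae) < prof(a)) a <- ae
  b <- mean(dat$R_obs - ((1 - a) * dat$Rh + a * dat$Rl))
  list(a = a, b = b, rss = prof(a), n = nrow(dat))
}

#' Fit Model 1 (group-shared weight, per-neuron offset)
#'
#' The shared weight `a` is found by 1-D bounded search on the profiled
#' objective: given `a`, each neuron's offset has the closed form
#' `b = mean(R_obs - (1 - a) Rh - a Rl)`.
#'
#' @param cm_list Named list of [condition_means()] tables, one per
#'   neuron of a tuning group.
#' @return List with `a`, named vector `b`, `rss` (total), `n` (total).
#' @export
fit_model1 <- function(cm_list) {
  dats <- lapply(cm_list, function(cm) cm[cm$pert == "lower", ])
  prof1 <- function(a, dat) {
    res <- dat$R_obs - ((1 - a) * dat$Rh + a * dat$Rl)
    sum((res - mean(res))^2)
  }
  prof <- function(a) sum(vapply(dats, prof1, numeric(1), a = a))
  op <- stats::optimize(prof, c(0, 1), tol = 1e-10)
  a <- op$minimum
  for (ae in c(0, 1)) if (prof(ae) < prof(a)) a <- ae
  b <- vapply(dats, function(dat)
    mean(dat$R_obs - ((1 - a) * dat$Rh + a * dat$Rl)), numeric(1))
  list(a = a, b = b, rss = prof(a),
       n = sum(vapply(dats, nrow, integer(1))))
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = n ln(RSS / n) + 2k + 2k(k + 1) / (n - k - 1)` (least-squares
#' form, constant terms dropped).  Undefined (NA) when `n <= k + 1`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of parameters (may be fractional when a shared
#'   parameter is amortized over a group).
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Evaluate predictions on a test half
#'
#' Cross-validated goodness of fit over the test condition means:
#' residual sum of squares, `R^2 = 1 - RSS / TSS` with TSS about the test
#' mean (may be negative for a bad model), and AICc.
#'
#' @param observed Observed test-half condition means.
#' @param predicted Model predictions for the same conditions.
#' @param k Parameter count attributed to the neuron.
#' @return List with `rss`, `r2`, `aicc`, `n`.
#' @export
evaluate_fit <- function(observed, predicted, k) {
  if (length(observed) == 0L) stop("empty test set")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  list(rss = rss, r2 = 1 - rss / tss, aicc = aicc(rss, length(observed), k),
       n = length(observed))
}

#' Split-half fitting and evaluation of all three models
#'
#' For each selected neuron the completed trials are split in half
#' (stratified by condition); the full model and Model 2 are fitted to
#' the training-half condition means, Model 1 jointly per tuning group;
#' all three are evaluated on the test half.  Prediction inputs `Rh`,
#' `Rl` are taken from the training half.  Model 1's parameter count per
#' neuron is `1 + 1/G` (its own offset plus an equal share of the group
#' weight, G = group size).
#'
#' @param session An `ofc_session`.
#' @param screening Output of [screen_neurons()].
#' @param neuron_ids Neurons to fit (default: all tuned neurons).
#' @param seed Seed for the split (per-neuron seeds are derived from it).
#' @param window Response window, ms.
#' @param n_starts Multi-starts for the full-model fit.
#' @return Data.frame `model_fits` with one row per neuron x model:
#'   parameters, train RSS, test RSS/R^2/AICc, split seed.
#' @export
fit_attention_models <- function(session, screening, neuron_ids = NULL,
                                 seed = 1L, window = c(200, 1000),
                                 n_starts = 16L) {
  sel <- screening[!is.na(screening$tuning), ]
  if (!is.null(neuron_ids)) sel <- sel[sel$neuron_id %in% neuron_ids, ]
  if (nrow(sel) == 0L) stop("no tuned neurons to fit")
  cm_train <- list(); cm_test <- list(); split_seeds <- integer(nrow(sel))
  for (k in seq_len(nrow(sel))) {
    id <- sel$neuron_id[k]
    split_seeds[k] <- (seed + 7L * k) %% .Machine$integer.max
    sp <- split_half(session$trials, seed = split_seeds[k])
    cm_train[[id]] <- condition_means(
      session, id, sel$preferred_value[k],
      trial_ids = sp$trial_id[sp$split == "train"], window = window)
    cm_test[[id]] <- condition_means(
      session, id, sel$preferred_value[k],
      trial_ids = sp$trial_id[sp$split == "test"], window = window)
  }
  rows <- list()
  for (grp in unique(sel$tuning)) {
    ids <- sel$neuron_id[sel$tuning == grp]
    m1 <- fit_model1(cm_train[ids])
    G <- length(ids)
    for (k in seq_along(ids)) {
      id <- ids[k]
      tr <- cm_train[[id]]
      te <- cm_test[[id]]
      # evaluation is on the attention-shift (lower-perturbed) conditions,
      # the set all three models are defined on; predictions use
      # training-half Rh/Rl for the test conditions
      te <- te[te$pert == "lower", ]
      te_in <- tr[match(te$condition_id, tr$condition_id), ]
      ok <- !is.na(te_in$Rh)
      te <- te[ok, ]; te_in <- te_in[ok, ]
      ff <- fit_full(tr, n_starts = n_starts,
                     seed = (split_seeds[match(id, sel$neuron_id)] + 1L))
      f2 <- fit_model2(tr)
      preds <- list(
        full = predict_full(te_in$Rh, te_in$Rl, ff$b, ff$c, ff$d, te$pert),
        model2 = predict_constant(te_in$Rh, te_in$Rl, f2$a, f2$b),
        model1 = predict_constant(te_in$Rh, te_in$Rl, m1$a, m1$b[[id]]))
      ks <- c(full = 3, model2 = 2, model1 = 1 + 1 / G)
      pars <- list(full = c(b = ff$b, c = ff$c, d = ff$d, a = NA),
                   model2 = c(b = f2$b, c = NA, d = NA, a = f2$a),
                   model1 = c(b = m1$b[[id]], c = NA, d = NA, a = m1$a))
      for (mn in names(preds)) {
        ev <- evaluate_fit(te$R_obs, preds[[mn]], ks[[mn]])
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = id, tuning = grp, model = mn,
          b = pars[[mn]]["b"], c = pars[[mn]]["c"], d = pars[[mn]]["d"],
          a = pars[[mn]]["a"], k = ks[[mn]],
          train_rss = switch(mn, full = ff$rss, model2 = f2$rss,
                             model1 = NA_real_),
          test_rss = ev$rss, test_r2 = ev$r2, test_aicc = ev$aicc,
          test_n = ev$n,
          split_seed = split_seeds[match(id, sel$neuron_id)],
          identifiable = if (mn == "full") ff$identifiable else NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the three models across neurons
#'
#' Per-neuron AICc winner counts and group-level paired two-tailed
#' t-tests of the full model's test AICc and R^2 against each reduced
#' model.
#'
#' @param fits Output of [fit_attention_models()].
#' @return List with `winner_counts`, the per-neuron delta table, and the
#'   paired-test p-values.
#' @export
compare_models <- function(fits) {
  wide <- function(col) {
    x <- stats::reshape(fits[, c("neuron_id", "model", col)],
                        idvar = "neuron_id", timevar = "model",
                        direction = "wide")
    names(x) <- sub(paste0(col, "."), "", names(x), fixed = TRUE)
    x
  }
  sseed <- fits$split_seed[match(unique(fits$neuron_id), fits$neuron_id)]
  if (length(unique(table(fits$neuron_id))) != 1L)
    stop("mismatched splits: every neuron needs all models")
  ac <- wide("test_aicc")
  r2 <- wide("test_r2")
  winner <- apply(ac[, c("full", "model1", "model2")], 1,
                  function(x) c("full", "model1", "model2")[which.min(x)])
  pt <- function(x, y) if (length(x) > 1L && stats::sd(x - y) > 0)
    stats::t.test(x, y, paired = TRUE)$p.value else NA_real_
  list(
    winner_counts = table(factor(winner,
                                 levels = c("full", "model1", "model2"))),
    deltas = data.frame(
      neuron_id = ac$neuron_id,
      d_aicc_full_m1 = ac$full - ac$model1,
      d_aicc_full_m2 = ac$full - ac$model2,
      d_r2_full_m1 = r2$full - r2$model1,
      d_r2_full_m2 = r2$full - r2$model2,
      split_seed = sseed),
    p_aicc_full_vs_m1 = pt(ac$full, ac$model1),
    p_aicc_full_vs_m2 = pt(ac$full, ac$model2),
    p_r2_full_vs_m1 = pt(r2$full, r2$model1),
    p_r2_full_vs_m2 = pt(r2$full, r2$model2),
    mean_r2_full = mean(r2$full))
}
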