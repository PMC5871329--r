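#' Define a cue set
#'
#' A cue set maps symbolic cue identities to reward magnitudes (drops of
#' juice).  The standard task uses five cues worth 0, 1, 2, 4 and 8 drops.
#'
#' @param values Integer vector of reward sizes in drops, one per cue.
#' @param cue_ids Character vector of unique cue labels.
#' @return A data.frame with columns `cue_id` and `value`.
#' @examples
#' cue_set()
#' @export
cue_set <- function(values = c(0L, 1L, 2L, 4L, 8L),
                    cue_ids = paste0("c", values)) {
  if (length(values) == 0L) stop("invalid cue set: empty")
  if (length(values) != length(cue_ids))
    stop("invalid cue set: values and cue_ids differ in length")
  if (anyDuplicated(cue_ids)) stop("invalid cue set: duplicate cue_id")
  if (any(values < 0)) stop("invalid cue set: negative value")
  data.frame(cue_id = as.character(cue_ids), value = as.integer(values),
             stringsAsFactors = FALSE)
}

#' Condition identifier
#'
#' The condition id is a pure function of the cue assignment and the
#' perturbed side, so it round-trips through serialization.
#'
#' @param left_cue_id,right_cue_id Cue labels ("-" substituted when absent).
#' @param perturbed_side One of "none", "left", "right".
#' @return Character vector of condition ids.
#' @export
condition_id <- function(left_cue_id, right_cue_id, perturbed_side) {
  l <- ifelse(is.na(left_cue_id), "-", left_cue_id)
  r <- ifelse(is.na(right_cue_id), "-", right_cue_id)
  p <- c(none = "n", left = "l", right = "r")[as.character(perturbed_side)]
  if (anyNA(p)) stop("perturbed_side must be none, left or right")
  paste0(l, ".", r, ".", p)
}

#' Enumerate the conditions of one block
#'
#' A block contains every single-cue condition (each cue on either side),
#' every ordered double-cue condition (left cue x right cue, identical
#' pairs included once per ordering), and both perturbed variants of every
#' double-cue condition.  For n cues this yields 2n + n^2 + 2n^2
#' conditions; the standard 5-cue set gives 85 (10 single, 25 double,
#' 50 perturbed).
#'
#' @param cues A cue set as returned by [cue_set()].
#' @return A data.frame of conditions with columns `condition_id`,
#'   `left_cue_id`, `left_value`, `right_cue_id`, `right_value`,
#'   `perturbed_side`, in a deterministic order.
#' @examples
#' nrow(enumerate_block_conditions(cue_set()))  # 85
#' @export
enumerate_block_conditions <- function(cues) {
  if (!is.data.frame(cues) || !all(c("cue_id", "value") %in% names(cues)))
    stop("invalid cue set: need a data.frame with cue_id and value")
  if (nrow(cues) == 0L) stop("invalid cue set: empty")
  if (anyDuplicated(cues$cue_id)) stop("invalid cue set: duplicate cue_id")
  n <- nrow(cues)
  na_c <- rep(NA_character_, n)
  na_i <- rep(NA_integer_, n)
  single_left <- data.frame(
    left_cue_id = cues$cue_id, left_value = cues$value,
    right_cue_id = na_c, right_value = na_i,
    perturbed_side = "none", stringsAsFactors = FALSE)
  single_right <- data.frame(
    left_cue_id = na_c, left_value = na_i,
    right_cue_id = cues$cue_id, right_value = cues$value,
    perturbed_side = "none", stringsAsFactors = FALSE)
  g <- expand.grid(li = seq_len(n), ri = seq_len(n))
  doubles <- data.frame(
    left_cue_id = cues$cue_id[g$li], left_value = cues$value[g$li],
    right_cue_id = cues$cue_id[g$ri], right_value = cues$value[g$ri],
    perturbed_side = "none", stringsAsFactors = FALSE)
  pert_l <- doubles; pert_l$perturbed_side <- "left"
  pert_r <- doubles; pert_r$perturbed_side <- "right"
  out <- rbind(single_left, single_right, doubles, pert_l, pert_r)
  out$condition_id <- condition_id(out$left_cue_id, out$right_cue_id,
                                   out$perturbed_side)
  if (anyDuplicated(out$condition_id))
    stop("internal error: duplicate condition_id")
  rownames(out) <- NULL
  out[, c("condition_id", "left_cue_id", "left_value",
          "right_cue_id", "right_value", "perturbed_side")]
}

#' Derived per-condition features
#'
#' Adds the columns used throughout the analyses: `n_cues`, the higher and
#' lower value (`v_high`, `v_low`), the single-cue value `v_single`, and
#' `perturbed_rank` ("higher", "lower", "equal" or NA) telling whether the
#' perturbation hit the higher- or lower-valued cue of the pair.
#'
#' @param conditions A condition table from [enumerate_block_conditions()].
#' @return The same data.frame with the derived columns appended.
#' @export
condition_features <- function(conditions) {
  lv <- conditions$left_value
  rv <- conditions$right_value
  n_cues <- (!is.na(lv)) + (!is.na(rv))
  v_high <- pmax(lv, rv, na.rm = TRUE)
  v_low <- pmin(lv, rv, na.rm = TRUE)
  v_single <- ifelse(n_cues == 1L, v_high, NA_integer_)
  pv <- ifelse(conditions$perturbed_side == "left", lv,
               ifelse(conditions$perturbed_side == "right", rv, NA))
  ov <- ifelse(conditions$perturbed_side == "left", rv,
               ifelse(conditions$perturbed_side == "right", lv, NA))
  perturbed_rank <- ifelse(is.na(pv), NA_character_,
                    ifelse(pv > ov, "higher",
                    ifelse(pv < ov, "lower", "equal")))
  cbind(conditions,
        data.frame(n_cues = as.integer(n_cues),
                   v_high = as.integer(v_high), v_low = as.integer(v_low),
                   v_single = as.integer(v_single),
                   perturbed_rank = perturbed_rank,
                   stringsAsFactors = FALSE))
}

#' Randomly interleave the conditions of a block
#'
#' @param conditions Condition table.
#' @param seed Optional integer; when given, the permutation is
#'   reproducible (the caller's RNG state is untouched).
#' @return A character vector: a permutation of `condition_id`.
#' @export
generate_block_order <- function(conditions, seed = NULL) {
  if (nrow(conditions) == 0L) stop("no conditions to order")
  with_seed(seed, sample(conditions$condition_id))
}

#' Assign the rewarded cue and reward size for a trial
#'
#' Single-cue trials pay the shown cue's value.  In double-cue trials one
#' side is selected with probability 0.5, independently of any
#' perturbation.
#'
#' @param condition A single-row condition data.frame.
#' @return A list with `side` ("left"/"right") and `drops`.
#' @export
assign_reward <- function(condition) {
  stopifnot(nrow(condition) == 1L)
  has_l <- !is.na(condition$left_value)
  has_r <- !is.na(condition$right_value)
  if (has_l && has_r) {
    side <- if (stats::runif(1) < 0.5) "left" else "right"
  } else if (has_l) side <- "left" else side <- "right"
  drops <- if (side == "left") condition$left_value else condition$right_value
  list(side = side, drops = as.integer(drops))
}

#' Build a multi-block trial schedule
#'
#' Trials follow the task's fixed timing: 2000 ms of fixation before cue
#' onset, a 1000 ms cue period, and a 1500 ms delay between cue offset and
#' reward.  All analysis times elsewhere in the package are expressed in
#' ms relative to cue onset; the schedule stores absolute event times on a
#' common session clock.  Fixation-break (incomplete) trials can be
#' generated at a configurable rate and are excluded by every analysis.
#'
#' @param conditions Condition table for one block.
#' @param n_blocks Number of blocks; each block contains one trial per
#'   condition in a fresh random order.
#' @param seed Optional integer seed for the block orders, reward draws and
#'   completion flags.
#' @param p_incomplete Probability that a trial ends with a fixation break.
#' @param iti_ms Inter-trial interval added between consecutive trials.
#' @return A data.frame of trials (one row per trial, in session order).
#' @export
build_trial_schedule <- function(conditions, n_blocks = 9L, seed = NULL,
                                 p_incomplete = 0, iti_ms = 1000) {
  stopifnot(n_blocks >= 1L)
  with_seed(seed, {
    cond_idx <- stats::setNames(seq_len(nrow(conditions)),
                                conditions$condition_id)
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      ord <- sample(conditions$condition_id)
      rows[[b]] <- data.frame(block_index = b, condition_id = ord,
                              stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows)
    n <- nrow(tr)
    tr$trial_id <- sprintf("t%05d", seq_len(n))
    tr$completed <- stats::runif(n) >= p_incomplete
    ci <- cond_idx[tr$condition_id]
    lv <- conditions$left_value[ci]
    rv <- conditions$right_value[ci]
    pick_left <- ifelse(is.na(rv), TRUE,
                 ifelse(is.na(lv), FALSE, stats::runif(n) < 0.5))
    tr$rewarded_side <- ifelse(pick_left, "left", "right")
    tr$reward_drops <- as.integer(ifelse(pick_left, lv, rv))
    # fixed epoch durations; fixation-break trials truncate at a random
    # point but keep nominal event times for bookkeeping
    fix_dur <- 2000; cue_dur <- 1000; delay <- 1500
    trial_len <- fix_dur + cue_dur + delay + iti_ms
    tr$t_fixation_on_ms <- (seq_len(n) - 1L) * trial_len
    tr$t_cue_on_ms <- tr$t_fixation_on_ms + fix_dur
    tr$t_cue_off_ms <- tr$t_cue_on_ms + cue_dur
    tr$t_reward_ms <- tr$t_cue_off_ms + delay
    tr[, c("trial_id", "block_index", "condition_id", "completed",
           "rewarded_side", "reward_drops", "t_fixation_on_ms",
           "t_cue_on_ms", "t_cue_off_ms", "t_reward_ms")]
  })
}

# Evaluate `expr` under a temporary seed without disturbing the caller's
# RNG state; with seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
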