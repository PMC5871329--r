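#' Default pipeline configuration
#'
#' Reads the packaged defaults file (`inst/config/defaults.yaml`), which
#' holds every analysis window, significance level and bound in one
#' place, and optionally merges a user YAML file over it.
#'
#' @param path Optional user YAML whose entries override the defaults.
#' @return Nested configuration list.
#' @export
default_config <- function(path = NULL) {
  cfg <- yaml::read_yaml(system.file("config", "defaults.yaml",
                                     package = "ofcattn"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("invalid config field: ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> screen -> perturb -> fit -> report, writing
#' each stage's outputs as CSV/JSON under `outdir` together with a run
#' manifest (config hash, per-file checksums, counts entering and
#' leaving each screening stage).  Stages are deterministic given the
#' seeds in the configuration.
#'
#' @param config Configuration list from [default_config()].
#' @param outdir Output directory.
#' @param seed Overrides `config$seeds$simulate` when non-NULL.
#' @param stages Character vector of stages to run (in order).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL,
                         stages = c("simulate", "screen", "perturb",
                                    "fit", "report")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$seeds$simulate <- seed
  manifest <- list(config_hash = digest_config(config),
                   package_version =
                     as.character(utils::packageVersion("ofcattn")),
                   stages = list())
  log <- list()
  need <- function(f) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) stop("dependency error: missing upstream file ", f)
    p
  }

  if ("simulate" %in% stages) {
    sc <- list(cues = cue_set(config$task$values),
               n_blocks = config$simulate$n_blocks,
               n_positive = config$simulate$n_positive,
               n_negative = config$simulate$n_negative,
               n_untuned = config$simulate$n_untuned,
               n_nonvisual = config$simulate$n_nonvisual,
               p_incomplete = config$simulate$p_incomplete,
               include_pupil = config$simulate$include_pupil)
    session <- simulate_session(sc, seed = config$seeds$simulate)
    write_session(session, outdir)
    manifest$stages$simulate <- stage_entry(outdir, c(
      "conditions.csv", "trials.csv", "spikes.csv", "neurons_truth.csv",
      if (isTRUE(sc$include_pupil)) "pupil.csv"))
  }

  if (any(c("screen", "perturb", "fit", "report") %in% stages)) {
    for (f in c("conditions.csv", "trials.csv", "spikes.csv")) need(f)
    session <- read_session(outdir)
  }

  if ("screen" %in% stages) {
    scr <- screen_neurons(session, alpha = config$analysis$alpha,
                          selectivity_window =
                            unlist(config$analysis$selectivity_window))
    utils::write.csv(scr, file.path(outdir, "screening.csv"),
                     row.names = FALSE)
    log$n_total <- nrow(scr)
    log$n_visual <- sum(scr$visually_responsive)
    log$n_selective <- sum(scr$value_selective, na.rm = TRUE)
    log$n_positive <- sum(scr$tuning == "positive", na.rm = TRUE)
    log$n_negative <- sum(scr$tuning == "negative", na.rm = TRUE)
    manifest$stages$screen <- stage_entry(outdir, "screening.csv")
  }

  if (any(c("perturb", "fit", "report") %in% stages)) {
    scr <- utils::read.csv(need("screening.csv"), stringsAsFactors = FALSE)
  }

  if ("perturb" %in% stages) {
    mod <- analyze_perturbation(
      session, scr,
      bin_step_ms = config$analysis$psth_bin_step_ms,
      window_ms = config$analysis$psth_window_ms,
      alpha = config$analysis$alpha)
    utils::write.csv(mod, file.path(outdir, "modulation.csv"),
                     row.names = FALSE)
    log$n_modulated <- sum(mod$modulated)
    manifest$stages$perturb <- stage_entry(outdir, "modulation.csv")
  }

  if ("fit" %in% stages) {
    fits <- fit_attention_models(session, scr, seed = config$seeds$split,
                                 window = unlist(config$analysis$model_window),
                                 n_starts = config$fit$n_starts)
    utils::write.csv(fits, file.path(outdir, "model_fits.csv"),
                     row.names = FALSE)
    manifest$stages$fit <- stage_entry(outdir, "model_fits.csv")
  }

  if ("report" %in% stages) {
    fits <- utils::read.csv(need("model_fits.csv"),
                            stringsAsFactors = FALSE)
    cmpr <- compare_models(fits)
    mod <- if (file.exists(file.path(outdir, "modulation.csv")))
      utils::read.csv(file.path(outdir, "modulation.csv"),
                      stringsAsFactors = FALSE) else NULL
    pupil_report <- NULL
    if (!is.null(session$pupil)) {
      resp <- extract_pupil_responses(session$pupil, session$trials)
      feats <- condition_features(session$conditions)
      tf <- feats[match(session$trials$condition_id[
        match(resp$trial_id, session$trials$trial_id)],
        feats$condition_id), ]
      utils::write.csv(resp, file.path(outdir, "pupil_responses.csv"),
                       row.names = FALSE)
      singles <- !is.na(tf$v_single)
      reg <- regress_pupil_on_value(
        data.frame(response = resp$response[singles],
                   value = tf$v_single[singles]))
      pupil_report <- list(b0 = reg$b0, b1 = reg$b1, p_b1 = reg$p_b1,
                           n = reg$n)
    }
    report <- list(
      pupil = pupil_report,
      counts = log,
      modulation = if (!is.null(mod)) list(
        n_modulated = sum(mod$modulated),
        n_consistent = sum(mod$consistency == "consistent", na.rm = TRUE),
        mean_mi = mean(mod$mi, na.rm = TRUE)),
      model_comparison = list(
        winner_counts = as.list(cmpr$winner_counts),
        mean_r2_full = cmpr$mean_r2_full,
        p_aicc_full_vs_m1 = cmpr$p_aicc_full_vs_m1,
        p_aicc_full_vs_m2 = cmpr$p_aicc_full_vs_m2))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$report <- stage_entry(outdir, c(
      "report.json", if (!is.null(pupil_report)) "pupil_responses.csv"))
  }

  manifest$log <- log
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_entry <- function(outdir, files) {
  files <- files[!vapply(files, is.null, logical(1))]
  sums <- tools::md5sum(file.path(outdir, unlist(files)))
  names(sums) <- unlist(files)
  as.list(sums)
}

digest_config <- function(config) {
  # stable content hash without extra dependencies
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Miniature session fixture
#'
#' A deterministic small session used throughout the test suite:
#' 2 blocks (170 completed trials) and 6 neurons (2 positive, 2 negative,
#' 1 untuned, 1 non-visual) at a fixed seed.  `size = "default"` returns
#' the 9-block, 15-neuron default instead.
#'
#' @param size "tiny" or "default".
#' @param seed Fixed seed (change only for exploratory use).
#' @param include_pupil Generate pupil traces as well.
#' @return An `ofc_session`.
#' @export
make_fixture <- function(size = c("tiny", "default"), seed = 20180313L,
                         include_pupil = TRUE) {
  size <- match.arg(size)
  cfg <- if (size == "tiny")
    list(n_blocks = 2L, n_positive = 2L, n_negative = 2L, n_untuned = 1L,
         n_nonvisual = 1L, include_pupil = include_pupil)
  else list(include_pupil = include_pupil)
  simulate_session(cfg, seed = seed)
}
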