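# Configuration, seed management and the end-to-end pipeline driver.

#' Default pipeline configuration
#'
#' A nested list describing every stage of a run. The demo sizes (24
#' channels at 10 kHz, 3 trials per movement) keep a full run to a couple
#' of minutes on one core; the synthetic-generator *defaults* (96 channels,
#' 30 kHz, 2.5-4.5 s cues) are unchanged and used when the corresponding
#' fields are set.
#'
#' @param seed Global seed; each stage derives its own seed from it and
#'   the stage name, so no stage consumes global randomness directly.
#' @return A `run_config` nested list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    synth = list(n_trials = 3, n_channels = 24, fs = 10000,
                 contrast = 2, baseline_sd = 10, lead_in = 3,
                 dur_range = c(2.5, 4.5),
                 movements = c("flexion", "extension", "wiggle"),
                 artifact_amplitude = 1000, artifact_rate = 50,
                 affected_fraction = 0.9),
    mwp = list(scales = c(3, 4, 5, 6), bin_width = 0.1, boxcar = 1,
               threshold = 500, n_monitor = 12, n_required = 4,
               window = 2.5e-3),
    cpg = list(tau1 = 0.10, tau2 = 0.20, beta = 8.44, mu21 = 4.94,
               mu12 = 6.00, c = 50.6, dt = 0.001, duration = 12),
    decode = list(cost = 1, gamma = NULL, min_bins = 20),
    loop = list(fps = 12, update_rate = 10, plant_tau = 0.2),
    eval = list(lag = 1.2, n_perm = 199, n_boot = 500)
  ), class = "run_config")
}

#' Derive a per-stage seed from the global seed
#'
#' FNV-1a hash of the stage name folded with the global seed, reduced
#' below 2^31 so it is a valid R integer seed. Stable across sessions and
#' platforms.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name string.
#' @return A positive integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483629
  as.integer((h + (global_seed %% 2^31) * 7919) %% (2^31 - 1) + 1)
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("load_config: unknown key '", full, "'")
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("load_config: '", full, "' must be a section")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      # `[<-` keeps NULL-valued keys instead of deleting them
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (cfg$cpg$tau1 <= 0) stop("load_config: cpg.tau1 must be > 0")
  if (cfg$cpg$tau2 <= 0) stop("load_config: cpg.tau2 must be > 0")
  if (cfg$synth$n_trials < 1) stop("load_config: synth.n_trials must be >= 1")
  if (cfg$synth$fs <= 0) stop("load_config: synth.fs must be > 0")
  if (cfg$mwp$bin_width <= 0) stop("load_config: mwp.bin_width must be > 0")
  if (cfg$loop$fps <= 0) stop("load_config: loop.fps must be > 0")
  invisible(cfg)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) file, fills unspecified fields from
#' [default_config()], rejects unknown keys by name, and validates basic
#' invariants.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pipeline_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(proc.time()[3] - t0), paste0(...)))
}

#' Run the full closed-loop pipeline
#'
#' Executes synth -> artifact excision -> MWP -> decoder training ->
#' closed loop -> evaluation, writing every intermediate artifact and a
#' manifest (config hash, seeds, package version) to `outdir`. A separate
#' test recording (independent seed, same profile) is decoded, so reported
#' accuracies are held-out. Idempotent per seed: identical configs produce
#' byte-identical evaluation reports.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @param outdir Output directory, created if missing.
#' @return Invisibly, a list with the evaluation report, the permutation
#'   p-value, the cue correlations, the decoder bank, and `outdir`.
#' @export
run_pipeline <- function(cfg = default_config(), outdir = tempfile("nbrun")) {
  stopifnot(inherits(cfg, "run_config"))
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  stage_seed <- function(stage) derive_seed(cfg$seed, stage)
  run_one <- function(which) {
    # which = "train" or "test": independent noise seeds, shared profile
    sched <- make_cue_schedule(cfg$synth$n_trials,
                               movements = cfg$synth$movements,
                               dur_range = cfg$synth$dur_range,
                               seed = stage_seed(paste0("schedule_", which)),
                               lead_in = cfg$synth$lead_in)
    prof <- channel_profile(cfg$synth$n_channels,
                            movements = cfg$synth$movements,
                            baseline_sd = cfg$synth$baseline_sd,
                            contrast = cfg$synth$contrast,
                            seed = stage_seed("profile"))
    rec <- generate_recording(sched, prof, fs = cfg$synth$fs,
                              seed = stage_seed(paste0("noise_", which)))
    # emulate NMES artifacts during movement epochs (decoders see data
    # from before and during stimulation)
    mov <- sched$events[sched$events$label != "rest", ]
    epochs <- lapply(seq_len(nrow(mov)), function(i)
      c(mov$start[i], mov$start[i] + mov$duration[i]))
    rec <- inject_artifacts(rec, epochs,
                            pulse_rate = cfg$synth$artifact_rate,
                            amplitude = cfg$synth$artifact_amplitude,
                            affected_fraction = cfg$synth$affected_fraction,
                            seed = stage_seed(paste0("artifacts_", which)))
    pipeline_log("synth", t0, which, ": ", ncol(rec$signal), " samples x ",
                 rec$n_channels, " channels")
    acfg <- artifact_config(threshold = cfg$mwp$threshold,
                            n_monitor = min(cfg$mwp$n_monitor,
                                            rec$n_channels),
                            n_required = cfg$mwp$n_required,
                            window = cfg$mwp$window,
                            monitor_seed = stage_seed("monitor"))
    det <- detect_artifacts(rec, acfg)
    exc <- excise_artifacts(rec, det, window = cfg$mwp$window)
    pipeline_log("mwp", t0, which, ": ", length(det),
                 " artifacts excised, retained ",
                 sprintf("%.3f", exc$retained_fraction))
    base_n <- round(cfg$synth$lead_in * cfg$synth$fs)
    baseline <- fit_baseline(exc$signal[, seq_len(min(base_n,
                                                      ncol(exc$signal))),
                                        drop = FALSE],
                             fs = cfg$synth$fs, scales = cfg$mwp$scales,
                             bin_width = cfg$mwp$bin_width)
    feats <- compute_mwp(exc$signal, baseline, sample_map = exc$sample_map,
                         fs = cfg$synth$fs)
    if (cfg$mwp$boxcar > 0)
      feats <- boxcar_smooth(feats, width = cfg$mwp$boxcar)
    list(sched = sched, rec = rec, feats = feats,
         labels = label_bins(feats, sched))
  }
  train <- run_one("train")
  write_mwp_csv(train$feats, file.path(outdir, "features_train.csv"),
                train$labels)
  bank <- train_decoders(train$feats, train$labels,
                         movements = cfg$synth$movements,
                         cost = cfg$decode$cost, gamma = cfg$decode$gamma,
                         min_bins = cfg$decode$min_bins,
                         seed = stage_seed("decode"))
  pipeline_log("decode", t0, "bank trained on ",
               nrow(train$feats$features), " bins")
  test <- run_one("test")
  write_mwp_csv(test$feats, file.path(outdir, "features_test.csv"),
                test$labels)
  cpg <- cpg_params(cfg$cpg$tau1, cfg$cpg$tau2, cfg$cpg$beta,
                    cfg$cpg$mu21, cfg$cpg$mu12, cfg$cpg$c)
  cpg_tr <- cpg_simulate(cpg, duration = max(cfg$cpg$duration, 12),
                         dt = cfg$cpg$dt)
  loop <- run_closed_loop(test$feats, bank, cpg_tr, fps = cfg$loop$fps,
                          update_rate = cfg$loop$update_rate,
                          tau = cfg$loop$plant_tau)
  utils::write.csv(loop$decisions, file.path(outdir, "decisions.csv"),
                   row.names = FALSE)
  utils::write.csv(loop$commands, file.path(outdir, "commands.csv"),
                   row.names = FALSE)
  utils::write.csv(loop$trajectory, file.path(outdir, "trajectory.csv"),
                   row.names = FALSE)
  pipeline_log("loop", t0, nrow(loop$trajectory), " frames")
  vc <- train_video_classifier(cpg_tr, movements = cfg$synth$movements,
                               fps = cfg$loop$fps,
                               seed = stage_seed("video"))
  frame_labels <- classify_movement(loop$trajectory, vc)
  report <- evaluate_frames(frame_labels, test$sched, lag = cfg$eval$lag,
                            fps = cfg$loop$fps)
  perm <- permutation_test(frame_labels, test$sched,
                           n_perm = cfg$eval$n_perm,
                           seed = stage_seed("perm"),
                           lag = cfg$eval$lag, fps = cfg$loop$fps)
  corr <- cue_mwp_correlation(test$feats, test$sched,
                              n_boot = cfg$eval$n_boot,
                              seed = stage_seed("boot"))
  pipeline_log("eval", t0, sprintf("overall accuracy %.3f, p = %.4g",
                                   report$overall_accuracy, perm$p_value))
  report_json <- list(
    overall_accuracy = report$overall_accuracy,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    per_movement = lapply(report$per_movement, function(p)
      p[c("accuracy", "sensitivity", "specificity")]),
    permutation_p = perm$p_value,
    n_frames = report$n_frames, lag = report$lag)
  jsonlite::write_json(report_json, file.path(outdir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   package_version =
                     as.character(utils::packageVersion("neurobypass")),
                   stage_seeds = list(
                     schedule_train = stage_seed("schedule_train"),
                     schedule_test = stage_seed("schedule_test"),
                     profile = stage_seed("profile"),
                     decode = stage_seed("decode")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, permutation = perm, correlation = corr,
                 bank = bank, frame_labels = frame_labels,
                 loop = loop, outdir = outdir))
}
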