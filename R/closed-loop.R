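#' Map a decoder decision to a stimulation command
#'
#' Flexion and extension decisions map to static stimulation of the
#' corresponding muscle group; a wiggle decision triggers CPG-driven
#' alternating stimulation whose phase is the sign of the oscillator
#' output sampled at the 10 Hz update rate (two-level discretization:
#' the stimulator only delivers maximal flexion or extension drive);
#' rest switches stimulation off.
#'
#' @param decision Character decision ("rest", "flexion", "extension",
#'   "wiggle").
#' @param y_out CPG oscillator output sample at the current update tick
#'   (used only for wiggle).
#' @return A `stim_command`: list with `mode` in off/flexion_static/
#'   extension_static/cpg_alternating and `phase` in -1/0/+1.
#' @export
encode_stimulation <- function(decision, y_out = 0) {
  mode <- switch(decision,
                 rest = "off",
                 flexion = "flexion_static",
                 extension = "extension_static",
                 wiggle = "cpg_alternating",
                 stop("encode_stimulation: unknown decision '", decision, "'"))
  phase <- if (mode == "cpg_alternating") sign(y_out) else 0
  structure(list(mode = mode, phase = phase), class = "stim_command")
}

#' Initial state of the virtual thumb plant
#'
#' @param thumb_pos Normalized thumb distance from the reference
#'   ("sixth finger"): -1 fully flexed, +1 fully extended, 0 at rest.
#' @param activation Current commanded drive (the pole being tracked).
#' @param t Time in seconds.
#' @return A `plant_state`.
#' @export
plant_state <- function(thumb_pos = 0, activation = 0, t = 0) {
  if (abs(thumb_pos) > 1) stop("plant_state: |thumb_pos| must be <= 1")
  structure(list(thumb_pos = thumb_pos, activation = activation, t = t),
            class = "plant_state")
}

stim_target <- function(cmd) {
  switch(cmd$mode,
         off = 0,
         flexion_static = -1,
         extension_static = 1,
         cpg_alternating = cmd$phase)
}

#' Advance the virtual thumb plant
#'
#' First-order response toward the commanded pole with a 0.2 s activation
#' time constant (about the continuous stimulation needed for a measurable
#' deflection), integrated with the exact exponential update so any step
#' size is stable. Deterministic.
#'
#' @param cmd A [encode_stimulation()] command.
#' @param state A [plant_state()].
#' @param dt Step in seconds (> 0).
#' @param tau Activation time constant in seconds.
#' @return The advanced `plant_state`.
#' @export
plant_step <- function(cmd, state, dt, tau = 0.2) {
  stopifnot(inherits(cmd, "stim_command"), inherits(state, "plant_state"))
  if (dt <= 0) stop("plant_step: dt must be > 0")
  target <- stim_target(cmd)
  alpha <- 1 - exp(-dt / tau)
  pos <- state$thumb_pos + (target - state$thumb_pos) * alpha
  plant_state(max(-1, min(1, pos)), activation = target, t = state$t + dt)
}

#' Run the decoder-driven closed loop on a feature stream
#'
#' Decisions are formed per 100 ms bin (the 10 Hz update limit), encoded
#' into stimulation commands (the CPG oscillator free-runs and is sampled
#' at the update ticks while a wiggle decision is active), and the virtual
#' plant is integrated on a 120 Hz grid, emitting thumb positions at the
#' 12 frames/s video rate.
#'
#' @param features `mwp_features` (with wall-clock bin midpoints) to
#'   decode.
#' @param bank A [train_decoders()] decoder bank.
#' @param cpg_trace A `cpg_trace` at least as long as the feature stream
#'   (recycled cyclically past its end, transient excluded).
#' @param fps Video frame rate (default 12).
#' @param update_rate Decision update rate in Hz (default 10).
#' @param tau Plant time constant in seconds.
#' @return A `closed_loop_run`: `decisions` (per bin), `commands` (per
#'   update tick), `trajectory` (t, thumb_pos at `fps`).
#' @export
run_closed_loop <- function(features, bank, cpg_trace, fps = 12,
                            update_rate = 10, tau = 0.2) {
  stopifnot(inherits(features, "mwp_features"),
            inherits(bank, "decoder_bank"))
  pred <- predict.decoder_bank(bank, features)
  bin_t <- features$bin_mid_times
  decisions <- data.frame(bin_mid_s = bin_t, pred)
  t_end <- max(bin_t) + features$bin_width
  # CPG lookup: map wall-clock time onto the post-transient trace, cyclic
  cpg_dt <- attr(cpg_trace, "dt")
  cpg_y <- cpg_trace$y_out[cpg_trace$t >= 2]
  cpg_at <- function(tt) cpg_y[(round(tt / cpg_dt) %% length(cpg_y)) + 1L]
  ticks <- seq(0, t_end, by = 1 / update_rate)
  dec_at_tick <- function(tt) {
    i <- findInterval(tt, bin_t)
    if (i < 1) "rest" else decisions$decision[i]
  }
  commands <- data.frame(t = ticks, mode = NA_character_, phase = 0)
  for (k in seq_along(ticks)) {
    cmd <- encode_stimulation(dec_at_tick(ticks[k]), cpg_at(ticks[k]))
    commands$mode[k] <- cmd$mode
    commands$phase[k] <- cmd$phase
  }
  # integrate the plant at 120 Hz (common multiple of 10 and 12)
  sim_rate <- 120
  n_sim <- ceiling(t_end * sim_rate)
  st <- plant_state()
  frame_t <- numeric(0); frame_pos <- numeric(0)
  cmd_idx <- 1L
  for (k in seq_len(n_sim)) {
    tt <- (k - 1) / sim_rate
    cmd_idx <- findInterval(tt, ticks)
    cmd <- structure(list(mode = commands$mode[max(1L, cmd_idx)],
                          phase = commands$phase[max(1L, cmd_idx)]),
                     class = "stim_command")
    st <- plant_step(cmd, st, 1 / sim_rate, tau = tau)
    if (k %% (sim_rate / fps) == 0) {
      frame_t <- c(frame_t, st$t)
      frame_pos <- c(frame_pos, st$thumb_pos)
    }
  }
  structure(list(decisions = decisions, commands = commands,
                 trajectory = data.frame(t = frame_t,
                                         thumb_pos = frame_pos),
                 fps = fps, update_rate = update_rate),
            class = "closed_loop_run")
}

#' @export
print.closed_loop_run <- function(x, ...) {
  cat(sprintf("Closed-loop run: %d decision bins, %d command ticks, %d frames\n",
              nrow(x$decisions), nrow(x$commands), nrow(x$trajectory)))
  cat("  decisions: ")
  print(table(x$decisions$decision))
  invisible(x)
}

traj_window_features <- function(pos) {
  zc <- sum(diff(sign(pos + (pos == 0) * 1e-12)) != 0)
  c(mean_pos = mean(pos), pos_range = diff(range(pos)),
    zc_rate = zc / length(pos))
}

#' Train the kinematics ("video") classifier on scripted stimulation
#'
#' Generates labelled thumb trajectories by driving the plant with
#' scripted commands for each movement (and rest), adds measurement
#' noise, extracts per-1-s-window features (mean position, position
#' range, zero-crossing rate), and trains the same one-vs-rest SVM +
#' arbitration machinery as the neural decoders on them.
#'
#' @param cpg_trace `cpg_trace` providing the alternation pattern for
#'   scripted wiggle.
#' @param movements Movements to script.
#' @param n_windows Training windows per class.
#' @param fps Frame rate (default 12).
#' @param noise_sd Measurement noise sd on positions.
#' @param seed Integer seed (noise and window jitter).
#' @return A `video_classifier` wrapping a [train_decoders()] bank.
#' @export
train_video_classifier <- function(cpg_trace,
                                   movements = c("flexion", "extension",
                                                 "wiggle"),
                                   n_windows = 80, fps = 12,
                                   noise_sd = 0.03, seed = 1) {
  win <- fps  # 1 s windows
  scripted <- function(label, t0) {
    # plant driven from rest for 3 s; keep the last `win` frames
    st <- plant_state()
    pos <- numeric(0)
    for (k in seq_len(3 * fps)) {
      tt <- t0 + (k - 1) / fps
      cmd <- encode_stimulation(label, cpg_at_time(cpg_trace, tt))
      st <- plant_step(cmd, st, 1 / fps)
      pos <- c(pos, st$thumb_pos)
    }
    utils::tail(pos, win)
  }
  dat <- with_seed(seed, {
    labs <- character(0)
    feats <- NULL
    for (label in c("rest", movements)) {
      for (r in seq_len(n_windows)) {
        pos <- scripted(label, t0 = stats::runif(1, 0, 2)) +
          stats::rnorm(win, 0, noise_sd)
        feats <- rbind(feats, traj_window_features(pos))
        labs <- c(labs, label)
      }
    }
    list(feats = feats, labs = labs)
  })
  bank <- train_decoders(dat$feats, dat$labs, movements = movements,
                         min_bins = 1, seed = seed)
  structure(list(bank = bank, fps = fps, window_s = 1, seed = seed),
            class = "video_classifier")
}

cpg_at_time <- function(cpg_trace, tt) {
  dt <- attr(cpg_trace, "dt")
  y <- cpg_trace$y_out[cpg_trace$t >= 2]
  y[(round(tt / dt) %% length(y)) + 1L]
}

#' Classify thumb movement from a trajectory
#'
#' One label per frame from features of the trailing 1 s window of
#' positions; once at least half a window of history exists the available
#' frames are used. Earlier frames are labelled rest (a wiggle cannot be
#' told from a flexion or extension until the thumb has moved back and
#' forth), with a warning when the whole trajectory is too short.
#'
#' @param trajectory Data frame with `t` and `thumb_pos` at the
#'   classifier's frame rate, or a numeric position vector.
#' @param classifier A [train_video_classifier()].
#' @return Character vector of per-frame labels.
#' @export
classify_movement <- function(trajectory, classifier) {
  stopifnot(inherits(classifier, "video_classifier"))
  pos <- if (is.numeric(trajectory)) trajectory else trajectory$thumb_pos
  win <- classifier$fps * classifier$window_s
  half <- ceiling(win / 2)
  n <- length(pos)
  if (n < half) {
    warning("classify_movement: trajectory shorter than half a window; ",
            "labelling rest")
    return(rep("rest", n))
  }
  feats <- t(vapply(seq_len(n), function(i) {
    if (i < half) return(c(mean_pos = NA_real_, pos_range = NA_real_,
                           zc_rate = NA_real_))
    traj_window_features(pos[max(1, i - win + 1):i])
  }, numeric(3)))
  out <- rep("rest", n)
  ok <- !is.na(feats[, 1])
  if (any(ok))
    out[ok] <- arbitrate(score_bin(classifier$bank,
                                   feats[ok, , drop = FALSE]))
  out
}

#' Frame-level evaluation against the cue schedule
#'
#' Classifier output is shifted earlier by `lag` seconds (reaction plus
#' system delay) and compared per frame with the active cue. Sensitivity
#' is the proportion of movement-cue frames identified correctly (per
#' movement and overall); specificity is the proportion of rest-cue
#' frames identified as rest; overall accuracy is the fraction of frames
#' whose label matches the cue.
#'
#' @param frame_labels Character vector, one label per frame.
#' @param schedule The [make_cue_schedule()] the frames were recorded
#'   under.
#' @param lag Shift in seconds (default 1.2).
#' @param fps Frame rate (default 12).
#' @return An `eval_report`: overall accuracy, overall sensitivity and
#'   specificity, per-movement accuracy/sensitivity/specificity, the
#'   confusion table, and the number of compared frames.
#' @export
evaluate_frames <- function(frame_labels, schedule, lag = 1.2, fps = 12) {
  stopifnot(inherits(schedule, "cue_schedule"))
  n <- length(frame_labels)
  shift <- round(lag * fps)
  if (shift >= n)
    stop("evaluate_frames: lag exceeds the labelled span")
  frame_t <- (seq_len(n) - 0.5) / fps
  cue <- cue_at(schedule, frame_t)
  lab <- frame_labels[(shift + 1):n]
  cue <- cue[seq_len(n - shift)]
  movements <- schedule$movements
  conf <- table(cue = factor(cue, levels = c("rest", movements)),
                label = factor(lab, levels = c("rest", movements)))
  per <- lapply(movements, function(m) {
    is_cue <- cue == m
    list(accuracy = mean((lab == m) == is_cue),
         sensitivity = if (any(is_cue)) mean(lab[is_cue] == m) else NA_real_,
         specificity = mean(lab[!is_cue] != m))
  })
  names(per) <- movements
  structure(list(overall_accuracy = mean(lab == cue),
                 sensitivity = if (any(cue != "rest"))
                   mean(lab[cue != "rest"] == cue[cue != "rest"]) else NA_real_,
                 specificity = if (any(cue == "rest"))
                   mean(lab[cue == "rest"] == "rest") else NA_real_,
                 per_movement = per, confusion = conf,
                 n_frames = length(lab), lag = lag, fps = fps),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Frame-level evaluation (%d frames, %.1f s lag):\n",
              x$n_frames, x$lag))
  cat(sprintf("  overall accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$overall_accuracy, x$sensitivity, x$specificity))
  for (m in names(x$per_movement)) {
    p <- x$per_movement[[m]]
    cat(sprintf("  %-10s acc %.3f  sens %.3f  spec %.3f\n",
                m, p$accuracy, p$sensitivity, p$specificity))
  }
  invisible(x)
}

#' Permutation test of frame-level accuracy
#'
#' Compares the observed overall accuracy with accuracies obtained after
#' permuting the movement identities across cue blocks (rest blocks keep
#' their label), preserving within-block autocorrelation. The p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param frame_labels Per-frame classifier labels.
#' @param schedule The cue schedule.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param lag,fps As in [evaluate_frames()].
#' @return List with `p_value`, `observed`, `null_accuracies`.
#' @export
permutation_test <- function(frame_labels, schedule, n_perm = 999, seed = 1,
                             lag = 1.2, fps = 12) {
  if (n_perm < 100) stop("permutation_test: n_perm must be >= 100")
  observed <- evaluate_frames(frame_labels, schedule, lag, fps)$overall_accuracy
  mov_idx <- which(schedule$events$label != "rest")
  null_acc <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- schedule
    perm$events$label[mov_idx] <-
      sample(schedule$events$label[mov_idx])
    evaluate_frames(frame_labels, perm, lag, fps)$overall_accuracy
  }, numeric(1)))
  list(p_value = (1 + sum(null_acc >= observed)) / (n_perm + 1),
       observed = observed, null_accuracies = null_acc)
}

#' Per-channel correlation between MWP and cue vectors
#'
#' For each movement, a 0/1 cue vector on the bin grid is correlated
#' (Pearson) with each channel's MWP series. Between-movement differences
#' per channel are tested with a trial-level bootstrap: cue blocks are
#' resampled with replacement within each label stratum, and the two-sided
#' p-value is the bootstrap probability mass of the difference's sign
#' flips.
#'
#' @param features An `mwp_features` object.
#' @param schedule The cue schedule.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return A `cue_correlation`: `r` (movements x channels matrix),
#'   `diff_p` (named list of per-channel two-sided p-values for each
#'   movement pair), `n_bins`.
#' @export
cue_mwp_correlation <- function(features, schedule, n_boot = 2000,
                                seed = 1) {
  stopifnot(inherits(features, "mwp_features"),
            inherits(schedule, "cue_schedule"))
  X <- features$features
  labels <- label_bins(features, schedule)
  movements <- schedule$movements
  for (m in movements)
    if (sum(schedule$events$label == m) < 2)
      stop("cue_mwp_correlation: need >= 2 trials of ", m)
  safe_cor <- function(X, v) {
    sds <- apply(X, 2, stats::sd)
    r <- rep(0, ncol(X))
    if (stats::sd(v) > 0) {
      ok <- sds > 0
      r[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok, drop = FALSE], v)))
    }
    r
  }
  r_for <- function(idx) {
    vapply(movements, function(m)
      safe_cor(X[idx, , drop = FALSE],
               as.numeric(labels[idx] == m)),
      numeric(ncol(X)))
  }
  all_idx <- seq_len(nrow(X))
  r_obs <- t(r_for(all_idx))
  rownames(r_obs) <- movements
  # map each bin to its cue block
  ev <- schedule$events
  block_of <- findInterval(features$bin_mid_times, ev$start)
  blocks_by_label <- split(seq_len(nrow(ev)), ev$label)
  boot_r <- with_seed(seed, {
    arr <- array(NA_real_, c(n_boot, length(movements), ncol(X)))
    for (b in seq_len(n_boot)) {
      picked <- unlist(lapply(blocks_by_label, function(bl)
        sample(bl, length(bl), replace = TRUE)))
      idx <- unlist(lapply(picked, function(bk) which(block_of == bk)))
      arr[b, , ] <- t(r_for(idx))
    }
    arr
  })
  pairs <- utils::combn(movements, 2, simplify = FALSE)
  diff_p <- lapply(pairs, function(pr) {
    i <- match(pr[1], movements); j <- match(pr[2], movements)
    d <- boot_r[, i, ] - boot_r[, j, ]
    # two-sided bootstrap sign test on the difference of correlations
    p_lo <- colMeans(d <= 0); p_hi <- colMeans(d >= 0)
    pmin(1, 2 * pmin(p_lo, p_hi))
  })
  names(diff_p) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  structure(list(r = r_obs, diff_p = diff_p, n_bins = nrow(X),
                 n_boot = n_boot),
            class = "cue_correlation")
}

#' @export
print.cue_correlation <- function(x, ...) {
  cat(sprintf("Cue/MWP correlation over %d bins:\n", x$n_bins))
  for (m in rownames(x$r))
    cat(sprintf("  %-10s r in [%.2f, %.2f], mean %.2f\n", m,
                min(x$r[m, ]), max(x$r[m, ]), mean(x$r[m, ])))
  invisible(x)
}
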