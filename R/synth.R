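#' Build a randomized cue schedule
#'
#' Alternating movement/rest cue blocks: each movement appears exactly
#' `n_trials` times, the order is shuffled, every movement cue is followed
#' by a rest cue, and every block duration is drawn uniformly from
#' `dur_range` (2.5-4.5 s by default). An optional initial rest block of
#' fixed length can be prepended to provide the baseline segment used for
#' feature standardization.
#'
#' @param n_trials Trials per movement (>= 1).
#' @param movements Character vector of movement labels (default flexion,
#'   extension, wiggle).
#' @param dur_range `c(min, max)` block duration in seconds.
#' @param seed Integer seed; the schedule is deterministic given it.
#' @param lead_in Length of an initial rest block in seconds (0 = none).
#' @return A `cue_schedule`: data frame `events` (label, start, duration)
#'   plus `total_duration`, `movements`, `seed`.
#' @export
make_cue_schedule <- function(n_trials,
                              movements = c("flexion", "extension", "wiggle"),
                              dur_range = c(2.5, 4.5), seed = 1,
                              lead_in = 0) {
  if (length(movements) == 0) stop("make_cue_schedule: empty movement list")
  if (n_trials < 1) stop("make_cue_schedule: n_trials must be >= 1")
  if ("rest" %in% movements)
    stop("make_cue_schedule: 'rest' is implicit, not a movement")
  sched <- with_seed(seed, {
    order <- sample(rep(movements, n_trials))
    n_mov <- length(order)
    durs_mov <- stats::runif(n_mov, dur_range[1], dur_range[2])
    durs_rest <- stats::runif(n_mov, dur_range[1], dur_range[2])
    labels <- as.vector(rbind(order, "rest"))
    durations <- as.vector(rbind(durs_mov, durs_rest))
    if (lead_in > 0) {
      labels <- c("rest", labels)
      durations <- c(lead_in, durations)
    }
    data.frame(label = labels,
               start = cumsum(c(0, durations[-length(durations)])),
               duration = durations)
  })
  structure(list(events = sched,
                 total_duration = sum(sched$duration),
                 movements = movements, seed = seed),
            class = "cue_schedule")
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf("Cue schedule: %d events over %.1f s (%s)\n",
              nrow(x$events), x$total_duration,
              paste(x$movements, collapse = ", ")))
  print(utils::head(x$events, 6))
  if (nrow(x$events) > 6) cat("  ...\n")
  invisible(x)
}

#' Active cue at given times
#'
#' @param schedule A [make_cue_schedule()] result.
#' @param times Numeric vector of times in seconds.
#' @return Character vector of labels ("rest" past the end).
#' @export
cue_at <- function(schedule, times) {
  ev <- schedule$events
  idx <- findInterval(times, ev$start)
  out <- rep("rest", length(times))
  ok <- idx >= 1 & times < schedule$total_duration
  out[ok] <- ev$label[idx[ok]]
  out
}

#' Per-channel modulation profile for the synthetic recordings
#'
#' Each channel has a baseline noise sd and a multiplicative gain on
#' multiunit-band power for each cue class (gain 1 at rest). A fraction of
#' channels is tuned to each movement (gain = `contrast` during that
#' movement); a further fraction of wiggle channels is suppressed
#' (gain = 1/`contrast`), mimicking the observed mixture of enhanced and
#' suppressed rhythmic-movement channels.
#'
#' @param n_channels Number of channels (default 96).
#' @param movements Movement labels.
#' @param baseline_sd Baseline noise sd in microvolts (scalar or per
#'   channel).
#' @param contrast Gain during a channel's preferred movement (> 0).
#' @param frac_tuned Fraction of channels tuned to each movement.
#' @param frac_suppressed Fraction of channels suppressed during wiggle.
#' @param seed Integer seed for the channel assignment.
#' @return A `channel_profile` with a `gains` matrix
#'   (channels x classes, classes = rest + movements).
#' @export
channel_profile <- function(n_channels = 96,
                            movements = c("flexion", "extension", "wiggle"),
                            baseline_sd = 10, contrast = 2,
                            frac_tuned = 0.25, frac_suppressed = 0.05,
                            seed = 1) {
  if (contrast <= 0) stop("channel_profile: contrast must be > 0")
  baseline_sd <- rep_len(baseline_sd, n_channels)
  if (any(baseline_sd <= 0)) stop("channel_profile: baseline_sd must be > 0")
  classes <- c("rest", movements)
  gains <- matrix(1, n_channels, length(classes),
                  dimnames = list(NULL, classes))
  with_seed(seed, {
    pool <- sample.int(n_channels)
    k <- max(1L, round(frac_tuned * n_channels))
    for (m in movements) {
      take <- utils::head(pool, k)
      pool <- utils::tail(pool, -k)
      gains[take, m] <- contrast
      if (m == "wiggle" && frac_suppressed > 0 && length(pool) > 0) {
        ks <- min(length(pool), max(1L, round(frac_suppressed * n_channels)))
        sup <- utils::head(pool, ks)
        pool <- utils::tail(pool, -ks)
        gains[sup, m] <- 1 / contrast
      }
    }
  })
  structure(list(n_channels = n_channels, baseline_sd = baseline_sd,
                 gains = gains, movements = movements, contrast = contrast,
                 seed = seed),
            class = "channel_profile")
}

#' Channels tuned to a given movement
#'
#' @param profile A [channel_profile()].
#' @param movement Movement label.
#' @return Integer vector of channel indices whose gain for `movement`
#'   exceeds their rest gain.
#' @export
tuned_channels <- function(profile, movement) {
  which(profile$gains[, movement] > profile$gains[, "rest"])
}

#' Generate a synthetic multichannel recording
#'
#' Per channel: Gaussian broadband noise band-limited to `band` (a 4th
#' order Butterworth band-pass applied forward and backward), scaled by a
#' per-sample envelope equal to the channel's baseline sd times its gain
#' for the cue class active at that sample. Gains ramp linearly over
#' `ramp` seconds at class transitions, modelling reaction time.
#' Deterministic given `seed`.
#'
#' @param schedule A [make_cue_schedule()].
#' @param profile A [channel_profile()].
#' @param fs Sampling rate in Hz (default 30000).
#' @param band Pass band in Hz; the upper edge is capped at 0.45 fs.
#' @param ramp Transition ramp in seconds (default 0.2).
#' @param seed Integer seed.
#' @return A `neural_recording`: `signal` (channels x samples, microvolts),
#'   `fs`, `n_channels`, `schedule`, `profile`, `artifact_times` (empty),
#'   `seed`.
#' @export
generate_recording <- function(schedule, profile, fs = 30000,
                               band = c(200, 4000), ramp = 0.2, seed = 1) {
  stopifnot(inherits(schedule, "cue_schedule"),
            inherits(profile, "channel_profile"))
  n <- round(fs * schedule$total_duration)
  n_ch <- profile$n_channels
  classes <- colnames(profile$gains)
  # per-sample class mixture weights (samples x classes), linear ramps
  t_samp <- (seq_len(n) - 1) / fs
  ev <- schedule$events
  w <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  prev_label <- ev$label[1]
  for (e in seq_len(nrow(ev))) {
    lab <- ev$label[e]
    i0 <- round(ev$start[e] * fs) + 1L
    i1 <- if (e < nrow(ev)) round(ev$start[e + 1] * fs) else n
    if (i1 < i0) next
    seg <- i0:i1
    if (e == 1 || ramp <= 0) {
      w[seg, lab] <- w[seg, lab] + 1
    } else {
      nr <- min(length(seg), round(ramp * fs))
      frac <- c(seq_len(nr) / nr, rep(1, length(seg) - nr))
      w[seg, lab] <- w[seg, lab] + frac
      w[seg, prev_label] <- w[seg, prev_label] + (1 - frac)
    }
    prev_label <- lab
  }
  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  sig <- matrix(NA_real_, n_ch, n)
  with_seed(seed, {
    for (ch in seq_len(n_ch)) {
      noise <- stats::rnorm(n)
      carrier <- signal::filtfilt(bf, noise)
      # renormalize so the in-band carrier has unit sd
      carrier <- carrier / stats::sd(carrier)
      envelope <- profile$baseline_sd[ch] *
        as.vector(w %*% profile$gains[ch, ])
      sig[ch, ] <- carrier * envelope
    }
  })
  structure(list(signal = sig, fs = fs, n_channels = n_ch,
                 schedule = schedule, profile = profile,
                 artifact_times = numeric(0), band = c(band[1], hi),
                 seed = seed),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("Neural recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              x$n_channels, ncol(x$signal), ncol(x$signal) / x$fs, x$fs))
  cat(sprintf("  band %g-%g Hz, %d injected artifacts, seed %d\n",
              x$band[1], x$band[2], length(x$artifact_times), x$seed))
  invisible(x)
}

#' Inject rectangular stimulation artifacts
#'
#' During each stimulation epoch, monophasic rectangular deflections of the
#' given amplitude and width are added at the pulse rate to a random subset
#' of channels. Ground-truth pulse onset times are recorded in
#' `artifact_times`. Overlapping epochs are merged with a warning.
#'
#' @param rec A [neural_recording()].
#' @param stim_epochs List (or 2-column matrix) of `c(start, end)` epochs
#'   in seconds.
#' @param pulse_rate Pulses per second (default 50).
#' @param amplitude Deflection amplitude in microvolts; must exceed the
#'   500 uV detection threshold so excision is exercised.
#' @param affected_fraction Fraction of channels carrying the artifact.
#' @param pulse_width Pulse width in seconds (default 500 us).
#' @param seed Seed for the affected-channel draw.
#' @return The recording with artifacts added and `artifact_times` set.
#' @export
inject_artifacts <- function(rec, stim_epochs, pulse_rate = 50,
                             amplitude = 1000, affected_fraction = 0.9,
                             pulse_width = 500e-6, seed = 1) {
  stopifnot(inherits(rec, "neural_recording"))
  if (amplitude <= 500)
    stop("inject_artifacts: amplitude must exceed the 500 uV detection ",
         "threshold")
  if (is.matrix(stim_epochs))
    stim_epochs <- split(stim_epochs, seq_len(nrow(stim_epochs)))
  if (length(stim_epochs) == 0) return(rec)
  ep <- do.call(rbind, lapply(stim_epochs, function(e) e[1:2]))
  ep <- ep[order(ep[, 1]), , drop = FALSE]
  merged <- ep[1, , drop = FALSE]
  for (i in seq_len(nrow(ep))[-1]) {
    if (ep[i, 1] < merged[nrow(merged), 2]) {
      warning("inject_artifacts: overlapping stimulation epochs merged")
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], ep[i, 2])
    } else merged <- rbind(merged, ep[i, , drop = FALSE])
  }
  n <- ncol(rec$signal)
  fs <- rec$fs
  pw <- max(1L, round(pulse_width * fs))
  n_aff <- max(1L, round(affected_fraction * rec$n_channels))
  affected <- with_seed(seed, sample.int(rec$n_channels, n_aff))
  times <- numeric(0)
  for (i in seq_len(nrow(merged))) {
    pt <- seq(merged[i, 1], merged[i, 2] - 1 / pulse_rate,
              by = 1 / pulse_rate)
    times <- c(times, pt)
  }
  for (tt in times) {
    i0 <- round(tt * fs) + 1L
    i1 <- min(n, i0 + pw - 1L)
    if (i0 > n) next
    rec$signal[affected, i0:i1] <- rec$signal[affected, i0:i1] + amplitude
  }
  rec$artifact_times <- sort(c(rec$artifact_times, times))
  rec$affected_channels <- affected
  rec
}
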