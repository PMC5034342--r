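# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Reference oscillator trace (10 s at 1 ms)
fx_ref_trace <- function() {
  fixture("ref_trace", function() cpg_simulate(cpg_params(), duration = 10))
}

# A synthetic cpg_trace whose y_out is a square alternation at `freq` Hz.
# Quarter-period phase offset keeps the zero crossings off the 10 Hz
# update ticks, so sampled phases are always +/-1.
fx_square_trace <- function(freq = 2.5, duration = 12, dt = 0.001) {
  tt <- seq(0, duration, by = dt)
  tr <- data.frame(t = tt,
                   y_out = sign(sin(2 * pi * freq * tt + pi / 4)))
  attr(tr, "dt") <- dt
  class(tr) <- c("cpg_trace", "data.frame")
  tr
}

# Decoder-recovery fixture: contrast-2 synthetic recordings at desk scale
# (24 channels, 10 kHz), 6 training trials and 3 held-out trials per
# movement, MWP features labelled at bin midpoints, plus a trained bank.
fx_recovery <- function() {
  fixture("recovery", function() {
    fs <- 10000
    prof <- channel_profile(24, contrast = 2, seed = 3)
    mk <- function(n_trials, seed_s, seed_n) {
      sched <- make_cue_schedule(n_trials, seed = seed_s, lead_in = 3)
      rec <- generate_recording(sched, prof, fs = fs, seed = seed_n)
      baseline <- fit_baseline(rec$signal[, seq_len(3 * fs)], fs = fs)
      feats <- suppressMessages(
        compute_mwp(rec$signal, baseline, fs = fs))
      list(feats = feats, labels = label_bins(feats, sched),
           sched = sched, rec = rec, baseline = baseline)
    }
    train <- mk(6, 2, 4)
    test <- mk(3, 12, 14)
    bank <- train_decoders(train$feats, train$labels, seed = 8)
    list(train = train, test = test, bank = bank, profile = prof, fs = fs)
  })
}

# End-to-end pipeline run on the default demo configuration
fx_pipeline_run <- function() {
  fixture("pipeline_run", function() {
    dir <- file.path(tempdir(), "nb_accept_run")
    suppressMessages(run_pipeline(default_config(seed = 1), outdir = dir))
  })
}

# Independent brute-force arbitration reference
ref_arbitrate <- function(scores) {
  best <- NULL
  best_s <- 0
  for (m in names(scores)) {
    if (scores[[m]] > 0 && (is.null(best) || scores[[m]] > best_s)) {
      best <- m
      best_s <- scores[[m]]
    }
  }
  if (is.null(best)) "rest" else best
}

# Forward-Euler reference integrator for the oscillator (independent of
# the RK4 implementation path)
euler_cpg <- function(state, params, dt, n_sub) {
  s <- c(state$x1, state$v1, state$x2, state$v2)
  h <- dt / n_sub
  for (i in seq_len(n_sub)) {
    y1 <- max(0, s[1]); y2 <- max(0, s[3])
    ds <- c((-s[1] - params$beta * s[2] - params$mu21 * y2 + params$c) /
              params$tau1,
            (-s[2] + y1) / params$tau2,
            (-s[3] - params$beta * s[4] - params$mu12 * y1 + params$c) /
              params$tau1,
            (-s[4] + y2) / params$tau2)
    s <- s + h * ds
  }
  s
}
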