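# Frozen reference: stationary db4 detail coefficients of a 32-sample
# signal, computed once with an independent wavelet implementation.
test_that("stationary db4 transform matches the frozen reference", {
  x <- c(1.624345, -0.611756, -0.528172, -1.072969, 0.865408, -2.301539,
         1.744812, -0.761207, 0.319039, -0.24937, 1.462108, -2.060141,
         -0.322417, -0.384054, 1.133769, -1.099891, -0.172428, -0.877858,
         0.042214, 0.582815, -1.100619, 1.144724, 0.901591, 0.502494,
         0.900856, -0.683728, -0.12289, -0.935769, -0.267888, 0.530355,
         -0.691661, -0.396754)
  d <- swt_detail(x, 1:3)
  expect_equal(unname(d[1:8, "s1"]),
               c(-0.30735009, 1.79660687, -2.73001953, 2.63634783,
                 -1.50138783, 0.35401986, -0.45680126, 1.64613915),
               tolerance = 1e-7)
  expect_equal(unname(d[1:8, "s2"]),
               c(-0.4022185, 0.38409107, 0.93316277, -0.25842057,
                 -0.03087061, 1.09080383, -0.34680187, -1.88952184),
               tolerance = 1e-7)
  expect_equal(unname(d[1:8, "s3"]),
               c(0.83944367, 0.81765493, 0.443268, 0.02791229,
                 -0.28620019, -0.39410984, -0.1192913, 0.0723856),
               tolerance = 1e-7)
})

test_that("dyadic band edges bracket the multiunit band at 30 kHz", {
  expect_equal(unname(wavelet_band_edges(30000, 3)), c(1875, 3750))
  e6 <- wavelet_band_edges(30000, 6)
  expect_equal(unname(e6), c(234.375, 468.75))
  expect_identical(floor(e6[["low"]]), 234)
  expect_equal(unname(wavelet_band_edges(1000, 1)), c(250, 500))
})

test_that("coincidence detector finds injected pulses and honours 4-of-12", {
  fs <- 1000
  set.seed(31)
  sig <- matrix(rnorm(16 * 4000, sd = 10), 16, 4000)
  truth <- c(0.5, 1.2, 2.8)
  for (tt in truth) {
    i <- round(tt * fs) + 1
    sig[1:14, i] <- sig[1:14, i] + 1000
  }
  det <- detect_artifacts(sig, artifact_config(monitor_seed = 2), fs = fs)
  expect_length(det, 3L)
  expect_true(all(abs(det - truth) < 2.5e-3))
  # same pulses on only 3 channels: below the 4-of-12 coincidence rule
  sig3 <- matrix(rnorm(16 * 4000, sd = 10), 16, 4000)
  for (tt in truth) {
    i <- round(tt * fs) + 1
    sig3[1:3, i] <- sig3[1:3, i] + 1000
  }
  det3 <- detect_artifacts(sig3, artifact_config(monitor_seed = 2),
                           fs = fs)
  expect_length(det3, 0L)
})

test_that("detector recall and precision reach 0.99 at twice threshold", {
  sched <- make_cue_schedule(1, movements = "flexion", seed = 2,
                             dur_range = c(4, 4), lead_in = 2)
  prof <- channel_profile(16, contrast = 1, seed = 1)
  rec <- generate_recording(sched, prof, fs = 10000, seed = 9)
  rec <- inject_artifacts(rec, list(c(2, 5.5)), pulse_rate = 50,
                          amplitude = 1000, affected_fraction = 0.9,
                          seed = 3)
  det <- detect_artifacts(rec, artifact_config(monitor_seed = 6))
  truth <- rec$artifact_times
  tol <- 2.5e-3
  hit <- vapply(truth, function(tt) any(abs(det - tt) <= tol), logical(1))
  matched <- vapply(det, function(d) any(abs(truth - d) <= tol), logical(1))
  expect_gte(mean(hit), 0.99)       # recall
  expect_gte(mean(matched), 0.99)   # precision
})

test_that("50 Hz pulse excision retains exactly 87.5% of the samples", {
  fs <- 30000
  sig <- matrix(0, 2, 2 * fs)
  times <- seq(0.01, 1.99, by = 0.02)  # 100 pulses, all interior
  exc <- excise_artifacts(sig, times, window = 2.5e-3, fs = fs)
  expect_identical(exc$retained_fraction, 0.875)
  expect_identical(ncol(exc$signal), as.integer(2 * fs * 0.875))
})

test_that("excision handles empty, overlapping and invalid inputs", {
  fs <- 1000
  sig <- matrix(seq_len(3000), 1, 3000)
  none <- excise_artifacts(sig, numeric(0), fs = fs)
  expect_identical(none$retained_fraction, 1.0)
  expect_identical(none$signal, sig)
  expect_error(excise_artifacts(sig, 5.0, fs = fs), "span")
  expect_error(excise_artifacts(sig, 1.0, window = 4, fs = fs),
               "shorter")
})

test_that("two pulses 1 ms apart merge into a single 3.5 ms excision", {
  fs <- 30000
  sig <- matrix(0, 1, 3000)
  two <- excise_artifacts(sig, c(0.05, 0.051), window = 2.5e-3, fs = fs)
  # hand count: 75-sample windows centred 30 samples apart overlap,
  # union spans 75 + 30 = 105 samples = 3.5 ms
  expect_identical(3000L - length(two$sample_map), 105L)
  expect_true(all(diff(two$sample_map) >= 1))
})

test_that("excision sample map realigns bins to wall-clock time", {
  fs <- 1000
  sig <- matrix(rnorm(1 * 5000), 1, 5000)
  exc <- excise_artifacts(sig, c(1.0, 1.5, 2.0), window = 0.1, fs = fs)
  expect_equal(exc$retained_fraction,
               length(exc$sample_map) / 5000)
  # mapped indices are strictly increasing originals
  expect_true(all(diff(exc$sample_map) >= 1))
  expect_identical(sig[1, exc$sample_map], exc$signal[1, ])
})

test_that("baseline standardization closes on held-out noise", {
  # long segments so the per-channel mean of the held-out standardized
  # MWP concentrates well inside +/- 0.1 bin-sd units
  fs <- 1000
  set.seed(5)
  sig <- matrix(rnorm(1000 * fs, sd = 8), 1)
  base <- fit_baseline(sig[, seq_len(500 * fs), drop = FALSE], fs = fs)
  feats <- compute_mwp(sig[, (500 * fs + 1):(1000 * fs), drop = FALSE],
                       base, fs = fs)
  expect_lt(max(abs(colMeans(feats$features))), 0.1)
})

test_that("baseline errors on degenerate input and scales linearly", {
  fs <- 2000
  expect_error(fit_baseline(matrix(0, 1, fs), fs = fs), "zero")
  expect_error(fit_baseline(matrix(1, 1, fs / 2), fs = fs), "1 s")
  set.seed(6)
  x <- matrix(rnorm(4 * fs), 1)
  b1 <- fit_baseline(x, fs = fs)
  b2 <- fit_baseline(2 * x, fs = fs)
  expect_equal(b2$sd, 2 * b1$sd, tolerance = 0.05)
  expect_equal(b2$mean, 2 * b1$mean, tolerance = 1e-10)
})

test_that("MWP yields one value per channel per 100 ms and kills DC", {
  fs <- 2000
  set.seed(8)
  sig <- matrix(rnorm(3 * 5 * fs), 3)
  base <- fit_baseline(sig[, seq_len(2 * fs)], fs = fs)
  feats <- compute_mwp(sig[, (2 * fs + 1):(5 * fs)], base, fs = fs)
  expect_identical(dim(feats$features), c(30L, 3L))
  shifted <- compute_mwp(sig[, (2 * fs + 1):(5 * fs)] + 100, base,
                         fs = fs)
  expect_equal(shifted$features, feats$features, tolerance = 1e-8)
  # bin count is exactly floor(samples / (fs * 0.1))
  odd <- suppressMessages(
    compute_mwp(sig[, 1:(2 * fs + 57)], base, fs = fs))
  expect_identical(nrow(odd$features),
                   as.integer(floor((2 * fs + 57) / (fs * 0.1))))
})

test_that("narrow-band power raises MWP only on the injected channel", {
  fs <- 10000
  set.seed(9)
  sig <- matrix(rnorm(4 * 6 * fs, sd = 5), 4)
  base <- fit_baseline(sig[, seq_len(3 * fs)], fs = fs)
  post <- sig[, (3 * fs + 1):(6 * fs)]
  ctrl <- compute_mwp(post, base, fs = fs)
  tt <- seq_len(ncol(post)) / fs
  post[2, ] <- post[2, ] + 10 * sin(2 * pi * 300 * tt)
  feats <- compute_mwp(post, base, fs = fs)
  shift <- colMeans(feats$features) - colMeans(ctrl$features)
  expect_gt(shift[2], 1)
  expect_lt(max(abs(shift[-2])), 0.2)
})

test_that("boxcar smoothing has the defining impulse and step responses", {
  const <- matrix(2, 25, 3)
  expect_equal(boxcar_smooth(const, width = 1, bin_width = 0.1), const)
  imp <- matrix(0, 30, 1); imp[11, 1] <- 1
  sm <- boxcar_smooth(imp, width = 1, bin_width = 0.1)
  expect_equal(sm[11:20, 1], rep(0.1, 10))
  expect_equal(sm[21, 1], 0)
  stepm <- matrix(rep(c(0, 1), c(15, 15)), 30, 1)
  sms <- boxcar_smooth(stepm, width = 1, bin_width = 0.1)
  half_rise <- which(sms[, 1] >= 0.5)[1] - 15
  expect_lte(abs(half_rise - 5), 1)
  expect_error(boxcar_smooth(imp, width = 0.25, bin_width = 0.1),
               "multiple")
})
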