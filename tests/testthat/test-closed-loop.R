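test_that("stimulation encoding maps decisions to modes and phase", {
  expect_identical(encode_stimulation("rest", 5)$mode, "off")
  expect_identical(encode_stimulation("flexion")$mode, "flexion_static")
  expect_identical(encode_stimulation("extension")$mode,
                   "extension_static")
  w <- encode_stimulation("wiggle", -3.2)
  expect_identical(w$mode, "cpg_alternating")
  expect_identical(w$phase, -1)
  expect_error(encode_stimulation("jump"), "unknown")
})

test_that("a 2.5 Hz alternation spans 2 update ticks per half-cycle", {
  tr <- fx_square_trace(2.5)
  ticks <- seq(0, 2 - 0.1, by = 0.1)  # 10 Hz updates over 2 s
  phases <- vapply(ticks, function(tt) {
    y <- tr$y_out[round(tt / attr(tr, "dt")) + 1]
    encode_stimulation("wiggle", y)$phase
  }, numeric(1))
  runs <- rle(phases)
  expect_true(all(runs$lengths == 2))
  # 5 full cycles in 2 s at 2.5 Hz
  expect_identical(sum(runs$values > 0), 5L)
})

test_that("plant holds at rest and saturates under static drive", {
  off <- encode_stimulation("rest")
  st <- plant_state()
  for (i in 1:20) st <- plant_step(off, st, 0.05)
  expect_identical(st$thumb_pos, 0)
  flex <- encode_stimulation("flexion")
  st <- plant_state()
  for (i in 1:100) st <- plant_step(flex, st, 0.01)  # 1 s = 5 tau
  expect_gte(abs(st$thumb_pos), 0.95)
  expect_identical(sign(st$thumb_pos), -1)
})

test_that("plant follows an alternating command at the drive frequency", {
  f <- 2.5
  fps <- 120
  st <- plant_state()
  pos <- numeric(6 * fps)
  for (k in seq_along(pos)) {
    phase <- sign(sin(2 * pi * f * (k - 1) / fps)) + 1e-9
    cmd <- encode_stimulation("wiggle", phase)
    st <- plant_step(cmd, st, 1 / fps)
    pos[k] <- st$thumb_pos
  }
  pos <- pos[-(1:fps)]
  spec <- Mod(stats::fft(pos - mean(pos)))[seq_len(length(pos) %/% 2)]
  f_dom <- which.max(spec[-1]) / (length(pos) / fps)
  expect_equal(f_dom, f, tolerance = fps / length(pos) + 1e-9)
  # exact steady state of a first-order lag under a +/-1 square drive
  # with half-period T/2: peak = tanh(T / (4 tau)), well inside the poles
  peak <- tanh((1 / f / 2) / (2 * 0.2))
  expect_equal(max(abs(pos)), peak, tolerance = 0.1)
  expect_gt(diff(range(pos)), 0.2)
})

test_that("the trajectory classifier recognises scripted movements", {
  vc <- train_video_classifier(fx_square_trace(2.5), seed = 1)
  expect_identical(classify_movement(rep(0, 24), vc)[24], "rest")
  expect_identical(classify_movement(rep(-1, 24), vc)[24], "flexion")
  expect_identical(classify_movement(rep(1, 24), vc)[24], "extension")
  # scripted 2.5 Hz oscillation: wiggle on >= 90% of frames after 0.5 s
  fps <- 12
  st <- plant_state()
  pos <- numeric(5 * fps)
  for (k in seq_along(pos)) {
    phase <- sign(sin(2 * pi * 2.5 * (k - 1) / fps)) + 1e-9
    st <- plant_step(encode_stimulation("wiggle", phase), st, 1 / fps)
    pos[k] <- st$thumb_pos
  }
  lab <- classify_movement(pos, vc)
  expect_gte(mean(lab[(0.5 * fps + 1):length(lab)] == "wiggle"), 0.9)
  expect_warning(classify_movement(rep(0, 3), vc), "shorter")
})

test_that("frame evaluation scores perfect and degenerate labellings", {
  sched <- make_cue_schedule(2, seed = 21)
  fps <- 12
  n <- ceiling(sched$total_duration * fps)
  lag <- 1.2
  shift <- round(lag * fps)
  cue <- cue_at(sched, (seq_len(n) - 0.5) / fps)
  # labels that equal the cue delayed by exactly the scored lag
  delayed <- c(rep("rest", shift), cue)[seq_len(n)]
  rep_perfect <- evaluate_frames(delayed, sched, lag = lag, fps = fps)
  expect_equal(rep_perfect$overall_accuracy, 1.0)
  expect_equal(rep_perfect$sensitivity, 1.0)
  expect_equal(rep_perfect$specificity, 1.0)
  all_rest <- evaluate_frames(rep("rest", n), sched, lag = lag,
                              fps = fps)
  expect_equal(all_rest$specificity, 1.0)
  for (m in names(all_rest$per_movement))
    expect_equal(all_rest$per_movement[[m]]$sensitivity, 0)
  expect_error(evaluate_frames(rep("rest", 5), sched, lag = 10,
                               fps = 1), "lag")
})

test_that("evaluation metrics match a hand-counted confusion matrix", {
  sched <- list(events = data.frame(label = c("flexion", "rest"),
                                    start = c(0, 1), duration = c(1, 1)),
                total_duration = 2, movements = "flexion")
  class(sched) <- "cue_schedule"
  # 20 frames at 10 fps, no lag; cue = 10 flexion then 10 rest
  labels <- c(rep("flexion", 8), rep("rest", 2),   # 8 hits, 2 miss
              rep("rest", 9), "flexion")           # 9 hits, 1 false alarm
  r <- evaluate_frames(labels, sched, lag = 0, fps = 10)
  expect_equal(r$overall_accuracy, 17 / 20)
  expect_equal(r$sensitivity, 8 / 10)
  expect_equal(r$specificity, 9 / 10)
  expect_equal(r$per_movement$flexion$accuracy, 17 / 20)
})

test_that("permutation test: near-exact on perfect labels, calibrated null", {
  sched <- make_cue_schedule(3, seed = 22)
  fps <- 12
  n <- ceiling(sched$total_duration * fps)
  cue <- cue_at(sched, (seq_len(n) - 0.5) / fps)
  pt <- permutation_test(cue, sched, n_perm = 999, seed = 1, lag = 0,
                         fps = fps)
  expect_lte(pt$p_value, 2 / 1000)
  # null labels: p should be roughly uniform, rarely below 0.05
  ps <- vapply(1:20, function(sd) {
    null_lab <- with_seed(sd, {
      perm <- sched
      mov <- which(perm$events$label != "rest")
      perm$events$label[mov] <- sample(perm$events$label[mov])
      cue_at(perm, (seq_len(n) - 0.5) / fps)
    })
    permutation_test(null_lab, sched, n_perm = 199, seed = sd + 100,
                     lag = 0, fps = fps)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_gte(stats::median(ps), 0.2)
})

test_that("cue/MWP correlations single out tuned channels", {
  fx <- fx_recovery()
  cc <- cue_mwp_correlation(fx$test$feats, fx$test$sched, n_boot = 400,
                            seed = 9)
  wig_ch <- tuned_channels(fx$profile, "wiggle")
  other <- setdiff(seq_len(24), unlist(lapply(
    c("flexion", "extension", "wiggle"),
    function(m) tuned_channels(fx$profile, m))))
  expect_gt(min(cc$r["wiggle", wig_ch]),
            max(cc$r["wiggle", other]))
  # tuned channels separate wiggle from flexion with bootstrap p < 0.05
  p_wf <- cc$diff_p[["flexion_vs_wiggle"]]
  if (is.null(p_wf)) p_wf <- cc$diff_p[["wiggle_vs_flexion"]]
  expect_true(all(p_wf[wig_ch] < 0.05))
})

test_that("a channel equal to the cue vector has correlation one", {
  sched <- make_cue_schedule(2, seed = 23)
  bins <- floor(sched$total_duration / 0.1)
  mid <- (seq_len(bins) - 0.5) * 0.1
  cue <- as.numeric(cue_at(sched, mid) == "flexion")
  set.seed(3)
  feats <- structure(list(features = cbind(cue, rnorm(bins)),
                          bin_mid_times = mid, bin_width = 0.1,
                          scales = 3:6, fs = 1000),
                     class = "mwp_features")
  cc <- cue_mwp_correlation(feats, sched, n_boot = 200, seed = 2)
  expect_equal(unname(cc$r["flexion", 1]), 1, tolerance = 1e-10)
  expect_lt(abs(cc$r["flexion", 2]), 0.3)
})

test_that("closed-loop wiggle drives the plant at the oscillator rhythm", {
  fx <- fx_recovery()
  tr <- fx_square_trace(2.5)
  # feature stream decided wiggle throughout: take real wiggle bins
  wig <- which(fx$test$labels == "wiggle")
  n_rep <- 60
  idx <- rep(wig[10:19], length.out = n_rep)
  feats <- fx$test$feats
  feats$features <- feats$features[idx, , drop = FALSE]
  feats$bin_mid_times <- (seq_len(n_rep) - 0.5) * 0.1
  run <- run_closed_loop(feats, fx$bank, tr)
  traj <- run$trajectory$thumb_pos
  traj <- traj[-(1:12)]
  spec <- Mod(stats::fft(traj - mean(traj)))[seq_len(length(traj) %/% 2)]
  f_dom <- which.max(spec[-1]) / (length(traj) / 12)
  expect_equal(f_dom, 2.5, tolerance = 12 / length(traj) + 1e-9)
})
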