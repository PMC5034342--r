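#' Stimulation-artifact detection configuration
#'
#' Artifacts are flagged when the absolute signal crosses `threshold` within
#' the same short window on at least `n_required` of `n_monitor` randomly
#' selected channels; flagged times are deduplicated within one excision
#' window.
#'
#' @param threshold Crossing threshold in microvolts (default 500).
#' @param n_monitor Number of monitored channels (default 12), drawn once
#'   per run from `monitor_seed`.
#' @param n_required Minimum simultaneous channels (default 4).
#' @param window Excision window in seconds (default 2.5 ms), also the
#'   deduplication span.
#' @param simultaneity Span in seconds within which crossings on different
#'   channels count as simultaneous (default 0.5 ms).
#' @param monitor_seed Seed for the monitored-channel draw.
#' @return An `artifact_config` list.
#' @export
artifact_config <- function(threshold = 500, n_monitor = 12, n_required = 4,
                            window = 2.5e-3, simultaneity = 0.5e-3,
                            monitor_seed = 1) {
  if (n_required > n_monitor)
    stop("artifact_config: n_required must be <= n_monitor")
  if (window <= 0 || simultaneity <= 0)
    stop("artifact_config: window and simultaneity must be > 0")
  structure(list(threshold = threshold, n_monitor = as.integer(n_monitor),
                 n_required = as.integer(n_required), window = window,
                 simultaneity = simultaneity,
                 monitor_seed = as.integer(monitor_seed)),
            class = "artifact_config")
}

#' Detect stimulation artifacts
#'
#' Implements the multi-channel coincidence rule: a sample is flagged when
#' the absolute signal has crossed `threshold` within the trailing
#' simultaneity window on at least `n_required` of the monitored channels.
#' Flags are deduplicated so that at most one detection falls within each
#' excision window.
#'
#' @param rec A [neural_recording()] or a channels x samples matrix.
#' @param cfg An [artifact_config()].
#' @param fs Sampling rate, taken from `rec` when it is a recording.
#' @return Numeric vector of detection times in seconds.
#' @export
detect_artifacts <- function(rec, cfg = artifact_config(), fs = NULL) {
  sig <- if (inherits(rec, "neural_recording")) rec$signal else rec
  if (is.null(fs)) {
    if (!inherits(rec, "neural_recording"))
      stop("detect_artifacts: fs required when rec is a bare matrix")
    fs <- rec$fs
  }
  n_ch <- nrow(sig)
  if (n_ch < cfg$n_monitor)
    stop("detect_artifacts: recording has ", n_ch,
         " channels, fewer than n_monitor = ", cfg$n_monitor)
  monitored <- with_seed(cfg$monitor_seed, sample.int(n_ch, cfg$n_monitor))
  w <- max(1L, round(cfg$simultaneity * fs))
  n <- ncol(sig)
  counts <- integer(n)
  for (ch in monitored) {
    crossed <- abs(sig[ch, ]) >= cfg$threshold
    # TRUE if a crossing occurred within the trailing w samples
    recent <- stats::filter(as.numeric(crossed), rep(1, w), sides = 1)
    recent[is.na(recent)] <- cumsum(crossed)[seq_len(w - 1)]
    counts <- counts + (recent > 0)
  }
  flagged <- which(counts >= cfg$n_required)
  if (length(flagged) == 0) return(numeric(0))
  dedup_span <- round(cfg$window * fs)
  keep <- flagged[1]
  last <- flagged[1]
  for (i in flagged[-1]) {
    if (i - last >= dedup_span) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1) / fs
}

#' Excise artifact windows and rejoin the signal
#'
#' Deletes a window centred on each detection time on all channels,
#' merging overlapping windows, and concatenates the remaining segments.
#' The returned sample-index map gives, for each retained sample, its
#' index in the original recording, so downstream bins can be re-aligned
#' to wall-clock time.
#'
#' @param rec A [neural_recording()] or a channels x samples matrix.
#' @param times Detection times in seconds.
#' @param window Excision window length in seconds (default 2.5 ms).
#' @param fs Sampling rate, taken from `rec` when it is a recording.
#' @return List with `signal` (cleaned channels x samples matrix),
#'   `sample_map` (integer vector of original sample indices), and
#'   `retained_fraction`.
#' @export
excise_artifacts <- function(rec, times, window = 2.5e-3, fs = NULL) {
  sig <- if (inherits(rec, "neural_recording")) rec$signal else rec
  if (is.null(fs)) {
    if (!inherits(rec, "neural_recording"))
      stop("excise_artifacts: fs required when rec is a bare matrix")
    fs <- rec$fs
  }
  n <- ncol(sig)
  if (round(window * fs) >= n)
    stop("excise_artifacts: window is not shorter than the recording")
  if (any(times < 0 | times > (n - 1) / fs))
    stop("excise_artifacts: times outside the recording span")
  keep <- rep(TRUE, n)
  half <- floor(round(window * fs) / 2)
  w <- round(window * fs)
  for (tt in times) {
    centre <- round(tt * fs) + 1L
    lo <- max(1L, centre - half)
    hi <- min(n, lo + w - 1L)
    keep[lo:hi] <- FALSE
  }
  sample_map <- which(keep)
  list(signal = sig[, keep, drop = FALSE],
       sample_map = sample_map,
       retained_fraction = length(sample_map) / n)
}

bin_means <- function(v, samples_per_bin) {
  n_bins <- floor(length(v) / samples_per_bin)
  if (n_bins == 0) stop("bin_means: fewer samples than one bin")
  m <- matrix(v[seq_len(n_bins * samples_per_bin)], nrow = samples_per_bin)
  colMeans(m)
}

#' Fit per-channel, per-scale baseline statistics from a rest segment
#'
#' The mean absolute detail coefficient is computed in 100 ms bins for each
#' channel and scale over a rest-period segment; the mean and standard
#' deviation of those bin values are the standardization constants applied
#' by [compute_mwp()].
#'
#' @param rest_signal Channels x samples matrix of rest-period raw signal.
#' @param fs Sampling rate in Hz.
#' @param scales Detail scales used (default 3:6, the multiunit band at
#'   30 kHz).
#' @param bin_width Bin width in seconds (default 0.1).
#' @return An `mwp_baseline` list with `mean` and `sd` matrices
#'   (channels x scales), plus `fs`, `scales`, `bin_width`.
#' @export
fit_baseline <- function(rest_signal, fs, scales = 3:6, bin_width = 0.1) {
  if (!is.matrix(rest_signal)) rest_signal <- matrix(rest_signal, nrow = 1)
  if (ncol(rest_signal) < fs)
    stop("fit_baseline: rest segment must be at least 1 s long")
  n_ch <- nrow(rest_signal)
  spb <- round(bin_width * fs)
  mu <- sdv <- matrix(NA_real_, n_ch, length(scales),
                      dimnames = list(NULL, paste0("s", scales)))
  for (ch in seq_len(n_ch)) {
    x <- rest_signal[ch, ]
    if (all(x == 0))
      stop("fit_baseline: channel ", ch, " is identically zero; ",
           "cannot standardize")
    d <- abs(swt_detail(x, scales))
    for (j in seq_along(scales)) {
      b <- bin_means(d[, j], spb)
      mu[ch, j] <- mean(b)
      sdv[ch, j] <- stats::sd(b)
    }
  }
  if (any(sdv < .Machine$double.eps)) {
    warning("fit_baseline: some baseline sds are ~0; flooring at machine ",
            "epsilon")
    sdv[sdv < .Machine$double.eps] <- .Machine$double.eps
  }
  structure(list(mean = mu, sd = sdv, fs = fs, scales = scales,
                 bin_width = bin_width, n_channels = n_ch),
            class = "mwp_baseline")
}

#' Compute mean-wavelet-power (MWP) features
#'
#' Per 100 ms bin and channel: the absolute stationary db4 detail
#' coefficients at the selected scales are averaged within the bin,
#' standardized per channel and scale against the baseline statistics, and
#' the scales are averaged, giving one value per channel per bin (96 values
#' per 100 ms for a 96-channel recording). An incomplete trailing bin is
#' dropped with a message.
#'
#' @param signal Channels x samples matrix (cleaned, artifact-excised).
#' @param baseline An [fit_baseline()] result with matching channel count.
#' @param sample_map Optional integer vector mapping retained samples to
#'   original sample indices (from [excise_artifacts()]); used to compute
#'   wall-clock bin midpoints.
#' @param fs Sampling rate; defaults to the baseline's.
#' @return An `mwp_features` object: matrix `features` (bins x channels),
#'   `bin_mid_times` (wall-clock midpoint of each bin, seconds),
#'   `bin_width`, `scales`.
#' @export
compute_mwp <- function(signal, baseline, sample_map = NULL, fs = NULL) {
  stopifnot(inherits(baseline, "mwp_baseline"))
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (is.null(fs)) fs <- baseline$fs
  n_ch <- nrow(signal)
  if (n_ch != baseline$n_channels)
    stop("compute_mwp: signal has ", n_ch, " channels but baseline has ",
         baseline$n_channels)
  spb <- round(baseline$bin_width * fs)
  n <- ncol(signal)
  n_bins <- floor(n / spb)
  if (n_bins == 0) stop("compute_mwp: signal shorter than one bin")
  if (n %% spb != 0)
    message("compute_mwp: dropping incomplete trailing bin (",
            n %% spb, " samples)")
  scales <- baseline$scales
  feats <- matrix(NA_real_, n_bins, n_ch)
  for (ch in seq_len(n_ch)) {
    d <- abs(swt_detail(signal[ch, ], scales))
    z <- matrix(NA_real_, n_bins, length(scales))
    for (j in seq_along(scales))
      z[, j] <- (bin_means(d[, j], spb) - baseline$mean[ch, j]) /
        baseline$sd[ch, j]
    feats[, ch] <- rowMeans(z)
  }
  colnames(feats) <- sprintf("ch%03d", seq_len(n_ch))
  if (is.null(sample_map)) sample_map <- seq_len(n)
  mid_idx <- pmin(length(sample_map),
                  round((seq_len(n_bins) - 0.5) * spb))
  structure(list(features = feats,
                 bin_mid_times = (sample_map[mid_idx] - 1) / fs,
                 bin_width = baseline$bin_width, scales = scales,
                 fs = fs),
            class = "mwp_features")
}

#' @export
print.mwp_features <- function(x, ...) {
  cat(sprintf("MWP features: %d bins x %d channels (%.0f ms bins, scales %s)\n",
              nrow(x$features), ncol(x$features), x$bin_width * 1000,
              paste(x$scales, collapse = ",")))
  invisible(x)
}

#' Causal boxcar smoothing of MWP features
#'
#' Trailing moving average over `width` seconds of bins (10 bins for the
#' default 1 s boxcar on 100 ms bins); the first bins average over the
#' available history only. Introduces a group delay of about `width / 2`.
#'
#' @param m An `mwp_features` object or a bins x channels matrix.
#' @param width Boxcar width in seconds; must be a multiple of the bin
#'   width.
#' @param bin_width Bin width when `m` is a bare matrix.
#' @return Same type as `m`, smoothed.
#' @export
boxcar_smooth <- function(m, width = 1, bin_width = NULL) {
  is_obj <- inherits(m, "mwp_features")
  feats <- if (is_obj) m$features else m
  bw <- if (is_obj) m$bin_width else bin_width
  if (is.null(bw)) stop("boxcar_smooth: bin_width required for a matrix")
  k <- width / bw
  if (abs(k - round(k)) > 1e-9)
    stop("boxcar_smooth: width must be a multiple of the bin width")
  k <- round(k)
  cs <- apply(rbind(0, feats), 2, cumsum)
  n <- nrow(feats)
  lo <- pmax(0, seq_len(n) - k)
  sm <- (cs[seq_len(n) + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) /
    (seq_len(n) - lo)
  dimnames(sm) <- dimnames(feats)
  if (is_obj) {
    m$features <- sm
    m
  } else sm
}

#' Label feature bins by the cue active at their wall-clock midpoint
#'
#' @param features An `mwp_features` object.
#' @param schedule A [make_cue_schedule()] result.
#' @return Character vector of labels, one per bin.
#' @export
label_bins <- function(features, schedule) {
  stopifnot(inherits(features, "mwp_features"),
            inherits(schedule, "cue_schedule"))
  cue_at(schedule, features$bin_mid_times)
}

#' Write MWP features (plus labels) to CSV
#'
#' @param features An `mwp_features` object.
#' @param path Output CSV path.
#' @param labels Optional per-bin labels.
#' @return `path`, invisibly.
#' @export
write_mwp_csv <- function(features, path, labels = NULL) {
  df <- data.frame(bin_mid_s = features$bin_mid_times,
                   features$features, check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
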