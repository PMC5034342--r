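# Stationary (undecimated) wavelet transform, db4, periodic boundary.
#
# The a-trous cascade keeps one coefficient per sample at every scale, so
# 100 ms feature bins contain the same number of coefficients at every
# scale. Filters at level j are the base 8-tap db4 pair upsampled by
# 2^(j-1); only the 8 nonzero taps are ever touched, so each level costs 8
# vectorized passes over the signal. Output is aligned to advance by half
# the upsampled filter length, matching the usual SWT convention.

# db4 decomposition filters (Daubechies, 4 vanishing moments, 8 taps)
DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.02798376941698385, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523)
DB4_HI <- c(-0.23037781330885523, 0.7148465705525415,
            -0.6308807679295904, -0.02798376941698385,
            0.18703481171888114, 0.030841381835986965,
            -0.03288301166698295, -0.010597401784997278)

# circular left-rotation: y[i] = a[((i-1+s) mod n)+1]
rotate_left <- function(a, s) {
  n <- length(a)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(a)
  c(a[(s + 1):n], a[1:s])
}

# circular convolution of `a` with the level-j a-trous filter `f`
# (8 taps at stride 2^(j-1)), output advanced by half the filter span
atrous_filter <- function(a, f, stride) {
  n <- length(a)
  advance <- 4L * stride
  acc <- numeric(n)
  for (k in 0:7)
    acc <- acc + f[k + 1] * rotate_left(a, advance - k * stride)
  acc
}

#' Stationary db4 detail coefficients
#'
#' Undecimated wavelet detail coefficients of a signal at the requested
#' dyadic scales, one coefficient per sample per scale, with periodic
#' boundary handling. Scale `j` nominally covers the band
#' `(fs / 2^(j+1), fs / 2^j)`.
#'
#' @param x Numeric signal vector.
#' @param scales Integer vector of detail scales to return (e.g. `3:6`).
#' @return Matrix `length(x)` x `length(scales)`, columns named `s<j>`.
#' @export
swt_detail <- function(x, scales = 3:6) {
  scales <- sort(as.integer(scales))
  if (any(scales < 1)) stop("swt_detail: scales must be >= 1")
  n <- length(x)
  if (n < 8L * 2L^(max(scales) - 1L))
    stop("swt_detail: signal shorter than the level-", max(scales),
         " filter span")
  out <- matrix(NA_real_, n, length(scales),
                dimnames = list(NULL, paste0("s", scales)))
  a <- x
  for (j in seq_len(max(scales))) {
    stride <- 2L^(j - 1L)
    if (j %in% scales)
      out[, paste0("s", j)] <- atrous_filter(a, DB4_HI, stride)
    if (j < max(scales))
      a <- atrous_filter(a, DB4_LO, stride)
  }
  out
}

#' Nominal frequency band of a dyadic detail scale
#'
#' @param fs Sampling rate in Hz.
#' @param level Detail scale (>= 1).
#' @return `c(low, high)` in Hz: `(fs / 2^(level+1), fs / 2^level)`. At
#'   30 kHz, scales 3 and 6 give 3750 Hz (upper) and ~234 Hz (lower),
#'   bracketing the multiunit band.
#' @export
wavelet_band_edges <- function(fs, level) {
  if (fs <= 0) stop("wavelet_band_edges: fs must be > 0")
  if (level < 1) stop("wavelet_band_edges: level must be >= 1")
  c(low = fs / 2^(level + 1), high = fs / 2^level)
}
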