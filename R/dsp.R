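## Zero-phase FFT-domain filtering, analytic signals and small DSP helpers.
## Everything here operates on uniformly sampled real vectors.

#' Raised-cosine band-pass gain vector for an FFT of length `n`
#'
#' Builds the two-sided frequency response of a zero-phase band-pass filter:
#' unit gain on `[f_lo, f_hi]`, raised-cosine roll-off of width `trans_lo`
#' below the band and `trans_hi` above it, zero elsewhere. Applying this gain
#' to an FFT and inverting realises an exactly zero-phase filter (the response
#' is real and even in frequency), which matters here because downstream
#' latencies are of the order of one sample period.
#'
#' @param n signal length in samples.
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi passband edges in Hz. `f_lo = 0` gives a low-pass.
#' @param trans_lo,trans_hi transition widths in Hz below/above the passband.
#' @return numeric vector of length `n` with gains in `[0, 1]`.
#' @keywords internal
band_gain <- function(n, fs, f_lo, f_hi, trans_lo, trans_hi) {
  stopifnot(n >= 2, fs > 0, f_hi > f_lo, f_hi + trans_hi <= fs / 2 + 1e-9)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # fold to [0, fs/2]
  g <- numeric(n)
  g[f >= f_lo & f <= f_hi] <- 1
  if (trans_lo > 0) {
    lo <- f_lo - trans_lo
    i <- f > lo & f < f_lo
    g[i] <- 0.5 * (1 - cos(pi * (f[i] - lo) / trans_lo))
  }
  if (trans_hi > 0) {
    hi <- f_hi + trans_hi
    i <- f > f_hi & f < hi
    g[i] <- 0.5 * (1 + cos(pi * (f[i] - f_hi) / trans_hi))
  }
  g
}

#' Apply a frequency-domain gain to a real signal (zero-phase filter)
#'
#' @param x real signal.
#' @param gain gain vector from [band_gain()] of the same length.
#' @return filtered real signal, same length as `x`.
#' @keywords internal
apply_gain <- function(x, gain) {
  stopifnot(length(x) == length(gain))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / length(x)
}

#' Zero-phase raised-cosine band-pass filter
#' @inheritParams band_gain
#' @param x real signal.
#' @return filtered signal of the same length.
#' @keywords internal
band_filter <- function(x, fs, f_lo, f_hi, trans_lo, trans_hi) {
  apply_gain(x, band_gain(length(x), fs, f_lo, f_hi, trans_lo, trans_hi))
}

#' Analytic signal via the frequency-domain Hilbert transform
#' @param x real signal.
#' @return complex vector; `Mod()` is the envelope, `Arg()` the phase.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Unwrap a phase sequence (remove 2*pi jumps)
#' @param p phase in radians.
#' @keywords internal
unwrap_phase <- function(p) {
  d <- diff(p)
  cumsum(c(p[1], d - 2 * pi * round(d / (2 * pi))))
}

#' Decimate a signal by an integer factor after anti-alias low-pass filtering
#'
#' All physiological content handled by this package lives below ~1 Hz, so the
#' 54 Hz device rate is heavily oversampled; model fitting runs on a decimated
#' grid for speed without losing timing precision (fitted onsets are continuous
#' parameters, not grid indices).
#'
#' @param x real signal.
#' @param fs sampling rate in Hz.
#' @param factor integer decimation factor.
#' @return list with `x` (decimated signal), `fs` (new rate), `t` (sample
#'   times in seconds, first sample at t = 0).
#' @keywords internal
decimate_signal <- function(x, fs, factor = 9L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor > 1L) {
    nyq <- fs / factor / 2
    x <- band_filter(x, fs, 0, 0.8 * nyq, 0, 0.15 * nyq)
    idx <- seq(1L, length(x), by = factor)
    x <- x[idx]
  }
  fsd <- fs / factor
  list(x = x, fs = fsd, t = (seq_along(x) - 1) / fsd)
}

#' Trapezoid pulse: linear ramp up, hold, linear ramp down
#'
#' Unit-height pulse starting at `t0`, ramping over `ramp` seconds, holding
#' for `hold` seconds, then ramping back down over `ramp` seconds.
#' @keywords internal
trapezoid <- function(t, t0, ramp, hold) {
  pmin(pmax((t - t0) / ramp, 0), 1) *
    pmin(pmax((t0 + 2 * ramp + hold - t) / ramp, 0), 1)
}

#' Closed-form running integral of [trapezoid()]
#' @keywords internal
trapezoid_integral <- function(t, t0, ramp, hold) {
  s <- pmin(pmax(t - t0, 0), 2 * ramp + hold)
  up <- pmin(s, ramp)
  mid <- pmin(pmax(s - ramp, 0), hold)
  dn <- pmax(s - ramp - hold, 0)
  up^2 / (2 * ramp) + mid + dn - dn^2 / (2 * ramp)
}

#' Centered moving-average smoother (reflecting ends)
#' @param x signal.
#' @param width window width in samples (coerced to odd).
#' @keywords internal
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) / 2L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  stats::filter(xp, rep(1 / width, width), sides = 2)[(half + 1L):(half + length(x))]
}

#' Running median smoother (stats::runmed with reflecting endrule)
#' @keywords internal
moving_median <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  as.numeric(stats::runmed(x, width, endrule = "median"))
}

#' Tukey (tapered cosine) window
#'
#' Flat in the middle, cosine roll-off over the first and last
#' `edge_frac` of the samples. Used to suppress spectral leakage of strong
#' out-of-band components in windowed least-squares fits.
#' @keywords internal
tukey_window <- function(n, edge_frac = 0.2) {
  w <- rep(1, n)
  ne <- floor(edge_frac * n)
  if (ne > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ne) / ne))
    w[seq_len(ne)] <- ramp
    w[n - seq_len(ne) + 1] <- ramp
  }
  w
}

## Maximal runs of TRUE in a logical vector, as a two-column matrix of
## (start, end) indices. Zero-row matrix when there are none.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
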