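## Channel aggregation, zero-phase band separation, movement-bout detection
## and instantaneous respiratory-rate estimation.

## Band definitions. The single published cutoffs are 0.15 Hz (movement) and
## 0.37 Hz (respiration); here they become raised-cosine band-passes whose
## passbands bracket the stated periodicities (0.198 Hz movement, 0.366 Hz
## respiration). Edges in Hz: c(pass_lo, pass_hi, trans_lo, trans_hi).
SM_BAND <- c(0.01, 0.15, 0.005, 0.10)
RR_BAND <- c(0.20, 0.55, 0.05, 0.06)

#' Collapse a multi-channel recording into movement and respiration composites
#'
#' The respiration composite is the variance-weighted channel mean (channels
#' carrying more signal get more weight); the movement composite is the
#' per-sample maximum of channel envelopes, which tracks bout energy wherever
#' on the mattress it appears. Channels are low-passed at 1 Hz before the
#' envelope to suppress out-of-band noise. Both composites are demeaned.
#'
#' @param raw an `smrr_recording`.
#' @param keep_channels also return the 1 Hz low-passed, decimated
#'   per-channel matrix used internally (needed by the latency refinement,
#'   which builds bout-localized channel composites).
#' @return list with `sm` and `rr` composite series and `sampling_rate`;
#'   with `keep_channels = TRUE` also `channels_dec` (matrix), `fs_dec`,
#'   `weights` (variance weights of the kept channels).
#' @export
aggregate_channels <- function(raw, keep_channels = FALSE) {
  stopifnot(inherits(raw, "smrr_recording"))
  sig <- raw$signal
  fs <- raw$sampling_rate
  if (nrow(sig) < 600 * fs)
    stop("aggregate_channels: recording shorter than 10 min")
  v <- apply(sig, 2, stats::var)
  floor_v <- 1e-12
  if (!any(v > floor_v)) stop("aggregate_channels: no signal (all channels flat)")
  keep <- v > floor_v
  w <- v * keep
  rr <- as.numeric(sig %*% (w / sum(w)))
  rr <- rr - mean(rr)

  ## channel envelopes: pre-subsample (all physiological content is below
  ## 1 Hz), low-pass at 1 Hz to suppress noise, take the analytic envelope on
  ## a decimated grid and interpolate back to the native grid (the envelope
  ## itself has sub-Hz bandwidth)
  n <- nrow(sig)
  ## pre-subsample by 3 (exact for the sub-Hz physiological components;
  ## folds only a small share of wideband noise), then a proper 1 Hz
  ## low-pass on the shorter grid
  pre <- if (fs > 20) 3L else 1L
  idx1 <- seq(1L, n, by = pre)
  fs1 <- fs / pre
  n1 <- length(idx1)
  dec <- max(1L, round(fs1 / 6))
  idx2 <- seq(1L, n1, by = dec)
  lp <- band_gain(n1, fs1, 0, 1.0, 0, 0.3)
  X <- stats::mvfft(sig[idx1, keep, drop = FALSE])
  Xl <- Re(stats::mvfft(X * lp, inverse = TRUE)) / n1
  env_max <- NULL
  for (j in seq_len(ncol(Xl))) {
    e <- Mod(analytic_signal(Xl[idx2, j]))
    env_max <- if (is.null(env_max)) e else pmax(env_max, e)
  }
  sm <- stats::approx(idx1[idx2], env_max, xout = seq_len(n), rule = 2)$y
  sm <- sm - mean(sm)
  out <- list(sm = sm, rr = rr, sampling_rate = fs)
  if (keep_channels) {
    out$channels_dec <- Xl[idx2, , drop = FALSE]
    out$fs_dec <- fs1 / dec
    out$weights <- (w / sum(w))[keep]
  }
  out
}

#' Split a composite series into movement-band and respiration-band streams
#'
#' Zero-phase separation: the movement (SM) stream keeps 0.01-0.15 Hz, the
#' respiration (RR) stream keeps 0.20-0.55 Hz (centred on the 0.366 Hz
#' respiratory carrier). Zero phase is essential because the downstream
#' coupling latency is of the order of one sample period.
#'
#' @param composite a single composite series.
#' @param sampling_rate sampling rate in Hz.
#' @return an `smrr_bands` list: `sm`, `rr` (same length as the input) and
#'   `sampling_rate`.
#' @export
#' @examples
#' fs <- 54; t <- seq(0, 600 - 1 / fs, by = 1 / fs)
#' b <- separate_bands(sin(2 * pi * 0.37 * t), fs)
#' sum(b$sm^2) / sum(b$rr^2)  # tone energy lands in the RR stream
separate_bands <- function(composite, sampling_rate) {
  fs <- sampling_rate
  if (fs < 2 * (RR_BAND[2] + RR_BAND[4]))
    stop("separate_bands: sampling rate below twice the upper band edge")
  if (length(composite) < 60 * fs)
    stop("separate_bands: input shorter than 60 s")
  structure(list(
    sm = band_filter(composite, fs, SM_BAND[1], SM_BAND[2], SM_BAND[3], SM_BAND[4]),
    rr = band_filter(composite, fs, RR_BAND[1], RR_BAND[2], RR_BAND[3], RR_BAND[4]),
    sampling_rate = fs), class = "smrr_bands")
}

## Envelope-geometry calibration for bout onset estimation. The SM band
## filter plus the 2 s envelope smoother inflate a bout's 50% width and can
## shift its apparent midpoint; both effects are measured once per sampling
## rate by passing reference bouts of several durations through the same
## chain, and inverted by interpolation during detection.
.sm_cal <- new.env(parent = emptyenv())
sm_envelope_cal <- function(fs) {
  key <- paste0("fs", fs)
  if (!is.null(.sm_cal[[key]])) return(.sm_cal[[key]])
  durs <- c(5, 8, 11, 15)
  n <- round(260 * fs)
  t <- (seq_len(n) - 1) / fs
  w50 <- mid_shift <- numeric(length(durs))
  for (i in seq_along(durs)) {
    d <- durs[i]
    ws <- ms <- numeric(0)
    for (fc in c(0.15, 0.18, 0.20)) {
      x <- trapezoid(t, 100, 2, d - 4) * sin(2 * pi * fc * (t - 100))
      smf <- band_filter(x, fs, SM_BAND[1], SM_BAND[2], SM_BAND[3], SM_BAND[4])
      env <- moving_average(Mod(analytic_signal(smf)), round(2 * fs))
      pk <- which.max(env)
      lev <- 0.25 * env[pk]
      on <- pk; while (on > 1L && env[on - 1L] > lev) on <- on - 1L
      off <- pk; while (off < n && env[off + 1L] > lev) off <- off + 1L
      ws <- c(ws, (off - on) / fs)
      ms <- c(ms, (on + off - 2) / 2 / fs - (100 + d / 2))
    }
    w50[i] <- mean(ws)   # width at the 25% level
    mid_shift[i] <- mean(ms)
  }
  .sm_cal[[key]] <- list(durs = durs, w50 = w50, mid_shift = mid_shift)
  .sm_cal[[key]]
}

#' Detect sleep-movement bouts on the movement stream
#'
#' A bout is a maximal interval where the movement envelope (analytic-signal
#' magnitude smoothed over 2 s) exceeds `median + 4 * MAD` of the night's
#' envelope. Intervals closer than `merge_gap` are merged and intervals
#' shorter than `min_duration` discarded. The reported onset/offset are the
#' 25%-of-peak crossings of the envelope around each detected interval, which
#' lands within ~1 s of the true onset on clean signals; sub-sample timing is
#' the job of the model-based refinement in [pair_and_latency()].
#'
#' @param sm movement-band stream (from [separate_bands()]).
#' @param sampling_rate sampling rate in Hz.
#' @param threshold_mads detection threshold in MADs above the median.
#' @param merge_gap merge bouts closer than this many seconds.
#' @param min_duration discard bouts shorter than this many seconds.
#' @return data frame with `onset_s`, `offset_s`, `peak_amplitude`, `auc`,
#'   sorted by onset, non-overlapping. Zero rows when nothing is detected.
#' @export
detect_sm_bouts <- function(sm, sampling_rate, threshold_mads = 4,
                            merge_gap = 10, min_duration = 2) {
  fs <- sampling_rate
  env <- moving_average(Mod(analytic_signal(sm)), round(2 * fs))
  med <- stats::median(env)
  mad_ <- stats::mad(env)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_amplitude = numeric(0), auc = numeric(0))
  if (mad_ <= 0) return(empty)
  thr <- med + threshold_mads * mad_
  r <- runs_of(env > thr)
  if (nrow(r) == 0L) return(empty)
  ## merge runs separated by < merge_gap
  merged <- r[1, , drop = FALSE]
  if (nrow(r) > 1L) for (i in 2:nrow(r)) {
    if ((r[i, 1] - merged[nrow(merged), 2]) / fs < merge_gap) {
      merged[nrow(merged), 2] <- r[i, 2]
    } else merged <- rbind(merged, r[i, , drop = FALSE])
  }
  dur <- (merged[, 2] - merged[, 1] + 1) / fs
  merged <- merged[dur >= min_duration, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)
  n <- length(env)
  out <- lapply(seq_len(nrow(merged)), function(i) {
    i1 <- max(1L, merged[i, 1] - as.integer(5 * fs))
    i2 <- min(n, merged[i, 2] + as.integer(5 * fs))
    seg <- env[i1:i2]
    pk <- which.max(seg)
    ## band-pass smearing is nearly symmetric, so the midpoint of the two 50%
    ## crossings sits at the bout centre; the onset estimate walks back half
    ## the (slightly inflated) 50% width plus half the 2 s rise ramp
    level <- med + 0.5 * (seg[pk] - med)
    on <- pk; while (on > 1L && seg[on - 1L] > level) on <- on - 1L
    off <- pk; while (off < length(seg) && seg[off + 1L] > level) off <- off + 1L
    lo25 <- med + 0.25 * (seg[pk] - med)
    on25 <- on; while (on25 > 1L && seg[on25 - 1L] > lo25) on25 <- on25 - 1L
    off25 <- off; while (off25 < length(seg) && seg[off25 + 1L] > lo25) off25 <- off25 + 1L
    ## geometry from the 25% crossings: mid-bout beating dips can split the
    ## 50% level but rarely reach 25%
    cal <- sm_envelope_cal(fs)
    w25m <- (off25 - on25) / fs
    d_hat <- stats::approx(cal$w50, cal$durs, xout = w25m, rule = 2)$y
    shift <- stats::approx(cal$durs, cal$mid_shift, xout = d_hat, rule = 2)$y
    mid <- (i1 + on25 - 2L + i1 + off25 - 2L) / 2 / fs - shift
    data.frame(onset_s = mid - d_hat / 2,
               offset_s = mid + d_hat / 2,
               peak_amplitude = seg[pk] - med,
               auc = sum(seg[on25:off25] - med) / fs)
  })
  out <- do.call(rbind, out)
  ## prominence floor: on sparse nights the adaptive MAD threshold can sit
  ## low enough that filter ringing crosses it; ringing lobes are far weaker
  ## than real bouts
  out <- out[out$peak_amplitude >= 0.2 * max(out$peak_amplitude), , drop = FALSE]
  ## the backtracking can re-join neighbours: keep non-overlapping
  keep <- c(TRUE, out$onset_s[-1] > out$offset_s[-nrow(out)])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instantaneous respiratory frequency and 2-minute binned rates
#'
#' The instantaneous frequency is the analytic-signal phase derivative of the
#' respiration stream, median-smoothed over `smooth_s` seconds. Samples are
#' valid where the envelope is above a noise floor and the local frequency is
#' stable (a narrowband oscillation, not filtered noise). Nights with under
#' 50% valid samples are flagged unusable.
#'
#' @param rr respiration-band stream (from [separate_bands()]).
#' @param sampling_rate sampling rate in Hz.
#' @param smooth_s median-smoothing window in seconds.
#' @param bin_s rate bin width in seconds (2-minute bins by default).
#' @return an `smrr_rate_series`: `freq` (smoothed instantaneous frequency,
#'   Hz, NA where invalid), `freq_raw` (unsmoothed), `valid` (logical),
#'   `usable` (night-level flag), `bins` data frame (`start_s`,
#'   `rate_bpm`, `valid`), `sampling_rate`.
#' @export
#' @examples
#' fs <- 54; t <- seq(0, 600 - 1 / fs, by = 1 / fs)
#' rs <- instantaneous_rr(sin(2 * pi * 0.37 * t), fs)
#' rs$bins$rate_bpm  # 0.37 Hz * 60 = 22.2 breaths/min
instantaneous_rr <- function(rr, sampling_rate, smooth_s = 10, bin_s = 120,
                             decimate = 9L) {
  ## all spectral content of the respiration stream is below ~0.7 Hz, so the
  ## analysis grid is decimated for speed; timing precision is unaffected
  ## because event onsets are refined on continuous-parameter model fits
  d <- decimate_signal(rr, sampling_rate, decimate)
  rr <- d$x
  fs <- d$fs
  z <- analytic_signal(rr)
  env <- Mod(z)
  ph <- unwrap_phase(Arg(z))
  n <- length(rr)
  f_raw <- numeric(n)
  f_raw[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) * fs / (4 * pi)
  f_raw[1] <- f_raw[2]; f_raw[n] <- f_raw[n - 1]
  w <- round(smooth_s * fs)
  f_med <- moving_median(f_raw, w)
  jitter <- moving_average(abs(f_raw - f_med), w)
  valid <- env > 0.3 * stats::median(env) & jitter < 0.05 &
    f_med > 0.05 & f_med < 1.5
  freq <- f_med
  freq[!valid] <- NA_real_
  usable <- mean(valid) >= 0.5
  nb <- floor(n / (bin_s * fs))
  bins <- data.frame(start_s = (seq_len(max(nb, 0)) - 1) * bin_s,
                     rate_bpm = NA_real_, valid = FALSE)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * bin_s * fs + 1):(b * bin_s * fs)
    ok <- mean(valid[idx]) >= 0.5
    bins$valid[b] <- ok
    if (ok) bins$rate_bpm[b] <- mean(freq[idx], na.rm = TRUE) * 60
  }
  structure(list(freq = freq, freq_raw = f_raw, valid = valid,
                 usable = usable, bins = bins, sampling_rate = fs),
            class = "smrr_rate_series")
}

#' @export
print.smrr_rate_series <- function(x, ...) {
  cat(sprintf("<smrr_rate_series> %d samples @ %g Hz, %.0f%% valid%s; %d bins\n",
              length(x$freq), x$sampling_rate, 100 * mean(x$valid),
              if (x$usable) "" else " (UNUSABLE)", nrow(x$bins)))
  invisible(x)
}
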