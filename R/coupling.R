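## Windowed coupling analysis: respiratory-event detection by the 1-SD rule,
## bout-event pairing, signed latencies, and per-case maximum-latency
## profiles.

#' Segment a night into contiguous 10-minute analysis windows
#'
#' @param duration_s usable night duration in seconds.
#' @param window_s window length (600 s).
#' @param night_index stored on the result.
#' @return data frame with `night`, `window`, `start_s`, `end_s`; the partial
#'   trailing window is dropped.
#' @export
#' @examples
#' segment_windows(7200)  # 12 windows
segment_windows <- function(duration_s, window_s = 600, night_index = 1L) {
  nw <- floor(duration_s / window_s)
  if (nw < 1) {
    warning("segment_windows: night shorter than one analysis window; excluded")
    return(data.frame(night = integer(0), window = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(night = as.integer(night_index), window = seq_len(nw),
             start_s = (seq_len(nw) - 1) * window_s,
             end_s = seq_len(nw) * window_s)
}

#' Detect respiratory-frequency-change events in one window by the 1-SD rule
#'
#' Within the window, the baseline is the median of the smoothed instantaneous
#' frequency and the threshold is `baseline + threshold_sds * SD`. An event is
#' a run above threshold sustained for at least `sustain_s` seconds; runs
#' separated by less than `merge_s` are merged first. Upward changes only
#' (respiratory upregulation); set `bidirectional = TRUE` to also detect
#' downward excursions.
#'
#' @param rate an `smrr_rate_series` from [instantaneous_rr()].
#' @param window one row of [segment_windows()] (list or data frame row).
#' @param threshold_sds threshold in window SDs (1.0, the published rule).
#' @param sustain_s minimum sustained duration in seconds.
#' @param merge_s merge sub-threshold gaps shorter than this.
#' @param bidirectional also detect downward frequency changes.
#' @return data frame with `onset_s`, `magnitude` (peak excursion in window
#'   SDs), `duration_s`, `direction`; attribute `valid` is FALSE when the
#'   window had under 50% valid rate samples (then zero rows are returned).
#' @export
detect_rr_events <- function(rate, window, threshold_sds = 1.0,
                             sustain_s = 3, merge_s = 5,
                             bidirectional = FALSE) {
  stopifnot(inherits(rate, "smrr_rate_series"))
  fs <- rate$sampling_rate
  i1 <- max(1L, floor(window$start_s * fs) + 1L)
  i2 <- min(length(rate$freq), ceiling(window$end_s * fs))
  f <- rate$freq[i1:i2]
  ok <- !is.na(f)
  empty <- data.frame(onset_s = numeric(0), magnitude = numeric(0),
                      duration_s = numeric(0), direction = character(0))
  if (mean(ok) < 0.5) {
    attr(empty, "valid") <- FALSE
    return(empty)
  }
  baseline <- stats::median(f[ok])
  sdv <- stats::sd(f[ok])
  if (!is.finite(sdv) || sdv == 0) {
    attr(empty, "valid") <- TRUE
    return(empty)
  }
  find_dir <- function(above, dir) {
    above[is.na(above)] <- FALSE
    r <- runs_of(above)
    if (nrow(r) == 0L) return(NULL)
    merged <- r[1, , drop = FALSE]
    if (nrow(r) > 1L) for (k in 2:nrow(r)) {
      if ((r[k, 1] - merged[nrow(merged), 2]) / fs < merge_s)
        merged[nrow(merged), 2] <- r[k, 2]
      else merged <- rbind(merged, r[k, , drop = FALSE])
    }
    dur <- (merged[, 2] - merged[, 1] + 1) / fs
    merged <- merged[dur >= sustain_s, , drop = FALSE]
    if (nrow(merged) == 0L) return(NULL)
    data.frame(
      onset_s = (i1 + merged[, 1] - 2) / fs,
      magnitude = vapply(seq_len(nrow(merged)), function(k) {
        seg <- f[merged[k, 1]:merged[k, 2]]
        max(abs(seg - baseline), na.rm = TRUE) / sdv
      }, 0),
      duration_s = (merged[, 2] - merged[, 1] + 1) / fs,
      direction = dir)
  }
  out <- find_dir(f > baseline + threshold_sds * sdv, "up")
  if (bidirectional)
    out <- rbind(out, find_dir(f < baseline - threshold_sds * sdv, "down"))
  if (is.null(out)) out <- empty
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "valid") <- TRUE
  out
}

#' Pair movement bouts with respiratory events and compute signed latencies
#'
#' Greedy nearest-in-time one-to-one pairing within `radius_s`; ties are
#' broken toward the earlier event. `latency_ms = (event_onset - bout_onset)
#' * 1000`, positive when the movement leads the respiratory change. Unpaired
#' bouts and events are discarded. When a refinement context is supplied,
#' both onsets of every pairing are re-estimated to sub-sample precision by
#' the local model fits in [refine_pair()]; otherwise the coarse detection
#' onsets are used.
#'
#' @param bouts data frame from [detect_sm_bouts()] (bouts in this window).
#' @param events data frame from [detect_rr_events()].
#' @param window one row of [segment_windows()].
#' @param ctx optional `smrr_refine_ctx` from [refine_context()].
#' @param radius_s pairing radius in seconds.
#' @return data frame with `night`, `window`, `bout_onset_s`,
#'   `event_onset_s`, `latency_ms`.
#' @export
pair_and_latency <- function(bouts, events, window, ctx = NULL,
                             radius_s = 30) {
  empty <- data.frame(night = integer(0), window = integer(0),
                      bout_onset_s = numeric(0), event_onset_s = numeric(0),
                      latency_ms = numeric(0))
  if (nrow(bouts) == 0L || nrow(events) == 0L) return(empty)
  cand <- expand.grid(b = seq_len(nrow(bouts)), e = seq_len(nrow(events)))
  cand$dt <- events$onset_s[cand$e] - bouts$onset_s[cand$b]
  cand <- cand[abs(cand$dt) <= radius_s, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ## nearest first; ties toward the earlier event
  cand <- cand[order(abs(cand$dt), events$onset_s[cand$e]), , drop = FALSE]
  used_b <- logical(nrow(bouts)); used_e <- logical(nrow(events))
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    b <- cand$b[i]; e <- cand$e[i]
    if (used_b[b] || used_e[e]) next
    used_b[b] <- TRUE; used_e[e] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(b, e)
  }
  out <- do.call(rbind, lapply(pairs, function(p) {
    b <- p[1]; e <- p[2]
    bo <- bouts$onset_s[b]; eo <- events$onset_s[e]
    if (!is.null(ctx)) {
      rf <- tryCatch(
        refine_pair(ctx, bo, bouts$offset_s[b], eo,
                    other_events = events$onset_s[-e],
                    event_duration = events$duration_s[e]),
        error = function(err) NULL)
      if (!is.null(rf) && is.finite(rf$bout_onset) && is.finite(rf$event_onset)) {
        bo <- rf$bout_onset; eo <- rf$event_onset
      }
    }
    data.frame(night = as.integer(window$night), window = as.integer(window$window),
               bout_onset_s = bo, event_onset_s = eo,
               latency_ms = (eo - bo) * 1000)
  }))
  out[order(out$bout_onset_s), , drop = FALSE]
}

#' Representative latency of one window: maximum absolute value, sign kept
#'
#' Ties between a positive and a negative latency of equal magnitude go to
#' the positive one. With `rule = "signed"` the plain signed maximum is
#' returned instead.
#'
#' @param latencies_ms latency samples in one window.
#' @param rule `"abs"` (default) or `"signed"`.
#' @return a single latency in ms, or `NA` for an empty window (the window is
#'   then not counted toward the case profile).
#' @export
#' @examples
#' window_max_latency(c(60, -90, 20))  # -90
#' window_max_latency(c(80, -80))      # +80 (tie rule)
window_max_latency <- function(latencies_ms, rule = c("abs", "signed")) {
  rule <- match.arg(rule)
  if (length(latencies_ms) == 0L) return(NA_real_)
  if (rule == "signed") return(max(latencies_ms))
  m <- max(abs(latencies_ms))
  if (any(latencies_ms == m)) m else -m
}

#' Per-case probability density of window-maximum latencies
#'
#' Pools the window maxima of both nights into a fixed-grid histogram
#' (20 ms bins over \[-1000, 1000\] ms, density-normalized). Cases with fewer
#' than `min_windows` usable windows are flagged low-coverage; the profile is
#' still produced and the flag propagates to reports.
#'
#' @param maxima_ms window-maximum latencies across both nights (NAs, from
#'   windows without pairings, are dropped).
#' @param case_id case identifier.
#' @param bin_ms histogram bin width.
#' @param range_ms histogram support.
#' @param min_windows low-coverage threshold.
#' @return an `smrr_profile`: `case_id`, `maxima_ms`, `breaks_ms`,
#'   `density` (per-ms), `n_usable_windows`, `low_coverage`.
#' @export
case_profile <- function(maxima_ms, case_id = "case", bin_ms = 20,
                         range_ms = c(-1000, 1000), min_windows = 5) {
  maxima_ms <- maxima_ms[!is.na(maxima_ms)]
  breaks <- seq(range_ms[1], range_ms[2], by = bin_ms)
  inside <- maxima_ms[maxima_ms >= range_ms[1] & maxima_ms <= range_ms[2]]
  counts <- if (length(inside))
    graphics::hist(inside, breaks = breaks, plot = FALSE)$counts
  else rep(0L, length(breaks) - 1L)
  dens <- if (sum(counts) > 0) counts / sum(counts) / bin_ms else counts * 0
  structure(list(case_id = case_id, maxima_ms = maxima_ms,
                 breaks_ms = breaks, density = dens,
                 n_usable_windows = length(maxima_ms),
                 low_coverage = length(maxima_ms) < min_windows),
            class = "smrr_profile")
}

#' @export
print.smrr_profile <- function(x, ...) {
  cat(sprintf("<smrr_profile> %s: %d usable windows%s, median max-latency %.0f ms\n",
              x$case_id, x$n_usable_windows,
              if (x$low_coverage) " (LOW COVERAGE)" else "",
              if (x$n_usable_windows) stats::median(x$maxima_ms) else NA))
  invisible(x)
}
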