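## Model-based sub-sample refinement of bout and respiratory-event onsets.
##
## Envelope-threshold onsets are only good to ~1 s because the narrow analysis
## bands smear 5-15 s bouts, while the coupling latency of interest is of the
## order of one sample period (18.5 ms at 54 Hz). Refinement therefore fits
## explicit local signal models by least squares on a decimated grid:
##
##   bout:  trapezoid-enveloped oscillation  A * trap(t; t0, ramp, d) * sin(...)
##   event: FM respiration carrier           sin(2*pi*(f0*t + f0*m*itrap(t; ev)))
##
## Linear parameters (amplitudes, carrier phase, baseline frequency, event
## magnitude) are profiled out; only onset, duration and carrier frequency are
## optimized numerically. A final joint fit of bout + respiration removes
## cross-talk bias between the two components. Fitted onsets are continuous
## parameters, so timing precision is not limited by the decimated grid.

## Frequency-restricted linear least squares: project data and basis onto the
## FFT bins whose frequency lies in [f_lo, f_hi] and solve for real
## coefficients. Restricting bins both rejects out-of-band interference and
## makes each objective evaluation cheap.
freq_bins <- function(n, fs, f_lo, f_hi) {
  f <- (seq_len(n) - 1) / n * fs
  which(f >= f_lo & f <= f_hi & f <= fs / 2)
}

freq_ls <- function(Bcols, bins, Xf) {
  A <- do.call(cbind, lapply(Bcols, function(b) stats::fft(b)[bins]))
  A <- rbind(Re(A), Im(A))
  y <- c(Re(Xf[bins]), Im(Xf[bins]))
  G <- crossprod(A)
  co <- tryCatch(solve(G, crossprod(A, y)), error = function(e) NULL)
  if (is.null(co)) return(list(sse = sum(y^2), coef = rep(0, length(Bcols))))
  list(sse = sum((y - A %*% co)^2), coef = as.numeric(co))
}

#' Build a refinement context for one night
#'
#' Decimates the respiration-path composite once and bundles the model
#' constants the local fits need.
#'
#' @param composite respiration-path composite series (linear channel mix).
#' @param sampling_rate native sampling rate in Hz.
#' @param ramp shared rise/fall ramp duration, seconds.
#' @param event_duration total upregulation duration, seconds.
#' @param resp_freq nominal baseline respiratory frequency, Hz.
#' @param decimate integer decimation factor for the fitting grid.
#' @param channels_dec optional decimated per-channel matrix (from
#'   [aggregate_channels()] with `keep_channels = TRUE`, same grid as the
#'   decimated composite); enables bout-localized channel weighting, which
#'   substantially improves the bout-to-respiration ratio seen by the fits.
#' @param weights global variance weights matching `channels_dec` columns.
#' @return an `smrr_refine_ctx` list.
#' @keywords internal
refine_context <- function(composite, sampling_rate, ramp = 2,
                           event_duration = 20, resp_freq = 0.366,
                           decimate = 9L, channels_dec = NULL,
                           weights = NULL) {
  d <- decimate_signal(composite, sampling_rate, decimate)
  if (!is.null(channels_dec)) {
    step <- nrow(channels_dec) / length(d$x)
    if (abs(step - round(step)) > 1e-9)
      stop("refine_context: channels_dec grid does not match the composite")
    if (step > 1)
      channels_dec <- channels_dec[seq(1, nrow(channels_dec), by = round(step)), ,
                                   drop = FALSE]
    if (nrow(channels_dec) != length(d$x))
      channels_dec <- channels_dec[seq_len(length(d$x)), , drop = FALSE]
  }
  ## measured noise level: RMS in a band holding no physiological content
  ## (all model content is below ~1 Hz); drives bias/variance choices in the
  ## joint polish
  nyq <- d$fs / 2
  noise_rms <- stats::sd(band_filter(d$x, d$fs, 0.55 * nyq, 0.85 * nyq,
                                     0.05 * nyq, 0.05 * nyq))
  clean <- noise_rms < 0.004 * stats::sd(d$x)
  structure(list(x = d$x, t = d$t, fs = d$fs, ramp = ramp,
                 hold = event_duration - 2 * ramp, resp_freq = resp_freq,
                 channels = channels_dec, weights = weights,
                 clean = clean),
            class = "smrr_refine_ctx")
}

## Bout-localized composite: weight channels by their excess variance inside
## the bout interval relative to the surrounding baseline, so that the
## channels the movement actually loads onto dominate. Falls back to the
## global composite when no channel shows excess variance (or when no
## channel matrix is available).
local_composite <- function(ctx, t0g, dg) {
  fallback <- ctx$x
  attr(fallback, "gain_ratio") <- 1
  if (is.null(ctx$channels)) return(fallback)
  ib <- ctx_window(ctx, t0g - 1, t0g + dg + 1)
  ibase <- c(ctx_window(ctx, t0g - 25, t0g - 5),
             ctx_window(ctx, t0g + dg + 5, t0g + dg + 25))
  if (length(ib) < 4 || length(ibase) < 8) return(fallback)
  vb <- apply(ctx$channels[ib, , drop = FALSE], 2, stats::var)
  v0 <- apply(ctx$channels[ibase, , drop = FALSE], 2, stats::var)
  w <- pmax(vb - v0, 0)
  if (sum(w) <= 0) return(fallback)
  wn <- w / sum(w)
  xc <- as.numeric(ctx$channels %*% wn)
  xc <- xc - mean(xc)
  ## how much weaker the bout appears in the global composite than here,
  ## approximated by the excess-variance ratio under the two weightings
  wg <- if (is.null(ctx$weights)) rep(1 / length(w), length(w)) else ctx$weights
  num <- sum(wg * sqrt(pmax(vb - v0, 0)))
  den <- sum(wn * sqrt(pmax(vb - v0, 0)))
  attr(xc, "gain_ratio") <- if (den > 0) num / den else 1
  xc
}

ctx_window <- function(ctx, t_from, t_to) {
  which(ctx$t >= max(t_from, 0) & ctx$t <= min(t_to, ctx$t[length(ctx$t)]))
}

## Fit the trapezoid-AM bout model in a local window. Returns onset, duration,
## carrier frequency and the linear coefficients; `wave(tt)` evaluates the
## fitted bout on an arbitrary grid.
fit_bout_template <- function(ctx, x, t0g, dg,
                              fc_starts = c(0.14, 0.16, 0.18, 0.20, 0.22),
                              coarse_grid = TRUE, nm_only = FALSE) {
  iw <- ctx_window(ctx, t0g - 8, t0g + dg + 8)
  tw <- ctx$t[iw]
  n <- length(iw)
  xw <- x[iw]
  ramp <- ctx$ramp
  d_lo <- 2 * ramp + 0.25
  ## plain time-domain least squares: the respiration carrier has already
  ## been subtracted from `x`, so no frequency restriction is needed and an
  ## objective evaluation is just two small basis vectors and a 2x2 solve,
  ## restricted to the template's support
  sum_x2 <- sum(xw^2)
  fsd <- ctx$fs
  tw1 <- tw[1]
  obj3 <- function(t0, d, fc) {
    j1 <- max(1L, floor((t0 - tw1) * fsd) + 1L)
    j2 <- min(n, ceiling((t0 + d - tw1) * fsd) + 1L)
    if (j2 - j1 < 4L) return(sum_x2)
    j <- j1:j2
    tj <- tw[j]
    e <- trapezoid(tj, t0, ramp, max(d - 2 * ramp, 0.1))
    w <- 2 * pi * fc * (tj - t0)
    b1 <- e * sin(w); b2 <- e * cos(w)
    xj <- xw[j]
    a11 <- sum(b1 * b1); a22 <- sum(b2 * b2); a12 <- sum(b1 * b2)
    y1 <- sum(b1 * xj); y2 <- sum(b2 * xj)
    det <- a11 * a22 - a12 * a12
    if (det < 1e-12) return(sum_x2)
    c1 <- (a22 * y1 - a12 * y2) / det
    c2 <- (a11 * y2 - a12 * y1) / det
    sum_x2 - (c1 * y1 + c2 * y2)
  }
  obj <- function(p) {
    d <- max(p[2], d_lo); fc <- min(max(p[3], 0.125), 0.255)
    pen <- (p[2] - d)^2 + 400 * (p[3] - fc)^2 +
      max(abs(p[1] - t0g) - 4.5, 0)^2
    obj3(p[1], d, fc) * (1 + pen)
  }
  if (nm_only) {
    ## refit pass: start from an already-good solution, no grid scan
    r <- stats::optim(c(t0g, dg, fc_starts[1]), obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10,
                                     parscale = c(0.5, 1, 0.01)))
    p <- r$par
    o <- stats::optimize(function(z) obj(c(z, p[2], p[3])),
                         c(p[1] - 0.3, p[1] + 0.3), tol = 1e-7)
    p[1] <- o$minimum
    t0 <- p[1]; d <- max(p[2], d_lo); fc <- min(max(p[3], 0.125), 0.255)
    e <- trapezoid(tw, t0, ramp, max(d - 2 * ramp, 0.1))
    w <- 2 * pi * fc * (tw - t0)
    co <- stats::lm.fit(cbind(e * sin(w), e * cos(w)), xw)$coefficients
    co[is.na(co)] <- 0
    return(list(t0 = t0, d = d, fc = fc, coef = co, sse = obj3(t0, d, fc),
                wave = function(tt) {
                  ee <- trapezoid(tt, t0, ramp, max(d - 2 * ramp, 0.1))
                  ww <- 2 * pi * fc * (tt - t0)
                  co[1] * ee * sin(ww) + co[2] * ee * cos(ww)
                }))
  }
  ## initialize from the envelope of the residual series: its 50% crossings
  ## give onset and duration far more sharply than the smeared
  ## movement-stream detection
  env <- Mod(analytic_signal(xw))
  base_e <- stats::median(env)
  ipk <- which.max(env)
  lev <- base_e + 0.5 * (env[ipk] - base_e)
  i_on <- ipk; while (i_on > 1L && env[i_on - 1L] > lev) i_on <- i_on - 1L
  i_off <- ipk; while (i_off < n && env[i_off + 1L] > lev) i_off <- i_off + 1L
  t0e <- tw[i_on] - ramp / 2
  de <- max(tw[i_off] - tw[i_on] + ramp, d_lo)
  ## dense local grid around the envelope estimate plus a coarse fallback
  ## around the detection onset; then simplex from the best separated starts
  cand <- expand.grid(t0 = t0e + seq(-1.2, 1.2, by = 0.1),
                      d = unique(pmax(de + c(-1.5, 0, 1.5), d_lo)),
                      fc = fc_starts)
  if (coarse_grid)
    cand <- rbind(cand,
                  expand.grid(t0 = t0g + seq(-4, 4, by = 0.5),
                              d = unique(pmax(c(0.65 * dg, dg), d_lo)),
                              fc = fc_starts))
  cand$v <- vapply(seq_len(nrow(cand)), function(i)
    obj(c(cand$t0[i], cand$d[i], cand$fc[i])), 0)
  cand <- cand[order(cand$v), ]
  starts <- cand[1, , drop = FALSE]
  for (i in seq_len(min(nrow(cand), 80))) {
    if (nrow(starts) >= 3) break
    if (all(abs(cand$t0[i] - starts$t0) > 0.9)) starts <- rbind(starts, cand[i, ])
  }
  best <- list(value = cand$v[1], par = c(cand$t0[1], cand$d[1], cand$fc[1]))
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(c(starts$t0[i], starts$d[i], starts$fc[i]), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10,
                                     parscale = c(0.5, 1, 0.01)))
    ## guard against simplex escapes into the flat region outside the window
    if (r$value < best$value && abs(r$par[1] - t0g) < 5.5) best <- r
  }
  p <- best$par
  o <- stats::optimize(function(z) obj(c(z, p[2], p[3])),
                       c(p[1] - 0.3, p[1] + 0.3), tol = 1e-7)
  p[1] <- o$minimum
  t0 <- p[1]; d <- max(p[2], d_lo); fc <- min(max(p[3], 0.125), 0.255)
  e <- trapezoid(tw, t0, ramp, max(d - 2 * ramp, 0.1))
  w <- 2 * pi * fc * (tw - t0)
  co <- stats::lm.fit(cbind(e * sin(w), e * cos(w)), xw)$coefficients
  co[is.na(co)] <- 0
  list(t0 = t0, d = d, fc = fc, coef = co, sse = obj3(t0, d, fc),
       wave = function(tt) {
         ee <- trapezoid(tt, t0, ramp, max(d - 2 * ramp, 0.1))
         ww <- 2 * pi * fc * (tt - t0)
         co[1] * ee * sin(ww) + co[2] * ee * cos(ww)
       })
}

## Fit the respiration FM model's event onset on the unwrapped analytic phase.
## `others` are onsets of additional upregulation events overlapping the
## window; each contributes a linear phase column so it cannot bias the focal
## onset. Returns the event onset plus everything needed to rebuild the
## respiration waveform and phase model.
fit_event_template <- function(ctx, x, iw, evg, others = numeric(0)) {
  tw <- ctx$t[iw]
  n <- length(iw)
  xw <- x[iw]
  g <- band_gain(n, ctx$fs, 0.27, 0.95, 0.05, 0.10)
  z <- analytic_signal(apply_gain(xw, g))
  ph <- unwrap_phase(Arg(z))
  env <- Mod(z)
  ## weight by squared envelope (phase noise variance scales as 1/amplitude^2)
  ## and exclude filter edge effects and low-envelope samples
  wgt <- env^2 / stats::median(env)^2
  wgt[env < 0.3 * stats::median(env)] <- 0
  wgt <- pmin(wgt, 4)
  edge <- tw < tw[1] + 3 | tw > tw[n] - 3
  wgt[edge] <- 0
  ramp <- ctx$ramp; hold <- ctx$hold
  other_cols <- lapply(others, function(e) trapezoid_integral(tw, e, ramp, hold))
  phase_fit <- function(ev) {
    B <- cbind(1, tw - tw[1], trapezoid_integral(tw, ev, ramp, hold))
    for (oc in other_cols) B <- cbind(B, oc)
    f <- stats::lm.fit(B * wgt, ph * wgt)
    list(sse = sum(f$residuals^2), coef = f$coefficients)
  }
  ## the 1-SD detection onset can be several seconds late when the event
  ## overlaps a movement bout (leakage corrupts the rate series there), so
  ## search asymmetrically around the detected onset
  es <- seq(evg - 10, evg + 5, by = 0.25)
  sses <- vapply(es, function(e) phase_fit(e)$sse, 0)
  e0 <- es[which.min(sses)]
  o <- stats::optimize(function(e) phase_fit(e)$sse, c(e0 - 0.3, e0 + 0.3),
                       tol = 1e-7)
  ev <- o$minimum
  co <- phase_fit(ev)$coef
  co[!is.finite(co)] <- 0
  phase_model <- function(tt) {
    phm <- co[1] + co[2] * (tt - tw[1]) +
      co[3] * trapezoid_integral(tt, ev, ramp, hold)
    if (length(others))
      for (k in seq_along(others))
        phm <- phm + co[3 + k] * trapezoid_integral(tt, others[k], ramp, hold)
    phm
  }
  ## amplitude/phase of the carrier itself, for waveform-level subtraction
  phm <- phase_model(tw)
  tap <- tukey_window(n, 0.15)
  tmid <- mean(tw); tsc_max <- max(tw - tmid); tsc <- (tw - tmid) / tsc_max
  amp_fit <- freq_ls(list(tap * sin(phm), tap * cos(phm),
                          tap * tsc * sin(phm), tap * tsc * cos(phm),
                          tap * tsc^2 * sin(phm), tap * tsc^2 * cos(phm)),
                     freq_bins(n, ctx$fs, 0.22, 0.95), stats::fft(tap * xw))
  a <- amp_fit$coef
  list(ev = ev, coef = co, base = co[2] / (2 * pi),
       phase_model = phase_model,
       wave = function(tt) {
         pm <- phase_model(tt)
         u <- (tt - tmid) / tsc_max
         (a[1] + a[3] * u + a[5] * u^2) * sin(pm) +
           (a[2] + a[4] * u + a[6] * u^2) * cos(pm)
       })
}

## Joint polish: bout and a residual respiration correction modelled together
## over one window with all four amplitudes profiled, removing residual
## cross-talk between the two component fits. `x` is normally the
## respiration-subtracted series, so the sin/cos phase-model columns only
## absorb what the subtraction missed. Only (t0, d, fc, ev) move.
joint_polish <- function(ctx, fb, fe, others = numeric(0), x = NULL,
                         bout_x = NULL, bout_gain = 1,
                         onsets_only = FALSE) {
  if (!is.null(bout_x)) x <- bout_x
  if (is.null(x)) x <- ctx$x
  ramp <- ctx$ramp; hold <- ctx$hold
  lo <- min(fb$t0, fe$ev) - 20
  hi <- max(fb$t0 + fb$d, fe$ev + hold + 2 * ramp) + 15
  iw <- ctx_window(ctx, lo, hi)
  tw <- ctx$t[iw]
  n <- length(iw)
  tap <- tukey_window(n, 0.15)
  Xf <- stats::fft(tap * x[iw])
  bins <- freq_bins(n, ctx$fs, 0.02, 0.95)
  co_e <- fe$coef
  d_lo <- 2 * ramp + 0.25
  ## phase contributions that do not depend on the moving parameters
  ph_fixed <- co_e[2] * (tw - tw[1])
  if (length(others))
    for (k in seq_along(others))
      ph_fixed <- ph_fixed + co_e[3 + k] * trapezoid_integral(tw, others[k], ramp, hold)
  ## on clean data the bout duration/carrier move with the onsets (their
  ## residual errors would otherwise bias the onset); under measured noise
  ## they are held at their component-fit values because profiling them
  ## inflates the onset variance for little bias benefit
  obj4 <- function(p) {
    if (!all(is.finite(p))) return(sum(Mod(Xf[bins])^2) * 4)
    d <- max(p[2], d_lo); fc <- min(max(p[3], 0.125), 0.255)
    pen <- (p[2] - d)^2 + 400 * (p[3] - fc)^2
    e <- trapezoid(tw, p[1], ramp, max(d - 2 * ramp, 0.1))
    w <- 2 * pi * fc * (tw - p[1])
    phm <- ph_fixed + co_e[3] * trapezoid_integral(tw, p[4], ramp, hold)
    v <- freq_ls(list(tap * e * sin(w), tap * e * cos(w),
                      tap * sin(phm), tap * cos(phm)), bins, Xf)$sse * (1 + pen)
    if (!is.finite(v)) sum(Mod(Xf[bins])^2) * 4 else v
  }
  if (isTRUE(ctx$clean) && !onsets_only) {
    r <- stats::optim(c(fb$t0, fb$d, fb$fc, fe$ev), obj4,
                      method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-11,
                                     parscale = c(0.3, 1, 0.01, 0.3)))
    r <- stats::optim(r$par, obj4, method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-11,
                                     parscale = c(0.1, 0.3, 0.004, 0.1)))
    return(list(t0 = r$par[1], ev = r$par[4]))
  }
  d <- max(fb$d, d_lo)
  fc <- min(max(fb$fc, 0.125), 0.255)
  obj <- function(p) obj4(c(p[1], d, fc, p[2]))
  r <- stats::optim(c(fb$t0, fe$ev), obj, method = "Nelder-Mead",
                    control = list(maxit = 220, reltol = 1e-11,
                                   parscale = c(0.3, 0.3)))
  list(t0 = r$par[1], ev = r$par[2])
}

## The respiration model was fitted on the global composite; the localized
## composite carries the same respiration phase but a different, slowly
## drifting effective gain (fewer channels are averaged). Fit a quadratic
## time-varying scale by least squares over the subtraction window and
## return the rescaled wave on that window.
fit_resp_local <- function(xl, fe, ctx, ir, exclude = NULL) {
  tt <- ctx$t[ir]
  wv <- fe$wave(tt)
  if (length(tt) < 8 || !any(is.finite(wv)) || sum(wv^2) <= 0)
    return(numeric(length(tt)))
  u <- (tt - mean(tt)) / max(abs(tt - mean(tt)))
  B <- cbind(wv, u * wv, u^2 * wv)
  ## fit the gain on the flanks only: including the bout interval would let
  ## the regression absorb part of the bout and inject bout-correlated junk
  wgt <- rep(1, length(tt))
  if (!is.null(exclude)) wgt[tt >= exclude[1] & tt <= exclude[2]] <- 0
  if (sum(wgt) < 8) wgt[] <- 1
  co <- stats::lm.wfit(B, xl[ir], wgt)$coefficients
  co[is.na(co)] <- 0
  as.numeric(B %*% co)
}

#' Refine one bout-event pairing to sub-sample precision
#'
#' @param ctx an `smrr_refine_ctx` from [refine_context()].
#' @param bout_onset,bout_offset coarse bout interval, seconds.
#' @param event_onset coarse respiratory event onset, seconds.
#' @param other_events onsets of other detected events near the pairing.
#' @return list with refined `bout_onset`, `event_onset` (seconds) and
#'   `latency_ms` (signed; positive when the bout leads).
#' @keywords internal
refine_pair <- function(ctx, bout_onset, bout_offset, event_onset,
                        other_events = numeric(0),
                        event_duration = NA_real_) {
  dg <- max(bout_offset - bout_onset - 2, 2 * ctx$ramp + 0.5)
  span <- ctx$hold + 2 * ctx$ramp
  iw_e <- ctx_window(ctx, event_onset - 35, event_onset + span + 20)
  others <- other_events[abs(other_events - event_onset) > 1]
  others <- others[others > ctx$t[iw_e[1]] - span & others < ctx$t[iw_e[length(iw_e)]]]
  ## respiration is the dominant composite component: model it first, fit the
  ## bout on the respiration-subtracted bout-localized composite, then refit
  ## and jointly polish on the localized composite
  fe1 <- fit_event_template(ctx, ctx$x, iw_e, event_onset, others)
  ## bout fits run on the bout-localized channel composite (better bout SNR);
  ## the respiration model is re-scaled to it on bout-excluded flanks, over a
  ## window just covering the bout fit where the local quadratic gain-drift
  ## approximation is most accurate
  xl <- local_composite(ctx, bout_onset, dg)
  ir <- ctx_window(ctx, bout_onset - 12, bout_onset + dg + 12)
  x_nor <- xl
  x_nor[ir] <- x_nor[ir] - fit_resp_local(xl, fe1, ctx, ir,
                                          exclude = c(bout_onset - 2.5,
                                                      bout_onset + dg + 2.5))
  fb <- fit_bout_template(ctx, x_nor, bout_onset, dg)
  x_nob <- ctx$x
  ib <- ctx_window(ctx, fb$t0 - 5, fb$t0 + fb$d + 5)
  x_nob[ib] <- x_nob[ib] - fb$wave(ctx$t[ib]) * attr(xl, "gain_ratio")
  fe <- fit_event_template(ctx, x_nob, iw_e, event_onset, others)
  ir2 <- ctx_window(ctx, fb$t0 - 12, fb$t0 + fb$d + 12)
  x_nor2 <- xl
  resp2 <- fit_resp_local(xl, fe, ctx, ir2,
                          exclude = c(fb$t0 - 1, fb$t0 + fb$d + 1))
  x_nor2[ir2] <- x_nor2[ir2] - resp2
  fb <- fit_bout_template(ctx, x_nor2, fb$t0, fb$d, fc_starts = fb$fc,
                          nm_only = TRUE)
  ## two joint polishes: the localized composite gives the sharpest bout
  ## onset (bout SNR), the full composite the sharpest event onset
  ## (respiration is coherent over all channels); take each one's strength
  jp <- joint_polish(ctx, fb, fe, others, bout_x = xl)
  jpG <- joint_polish(ctx, fb, fe, others, onsets_only = TRUE)
  jp$ev <- jpG$ev
  ## plausibility guard: refined onsets must stay near the detections and the
  ## latency within the pairing radius; otherwise fall back to the component
  ## fits, then to the coarse onsets
  plausible <- function(b, e)
    abs(b - bout_onset) < 6 && (e - event_onset) < 6 &&
      (e - event_onset) > -11 && abs(e - b) < 30
  if (plausible(jp$t0, jp$ev)) {
    b <- jp$t0; e <- jp$ev
  } else if (plausible(fb$t0, fe$ev)) {
    b <- fb$t0; e <- fe$ev
  } else {
    b <- bout_onset; e <- event_onset
  }
  list(bout_onset = b, event_onset = e, latency_ms = (e - b) * 1000)
}
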