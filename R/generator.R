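## Synthetic bed-sensor cohort generator with ground-truth coupling latencies.
##
## The generator states the world the rest of the package is tested against:
## a respiration carrier near 0.366 Hz whose instantaneous frequency is
## transiently upregulated after (or, atypically, before) each sleep-movement
## bout, movement bouts as amplitude-modulated oscillations in the 0.15-0.20 Hz
## band recurring roughly every 2 minutes, smooth random sensor gains, and
## additive Gaussian noise.

#' Configuration for the synthetic recording generator
#'
#' Defaults encode the device and signal constants of the mattress system this
#' package emulates: 32 pressure channels sampled at 54 Hz, respiration near
#' 0.366 Hz, movement bouts with ~2 min recurrence and band content below
#' 0.2 Hz, and a transient ~15% respiratory-frequency upregulation lasting
#' 20 s coupled to each bout.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param night_duration night length in seconds (full nights are 28800 s;
#'   tests use 7200 s for runtime).
#' @param n_sensors number of pressure channels.
#' @param resp_base_freq baseline respiratory frequency in Hz.
#' @param resp_amplitude respiration amplitude, arbitrary pressure units.
#' @param bout_recurrence_mean,bout_recurrence_sd mean and jitter SD of the
#'   interval between consecutive bout onsets, seconds.
#' @param bout_duration_range min/max bout duration in seconds (includes the
#'   rise and fall ramps).
#' @param bout_band_freq min/max of the in-bout oscillation frequency, Hz.
#' @param bout_amplitude peak bout amplitude, pressure units.
#' @param ramp_duration rise/fall time in seconds shared by the bout amplitude
#'   envelope and the respiratory-frequency upregulation (a linear ramp keeps
#'   instantaneous-frequency estimation well-posed).
#' @param upregulation_magnitude fractional increase of respiratory frequency
#'   at a coupled event.
#' @param upregulation_duration total event duration in seconds (ramp up,
#'   hold, ramp down).
#' @param uncoupled_fraction fraction of bouts with no respiratory response.
#' @param noise_sd per-channel additive Gaussian noise SD, pressure units.
#' @param n_bout_channels number of contiguous channels a bout loads onto.
#' @return an object of class `smrr_generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(night_duration = 1200, noise_sd = 0)
generator_config <- function(sampling_rate = 54,
                             night_duration = 28800,
                             n_sensors = 32L,
                             resp_base_freq = 0.366,
                             resp_amplitude = 1.0,
                             bout_recurrence_mean = 120,
                             bout_recurrence_sd = 20,
                             bout_duration_range = c(5, 15),
                             bout_band_freq = c(0.15, 0.20),
                             bout_amplitude = 2.0,
                             ramp_duration = 2,
                             upregulation_magnitude = 0.15,
                             upregulation_duration = 20,
                             uncoupled_fraction = 0.10,
                             noise_sd = 0.3,
                             n_bout_channels = 8L) {
  cfg <- list(
    sampling_rate = sampling_rate, night_duration = night_duration,
    n_sensors = as.integer(n_sensors), resp_base_freq = resp_base_freq,
    resp_amplitude = resp_amplitude,
    bout_recurrence_mean = bout_recurrence_mean,
    bout_recurrence_sd = bout_recurrence_sd,
    bout_duration_range = bout_duration_range,
    bout_band_freq = bout_band_freq, bout_amplitude = bout_amplitude,
    ramp_duration = ramp_duration,
    upregulation_magnitude = upregulation_magnitude,
    upregulation_duration = upregulation_duration,
    uncoupled_fraction = uncoupled_fraction, noise_sd = noise_sd,
    n_bout_channels = as.integer(n_bout_channels)
  )
  num <- unlist(cfg[c("sampling_rate", "night_duration", "resp_base_freq",
                      "resp_amplitude", "bout_recurrence_mean",
                      "bout_recurrence_sd", "bout_duration_range",
                      "bout_band_freq", "bout_amplitude", "ramp_duration",
                      "upregulation_magnitude", "upregulation_duration",
                      "uncoupled_fraction", "noise_sd")])
  if (!all(is.finite(num)))
    stop("generator_config: all numeric parameters must be finite")
  if (cfg$sampling_rate <= 0) stop("generator_config: sampling_rate must be > 0")
  if (cfg$night_duration <= 600)
    stop("generator_config: night_duration must exceed 600 s")
  if (cfg$n_sensors < 1L) stop("generator_config: n_sensors must be >= 1")
  if (diff(cfg$bout_duration_range) < 0 ||
      cfg$bout_duration_range[1] <= 2 * cfg$ramp_duration)
    stop("generator_config: bout durations must exceed the two ramps")
  if (cfg$upregulation_duration <= 2 * cfg$ramp_duration)
    stop("generator_config: upregulation_duration must exceed the two ramps")
  if (cfg$uncoupled_fraction < 0 || cfg$uncoupled_fraction >= 1)
    stop("generator_config: uncoupled_fraction must be in [0, 1)")
  if (cfg$noise_sd < 0) stop("generator_config: noise_sd must be >= 0")
  if (cfg$n_bout_channels > cfg$n_sensors)
    stop("generator_config: n_bout_channels exceeds n_sensors")
  class(cfg) <- "smrr_generator_config"
  cfg
}

## Quantize a time in seconds to the sample grid.
quantize_time <- function(t, fs) round(t * fs) / fs

## Draw one night's bout/event schedule. Returns the ground-truth data frame.
## All onsets are quantized to the sample grid so that true_latency is
## representable exactly.
draw_schedule <- function(cfg, latency_mean, latency_sd) {
  fs <- cfg$sampling_rate
  onsets <- numeric(0)
  t <- 60 + abs(stats::rnorm(1, 0, cfg$bout_recurrence_sd))
  while (t < cfg$night_duration - 60) {
    onsets <- c(onsets, t)
    gap <- stats::rnorm(1, cfg$bout_recurrence_mean, cfg$bout_recurrence_sd)
    gap <- max(gap, cfg$bout_duration_range[2] + cfg$upregulation_duration + 5)
    t <- t + gap
  }
  nb <- length(onsets)
  if (nb == 0L) return(empty_truth())
  durations <- stats::runif(nb, cfg$bout_duration_range[1], cfg$bout_duration_range[2])
  coupled <- stats::runif(nb) >= cfg$uncoupled_fraction
  latency_ms <- stats::rnorm(nb, latency_mean, latency_sd)
  make_truth(cfg, onsets, durations, coupled, latency_ms)
}

make_truth <- function(cfg, onsets, durations, coupled, latency_ms) {
  fs <- cfg$sampling_rate
  onsets <- quantize_time(onsets, fs)
  event_onset <- quantize_time(onsets + latency_ms / 1000, fs)
  latency_q <- (event_onset - onsets) * 1000
  event_onset[!coupled] <- NA_real_
  latency_q[!coupled] <- NA_real_
  ## pairing-ambiguity guard: a latency reaching past half the gap to the
  ## neighbouring bout would make bout-event pairing ill-defined
  if (length(onsets) > 1L) {
    gaps <- diff(onsets)
    half_gap <- pmin(c(Inf, gaps), c(gaps, Inf)) / 2
    bad <- !is.na(latency_q) & abs(latency_q) / 1000 > half_gap
    if (any(bad))
      stop("generator: injected latency exceeds half the inter-bout gap; ",
           "pairings would be ambiguous (bout at ",
           paste(round(onsets[bad], 1), collapse = ", "), " s)")
  }
  data.frame(
    bout_onset_s = onsets,
    bout_offset_s = onsets + durations,
    event_onset_s = event_onset,
    latency_ms = latency_q,
    coupled = coupled
  )
}

empty_truth <- function() {
  data.frame(bout_onset_s = numeric(0), bout_offset_s = numeric(0),
             event_onset_s = numeric(0), latency_ms = numeric(0),
             coupled = logical(0))
}

#' Generate one synthetic night of multi-channel bed-pressure data
#'
#' Assembles a recording as the sensor-mixed sum of (a) a respiration carrier
#' whose instantaneous frequency ramps up by `upregulation_magnitude` for
#' `upregulation_duration` seconds at each coupled event onset, (b) movement
#' bouts as trapezoid-enveloped oscillations in the bout band loading onto a
#' random contiguous channel subset, and (c) additive Gaussian noise. The
#' respiration phase is integrated in closed form so that injected event
#' onsets are exact on the sample grid.
#'
#' @param config a [generator_config()].
#' @param latency_mean,latency_sd class latency distribution in ms (positive
#'   mean = movement typically leads the respiratory response).
#' @param seed integer seed; all randomness in the night flows from it.
#' @param schedule optional explicit schedule overriding the random one: a
#'   data frame with columns `onset_s`, `duration_s`, `coupled`, `latency_ms`
#'   (one row per bout; may have zero rows for a bout-free night).
#' @param case_id,night_index identifiers stored on the recording.
#' @param return_components also return the unmixed respiration and bout
#'   component series (used by spectral sanity checks).
#' @return list with `recording` (an `smrr_recording`: `signal` matrix of
#'   n_samples x n_sensors, `sampling_rate`, `case_id`, `night_index`) and
#'   `truth` (ground-truth data frame: `bout_onset_s`, `bout_offset_s`,
#'   `event_onset_s`, `latency_ms`, `coupled`).
#' @export
#' @examples
#' cfg <- generator_config(night_duration = 1200, noise_sd = 0)
#' night <- generate_night(cfg, latency_mean = 150, latency_sd = 40, seed = 1)
#' night$truth
generate_night <- function(config, latency_mean, latency_sd, seed,
                           schedule = NULL, case_id = "case",
                           night_index = 1L, return_components = FALSE) {
  stopifnot(inherits(config, "smrr_generator_config"))
  if (!is.finite(latency_mean) || !is.finite(latency_sd) || latency_sd < 0)
    stop("generate_night: latency distribution parameters must be finite")
  set.seed(as.integer(seed))
  cfg <- config
  fs <- cfg$sampling_rate
  n <- round(cfg$night_duration * fs)
  t <- (seq_len(n) - 1) / fs

  truth <- if (is.null(schedule)) {
    draw_schedule(cfg, latency_mean, latency_sd)
  } else {
    if (nrow(schedule) == 0L) empty_truth() else
      make_truth(cfg, schedule$onset_s, schedule$duration_s,
                 schedule$coupled, schedule$latency_ms)
  }

  ramp <- cfg$ramp_duration
  hold <- cfg$upregulation_duration - 2 * ramp

  ## respiration: closed-form phase integral of the upregulated frequency
  ## (each event touches only its own support; afterwards it contributes a
  ## constant phase offset)
  uplift <- numeric(n)
  for (ev in truth$event_onset_s[truth$coupled]) {
    i1 <- max(1L, floor(ev * fs) + 1L)
    i2 <- min(n, ceiling((ev + 2 * ramp + hold) * fs) + 1L)
    if (i1 <= i2)
      uplift[i1:i2] <- uplift[i1:i2] + trapezoid_integral(t[i1:i2], ev, ramp, hold)
    if (i2 < n)
      uplift[(i2 + 1L):n] <- uplift[(i2 + 1L):n] + (ramp + hold)
  }
  phase0 <- stats::runif(1, 0, 2 * pi)
  phase <- phase0 + 2 * pi * cfg$resp_base_freq * (t + cfg$upregulation_magnitude * uplift)
  resp <- cfg$resp_amplitude * sin(phase)

  ## bouts: trapezoid-AM oscillation, per-bout carrier and phase
  nb <- nrow(truth)
  bout_sum <- numeric(n)
  bout_wave <- vector("list", nb)
  if (nb > 0L) {
    bout_fc <- stats::runif(nb, cfg$bout_band_freq[1], cfg$bout_band_freq[2])
    bout_ph <- stats::runif(nb, 0, 2 * pi)
    for (b in seq_len(nb)) {
      on <- truth$bout_onset_s[b]
      dur <- truth$bout_offset_s[b] - on
      idx <- max(1L, floor(on * fs)):min(n, ceiling((on + dur) * fs) + 1L)
      env <- trapezoid(t[idx], on, ramp, dur - 2 * ramp)
      w <- cfg$bout_amplitude * env *
        sin(2 * pi * bout_fc[b] * (t[idx] - on) + bout_ph[b])
      bout_wave[[b]] <- list(idx = idx, w = w)
      bout_sum[idx] <- bout_sum[idx] + w
    }
  }

  ## sensor mixing: respiration loads on all channels with smoothly drifting
  ## gains; each bout loads on a random contiguous channel block
  nc <- cfg$n_sensors
  g0 <- stats::runif(nc, 0.6, 1.4)
  drift_T <- stats::runif(nc, 300, 900)
  drift_ph <- stats::runif(nc, 0, 2 * pi)
  sig <- matrix(0, n, nc)
  for (c in seq_len(nc)) {
    gain <- g0[c] * (1 + 0.05 * sin(2 * pi * t / drift_T[c] + drift_ph[c]))
    sig[, c] <- gain * resp
  }
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      k <- min(cfg$n_bout_channels, nc)
      start <- sample.int(nc - k + 1L, 1L)
      chans <- start:(start + k - 1L)
      bg <- stats::runif(k, 0.5, 1.5)
      iw <- bout_wave[[b]]
      for (j in seq_along(chans))
        sig[iw$idx, chans[j]] <- sig[iw$idx, chans[j]] + bg[j] * iw$w
    }
  }
  if (cfg$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(n * nc, 0, cfg$noise_sd), n, nc)

  rec <- structure(
    list(signal = sig, sampling_rate = fs, case_id = case_id,
         night_index = as.integer(night_index)),
    class = "smrr_recording")
  out <- list(recording = rec, truth = truth)
  if (return_components) {
    out$components <- list(resp = resp, bouts = bout_sum)
  }
  out
}

#' @export
print.smrr_recording <- function(x, ...) {
  cat(sprintf("<smrr_recording> case %s night %d: %d samples x %d channels @ %g Hz (%.1f min)\n",
              x$case_id, x$night_index, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, nrow(x$signal) / x$sampling_rate / 60))
  invisible(x)
}

#' Generate a balanced two-class synthetic cohort
#'
#' Draws `n_per_class` MCI-like and `n_per_class` NC-like cases, two nights
#' each. Per-case latencies are i.i.d. from the class latency distribution.
#' Recordings are not materialized here (a full cohort would not fit in
#' memory); each night's signal is regenerated deterministically from its
#' stored seed by [cohort_night()]. Ground truths and the manifest are
#' materialized immediately and are byte-identical across runs with the same
#' seed.
#'
#' @param n_per_class cases per class, at least 2.
#' @param mci_latency_params,nc_latency_params lists with elements `mean` and
#'   `sd` (ms) giving each class's window-latency distribution. The defaults
#'   straddle the 70 ms screening cutoff: MCI-like latencies are typically
#'   negative (respiration change leads movement), NC-like strongly positive.
#' @param config a [generator_config()].
#' @param seed integer master seed.
#' @return an `smrr_cohort`: `manifest` data frame (`case_id`, `label`,
#'   `night_seed1`, `night_seed2`), `truth` (named list of per-case lists of
#'   two ground-truth data frames), `config` and class parameters.
#' @export
#' @examples
#' cfg <- generator_config(night_duration = 1200)
#' coh <- generate_cohort(3, config = cfg, seed = 42)
#' coh$manifest
generate_cohort <- function(n_per_class,
                            mci_latency_params = list(mean = -50, sd = 40),
                            nc_latency_params = list(mean = 150, sd = 40),
                            config = generator_config(),
                            seed) {
  stopifnot(inherits(config, "smrr_generator_config"))
  if (n_per_class < 2) stop("generate_cohort: n_per_class must be >= 2")
  pars <- c(mci_latency_params$mean, mci_latency_params$sd,
            nc_latency_params$mean, nc_latency_params$sd)
  if (length(pars) != 4 || !all(is.finite(pars)))
    stop("generate_cohort: latency distribution parameters must be finite")
  seed <- as.integer(seed)
  n_cases <- 2L * n_per_class
  labels <- rep(c("MCI", "NC"), each = n_per_class)
  case_id <- sprintf("%s%02d", labels, c(seq_len(n_per_class), seq_len(n_per_class)))
  ## per-night seeds derived from the master seed, kept within 32-bit range
  night_seed <- (seed %% 1000000L) * 1000L + outer(seq_len(n_cases), c(0L, 500L), `+`)
  manifest <- data.frame(case_id = case_id, label = labels,
                         night_seed1 = night_seed[, 1],
                         night_seed2 = night_seed[, 2])
  truth <- vector("list", n_cases)
  names(truth) <- case_id
  for (i in seq_len(n_cases)) {
    lp <- if (labels[i] == "MCI") mci_latency_params else nc_latency_params
    truth[[i]] <- lapply(1:2, function(k) {
      set.seed(night_seed[i, k])
      draw_schedule(config, lp$mean, lp$sd)
    })
  }
  structure(list(manifest = manifest, truth = truth, config = config,
                 mci_latency_params = mci_latency_params,
                 nc_latency_params = nc_latency_params, seed = seed),
            class = "smrr_cohort")
}

#' Materialize one night of a synthetic cohort
#'
#' Regenerates the full multi-channel recording for `case_id`, night `night`,
#' deterministically from the cohort's stored per-night seed. The returned
#' truth is identical to the one stored in the cohort.
#'
#' @param cohort an `smrr_cohort` from [generate_cohort()].
#' @param case_id case identifier from the manifest.
#' @param night night index, 1 or 2.
#' @return as [generate_night()].
#' @export
cohort_night <- function(cohort, case_id, night) {
  stopifnot(inherits(cohort, "smrr_cohort"), night %in% 1:2)
  row <- match(case_id, cohort$manifest$case_id)
  if (is.na(row)) stop("cohort_night: unknown case_id ", case_id)
  lp <- if (cohort$manifest$label[row] == "MCI")
    cohort$mci_latency_params else cohort$nc_latency_params
  seed <- cohort$manifest[[paste0("night_seed", night)]][row]
  generate_night(cohort$config, lp$mean, lp$sd, seed = seed,
                 case_id = case_id, night_index = night)
}

#' @export
print.smrr_cohort <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat(sprintf("<smrr_cohort> %d cases (%s), 2 nights each, %.1f h/night, seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$config$night_duration / 3600, x$seed))
  invisible(x)
}
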