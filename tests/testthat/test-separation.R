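test_that("pure tones land in the correct stream (<1% cross-band energy)", {
  fs <- 54
  b_rr <- separate_bands(sine_series(0.37), fs)
  expect_lt(sum(b_rr$sm^2) / sum(b_rr$rr^2), 0.01)
  b_sm <- separate_bands(sine_series(0.08), fs)
  expect_lt(sum(b_sm$rr^2) / sum(b_sm$sm^2), 0.01)
  z <- separate_bands(rep(0, 600 * fs), fs)
  expect_equal(max(abs(z$sm)), 0)
  expect_equal(max(abs(z$rr)), 0)
})

test_that("separate_bands validates rate and duration", {
  expect_error(separate_bands(rep(0, 1000), 1), "sampling rate")
  expect_error(separate_bands(rep(0, 100), 54), "60 s")
  b <- separate_bands(sine_series(0.37), 54)
  expect_length(b$sm, 600 * 54)
  expect_length(b$rr, 600 * 54)
})

test_that("aggregate_channels: identity, weighting, and no-signal error", {
  night <- fixture_night()
  rec <- night$recording
  ## single channel: respiration composite equals the demeaned channel
  rec1 <- structure(list(signal = rec$signal[, 1, drop = FALSE],
                         sampling_rate = 54, case_id = "x", night_index = 1L),
                    class = "smrr_recording")
  comp1 <- aggregate_channels(rec1)
  expect_equal(comp1$rr, rec1$signal[, 1] - mean(rec1$signal[, 1]),
               tolerance = 1e-12)
  ## a clean channel plus a tiny-variance noise channel: composite follows
  ## the clean channel
  set.seed(2)
  clean <- rec$signal[, 2]
  noisy <- rnorm(length(clean), 0, 1e-3)
  rec2 <- structure(list(signal = cbind(clean, noisy), sampling_rate = 54,
                         case_id = "x", night_index = 1L),
                    class = "smrr_recording")
  comp2 <- aggregate_channels(rec2)
  expect_gt(cor(comp2$rr, clean), 0.99)
  ## all-flat input errors
  rec0 <- structure(list(signal = matrix(1, 600 * 54, 3), sampling_rate = 54,
                         case_id = "x", night_index = 1L),
                    class = "smrr_recording")
  expect_error(aggregate_channels(rec0), "no signal")
})

test_that("bout detection recovers injected bouts on a clean night", {
  onsets <- seq(150, 1050, by = 100)
  night <- fixture_night(latencies_ms = rep(100, length(onsets)),
                         onsets = onsets, durations = rep(10, length(onsets)))
  comp <- aggregate_channels(night$recording)
  sm <- separate_bands(comp$sm, 54)$sm
  bouts <- detect_sm_bouts(sm, 54)
  expect_equal(nrow(bouts), length(onsets))
  ## coarse onsets are limited to ~2 s by band-edge smearing; sub-sample
  ## timing is the refinement stage's job (see test-acceptance.R)
  expect_lt(max(abs(bouts$onset_s - night$truth$bout_onset_s)), 2.5)
  expect_true(all(diff(bouts$onset_s) > 0))
  expect_true(all(bouts$offset_s > bouts$onset_s))
  expect_true(all(bouts$peak_amplitude > 0))
  expect_true(all(bouts$auc > 0))
})

test_that("bout detection merges close bouts and returns empty on flat input", {
  night <- fixture_night(latencies_ms = c(100, 100), onsets = c(400, 409),
                         durations = c(6, 6))
  comp <- aggregate_channels(night$recording)
  sm <- separate_bands(comp$sm, 54)$sm
  bouts <- detect_sm_bouts(sm, 54)
  expect_equal(nrow(bouts), 1L)   # 5 s apart < 10 s merge gap
  expect_equal(nrow(detect_sm_bouts(rep(0, 600 * 54), 54)), 0L)
})

test_that("instantaneous_rr: constant tone gives exact 2-min bins", {
  rs <- instantaneous_rr(sine_series(0.37, duration = 600), 54)
  expect_true(rs$usable)
  expect_equal(nrow(rs$bins), 5L)
  expect_true(all(rs$bins$valid))
  expect_equal(rs$bins$rate_bpm, rep(0.37 * 60, 5), tolerance = 0.1)
})

test_that("instantaneous_rr flags pure noise unusable", {
  set.seed(3)
  noise <- band_filter(rnorm(600 * 54), 54, 0.2, 0.55, 0.05, 0.06)
  rs <- instantaneous_rr(noise, 54)
  expect_false(rs$usable)
})

test_that("upregulation raises instantaneous frequency by the configured factor", {
  night <- fixture_night(latencies_ms = 100, onsets = 600, durations = 10)
  comp <- aggregate_channels(night$recording)
  rr <- separate_bands(comp$rr, 54)$rr
  rs <- instantaneous_rr(rr, 54)
  fsr <- rs$sampling_rate
  ev <- night$truth$event_onset_s
  during <- rs$freq[round((ev + 5) * fsr):round((ev + 15) * fsr)]
  before <- rs$freq[round((ev - 60) * fsr):round((ev - 20) * fsr)]
  expect_gte(max(during, na.rm = TRUE) / median(before, na.rm = TRUE), 1.14)
})

test_that("binned rate agrees with an independent zero-crossing count", {
  x <- sine_series(0.37, duration = 600)
  rs <- instantaneous_rr(x, 54)
  crossings <- sum(diff(sign(x)) > 0)   # upward zero-crossings = breaths
  zc_bpm <- crossings / 600 * 60
  expect_lt(max(abs(rs$bins$rate_bpm - zc_bpm)), 1)
})
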