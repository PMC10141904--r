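test_that("segment_windows floors to whole 10-min windows", {
  expect_equal(nrow(segment_windows(7200)), 12L)
  expect_equal(nrow(segment_windows(605)), 1L)
  expect_warning(w <- segment_windows(300), "excluded")
  expect_equal(nrow(w), 0L)
  w <- segment_windows(1500, night_index = 2L)
  expect_equal(w$start_s, c(0, 600))
  expect_equal(w$end_s - w$start_s, c(600, 600))
  expect_equal(w$night, c(2L, 2L))
})

## rate-series stub on a 6 Hz analysis grid
stub_rate <- function(freq_vec, fs = 6) {
  structure(list(freq = freq_vec, freq_raw = freq_vec,
                 valid = !is.na(freq_vec), usable = TRUE,
                 bins = data.frame(), sampling_rate = fs),
            class = "smrr_rate_series")
}

test_that("detect_rr_events applies the 1-SD sustain-and-merge rule", {
  fs <- 6
  w <- list(night = 1L, window = 1L, start_s = 0, end_s = 600)
  ## constant frequency: no events
  expect_equal(nrow(detect_rr_events(stub_rate(rep(0.366, 600 * fs)), w)), 0L)
  ## one clear sustained excursion
  f <- rep(0.366, 600 * fs)
  f[(300 * fs):(315 * fs)] <- 0.44
  ev <- detect_rr_events(stub_rate(f), w)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 300), 1)
  expect_gte(ev$magnitude, 1)
  expect_equal(ev$direction, "up")
  ## a 2-s excursion violates the 3-s sustain rule
  f2 <- rep(0.366, 600 * fs)
  f2[(300 * fs):(302 * fs)] <- 0.6
  expect_equal(nrow(detect_rr_events(stub_rate(f2), w)), 0L)
  ## runs separated by < 5 s merge into one event
  f3 <- rep(0.366, 600 * fs)
  f3[(300 * fs):(304 * fs)] <- 0.44
  f3[(307 * fs):(311 * fs)] <- 0.44
  expect_equal(nrow(detect_rr_events(stub_rate(f3), w)), 1L)
  ## invalid window: under 50% valid samples
  f4 <- rep(NA_real_, 600 * fs)
  out <- detect_rr_events(stub_rate(f4), w)
  expect_equal(nrow(out), 0L)
  expect_false(attr(out, "valid"))
})

test_that("downward changes only appear in bidirectional mode", {
  fs <- 6
  w <- list(night = 1L, window = 1L, start_s = 0, end_s = 600)
  f <- rep(0.366, 600 * fs)
  f[(200 * fs):(215 * fs)] <- 0.28
  expect_equal(nrow(detect_rr_events(stub_rate(f), w)), 0L)
  ev <- detect_rr_events(stub_rate(f), w, bidirectional = TRUE)
  expect_equal(ev$direction, "down")
})

test_that("pairing is greedy nearest-in-time, one-to-one, within the radius", {
  w <- list(night = 1L, window = 1L, start_s = 0, end_s = 600)
  bouts <- data.frame(onset_s = c(100, 200, 300), offset_s = c(110, 210, 310))
  events <- data.frame(onset_s = c(100.074, 199.95, 340))
  s <- pair_and_latency(bouts, events, w)
  expect_equal(nrow(s), 2L)          # bout at 300: nearest event 40 s away
  expect_equal(s$latency_ms[1], 74, tolerance = 1)
  expect_equal(s$latency_ms[2], -50, tolerance = 1)
  ## one-to-one: no event is reused
  expect_false(any(duplicated(s$event_onset_s)))
  ## tie toward the earlier event
  s2 <- pair_and_latency(data.frame(onset_s = 100, offset_s = 110),
                         data.frame(onset_s = c(99, 101)), w)
  expect_equal(s2$event_onset_s, 99)
  expect_equal(nrow(pair_and_latency(bouts[0, ], events, w)), 0L)
})

test_that("window_max_latency keeps the sign of the largest magnitude", {
  expect_equal(window_max_latency(c(60, -90, 20)), -90)
  expect_equal(window_max_latency(74), 74)
  expect_equal(window_max_latency(c(80, -80)), 80)   # tie rule: positive
  expect_true(is.na(window_max_latency(numeric(0))))
  expect_equal(window_max_latency(c(60, -90, 20), rule = "signed"), 60)
})

test_that("case_profile builds a normalized density with coverage flags", {
  p <- case_profile(rep(74, 10), "a")
  expect_equal(sum(p$density * 20), 1, tolerance = 1e-9)
  bin <- findInterval(74, p$breaks_ms)
  expect_equal(p$density[bin] * 20, 1)
  expect_false(p$low_coverage)
  p2 <- case_profile(c(10, 20, 30), "b")
  expect_true(p2$low_coverage)
  set.seed(9)
  m <- rnorm(200, 150, 40)
  p3 <- case_profile(m, "c")
  expect_lt(abs(mean(p3$maxima_ms) - 150), 3 * 40 / sqrt(200))
  expect_equal(sum(p3$density * 20), 1, tolerance = 1e-9)
})

test_that("PDF normalization holds across random profiles", {
  set.seed(21)
  for (k in 1:20) {
    m <- rnorm(sample(5:60, 1), sample(c(-200, 0, 300), 1), runif(1, 10, 200))
    p <- case_profile(m, "x")
    inside <- sum(m >= -1000 & m <= 1000)
    if (inside > 0)
      expect_equal(sum(p$density * 20), 1, tolerance = 1e-9)
  }
})

test_that("full-night latency recovery on a clean fixture night", {
  ## end-to-end through process_night: every recovered latency within one
  ## sample period of its injected value, signs all correct
  night <- fixture_night(latencies_ms = c(150, 74.074, -100),
                         onsets = c(200, 500, 800),
                         durations = c(10, 8, 12))
  pn <- process_night(night$recording)
  s <- pn$samples
  expect_equal(nrow(s), 3L)
  tr <- night$truth
  m <- vapply(s$bout_onset_s, function(b) which.min(abs(tr$bout_onset_s - b)), 0L)
  err <- s$latency_ms - tr$latency_ms[m]
  expect_lt(max(abs(err)), 1000 / 54)
  expect_equal(sign(s$latency_ms), sign(tr$latency_ms[m]))
})

test_that("uncoupled bouts produce no latency sample", {
  sched <- data.frame(onset_s = c(200, 500), duration_s = c(10, 10),
                      coupled = c(TRUE, FALSE), latency_ms = c(100, NA))
  night <- generate_night(fast_config(), 150, 40, seed = 33, schedule = sched)
  pn <- process_night(night$recording)
  expect_equal(nrow(pn$samples), 1L)
  expect_lt(abs(pn$samples$bout_onset_s - 200), 2)
})
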