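test_that("injected latency is reproduced exactly in the ground truth", {
  night <- fixture_night(latencies_ms = 74.074, onsets = 300,
                         durations = 10)
  ## 74.074 ms is 4 sample periods at 54 Hz; the grid-quantized truth is
  ## exactly 4/54 s
  expect_equal(night$truth$latency_ms, 4000 / 54, tolerance = 1e-12)
  expect_equal(night$truth$event_onset_s - night$truth$bout_onset_s,
               4 / 54, tolerance = 1e-12)
  ## onsets quantized to the 54 Hz grid
  fs <- 54
  expect_equal(night$truth$bout_onset_s * fs,
               round(night$truth$bout_onset_s * fs))
  expect_equal(night$truth$event_onset_s * fs,
               round(night$truth$event_onset_s * fs))
})

test_that("empty schedule gives respiration-plus-noise only", {
  cfg <- fast_config()
  sched <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      coupled = logical(0), latency_ms = numeric(0))
  night <- generate_night(cfg, 150, 40, seed = 4, schedule = sched,
                          return_components = TRUE)
  expect_equal(nrow(night$truth), 0)
  expect_equal(night$components$bouts, rep(0, nrow(night$recording$signal)))
})

test_that("ground-truth latency sign convention: positive = movement leads", {
  night <- fixture_night(latencies_ms = c(100, -100), onsets = c(200, 500),
                         durations = c(8, 8))
  expect_gt(night$truth$event_onset_s[1], night$truth$bout_onset_s[1])
  expect_lt(night$truth$event_onset_s[2], night$truth$bout_onset_s[2])
})

test_that("respiration power is concentrated at the base frequency", {
  ## spectral check on the generator's own component, no bouts, no noise
  cfg <- fast_config()
  sched <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      coupled = logical(0), latency_ms = numeric(0))
  night <- generate_night(cfg, 150, 40, seed = 5, schedule = sched,
                          return_components = TRUE)
  resp <- night$components$resp
  n <- length(resp)
  p <- Mod(stats::fft(resp))^2
  f <- (seq_len(n) - 1) / n * cfg$sampling_rate
  half <- f <= cfg$sampling_rate / 2
  inband <- abs(f - cfg$resp_base_freq) <= 0.05 & half
  expect_gt(sum(p[inband]) / sum(p[half]), 0.95)
})

test_that("ambiguity guard rejects latencies past half the inter-bout gap", {
  cfg <- fast_config()
  sched <- data.frame(onset_s = c(300, 360), duration_s = c(8, 8),
                      coupled = TRUE, latency_ms = c(40000, 100))
  expect_error(generate_night(cfg, 150, 40, seed = 1, schedule = sched),
               "ambiguous")
})

test_that("generator config validation", {
  expect_error(generator_config(night_duration = 300), "600")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(sampling_rate = 0), "sampling_rate")
  expect_error(generator_config(uncoupled_fraction = 1.2), "uncoupled")
  expect_error(generate_night(generator_config(night_duration = 1200),
                              NaN, 40, seed = 1), "finite")
})

test_that("cohorts are balanced, unique and byte-identical under one seed", {
  cfg <- fast_config()
  c1 <- generate_cohort(3, config = cfg, seed = 42)
  c2 <- generate_cohort(3, config = cfg, seed = 42)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truth, c2$truth)
  expect_equal(as.vector(table(c1$manifest$label)), c(3L, 3L))
  expect_false(any(duplicated(c1$manifest$case_id)))
  c3 <- generate_cohort(3, config = cfg, seed = 43)
  expect_false(identical(c1$truth, c3$truth))
  expect_error(generate_cohort(1, config = cfg, seed = 1), "n_per_class")
  expect_error(generate_cohort(3, mci_latency_params = list(mean = Inf, sd = 40),
                               config = cfg, seed = 1), "finite")
})

test_that("materialized nights match the stored ground truth", {
  cfg <- fast_config()
  coh <- generate_cohort(2, config = cfg, seed = 7)
  for (id in coh$manifest$case_id[c(1, 3)]) {
    m <- cohort_night(coh, id, 1)
    expect_identical(m$truth, coh$truth[[id]][[1]])
    expect_equal(m$recording$case_id, id)
  }
  expect_error(cohort_night(coh, "nope", 1), "unknown")
})

test_that("class latency means are recovered by the generator (law of large numbers)", {
  cfg <- generator_config(night_duration = 7200, noise_sd = 0)
  coh <- generate_cohort(4,
                         mci_latency_params = list(mean = -50, sd = 40),
                         nc_latency_params = list(mean = 150, sd = 40),
                         config = cfg, seed = 11)
  lat <- function(label) {
    ids <- coh$manifest$case_id[coh$manifest$label == label]
    unlist(lapply(ids, function(id)
      lapply(coh$truth[[id]], function(tr) tr$latency_ms[tr$coupled])))
  }
  mci <- lat("MCI"); nc <- lat("NC")
  expect_lt(abs(mean(mci) - (-50)), 3 * 40 / sqrt(length(mci)))
  expect_lt(abs(mean(nc) - 150), 3 * 40 / sqrt(length(nc)))
})
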