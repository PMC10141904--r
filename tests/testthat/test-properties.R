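## Property-style invariants on generated nights (fixed seeds).

bout_f1 <- function(night, pn, tol_s = 5) {
  truth <- night$truth$bout_onset_s
  det <- pn$bouts$onset_s
  tp <- sum(vapply(truth, function(x) any(abs(det - x) < tol_s), TRUE))
  fp <- length(det) - sum(vapply(det, function(x) any(abs(truth - x) < tol_s), TRUE))
  fn <- length(truth) - tp
  2 * tp / (2 * tp + fp + fn)
}

test_that("bout detection F1 on full nights: >=0.95 clean, >=0.85 at half-amplitude noise", {
  cfg0 <- generator_config(night_duration = 3600, noise_sd = 0)
  night0 <- generate_night(cfg0, 150, 40, seed = 21)
  pn0 <- process_night(night0$recording, analysis_config(refine = FALSE))
  expect_gte(bout_f1(night0, pn0), 0.95)
  ## noise SD equal to 50% of the bout amplitude (2.0)
  cfg1 <- generator_config(night_duration = 3600, noise_sd = 1.0)
  night1 <- generate_night(cfg1, 150, 40, seed = 22)
  pn1 <- process_night(night1$recording, analysis_config(refine = FALSE))
  expect_gte(bout_f1(night1, pn1), 0.85)
})

test_that("latency error at moderate noise: median absolute error <= 25 ms", {
  ## pooled over three seeded nights: the single-night median fluctuates by
  ## several ms between nights, the pooled median estimates the method
  cfg <- generator_config(night_duration = 7200, noise_sd = 0.3)
  errs <- c()
  for (seed in 1:3) {
    night <- generate_night(cfg, 150, 40, seed = seed)
    pn <- process_night(night$recording)
    s <- pn$samples
    tr <- night$truth[night$truth$coupled, ]
    m <- vapply(s$bout_onset_s, function(b)
      which.min(abs(tr$bout_onset_s - b)), 0L)
    errs <- c(errs, s$latency_ms - tr$latency_ms[m])
  }
  expect_lte(median(abs(errs)), 25)
})

test_that("pairing is one-to-one on every window of a processed night", {
  night <- fixture_night(latencies_ms = c(120, -60, 90, 150),
                         onsets = c(150, 400, 650, 950),
                         durations = c(8, 10, 6, 12))
  pn <- process_night(night$recording)
  s <- pn$samples
  expect_false(any(duplicated(s$bout_onset_s)))
  expect_false(any(duplicated(s$event_onset_s)))
})

test_that("pipeline determinism: identical samples across repeated runs", {
  night <- fixture_night()
  p1 <- process_night(night$recording)
  p2 <- process_night(night$recording)
  expect_identical(p1$samples, p2$samples)
})
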