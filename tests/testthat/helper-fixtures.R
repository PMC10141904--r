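## Shared fixtures. Small, fast configurations used across test files; the
## heavyweight cohort for the acceptance criteria is built (once) in
## test-acceptance.R.

fast_config <- function(...) {
  args <- list(...)
  defaults <- list(night_duration = 1200, noise_sd = 0)
  defaults[names(args)] <- args
  do.call(generator_config, defaults)
}

## a clean 20-min night with a known schedule
fixture_night <- function(latencies_ms = c(150, 74.074, -100),
                          onsets = c(200, 500, 800),
                          durations = c(10, 8, 12),
                          noise_sd = 0, seed = 101) {
  sched <- data.frame(onset_s = onsets, duration_s = durations,
                      coupled = TRUE, latency_ms = latencies_ms)
  generate_night(fast_config(noise_sd = noise_sd), 150, 40, seed = seed,
                 schedule = sched)
}

## pure sinusoid helper
sine_series <- function(freq, duration = 600, fs = 54, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

## brute-force Mann-Whitney AUC oracle: concordant pairs + half ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "MCI"]
  neg <- scores[labels == "NC"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
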