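# smrr — sleep movement–respiration coupling biometrics

`smrr` turns raw multi-channel bed-pressure recordings (a sensor mattress
with ~32 piezo-resistive channels sampled at 54 Hz) into a candidate
screening biometric for mild cognitive impairment (MCI): the signed time
latency between a sleep-movement (SM) bout and the transient respiratory
(RR) frequency upregulation coupled to it.

During healthy sleep, movement typically *leads* the respiratory response
by a positive latency; in MCI-like sleep the coupling shortens or reverses
(respiration change leading movement). The package implements the full
chain:

```
raw pressure matrix ──► SM / RR composites ──► zero-phase band streams
      (0.01–0.15 Hz movement, 0.20–0.55 Hz respiration)
  ──► bout detection (median + 4·MAD envelope rule)
  ──► instantaneous respiratory frequency, 2-min binned rates
  ──► 10-min windows, respiratory events by the 1-SD rule
  ──► bout↔event pairing + model-based sub-sample latency refinement
  ──► per-case PDF of window-maximum latencies (20 ms bins)
  ──► LOOCV classification (neural net / Gaussian / kernel / 70 ms rule)
  ──► ROC, Youden operating point, sensitivity/specificity/PPV/NPV
```

The core statistic per analysis window is the latency of largest absolute
value (sign retained); a case is summarized by the density of those window
maxima over both recording nights, and classified MCI-like when latencies
sit at or below the 70 ms cutoff (threshold rule) or by
leave-one-out-validated learned classifiers.

Because the motivating clinical recordings are not public, the package
ships a first-class synthetic cohort generator (`generate_cohort()`) that
emulates the mattress signals — respiration carrier at 0.366 Hz with
trapezoidal +15% frequency upregulation events, movement bouts in the
0.15–0.20 Hz band recurring every ~2 min, smooth random sensor mixing,
additive noise — with exact ground-truth event times and latencies, so
every stage is testable end to end.

## Worked example

```r
library(smrr)

## one clean 20-minute night with three injected couplings
cfg <- generator_config(night_duration = 1200, noise_sd = 0)
sched <- data.frame(onset_s = c(200, 500, 800), duration_s = c(10, 8, 12),
                    coupled = TRUE, latency_ms = c(150, 74.074, -100))
night <- generate_night(cfg, latency_mean = 150, latency_sd = 40,
                        seed = 101, schedule = sched)
night$truth$latency_ms          # grid-quantized injected latencies
#> [1] 148.14815  74.07407 -92.59259
pn <- process_night(night$recording)
pn$samples
#>   night window bout_onset_s event_onset_s latency_ms
#> 2     1      1     199.9871      200.1497   162.57394
#> 1     1      1     500.0079      500.0730    65.07430
#> 11    1      2     799.9948      799.9081   -86.72105
```

Each injected latency is recovered to within one 54 Hz sample period
(18.5 ms), including the sign of the atypical negative coupling — the
pattern that marks the MCI-like class.

Cohort-level screening on the bundled synthetic world:

```r
cohort <- generate_cohort(20, config = generator_config(night_duration = 7200),
                          seed = 42)
cp <- cohort_profiles(cohort)                    # ~15 min, one CPU
ev <- evaluate_cohort(cp$features, cp$labels, seed = 42)
ev$neural_network$roc
#> <smrr_roc> AUC 1.000 | thr 4.23 | sens 1.00 spec 1.00 ppv 1 npv 1
```

with 20 MCI-like cases (latencies ~ Normal(−50 ms, 40 ms)) and 20 NC-like
cases (~ Normal(+150 ms, 40 ms)), two 2-hour nights each: recovered
per-case median window-maximum latencies land near −104 ms (MCI-like) vs
+205 ms (NC-like), the profiles separate perfectly (AUC 1.0, sensitivity /
specificity / PPV all 100%), comfortably above the published operating
point (87% sensitivity / 89% specificity / 88% PPV) that the acceptance
targets require.

## Command line

```sh
Rscript -e 'smrr::smrr_cli()' run-all  --out out/ --seed 42
Rscript -e 'smrr::smrr_cli()' simulate --out cohort/ --seed 7
Rscript -e 'smrr::smrr_cli()' separate --in cohort/MCI01_n1.h5 --out sep/
Rscript -e 'smrr::smrr_cli()' classify --profiles out/profiles \
        --manifest out/manifest.csv --family neural_network,gaussian --seed 42 --out report/
```

## Layout

* `R/generator.R` — synthetic cohort generator with ground truth
* `R/separation.R` — composites, band streams, bout detection, respiratory rate
* `R/coupling.R` — windows, 1-SD events, pairing, latency profiles
* `R/refine.R` — model-based sub-sample onset refinement
* `R/classifier.R` — LOOCV classifiers, ROC, confusion metrics
* `R/pipeline.R`, `R/cli.R`, `R/io.R` — orchestration, CLI, HDF5/CSV/JSON I/O
* `vignettes/smrr-methods.Rmd` — models, assumptions, tunables, limitations
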