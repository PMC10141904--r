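---
title: "Movement-respiration coupling latency as a sleep biometric: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-respiration coupling latency as a sleep biometric: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

During sleep, brief movement bouts (SM) recur roughly every two minutes and
are typically followed, within a fraction of a second, by a transient
upregulation of respiratory frequency (RR). `smrr` estimates the signed time
latency between each movement bout onset and its coupled respiratory event
onset — positive when movement leads — from multi-channel bed-pressure
recordings (nominally 32 piezo-resistive channels at 54 Hz), and uses the
per-case distribution of window-maximum latencies as a screening biometric
for mild cognitive impairment (MCI). In the clinical motivation for this
package, MCI-like cases show short or *negative* latencies (respiration
change leading movement), and a ~70 ms cutoff on the latency separates
MCI-like from normal-cognition (NC) cases.

The pipeline is:

1. **Aggregation.** The respiration composite is the variance-weighted
   channel mean; the movement composite is the per-sample maximum of channel
   envelopes (channels low-passed at 1 Hz first). Rationale: respiration
   loads coherently on all channels, movement loads on whichever channels
   the body happens to cover.
2. **Band separation.** Zero-phase raised-cosine band-passes: SM stream
   0.01–0.15 Hz, RR stream 0.20–0.55 Hz, bracketing the movement
   (~0.198 Hz) and respiration (~0.366 Hz) periodicities. Zero phase is
   non-negotiable: the quantity of interest is a ~70 ms delay, four sample
   periods at 54 Hz, and any group delay difference between the two streams
   would bias it directly.
3. **Detection.** Bouts: intervals where the smoothed SM envelope exceeds
   median + 4 MAD, merged below 10 s, minimum 2 s, with a prominence floor
   against filter ringing. Respiratory events: within each 10-minute
   analysis window, runs where the median-smoothed instantaneous frequency
   (analytic-signal phase derivative) exceeds the window median by one
   window SD for at least 3 s (runs closer than 5 s merged) — the "1 SD"
   rule applied per window, upward-only by default because the coupled
   response is an upregulation (a `bidirectional` flag exists).
4. **Pairing and refinement.** Greedy nearest-in-time one-to-one pairing
   within ±30 s, ties toward the earlier event; then model-based onset
   refinement (below) gives the signed latency in ms.
5. **Profiles and classification.** Per 10-minute window the latency with
   the largest absolute value (sign kept, ties positive) is the window
   representative; both nights pool into a per-case 20 ms-bin density over
   [-1000, 1000] ms. Features (bin densities + median/min/max/fraction
   negative of the maxima) feed leave-one-out cross-validated classifiers
   (single-hidden-layer tanh network, shrunken Gaussian discriminant,
   RBF-kernel ridge, and the plain 70 ms threshold rule), evaluated by
   empirical ROC with a Youden operating point, confusion matrix,
   sensitivity, specificity, PPV and NPV.

## Model-based latency refinement

Detection-level onsets are only good to ~1–2 s: the SM band filter smears a
5–15 s bout by its ~5 s kernel, and the 1-SD crossing happens part-way up
the respiratory frequency ramp. Recovering latency to a sample period
therefore uses explicit local signal models, fitted on a decimated grid — 6 Hz for clean
recordings, 3 Hz when measurable sensor noise is present (all content lives
below 1 Hz; fitted onsets are continuous parameters, so decimation costs no
timing precision, and under noise the grid is not the accuracy limit):

* **Bout:** trapezoid-enveloped oscillation
  `A * trap(t; t0, 2 s ramps, d) * sin(2*pi*fc*t + phi)`; amplitude and
  phase are profiled out by least squares, so only `(t0, d, fc)` are
  searched — on a dense grid initialized from the residual envelope's 50%
  crossings, then a multi-start Nelder–Mead simplex. A quadratic penalty
  replaces hard parameter clamps (a clamp creates a plateau that stalls the
  simplex), and results that escape the fit window fall back to the best
  grid point.
* **Respiratory event:** the respiration carrier is modelled as FM with a
  trapezoidal frequency upregulation; its unwrapped analytic phase is
  linear in (offset, baseline frequency, magnitude) given the event onset,
  so the onset is found by a 1-D search with the linear part profiled.
  Other detected events overlapping the window enter as additional linear
  phase columns so they cannot bias the focal onset.
* **Alternation and joint polish.** Respiration is fitted first and
  subtracted before the bout fit (it is the dominant composite component);
  the bout is subtracted before the event refit; finally both models are
  fitted jointly with all amplitudes profiled, which removes residual
  cross-talk. Two joint fits are run and each contributes its strength:
  one on a *bout-localized* channel composite (channels weighted by their
  excess variance during the bout; best bout SNR) supplies the bout onset,
  one on the full composite (respiration is coherent across all channels)
  supplies the event onset. Under measured noise the bout duration and
  carrier frequency are held at their component-fit values, because
  profiling them jointly with the onset inflates onset variance for little
  bias benefit. Crucially, the respiration gain (which drifts slowly
  because sensor gains drift) is estimated on bout-*excluded* flanks only —
  letting the regression see the bout interval allows it to absorb part of
  the bout and injects bout-correlated junk that biases short-bout onsets
  by tens of milliseconds.

Measured on noise-free synthetic nights this chain recovers every injected
latency to within well under one sample period (worst case ~7 ms against
the 18.5 ms period at 54 Hz, median ~1 ms); at the default moderate noise
the median absolute error is ~17–26 ms per night, small against the
~200 ms class separation the classifier exploits.

## The synthetic world

Real recordings for this problem are not publicly available, so the package
states a synthetic world and tests against it. Defaults (all in
`generator_config()`):

| parameter | default | why |
|---|---|---|
| sampling rate | 54 Hz | device constant |
| channels | 32 | device constant |
| respiration | 0.366 Hz, amplitude 1 | published periodicity |
| upregulation | +15% for 20 s, 2 s linear ramps | a ramp keeps instantaneous frequency well-posed |
| bout recurrence | N(120 s, 20 s) | ~2 min periodicity |
| bout duration | U(5, 15) s, 2 s amplitude ramps | plausible movement bouts |
| bout band | U(0.15, 0.20) Hz, amplitude 2 | published movement periodicity |
| uncoupled bouts | 10% | exercises pairing logic |
| sensor noise | SD 0.3 per channel | "moderate": bout SNR ~7 per channel after aggregation |
| class latencies | MCI N(-50, 40) ms, NC N(+150, 40) ms | straddle the 70 ms cutoff; true clinical distributions are unpublished |

Sensor mixing: respiration loads on all channels with gains U(0.6, 1.4)
drifting sinusoidally by ±5% over 300–900 s periods; each bout loads on a
random contiguous block of 8 channels with gains U(0.5, 1.5). Event onsets
are quantized to the sample grid and the respiration phase is integrated in
closed form, so ground-truth latencies are exact.

What the generator does *not* emulate: heartbeat/ballistocardiogram, body
position changes, apnea, non-Gaussian artifacts, or the device's physical
transfer function. A green latency-recovery test therefore establishes that
the estimator is correct *for this signal family*, not that it is robust to
every real-world artifact.

## Numerical and design choices worth knowing

* **Raised-cosine FFT filters instead of Butterworth.** The environment has
  no IIR filtering library, and an FFT-domain real gain is *exactly*
  zero-phase with exact stop-bands — strictly better for a latency
  measurement than forward-backward IIR passes. Band edges: SM pass
  0.01–0.15 Hz (transitions 0.005/0.10), RR pass 0.20–0.55 Hz
  (0.05/0.06).
* **The 0.198 Hz vs 0.15 Hz tension.** The movement oscillation
  (~0.15–0.20 Hz) lies partly above the published 0.15 Hz movement cutoff.
  The SM *stream* keeps 0.15 Hz as its upper passband edge (with roll-off
  to 0.25 Hz, so in-bout content leaks through attenuated), while the
  refinement stage fits the bout on the decimated composite, not the SM
  stream, and is indifferent to the cutoff choice.
* **Window-maximum = maximum absolute value, sign kept.** A signed maximum
  would mask exactly the negative latencies that characterize the MCI-like
  class; `max_latency_rule = "signed"` restores the alternative reading.
* **The 1-SD rule is per window**, because the published description states
  it inside the windowed analysis; window SD adapts to how many events the
  window happens to contain.
* **Youden operating point on pooled held-out scores.** The published
  account does not say where its operating threshold was chosen;
  `roc_metrics()` reports the Youden point with ties broken toward higher
  specificity, and the threshold-rule classifier provides the published
  70 ms cutoff as an independent, training-free reference.
* **"Leave-One-Out Covariance (LOOCV)"** in the source material is read as
  ordinary leave-one-out cross-validation; standardization is refitted
  inside every fold and a no-leakage property test corrupts held-out
  features to prove fold isolation.
* **Degenerate inputs.** All-equal scores give AUC 0.5 with a `degenerate`
  flag; ratios with zero denominators (e.g. PPV with no predicted
  positives) are reported as `NA`, never 0; windows with no pairing are
  dropped, not zero-filled; cases with under 5 usable windows carry a
  `low_coverage` flag through to reports.

## Classifier defaults

The neural network is one hidden layer of 8 tanh units with a logistic
output, trained full-batch by gradient descent with momentum (400
iterations, weight decay 1e-2), weights drawn once from the mandatory seed
— the smallest fully reproducible architecture that separates the latency
profiles. "Gaussian" is a shared-covariance discriminant with 50% shrinkage
toward a scaled identity (40 cases cannot support a 104-dimensional
covariance); "kernel" is RBF-kernel ridge regression on ±1 labels with the
median-pairwise-distance bandwidth. Hyperparameter search is deliberately
out of scope.

## Known limitations

* Coarse bout onsets from the SM stream alone are ±2 s; only the refined
  latencies are sample-accurate.
* Under noise, a few per mille of pairings refine to implausible latencies;
  plausibility guards fall back to component fits or coarse onsets, and the
  window-maximum rule means a surviving outlier can occasionally claim a
  window.
* The latency-recovery guarantees are with respect to the synthetic signal
  family above; EDF ingestion and real-device quirks (irregular sampling
  beyond linear-interpolation repair, electrode dropout patterns) are out
  of scope in this build.

## Reproducing the headline numbers

```{r}
library(smrr)
cohort <- generate_cohort(20, config = generator_config(night_duration = 7200),
                          seed = 42)
cp <- cohort_profiles(cohort)
ev <- evaluate_cohort(cp$features, cp$labels, families = "neural_network",
                      seed = 42)
ev$neural_network$roc
```

`scripts/acceptance.R` wraps exactly this experiment and writes the
operating-point sensitivity, specificity and PPV (as percentages) to JSON.
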