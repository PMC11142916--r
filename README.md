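# nanorotor

Analysis pipeline for ultrafast single-molecule DNA twist measurements
made with a plasmonic DNA-origami nano-rotor, plus the stopped-flow and
kymograph ensemble assays that accompany them. It is written for
single-molecule biophysicists who need to turn tracked nanoparticle
positions into calibrated twist traces, call enzyme binding states,
quantify DNA loop-translocation events, and fit the population kinetics.

## What it computes

A nano-rotor converts the twist of a torsionally constrained DNA domain
into the polar angle θ of a gold nanoparticle, imaged at 4 kHz. With
B-DNA's helical pitch of 10.5 bp/turn, twist converts to base pairs as

    Δbp = Δθ / (2π / 10.5) = Δθ / 0.598 rad

The package covers:

* **Angle extraction** — sub-pixel 2D-Gaussian spot fitting, algebraic
  circle fit of the rotation centre, `atan2` unwrapping, 100-point
  sliding average (4 kHz → 40 Hz).
* **State segmentation** — a two-level Gaussian-emission hidden Markov
  model (free vs bound; site engagement adds a ~0.60 rad ≈ 1 bp twist
  offset), with K selected by BIC and Viterbi state paths.
* **Sawtooth event detection** — loop-translocation events appear as
  linear positive twist ramps ending in abrupt collapse; the detector
  delimits them, sizes them in bp, fits their ramp rate in bp/s, and
  classifies them (single-to-bound / single-to-free / clustered /
  long-range).
* **Population statistics** — EM fits of bimodal Gaussian mixtures
  (event sizes and rates), exponential-mixture dwell-time MLE with
  BIC model selection and optional right-censoring, Wilson summary
  fractions.
* **Stopped-flow kinetics** — fluorescence anisotropy
  r = (I_VV/(G·I_VH) − 1)/(I_VV/(G·I_VH) + 2), single/double
  exponential phase fits, phosphate-release calibration, and biphasic
  ATPase burst amplitudes in ATPs per enzyme.
* **Kymograph sliding detection** — single-particle tracks from
  confocal line scans and the 4-sd / 5-frame displacement rule for
  sliding initiation.
* **Synthetic data** — a generator for every input (angular traces with
  ground-truth events and dwells, camera frames, kinetic traces,
  kymographs), used throughout the tests for parameter recovery.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate five minutes of a rotor trace at the measured conditions and
run the full chain:

```r
library(nanorotor)

cfg <- rotor_sim_config(duration = 300, seed = 11)
res <- run_pipeline(sim_config = cfg)
print(res)
```

```
<nanorotor_results>
  trace: 1200000 samples at 4000 Hz (300.0 s)
  segmentation: K = 2, bound shift 0.597 +/- 0.018 rad
  events: 13 detected
  -- size_mix --
<gauss_mix_fit> K = 2, n = 13, BIC = 71.3
  1: weight 0.85, mean 5.297 +/- 0.370 (sd 1.227)
  2: weight 0.15, mean 24.328 +/- 3.098 (sd 4.382)
  -- rate_mix --
<gauss_mix_fit> K = 2, n = 13, BIC = 105.7
  1: weight 0.37, mean 9.792 +/- 0.872 (sd 1.925)
  2: weight 0.63, mean 31.398 +/- 2.742 (sd 7.818)
  -- bound_dwell_fit --
<exp_mix_fit> K = 2 (BIC-selected), n = 28, censoring = drop
  1: weight 0.49, lifetime 0.371 +/- 0.129 s
  2: weight 0.51, lifetime 18.580 +/- 5.189 s
  mixture mean 9.66 s
```

Reading the output: the HMM found two angular levels 0.597 rad apart —
the generator's bound-state twist offset (0.60 rad ≈ 1.0 bp) recovered
within its standard error. Thirteen sawtooth events were detected in
300 s; their maximum loop sizes and ramp rates are each fitted as
two-component Gaussian mixtures (at n = 13 the component means are
still noisy — the full-scale recovery below uses 3000 s and ~150
events). Bound dwell times follow a two-component exponential mixture,
as expected when translocation-competent and quiescent engagements mix.

Individual stages compose with the pipe as well:

```r
sim <- simulate_rotor_trace(cfg)
ev  <- sim$trace |>
  sliding_average(window = 100) |>
  (\(tr) detect_sawtooth_events(tr, segment_two_level(tr)))() |>
  classify_events()
summarize_fractions(ev)
```

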