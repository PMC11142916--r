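---
title: "Models and methods behind nanorotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanorotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanorotor)
```

# The measurement and its observables

A plasmonic DNA-origami nano-rotor converts DNA twist into the angular
position of a gold nanoparticle orbiting a fixed centre, sampled by
backscattering imaging at 4 kHz. Because 1 bp of B-DNA corresponds to a
twist of $2\pi/10.5 \approx 0.598$ rad, the unwrapped polar angle of the
particle reports, in real time:

* a reversible positive offset of ~0.60 rad (~1 bp) when the enzyme
  engages its recognition site (the *bound* state),
* sawtooth excursions — a linear positive twist ramp as the motor pumps
  downstream DNA into a constrained loop, terminated by an abrupt
  collapse when the loop releases.

The package implements the full chain from tracked spot positions to
population statistics, together with a synthetic-data generator that
produces every input with known ground truth. Everything downstream is
exercised against that ground truth, so "recovery" always means:
simulate at the study's conditions, analyse blind, compare to truth.

The ensemble side (stopped-flow anisotropy and fluorescence transients,
phosphate-release ATPase bursts) and the confocal kymograph side
(sliding-initiation detection) have their own small models, described
below.

# Angle extraction

`fit_spot()` refines the brightest pixel to sub-pixel precision with a
symmetric 2D Gaussian least-squares fit in a 13 x 13 pixel window.
`estimate_rotation_center()` uses the algebraic (Kasa) circle fit; no
iterative geometric refinement is applied because rotor tracks cover
enough of the circle that the two fits differ by far less than the
tracking noise (the choice matters at the $10^{-3}$ pixel level, so it
is recorded here). `to_angles()` takes `atan2` angles and unwraps them
so successive differences lie in $(-\pi, \pi]$; the sign convention —
increasing angle = downstream translocation — is stored in the trace
metadata.

`sliding_average()` implements the 100-point centred boxcar (4 kHz
$\to$ 40 Hz). Edge policy: the window radius shrinks symmetrically near
the boundaries (a `"valid"` mode that marks incomplete windows `NA` is
available). Odd windows are truly centred and preserve constant and
linear traces exactly; even windows take the extra sample trailing (the
usual boxcar convention), which introduces a half-sample lag. No local
averaging scheme preserves the global mean *exactly* on arbitrary
traces — the edge columns of the smoothing matrix cannot all sum to
one — but the error is $O(\mathrm{window}/n)$ and is property-tested at
that bound.

# The synthetic rotor trace

`simulate_rotor_trace()` builds a continuous-time state sequence and
samples it at 4 kHz:

* free dwells, exponential with mean `dwell_free` (default 1.5 s — the
  paper-scale enzyme concentration binds the site within seconds; this
  value is not a measured quantity, it simply sets how much free-state
  baseline a trace contains);
* bound dwells from the measured exponential mixture (41% at 1.6 s,
  59% at 35.4 s for the ATP condition; 57.4 s single-exponential
  without ATP);
* with probability `event_prob_per_bound` (0.95) a bound dwell ends in
  a sawtooth event: size drawn from a two-mode Gaussian mixture
  (means 4.9 / 21.5 bp), ramp rate from a two-mode mixture
  (11.4 / 32.7 bp/s), duration = size/rate, the ramp rising at
  `rate * 2 * pi / pitch` rad/s from the bound level and collapsing to the
  post-event level within one sample (loop release is not resolved in
  time, so instantaneous collapse is the right idealisation);
* collapse lands in a bound state with probability `p_post_bound`
  (0.77), whose dwell follows the short post-event mixture (37% at
  0.17 s, 63% at 3.5 s); with probability `p_cluster` (0.35) another
  event follows within `cluster_gap`, producing clustered events.

Three generator choices deserve justification:

**Mode weights and rate coupling.** Only the mode *means* are reported
quantities; the weights are not. The package couples events larger than
12 bp to the fast rate mode (the observation is that large events
exclusively translocate fast) and uses size weights (0.75, 0.25) with
marginal rate weights (0.34, 0.66). With those numbers the mean true
event duration is

$$0.75\left(0.453\,\tfrac{4.9}{11.4} + 0.547\,\tfrac{4.9}{32.7}\right)
  + 0.25\,\tfrac{21.5}{32.7} \approx 0.372\ \mathrm{s},$$

matching the reported ~370 ms average loop-translocation lifetime.
Mode standard deviations (1.2 / 3.0 bp, 1.5 / 3.5 bp/s) are set to
plausible single-molecule spreads; size draws are truncated at 2.5 bp
because events below the ~1 bp / 80 ms resolution are not reportable
anyway.

**Angular noise is an Ornstein–Uhlenbeck process.** The measured
fluctuation, 0.35 rad, is quoted *after* 40 Hz filtering, which is only
physical if the raw noise is correlated — white noise at any amplitude
would filter down by $1/\sqrt{100}$. With correlation time
$\tau = 10$ ms, the variance-reduction factor of a 25 ms boxcar is
$2(\tau/T)\left[1 - (\tau/T)(1 - e^{-T/\tau})\right] \approx 0.506$, so
the stationary sd default is 0.49 rad, which filters to
$0.49\sqrt{0.506} \approx 0.35$ rad (verified by simulation in the test
suite). The rotor's true noise spectrum (rotational drag, bead coupling)
is not published; the OU form is a modelling choice recorded in the
configuration.

**Resolvability is enforced, not emergent.** The study reports that 95%
of events are preceded by a clearly resolvable bound state. Short
post-event dwells (0.17 s component) would otherwise make the
resolvable fraction an accident of the dwell mixture, so the generator
enforces it: with probability `p_pre_bound` the pre-event dwell is
drawn conditioned on exceeding 0.1 s (removing only ~3% of the bound
mixture's mass), otherwise it is truncated below 0.045 s ("binding and
initiation closely spaced"). Clustered follow-up events obey the same
rule, which conditions their gap distribution slightly.

One master seed spawns independent per-stream seeds, so regenerating
with the same configuration is bit-identical, and adding a stream never
perturbs another.

# Segmentation

`segment_two_level()` is a Gaussian-emission hidden Markov model
(Baum–Welch + Viterbi, implemented in C++), selecting K = 1 vs K = 2 by
BIC. Three implementation points matter:

* **Emissions are coarse raw-angle bin means** (default 4 filter
  windows = 100 ms). The OU noise is still appreciably correlated
  between 25 ms bins ($\rho \approx 0.3$), and a 2-state HMM on
  correlated emissions will happily *split a single level in two* to
  model the autocorrelation — with a likelihood gain that grows
  linearly in trace length, so no fixed prior can beat it. At 100 ms
  raw bins $\rho \approx 0.05$ and the pathology disappears, while the
  free/bound separation is still ~3 bin-sigma.
* **A fixed broad "ramp" state** rides along with the level states.
  Translocation ramps are strongly positive excursions that would
  otherwise drag the bound level upward; the auxiliary state (mean
  10 MAD above the median, sd 10 MAD, parameters not updated by EM)
  absorbs them, and its bins inherit the nearest level's label.
  Reported levels are per-state *medians* of the bin means, robust to
  the few ramp bins that leak through.
* **Boundary refinement.** After expanding the Viterbi path to full
  rate, each state boundary is moved to the filtered trace's nearest
  midpoint crossing within one bin, restoring filter-window (25 ms)
  boundary resolution. Dwells shorter than ~2–3 bins (0.3 s) are below
  the segmentation's persistence horizon and are swallowed; the event
  detector handles the short post-collapse dwells separately.

`estimate_bound_shift()` recomputes levels as medians of the per-state
bin means, excluding bins adjacent to a transition (and, after
`relabel_events()`, bins inside events), and propagates an AR(1)
effective-sample-size-corrected standard error.

# Sawtooth event detection

Detection runs on the filtered trace on top of the segmentation, rather
than as extra HMM states: ramps are non-stationary and are poorly
modelled by constant-emission states.

1. *Candidates* are maximal runs where the filtered angle exceeds the
   bound level by `rise_threshold` (default 2 filtered-noise sd).
   A run immediately followed (within the collapse window) by a higher
   run is a leading bump of the same ramp and is skipped.
2. *Collapse* is checked after the run's end: within `collapse_window`
   (50 ms) the trace must lose at least `collapse_fraction` (0.8) of
   the accrued rise. Anchoring at the run end, not at the in-run
   argmax, matters: the argmax of a noisy ramp is often mid-ramp.
3. *The ramp foot* is traced back to the last crossing of the bound
   baseline; the *slope* is fitted on the **raw** trace (the boxcar
   smears the ramp ends) with `MASS::rlm` (OLS fallback), iterating the
   baseline-crossing start point to self-consistency.
4. *Significance*: the slope t-statistic is corrected for residual
   autocorrelation with an AR(1) effective sample size — raw-sample OLS
   standard errors are optimistic by almost an order of magnitude —
   and must exceed `slope_tmin` (3). This is what keeps the
   false-positive rate on event-free traces at zero over 600 s while
   retaining unit sensitivity for slow events of 3 bp and above.
5. *Sizing*: the filtered peak lags and underestimates the true
   pre-collapse peak by about `slope * window / (2 * fs)`, so the maximum
   loop size is the ramp fit evaluated at the smear-corrected collapse
   time, minus the pre-event baseline. Duration is the span from the
   fitted baseline crossing to that collapse time, so
   `duration ~ size / rate` by construction when the ramp is linear.

Minimum reportable size is 2 bp (below the stated ~1 bp / 80 ms
resolution sizing is meaningless) and minimum duration 100 ms; all
thresholds are configuration-exposed and echoed into the run manifest.

Per-event precision at the measured noise level: sizes are good to
about ±0.5 bp, but ramp-slope rates carry ~10% (1 sigma) scatter for
typical event lengths — an irreducible consequence of fitting a slope
through 0.1–0.6 s of correlated 0.49 rad noise. Population mode means
are therefore the meaningful quantities; the fitted fast-mode *spread*
is dominated by measurement noise, just as in the real data.

**Pre/post states.** The state before an event is read from the
Viterbi labels one filter window before the ramp foot — pre-event
dwells are long, so HMM persistence beats any local window average.
The state after collapse can be much shorter than an HMM bin, so it is
classified by level proximity of a short window after the collapse has
settled, truncated at the next event; windows too short to classify
give `unresolved`. Consequence (documented deliberately): post-collapse
bound dwells shorter than ~80 ms are unclassifiable, so the end-to-end
post-bound fraction is biased low by roughly 5–10% relative to the
generator's `p_post_bound`; `summarize_fractions()` therefore excludes
unresolved post states from that denominator, while the pre-bound
fraction keeps unresolved cases in its denominator, mirroring the
"95% clear / 5% ambiguous" accounting of the original analysis.

`classify_events()` applies the closed-interval cluster rule (gap
$\le$ 2 s) and the 12 bp long-range threshold; alternative thresholds
are arguments, not constants.

# Population statistics

`fit_gaussian_mixture()` and `fit_exp_mixture()` are EM fitters with
seeded restarts; both record their log-likelihood trajectory, and
monotonicity is asserted in the tests. K for dwell mixtures is chosen
by BIC (the original analysis names no criterion; BIC is the
conservative default for nested exponential families). Censored dwells
are dropped by default — there is no indication censoring was modelled
in the source analysis — and a right-censored EM (`censoring = "mle"`,
using the exponential memorylessness in the E-step) is available and
demonstrably less biased under heavy censoring. Standard errors come
from the observed Fisher information (numerical Hessian); the K = 1
exponential closed forms are exact. Sizes and rates are fitted as
independent 1D mixtures, as in the source analysis, which found no
direct size–rate dependence; no joint 2D mixture is attempted.

# Stopped-flow kinetics

`anisotropy()` implements $r = (I_{VV}/(G I_{VH}) - 1)/(I_{VV}/(G I_{VH}) + 2)$,
bounded in $[-0.5, 1)$ for positive intensities and invariant under
common channel scaling (both property-tested). `fit_exponential_phases()`
fits one or two saturating/decaying exponentials by Levenberg–Marquardt
(`minpack.lm`), auto-detecting direction, excluding a configurable
2 ms mixing dead time, and reporting rates fastest-first.
`pbp_calibrate()` grows the calibration line from the three lowest
standards until a point's prediction residual signals saturation
(fluorescence saturates as free phosphate approaches the reporter
concentration). `atpase_burst()` converts fluorescence to phosphate to
ATPs per enzyme and fits two rising phases; the biphasic model uses two
saturating exponentials (a burst + linear-tail variant sits behind
`model = "burst_linear"`), reports the fast amplitude as the burst size,
and flags the slow phase poorly constrained when the trace is shorter
than $2/k_{slow}$. Whether the "ATPs in the first phase" should be the
fast amplitude or the value at a cutoff time is not specified in the
source; the amplitude is used and the full fit is returned so the
alternative is one line away. `cumulative_steps()` and `half_time()`
are the small utilities behind step overlays and 50%-crossing times.

# Kymograph sliding detection

`build_track()` takes per-line background-subtracted centroids around
the brightest pixel, greedily linked within a max-jump window; lines
without a qualifying pixel stay as gaps. `detect_sliding()` is the
displacement rule verbatim: an event is a maximal run of at least 5
consecutive non-gap lines displaced from the baseline mean by strictly
more than 4 baseline sd. Gaps reset the run (the conservative reading —
the source does not say how its tracker handled gaps), the sd is
floored at 0.05 px to avoid zero-sd degeneracy on noiseless synthetic
tracks, and the baseline defaults to all pre-time-zero lines.
Initiation time is `(start_line - t0_line) * line_time`; detection
latency (the time diffusion needs to exceed 4 sd for 5 lines) is
reported separately by the tests, and shrinks with the diffusion
coefficient.

# Problem sizes, tolerances, degenerate inputs

The recovery suites run at the sizes a desk check warrants: the
end-to-end trace is 3000 s at 4 kHz (~170 true events, the scale at
which all mode means resolve at 3 s.e.), dwell fits use 2000 draws,
K-selection accuracy uses 100 seeded repeats at 600 draws each, and
Monte-Carlo checks use tens of seeds. EM tolerances are
$10^{-8}$–$10^{-10}$ relative log-likelihood with 4–10 restarts;
HMM emissions floor their sd at machine level so noiseless traces
segment exactly; all-identical mixture inputs, empty event lists,
collinear circle points, flat frames and saturated calibrations raise
informative errors rather than numbers.

# What the generator does not emulate

Synthetic traces contain no slow instrumental drift, no bead-tether
compliance or z-coupling, no tracking dropouts, no negative
(upstream) twist excursions, and stationary Gaussian OU noise rather
than the possibly heavier-tailed fluctuations of a real rotor. Passing
recovery tests therefore demonstrates the *analysis chain's*
correctness and calibration at realistic noise, not robustness to every
instrumental pathology; the thresholds most sensitive to that gap
(rise threshold, collapse window, slope significance) are deliberately
configuration-exposed.

# Known limitations

* The segmentation cannot resolve level dwells below ~0.3 s; short
  post-collapse dwells are handled by the event classifier instead,
  with the documented downward bias on the post-bound fraction.
* Per-event rates carry ~10% scatter at the measured noise level;
  single events should not be over-interpreted.
* The detector does not look for negative ramps (none were observed in
  the source data); a negative excursion would at most appear as an
  unexplained free-level dip.
* The exponential-mixture Hessian can be ill-conditioned when
  component lifetimes approach each other; standard errors are then
  reported as `NA` rather than invented.
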