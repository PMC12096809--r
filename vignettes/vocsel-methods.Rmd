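---
title: "Quantifying call selectivity of simulated cortical units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying call selectivity of simulated cortical units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocsel)
```

## The problem

Bats use a rich vocal repertoire: millisecond-scale multiharmonic
echolocation clicks, tonal harmonic "appeasement" calls, and long pulsed
aggression trains. How specifically single cortical units encode these call
types can be quantified in two complementary ways: by *response strength*
(does one call or call category drive many more spikes per bin than the
others?) and by the *temporal spike pattern* (can a single trial's spike
train be assigned to the call category that evoked it?). `vocsel`
implements both analyses together with a synthetic stimulus library and a
parametric spiking-unit simulator, so that the full pipeline is testable
end to end without access to recorded data, which are not publicly
available for this preparation.

The two simulated unit classes mirror the two cortical regions compared in
the underlying experiments: *frontal auditory field* (FAF)-like units with
long latency (35 ms), tonic ~95 ms responses, high trial-to-trial jitter
and weak stimulus locking, and *dorsal auditory cortex* (dAC)-like units
with short latency (6 ms), phasic, precisely envelope-locked responses.

## Stimulus synthesis

`synth_call_library()` builds 15 calls in 3 categories of 5 variants:

* **echolocation** — < 3 ms, downward frequency-modulated, multiharmonic;
  the fundamental sweeps ~45 to 21 kHz so that the dominant second harmonic
  spans ~90 to 42 kHz. (A fundamental itself sweeping 90 to 40 kHz could
  not carry harmonics below the 96 kHz Nyquist limit of the 192 kHz
  sampling rate.)
* **appeasement** — 25 to 46 ms harmonic stacks on a ~17 kHz fundamental
  with shallow sinusoidal frequency modulation.
* **aggression** — 134 to 271 ms trains of ~4 ms broadband elements at
  ~8 ms intervals on a 8 to 12.5 kHz fundamental.

Variants within a category differ deterministically (per seed) in duration,
fundamental frequency (±5 %) and modulation parameters. All calls are
peak-normalized; absolute level is a per-unit property applied by the
simulator, because stimulation in the reference experiments was calibrated
relative to each unit's threshold. `acoustic_features()` computes the four
descriptors used to verify that the categories cluster (spectral centroid,
temporal centroid, duration, harmonic ratio). The harmonic ratio uses ±3 %
bands around the first 10 multiples of the autocorrelation-estimated
fundamental — the feature name fixes the quantity, not the estimator, so
the estimator is a package choice.

## The unit simulator

`simulate_call_response()` draws independent trials from an inhomogeneous
Poisson process (exact thinning on a 0.25 ms grid):

```
rate(t) = baseline + gain * weight(category) * kernel(t - onset - latency_i)
```

with per-trial latency `latency_i` jittered by a zero-truncated Gaussian.
The driven kernel is built from the stimulus envelope (analytic-signal
magnitude, 1 ms smoothing):

* a **sustained** component — the envelope convolved with a causal
  exponential (`decay_ms`), modeling response persistence beyond stimulus
  offset;
* a **transient** component — the 4th power of the positive envelope
  derivative, concentrated within ~0.5 ms of each amplitude-modulation
  onset. This is what gives phasic units reproducible millisecond spike
  timing: a smooth envelope-shaped rate alone produces no repeatable fine
  structure across Poisson trials, and nearest-template classification at
  fine resolution then degenerates into a bias toward low-spike-count
  templates.

`transient_weight` sets the fraction of driven spikes locked to AM onsets
(0.6 for phasic, 0 for tonic units). Tonic units use a latency-delayed
plateau of `response_duration_ms` mixed with a weak (20 %) envelope-locked
component; a pure plateau would carry *zero* category information at any
timescale, contradicting the above-chance FAF classification the analysis
is meant to exhibit. Total driven spike mass grows sublinearly with
effective stimulus duration (`1.6 * t_eff^0.75`, instantaneous rate capped
at 3x gain), an adaptation-like compression without which a 200 ms
aggression train would trivially evoke ~20x the spikes of an echolocation
click and reduce classification to spike counting. With the dAC defaults
this yields ~3 (echolocation), ~10 (appeasement) and ~25 (aggression)
spikes per trial.

`simulate_tone_grid()` drives the same kernels over the 5–80 kHz
(1/8-octave) x 80–15 dB tone grid with a V-shaped threshold curve whose
slope is set by the profile's Q10dB, making closed-loop parameter recovery
possible. The SPL step (5 dB) is a package default; only the range is
anchored. `make_population()` produces log-normally jittered copies of a
template profile; the category-weight spread (sd 0.3) was chosen so that
only a minority of units are strength-selective for a single category
(PIcat = 1), matching the reported population distributions.

## Tuning metrics

`compute_fra()` reduces each grid cell to the median driven count over the
10 repetitions inside a counting window (onset to onset + 100 ms by
default; configurable for longer tonic responses), minus the expected
spontaneous count scaled from the 50 ms pre-stimulus window. Whether the
published analysis subtracted spontaneous counts is not stated; we
subtract and document it. A cell is *responsive* when its median count
exceeds the pooled spontaneous mean + 2 SD (counts scaled to the window).
BF is the argmax cell (ties: lowest frequency, then highest level); CF is
the responsive cell at the lowest level (ties: frequency nearest BF);
Q10dB divides CF by the width of the contiguous responsive run at
CF-threshold + 10 dB, with edges at the outermost responsive grid
frequencies and a `censored` flag when the run touches the grid edge.

Latency and response duration come from a 1 ms PSTH (pooled over
responsive grid cells). The evoked epoch consists of bins above the
spontaneous mean + 2 SD with at least two consecutive suprathreshold bins,
*anchored at the response maximum* and extended in both directions over
gaps of at most 10 ms. Anchoring matters: with pooled PSTHs of hundreds of
trials, ~2 % of pre-onset bins cross a 2 SD threshold by chance, and a
naive "first crossing" rule mis-assigned latencies by tens of ms in ~7 %
of long-latency units. Latency uses the first epoch bin's midpoint (the
increase occurs at an unknown time within the bin). First-crossing
latencies are still biased early by roughly twice the trial-to-trial
jitter SD — an intrinsic property of threshold-crossing latency
estimation, which is why parameter-recovery checks use low-jitter
(≤ 1 ms) units. Across a 40-unit population, programmed CF, latency and
duration are recovered with rank correlations > 0.99.

## Response-strength selectivity

All 15 calls share one *response window*: per call, the evoked epoch of
the 2 ms trial-summed PSTH is found with the same mean + 2 SD rule; the
window starts at the earliest onset across calls and has the length of the
longest per-call evoked duration. Response strength is the maximum bin
count inside the window; the category response is the *sum of the five
per-call strengths* (the printed definition supports either sum-of-max or
max-of-sum; sum-of-max keeps the call- and category-level indices on the
same per-call statistic). PIcat counts categories at ≥ 50 % of the
maximum category response (1 = fully selective, 3 = unselective); PIcall
does the same across the 5 calls of one category (1 to 5). The 50 %
boundary is inclusive. Both indices are invariant to uniform scaling of
all responses.

## Spike-pattern classification

The core computation. Single-trial PSTHs (1 ms bins) are convolved with a
unit-area Gaussian whose *total support* is the integration window (2 or
200 ms) and sigma = support/6, truncated at ±3 sigma — the Gaussian
parameterization is not fixed by the published description, so it is a
documented package convention (note that under it, two impulses 100 ms
apart remain bimodal even at the 200 ms window, since their separation is
3 sigma). Patterns are restricted to the shared response window and
zero-padded to a common length.

Per resample, a test (call, trial) is drawn — test calls stratified so
each call serves equally often — one template trial is drawn per candidate
call ("from all other presentations": the test call's template comes from
its remaining 19 trials, so a pattern is never compared to itself), and
the test is assigned to the class of the Euclidean-nearest template, with
exact ties broken uniformly at random (forced choice). 10,000 resamples
accumulate into a row-stochastic confusion matrix (3x3 over categories, or
5x5 over one category's calls). The engine is verified against exhaustive
enumeration of all test/template combinations on small cases. Single-trial
templates are the default; trial-averaged templates were considered and
rejected as the default because the description compares against
individual presentations.

The selectivity index of a probability row is
`SI = max - (mean(rest) + sd(rest))` with the sample (n-1) SD; its maximum
is 1, and a chance row yields 0. A unit-level SI is the maximum over rows.

## What the synthetic tests do and do not show

The simulated cohorts reproduce the qualitative physiology: dAC-like units
classify categories far better than FAF-like units at both integration
windows and carry higher SIs; within the FAF-like cohort the 2 ms window
beats the 200 ms window; echolocation calls are classified best at 2 ms
and aggression calls at 200 ms. Two caveats are worth stating plainly:

* **Chance matrices are not entry-wise uniform.** For a *fixed* finite
  data set, nearest-template decoding of pure-baseline activity favors
  whichever call's realized trials contain the lowest-norm patterns (an
  empty template at 2 ms smoothing beats every non-overlapping
  alternative). Entries deviate from 1/K by up to ~0.1–0.2 per data
  realization — far beyond the binomial resampling error — and only
  average out over many independent units. This excess variance of
  cross-validated chance decoders is intrinsic to the method; the engine's
  unbiasedness is instead established by enumeration equivalence and
  symmetry tests.
* **The 200 ms window is "too good" in simulation for dAC-like units.**
  Stationary Poisson units retain perfectly stable spike-count and
  response-duration differences between categories, so coarse-resolution
  classification sits near ceiling (~0.98) and the recorded-population
  advantage of the 2 ms window over the 200 ms window does not reproduce
  in the dAC-like cohort (it does in the FAF-like cohort). Recorded units
  presumably carry slow nonstationarities that degrade rate cues; the
  simulator deliberately does not model them.

The generator emulates first-order response statistics (latency, duration,
jitter, envelope locking, adaptation-like count compression) but not
refractoriness, non-Poisson reliability, across-trial drift, or
anesthesia-state dynamics. Passing tests therefore validate the *analysis
chain*, not biological realism of every spike.

## Problem sizes and numerical choices

Default test and pipeline sizes keep everything deterministic and fast:
20 trials per call, 10 per tone, 500–2,000 resamples for cohort-level
checks and the full 10,000 for single-unit matrices; cohorts of 20 + 20
units for directional comparisons and 40 units for tuning recovery. Exact
distance ties are detected with a relative tolerance of 1e-9; all RNG use
passes through explicit seeds fanned out per unit and stimulus by stable
string hashing, so adding units never perturbs existing spike trains.
Statistical comparisons (two-sample t, Wilcoxon rank sum, one-way ANOVA
with Tukey HSD) delegate to the standard R implementations at alpha = 0.05.
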