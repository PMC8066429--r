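---
title: "Spike-train e-types, event responses, and synchrony: methods"
author: "spikeEtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train e-types, event responses, and synchrony: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeEtypes)
```

## What this package computes

`spikeEtypes` analyzes extracellular spike trains recorded while an animal
performs probabilistic Pavlovian conditioning: two auditory cues predict
water reward or air-puff punishment with fixed contingencies (by default
80/10/10 reward/punishment/omission after the likely-reward cue and
25/65/10 after the likely-punishment cue), and reinforcement arrives at a
uniformly random 400--600 ms delay after cue offset. From the spike
timestamps, trial table and lick timestamps of one session the package

1. classifies each unit into electrophysiological types ("e-types") from
   its spike autocorrelogram: bursting vs non-bursting, and beta- vs
   gamma-rhythmic;
2. splits each train into burst events and single spikes by an
   inter-spike-interval rule and asks whether the two streams carry
   different event information;
3. tests peri-event responses (activation/inhibition, latency,
   expectation contrasts) for cues, reward, punishment and virtual
   omission events;
4. quantifies anticipatory licking and its discrimination between cues;
5. detects fine-timescale pairwise correlations (zero-lag synchrony,
   putative monosynaptic excitation) against jitter-surrogate confidence
   bands, and groups synchronously firing units into assemblies.

Because the recordings this style of analysis targets are not freely
redistributable, the package ships a fully seeded synthetic-session
generator with ground truth. Every analysis stage is validated against
that generator; the same generator drives the test suite.

## Data model and conventions

All event times are **seconds** on one session clock, as floating point;
milliseconds appear only on correlogram lag axes and are labeled as such.
Every binned quantity uses half-open intervals `[lo, hi)` so no event is
counted twice at a bin edge. Sessions round-trip through a plain-text
bundle (`spikes.csv`, `trials.csv`, `licks.csv`, `units.csv`,
`meta.json`) with timestamps written at 0.1 microsecond precision.
Omission trials carry no reinforcement time; analyses that need an
omission alignment point use a *virtual* reinforcement at cue offset +
500 ms, the midpoint of the 400--600 ms delay distribution.

## Correlograms

Auto- and cross-correlograms count ordered spike pairs by lag in bins
centered on multiples of the bin width. Defaults: ACG 1 ms bins,
±500 ms window (resolves sub-10 ms burst peaks and leaves a long
baseline); CCG 0.5 ms bins, ±50 ms window (resolves 1--2 ms synchrony
features). The ACG zero-lag bin is excluded -- self-coincidences carry no
information -- and ACGs are exactly symmetric. The implementation is a
sort-merge sweep (O(n log n + pairs)), but its correctness is defined by,
and tested against, brute-force pair enumeration. Smoothing uses a
mass-conserving Gaussian kernel (edge kernels renormalized to their
in-range mass).

## Burst and rhythmicity indices

ACG-peak-based burst and rhythmicity criteria are widely used but rarely
standardized across laboratories, so the indices here are this package's
own bounded, scale-free formulations of those criteria, and every
constant is a configuration key.

**Burst index.** `BI = (P - B) / max(P, B)` with `P` the maximum smoothed
ACG count over 1--10 ms lags and `B` the mean over 180--200 ms. `BI` is
bounded in [-1, 1], scale-free, and 0 for an empty ACG. A unit is
*bursting* when `BI >= 0.5` (and has at least 100 spikes; fewer spikes
mean "excluded", not "non-bursting"). The 0.5 default asks the short-lag
peak to at least double the baseline. This cut was chosen analytically
from the generator classes before any test was run: simulated bursters
(intra-burst ISIs 3--8 ms) sit near 0.9, homogeneous Poisson units near
0.1, and -- importantly -- strongly rate-modulated units sit near 0.3,
because a sinusoidal rate modulation of depth m elevates the expected ACG
at short lags by m²/2 (≈ 0.32 at m = 0.8) without any burst firing. A
threshold of 0.2 would call every deeply modulated rhythmic unit
bursting; 0.5 separates all three classes.

**Rhythmicity indices.** For each band (beta 13--30 Hz, lags 33.3--76.9
ms; gamma 30--100 Hz, lags 10--33.3 ms),
`RI = (P - T) / max(P, T)` with `P` and `T` the in-band maximum and
minimum of the smoothed ACG. An oscillation at frequency f swings the ACG
between `1 + m²/2` and `1 - m²/2` times baseline within its band, so the
in-band peak-to-trough contrast reaches ≈ 0.49 at m = 0.8 while a Poisson
unit stays near 0.15; the rhythmicity threshold is `RI >= 0.35`. A
long-lag baseline (as used for the burst index) was rejected for RI on
analytic grounds: at beta frequencies the 180--200 ms window itself
contains oscillation peaks (3.6--4 periods of 20 Hz), biasing the
reference upward and pushing the index of a genuine m = 0.8 oscillator
below any workable threshold.

**Band assignment and frequency.** The ACG of an f Hz oscillator has
equal-height peaks at 1/f, 2/f, 3/f, ...: a 40 Hz unit shows a 50 ms peak
squarely inside the beta lag range, so "which band has the larger index"
cannot identify the band. The band is instead assigned from the *first*
prominent ACG peak in the combined 10--76.9 ms range -- the fundamental --
and the rhythm frequency is `1000 / lag` of that peak. Peak finding uses
a slightly wider smoothing kernel (≥ 2 ms SD) than the indices and
requires an interior local maximum at least halfway between the in-range
minimum and maximum, so single-bin noise bumps on a rising flank are not
mistaken for the fundamental. On top of the index threshold, the rhythmic
label requires the in-band peak-to-trough swing to exceed 8 Poisson-noise
SDs (with the smoothing-adjusted count variance): the bounded index alone
is blind to sample size, and for low-rate or short recordings the band
extrema of a *flat* ACG already reach RI ≈ 0.35. The constant 8 sits
above the measured null distribution of the swing z-score (99.9th
percentile ≈ 7 across Poisson units spanning 4--20 Hz and 600--1500 s)
and far below the weakest genuine m = 0.8 oscillator (z ≈ 13). Bursting
and rhythmic labels are independent; a unit can be both.

```{r etype-demo}
u <- simulateUnit(unitSpec("rhythmic", baselineHz = 10,
                           rhythm = list(freqHz = 40, depth = 0.8)),
                  durationS = 600, seed = 1)$spikes
classifyEtype(u)[, c("burst_index", "beta_index", "gamma_index",
                     "rhythm_band", "rhythm_freq_hz")]
```

## Burst parsing

A burst starts at a spike whose ISI to the next spike is **< 10 ms** and
extends while subsequent ISIs stay **< 15 ms**; a spike inside a burst
cannot start a new one; all other spikes are singles (strict
inequalities). The intra-burst bound is configurable up to 30 ms to
support robustness checks with slower bursts. For event alignment each
burst is represented by its first spike (one event per physiological
burst); an all-burst-spikes mode is available since the field uses both.
The burst/single dissociation test runs the standard event-response test
separately on the burst-event train and the single-spike train at
alpha = 0.01 and reports the joint category (concordant / opposite /
burst-only / single-only / neither).

A caveat the synthetic experiments exposed: when the single-spike rate is
strongly driven after an event, chance ISIs below 10 ms in the dense
single train create spurious burst onsets that can mask genuine burst
suppression. This is a property of any ISI-threshold parser at high
rates, not of this implementation.

## Event responses

PETHs are trial-averaged rates (spike count per bin across events divided
by `n_trials x bin`), 20 ms bins over ±1 s by default. Z-scoring uses the
baseline window's own bin mean and SD, so baseline bins have mean 0 and
SD 1 by construction; a zero-SD baseline raises a typed
`degenerateBaseline` condition that the pipeline records instead of
crashing.

Significance uses per-trial spike counts in baseline `[-0.5, 0)` vs
response `[0, 0.5)` windows (converted to rates so unequal windows stay
comparable) under a two-sided Mann-Whitney U test at alpha 0.001; the
direction is the sign of the median difference. The windows fit inside
the cue-to-reinforcement epoch and are configurable, since the upstream
convention is not published. Latency is the time of the |z| extremum
within `[0, 0.6)` s. Expectation contrasts compare mean response-window
counts between two outcome conditions per unit, excluding units with
fewer than 5 trials in either condition, and test the per-unit
differences with a two-sided Wilcoxon signed-rank test. Response
fractions are reported raw, without multiple-comparison correction across
units (noted in the output metadata); group contrasts of fractions use
2x2 chi-square tests without continuity correction.

## Behavior

Anticipatory licking is counted per trial between cue onset and (virtual)
reinforcement and normalized by the window length. Because trials of the
two cue types are unpaired, the default discrimination test is the
rank-sum test, although a paired session-block mode (pairing trials by
within-cue order, Wilcoxon signed-rank) is provided for fidelity with the
field's reporting habits. Zero licking yields a degenerate,
non-discriminating result rather than an error. Per-subject
discrimination deltas can be rank-correlated (Spearman) with per-subject
neural responsiveness fractions.

## Synchrony and assemblies

The null model for a pair's CCG is spike-time jitter: every target spike
is displaced by Uniform(±25 ms) in each of 1000 surrogates, which
destroys structure at the few-millisecond co-firing scale while
preserving slower rate comodulation. Pointwise 95% bands are per-bin
percentiles of the surrogate CCGs. Both the observed CCG and every
surrogate are smoothed with the same 0.5 ms SD kernel before percentiles
are taken -- the statistic remains exchangeable under the null, and wide
peaks stop fragmenting into noisy sub-runs.

Features are maximal runs of at least 2 consecutive bins above the upper
band (an implicit guard against isolated exceedances among ~200 bins).
Feature width is the full width at half maximum of the excess above the
band midline around the run's peak: unlike the raw run length, FWHM does
not grow with peak amplitude, so the narrow/broad boundary reflects peak
shape. Classes follow the field's reading: a run containing lag 0 is
narrow zero-lag synchrony if narrower than 3 ms, broad otherwise
(the printed narrow range is "1--2 ms", broad "≥ 3 ms"; the 2--3 ms gap
resolves to narrow); a run not containing 0, at most 2 ms wide and
centered 1--4 ms from zero, is putative monosynaptic excitation.
Inhibitory (trough) features are deliberately out of scope.

Zero-lag false positives require the lag-0 bin *and* a neighbor to exceed
the 97.5th percentile simultaneously, which keeps the empirical sync
false-positive rate on independent Poisson pairs well under 5% (measured
over 500 pairs in the test suite). Assemblies are connected components
(size ≥ 2) of the synchrony subgraph; a unit is "synchronous" iff it has
at least one synchrony edge -- monosynaptic edges do not confer
membership.

## The synthetic-session generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is validated under.

* **Trials**: cues equiprobable; outcomes from the 80/10/10 and 25/65/10
  contingency tables; reinforcement delay Uniform(0.4, 0.6) s after cue
  offset; cue duration 0.5 s; inter-trial interval Uniform(3, 6) s plus a
  2 s post-trial consumption buffer. Cue duration and ITI are not printed
  in the source literature; 0.5 s tones and multi-second ITIs are
  standard for head-fixed Pavlovian work.
* **Units**: homogeneous Poisson (baseline 10--20 Hz, typical pallidal
  rates); bursting units as a Poisson burst-initiation process (2 Hz)
  each emitting 1 + Poisson(2) extra spikes at Uniform(3, 8) ms ISIs --
  safely inside the <10/<15 ms parse rule -- over sparse 2 Hz singles;
  rhythmic units as inhomogeneous Poisson with rate
  `r0 (1 + m cos 2πft)`, m = 0.8. Event responses are multiplicative
  alpha-function rate kernels (sign, amplitude, onset latency, rise time),
  multiplicative so that inhibition can never push a rate below zero.
* **Pairs**: common input as a shared 2 Hz Poisson event train copied by
  each unit with probability 0.3 (narrow: 0.5 ms copy jitter) or 0.5
  (broad: 3 ms jitter) over 5 Hz backgrounds; synaptic coupling as a 15%
  per-presynaptic-spike transmission probability at Normal(2, 0.3) ms
  delay.
* **Licks**: piecewise-constant inhomogeneous Poisson -- 0.5 Hz baseline,
  cue-dependent anticipatory rates (6 vs 2 Hz), 8 Hz consumption bursts
  after reward.

Everything is a deterministic function of (config, seed); a session
written twice is byte-identical.

What the generator does **not** emulate -- and what passing tests
therefore cannot certify on real data: refractory periods and spike-sorting
artifacts; oscillation decoherence (real rhythms drift in phase, so real
ACG harmonics decay with lag; the earliest-peak band rule is robust to
both cases); slow nonstationarity (drift, satiety); learning within a
session; correlated trial-to-trial gain; and genuinely contingent
behavior (licks do not influence trials).

## Problem sizes and numerical choices

The test suite exercises: brute-force correlogram equality on 1000 random
trains (≤ 200 spikes); burst-parse equality on 1000 random trains;
type-I calibration of the response test on 1000 null units at alphas
0.05/0.01/0.001; synchrony false positives on 500 independent Poisson
pairs (5 Hz, 300 s); label recovery on 200-unit bursting/Poisson and
40-unit rhythmic cohorts (1200 s trains); coupling-class recovery on 20
pairs per class (1200 s); response direction/latency on 60 units at 60
trials; and a 200-unit depth-graded cohort (600 s). These sizes keep the
default suite under a few minutes on one core while leaving every
acceptance margin comfortably wide of its threshold.

Ties and degenerate inputs: rank tests use the normal approximation
(`exact = FALSE`) because spike counts are heavily tied; all-equal
samples short-circuit to p = 1; constant inputs to correlations return NA
with a warning rather than an error; expected-zero chi-square cells raise
a degenerate-table error.

## Known limitations

* The index formulas and thresholds are reconstructions, not the
  originals; cross-study comparability of absolute index values is not
  claimed. All constants are exposed as configuration.
* Strong burst firing inflates the gamma-band rhythmicity index (the
  burst tail of the ACG decays through the gamma lag range); the
  fundamental-peak requirement keeps such units from being *labeled*
  rhythmic, but the index value itself should not be read as oscillation
  strength for bursty units.
* Flanks of strong broad-synchrony peaks can exceed the band in side
  runs and be reported as spurious monosynaptic features alongside the
  (correct) broad feature; assembly membership is unaffected because it
  keys on zero-lag classes only.
* Jitter surrogates assume stationarity at the 25 ms scale; faster
  common rate fluctuations would be (correctly) flagged as synchrony but
  are not distinguishable from shared input.
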