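# spikeEtypes

Spike-train analysis for probabilistic Pavlovian conditioning: e-type
classification, burst/single-spike parsing, peri-event responses,
anticipatory licking, and fine-timescale synchrony with assembly
detection — plus a fully seeded synthetic-session generator that makes
every stage verifiable without access to recordings.

## The problem

In head-fixed Pavlovian conditioning, two auditory cues predict water
reward or air-puff punishment probabilistically (default contingencies
80/10/10 and 25/65/10 for reward/punishment/omission), with the
reinforcement delivered at a uniform 400–600 ms delay after cue offset.
Extracellular recordings from such tasks yield, per session, spike
timestamps for dozens of units, a trial table, and lick timestamps. The
scientific questions this package operationalizes, for electrophysiologists
analyzing basal-forebrain/basal-ganglia (e.g. ventral pallidal) recordings:

* Which **electrophysiological types** are present? Units are classified
  from their spike autocorrelogram (ACG): a *burst index*
  `BI = (P − B)/max(P, B)` contrasts the short-latency (1–10 ms) ACG peak
  `P` against a long-lag baseline `B` (180–200 ms); *rhythmicity indices*
  contrast the in-band peak and trough of the ACG in the beta (13–30 Hz)
  and gamma (30–100 Hz) lag ranges, with the rhythm frequency read off
  the first ACG peak, `f = 1000 / lag`.
* Do bursts and single spikes carry **separate event codes**? Bursts are
  parsed by the ISI rule "first ISI < 10 ms, subsequent ISIs < 15 ms",
  and the burst-event and single-spike trains are tested for responses
  independently.
* Which units **respond to task events** (cues, reward, punishment,
  virtual omission), in which direction, at what latency? Per-trial
  baseline vs response window spike counts, Mann–Whitney U at
  alpha = 0.001; latency from the Z-scored PETH extremum; expectation
  contrasts by Wilcoxon signed-rank over per-unit condition differences.
* Do units fire **synchronously**? Cross-correlograms against
  jitter-surrogate 95% confidence bands (±25 ms uniform jitter, 1000
  surrogates) yield narrow (<3 ms) and broad (≥3 ms) zero-lag synchrony
  and putative monosynaptic excitation (≤2 ms wide, centered 1–4 ms from
  zero); synchronous units form assemblies as connected components of
  the synchrony graph.

## Worked example

Simulate a 120-trial session with a bursting unit that responds to
reward, a 40 Hz gamma-rhythmic unit, and one narrowly synchronized pair;
then analyze it:

```r
library(spikeEtypes)

cfg <- simConfig(nTrials = 120, seed = 7,
  units = list(
    unitSpec("bursting", baselineHz = 0, dvUm = 150,
             responses = list(reward = list(sign = 1, amplitude = 1.5,
                                            latencyS = 0, decayS = 0.08))),
    unitSpec("rhythmic", baselineHz = 12,
             rhythm = list(freqHz = 40, depth = 0.8), dvUm = 650)),
  pairs = list(pairSpec("common_input", copyJitterSdMs = 0.5)))
simulateSession(cfg, path = "demo_bundle")
sess <- readSessionBundle("demo_bundle")
sess
#> Session: 4 units, 120 trials, 1237 licks

do.call(rbind, lapply(spikeTrains(sess), classifyEtype))[,
  c("unit_id", "burst_index", "is_bursting", "gamma_index",
    "rhythm_band", "rhythm_freq_hz")]
#>   unit_id burst_index is_bursting gamma_index rhythm_band rhythm_freq_hz
#> 1    u001      0.9228        TRUE       0.837        none             NA
#> 2    u002      0.1573       FALSE       0.413       gamma           38.5
#> 3   p001a     -0.0431       FALSE       0.285        none             NA
#> 4   p001b     -0.0598       FALSE       0.368        none             NA
```

The burster is labeled bursting (BI 0.92 ≫ 0.5); the rhythmic unit is
assigned the gamma band with its frequency recovered to within 4% (38.5
vs 40 Hz generated); the pair's background units are neither. (The
burster's high gamma *index* without a rhythmic *label* is deliberate:
burst ACG tails raise the in-band contrast, but no fundamental peak
exists — see the vignette.) The reward response and the pair's synchrony:

```r
testEventResponse(spikeTrains(sess)[[1]], eventTimes(trials(sess), "reward"))
#>   unit_id event_label direction  p_value effect_hz n_trials
#> 1    u001             activated 1.64e-05      7.27       60

analyzePair(spikeTrains(sess)[[3]], spikeTrains(sess)[[4]], seed = 1)@features
#>   run_start_ms run_end_ms width_ms center_ms        class
#> 1       -44.75     -43.75      1.5 -44.25018 unclassified
#> 2        -1.75       1.75      1.5   0.00635  narrow_sync
```

The injected common input is recovered as a narrow (1.5 ms FWHM)
zero-lag peak. Anticipatory licking discriminates the cues (5.77 vs
1.88 Hz, p = 2.4e-15, rank-sum), as generated (6 vs 2 Hz).

The whole pipeline, bundle in → tables out:

```r
runPipeline("demo_bundle", "results/")   # etypes.csv, responses.csv,
                                         # pairs.csv, assemblies.json, ...
```

or from a shell, `Rscript inst/scripts/etype-pipeline.R run-all
demo_bundle --out results/`.

## Package layout

* `R/session.R` — session bundle I/O and validation (`readSessionBundle`,
  `writeSessionBundle`, `validateSession`)
* `R/correlograms.R`, `src/correlograms.cpp` — ACG/CCG primitives
* `R/etype.R` — burst/rhythmicity indices and e-type classification
* `R/bursts.R` — ISI-rule burst parsing and burst/single dissociation
* `R/responses.R` — PETHs, Z-scoring, response tests, contrasts
* `R/behavior.R` — lick PETHs and anticipatory discrimination
* `R/synchrony.R` — jitter surrogates, pair classification, assemblies
* `R/simulate.R` — the seeded synthetic-session generator
* `R/pipeline.R`, `inst/scripts/etype-pipeline.R` — orchestration and CLI
* `vignettes/spike-etype-analysis.Rmd` — the methods vignette (models,
  assumptions, parameter rationale, limitations)
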