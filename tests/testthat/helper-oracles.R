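# Brute-force reference implementations, deliberately independent of the
# package's algorithms: all-pairs enumeration for correlograms and a direct
# re-scan for the burst parser. Only usable on small inputs.

bfLagCounts <- function(ref, target, binMs, windowMs) {
  m <- floor(windowMs / binMs + 1e-9)
  centers <- seq.int(-m, m) * binMs
  cts <- numeric(length(centers))
  for (i in seq_along(ref)) for (j in seq_along(target)) {
    lag <- (target[j] - ref[i]) * 1000
    for (k in seq_along(centers)) {
      if (lag >= centers[k] - binMs / 2 && lag < centers[k] + binMs / 2) {
        cts[k] <- cts[k] + 1
        break
      }
    }
  }
  cts
}

# Same enumeration via outer(): fast enough for thousands of trains while
# still independent of the package's sort-merge implementation.
bfLagCountsOuter <- function(ref, target, binMs, windowMs) {
  m <- floor(windowMs / binMs + 1e-9)
  lag <- as.vector(outer(target, ref, "-")) * 1000
  k <- floor(lag / binMs + 0.5)
  k <- k[k >= -m & k <= m]
  tabulate(k + m + 1L, nbins = 2L * m + 1L)
}

bfAutocorrelogram <- function(times, binMs, windowMs) {
  cts <- bfLagCounts(times, times, binMs, windowMs)
  m <- floor(windowMs / binMs + 1e-9)
  cts[m + 1] <- 0  # exclude self/zero-lag coincidences
  cts
}

# Direct transcription of the burst rule, recursion instead of the
# package's scan loop.
bfParseLabels <- function(timesS, firstMaxMs = 10, intraMaxMs = 15) {
  n <- length(timesS)
  labels <- rep("single", n)
  if (n < 2) return(labels)
  isi <- diff(timesS) * 1000
  inBurst <- FALSE
  for (i in seq_len(n)) {
    if (!inBurst) {
      if (i < n && isi[i] < firstMaxMs) {
        labels[i] <- "burst_first"
        inBurst <- TRUE
      }
    } else {
      labels[i] <- "burst_member"
      inBurst <- i < n && isi[i] < intraMaxMs
    }
  }
  labels
}

randomTrain <- function(n, durationS = 2) sort(runif(n, 0, durationS))

# A train with realistic ISI clumping so bursts actually occur.
randomBurstyTrain <- function(n) {
  isis <- ifelse(runif(n) < 0.4, runif(n, 0.002, 0.014),
                 rexp(n, 10) + 0.015)
  cumsum(isis)
}

makeTrials <- function(events, cue = "likely_reward", outcome = "reward",
                       cueDur = 0.5, delay = 0.5) {
  oc <- rep(outcome, length.out = length(events))
  data.frame(trial_id = seq_along(events), cue = cue, outcome = oc,
             t_cue_on_s = events, t_cue_off_s = events + cueDur,
             t_reinforcement_s = ifelse(oc == "omission", NA_real_,
                                        events + cueDur + delay),
             stringsAsFactors = FALSE)
}

# Small fully-populated session used by IO/pipeline tests.
smallDemoSession <- function(seed = 42, nTrials = 40) {
  cfg <- simConfig(
    nTrials = nTrials, seed = seed,
    units = list(
      unitSpec("poisson", baselineHz = 8, dvUm = 300,
               responses = list(reward = list(sign = 1, amplitude = 1.5,
                                              latencyS = 0, decayS = 0.08))),
      unitSpec("bursting", baselineHz = 0, dvUm = 150),
      unitSpec("rhythmic", baselineHz = 10,
               rhythm = list(freqHz = 40, depth = 0.8), dvUm = 600)),
    pairs = list(pairSpec("common_input", copyJitterSdMs = 0.5)))
  simulateSession(cfg)
}
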