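# Constructs an ACG object with prescribed counts (symmetric, zero center).
syntheticAcg <- function(posCounts, binMs = 1) {
  n <- length(posCounts)
  new("Correlogram", lags = seq(-n, n) * binMs,
      counts = c(rev(posCounts), 0, posCounts), binMs = binMs,
      windowMs = n * binMs, nRefSpikes = 1000L, kind = "auto",
      normalization = "raw_counts", ciLower = numeric(0),
      ciUpper = numeric(0))
}

test_that("burst index follows its peak/baseline definition", {
  # peak 10 at 5 ms, baseline 2 over 180-200 ms -> (10 - 2) / 10 = 0.8
  pos <- rep(2, 200)
  pos[5] <- 10
  acg <- syntheticAcg(pos)
  expect_equal(burstIndex(acg, smoothSdMs = 0), 0.8)
  # flat-zero ACG defines BI = 0
  expect_equal(burstIndex(syntheticAcg(rep(0, 200)), smoothSdMs = 0), 0)
  # scale invariance of the ratio form
  acg2 <- syntheticAcg(pos * 7.3)
  expect_equal(burstIndex(acg2, smoothSdMs = 0),
               burstIndex(acg, smoothSdMs = 0))
  # short window is a parameter error
  expect_error(burstIndex(syntheticAcg(rep(1, 150))), "window")
})

test_that("a homogeneous Poisson train has near-zero burst index", {
  over <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    tt <- sort(runif(rpois(1, 10 * 1200), 0, 1200))
    bi <- burstIndex(autocorrelogram(tt))
    if (abs(bi) >= 0.15) over <- over + 1
  }
  expect_lte(over, 1)
})

test_that("simulated bursters and Poisson units are labeled correctly", {
  okB <- 0; okP <- 0
  for (s in 1:10) {
    b <- simulateUnit(unitSpec("bursting", baselineHz = 0),
                      durationS = 1200, seed = 500 + s)$spikes
    p <- simulateUnit(unitSpec("poisson", baselineHz = 10),
                      durationS = 1200, seed = 600 + s)$spikes
    okB <- okB + (classifyBursting(b)$status == "bursting")
    okP <- okP + (classifyBursting(p)$status == "non_bursting")
  }
  expect_gte(okB, 9)
  expect_gte(okP, 9)
})

test_that("units under 100 spikes are excluded from bursting classification", {
  tt <- sort(runif(99, 0, 100))
  expect_equal(classifyBursting(SpikeTrain(tt))$status, "excluded")
  expect_true(is.na(classifyEtype(SpikeTrain(tt))$is_bursting))
  tt2 <- sort(runif(100, 0, 100))
  expect_true(classifyBursting(SpikeTrain(tt2))$status != "excluded")
})

test_that("rhythmicity index is zero on flat ACGs and detects oscillation", {
  flat <- syntheticAcg(rep(5, 200))
  expect_equal(rhythmicityIndex(flat, "beta", smoothSdMs = 0), 0)
  expect_equal(rhythmicityIndex(flat, "gamma", smoothSdMs = 0), 0)
  expect_error(rhythmicityIndex(flat, "theta"))
  u <- simulateUnit(unitSpec("rhythmic", baselineHz = 10,
                             rhythm = list(freqHz = 40, depth = 0.8)),
                    durationS = 1200, seed = 77)$spikes
  acg <- autocorrelogram(u)
  expect_gte(rhythmicityIndex(acg, "gamma"), 0.35)
})

test_that("rhythm frequency comes from the first band peak", {
  # clean 40 Hz oscillation: peaks at 25, 50, 75 ms
  pos <- 100 * (1 + 0.4 * cos(2 * pi * 40 * (1:200) / 1000))
  acg <- syntheticAcg(pos)
  expect_equal(estimateRhythmFrequency(acg, "gamma", smoothSdMs = 0), 40)
  # 20 Hz: first (and only) band peak at 50 ms
  pos2 <- 100 * (1 + 0.4 * cos(2 * pi * 20 * (1:200) / 1000))
  expect_equal(estimateRhythmFrequency(syntheticAcg(pos2), "beta",
                                       smoothSdMs = 0), 20)
  expect_error(estimateRhythmFrequency(syntheticAcg(rep(5, 200)), "beta"),
               "supra-threshold")
})

test_that("classifyEtype recovers simulated e-types and frequencies", {
  bandOk <- 0; freqOk <- 0; n <- 0
  for (s in 1:9) {
    f <- c(20, 40, 60)[(s - 1) %% 3 + 1]
    u <- simulateUnit(unitSpec("rhythmic", baselineHz = 10,
                               rhythm = list(freqHz = f, depth = 0.8)),
                      durationS = 1200, seed = 700 + s)$spikes
    e <- classifyEtype(u)
    n <- n + 1
    trueBand <- if (f < 30) "beta" else "gamma"
    bandOk <- bandOk + (e$is_rhythmic && e$rhythm_band == trueBand)
    freqOk <- freqOk + (!is.na(e$rhythm_freq_hz) &&
                          abs(e$rhythm_freq_hz - f) / f <= 0.1)
    expect_false(isTRUE(e$is_bursting))
  }
  expect_gte(bandOk, 8)
  expect_gte(freqOk, 8)
  # plain Poisson: neither bursting nor rhythmic
  p <- simulateUnit(unitSpec("poisson", baselineHz = 10),
                    durationS = 1200, seed = 710)$spikes
  ep <- classifyEtype(p)
  expect_false(ep$is_bursting)
  expect_false(ep$is_rhythmic)
  expect_equal(ep$rhythm_band, "none")
  expect_true(is.na(ep$rhythm_freq_hz))
})

test_that("indices are deterministic and scale-invariant on a fixed ACG", {
  set.seed(9)
  u <- randomBurstyTrain(3000)
  acg <- autocorrelogram(u)
  expect_identical(burstIndex(acg), burstIndex(acg))
  scaled <- initialize(acg, counts = counts(acg) * 3.7)
  expect_equal(burstIndex(scaled), burstIndex(acg))
  expect_equal(rhythmicityIndex(scaled, "gamma"),
               rhythmicityIndex(acg, "gamma"))
})

test_that("index-depth correlation behaves at both extremes", {
  dv <- seq(100, 900, length.out = 20)
  idx <- 1 - dv / 1000
  r <- correlateIndexWithPosition(idx, dv)
  expect_equal(r$r, -1)
  expect_error(correlateIndexWithPosition(c(1, 2), c(1, 2)), "insufficient")
  # independence: p roughly uniform over permutations
  set.seed(21)
  ps <- replicate(50, correlateIndexWithPosition(sample(idx), dv)$p)
  expect_gt(mean(ps > 0.05), 0.8)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.25)
})
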