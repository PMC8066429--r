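test_that("trial simulation reproduces contingencies and delay bounds", {
  cfg <- simConfig(nTrials = 10000, seed = 81)
  tr <- simulateTrials(cfg)
  expect_equal(nrow(tr), 10000)
  for (cue in names(cfg$contingencies)) {
    sub <- tr[tr$cue == cue, ]
    for (oc in c("reward", "punishment", "omission")) {
      pHat <- mean(sub$outcome == oc)
      p0 <- cfg$contingencies[[cue]][[oc]]
      ciHalf <- qnorm(0.995) * sqrt(p0 * (1 - p0) / nrow(sub))
      expect_lt(abs(pHat - p0), ciHalf + 1e-12)
    }
  }
  d <- tr$t_reinforcement_s - tr$t_cue_off_s
  expect_true(all(is.na(d) == (tr$outcome == "omission")))
  expect_true(all(d[!is.na(d)] >= 0.4 & d[!is.na(d)] <= 0.6))
  # determinism
  expect_identical(tr, simulateTrials(cfg))
  # non-overlap and ordering
  expect_equal(nrow(validateSession(Session(trials = tr,
                                            meta = list(synthetic = TRUE)))),
               0)
  expect_error(simConfig(seed = 1, contingencies = list(
    likely_reward = c(reward = 0.5, punishment = 0.3, omission = 0.1),
    likely_punishment = c(reward = 0.25, punishment = 0.65,
                          omission = 0.10))), "config error")
})

test_that("bursting generator bookkeeping matches the parse", {
  # burst initiations 2 Hz, 1 + Poisson(2) extra spikes each, singles 2 Hz:
  # expected burst-spike fraction = 2*(2+2) / (2*(2+2) + 2) = 0.8
  fr <- vapply(1:5, function(s) {
    u <- simulateUnit(unitSpec("bursting", baselineHz = 0),
                      durationS = 1200, seed = 820 + s)$spikes
    bp <- parseBursts(u)
    sum(bp@burstSizes) / nSpikes(u)
  }, 0)
  expect_true(all(abs(fr - 0.8) < 0.08))
})

test_that("rhythmic generator puts the ACG band peak at the period", {
  u <- simulateUnit(unitSpec("rhythmic", baselineHz = 10,
                             rhythm = list(freqHz = 40, depth = 0.8)),
                    durationS = 1200, seed = 83)$spikes
  acg <- smoothCorrelogram(autocorrelogram(u), 2)
  gam <- lags(acg) >= 10 & lags(acg) <= 33.3
  pk <- lags(acg)[gam][which.max(counts(acg)[gam])]
  expect_lt(abs(pk - 25), 2.5)
  expect_error(simulateUnit(unitSpec("rhythmic",
                                     rhythm = list(freqHz = 40, depth = 1.2)),
                            durationS = 10), "config error")
})

test_that("zero-amplitude kernels leave the unit at its Poisson null", {
  events <- seq(10, 490, by = 8)
  trialsDf <- makeTrials(events)
  spec <- unitSpec("poisson", baselineHz = 15,
                   responses = list(reward = list(sign = 1, amplitude = 0,
                                                  latencyS = 0,
                                                  decayS = 0.08)))
  ps <- vapply(1:10, function(s) {
    u <- simulateUnit(spec, trialsDf, durationS = 500,
                      seed = 840 + s)$spikes
    testEventResponse(u, eventTimes(trialsDf, "reward"))$p_value
  }, 0)
  expect_gte(sum(ps > 0.001), 9)
  # rate matches baseline
  u <- simulateUnit(spec, trialsDf, durationS = 500, seed = 851)$spikes
  expect_lt(abs(nSpikes(u) / 500 - 15) / 15, 0.05)
})

test_that("uncoupled pairs are independent by construction", {
  nSync <- 0
  for (s in 1:10) {
    pr <- simulatePair(pairSpec("common_input", copyProb = 0),
                       600, seed = 860 + s)
    r <- analyzePair(pr$a, pr$b, nSurrogates = 200, seed = s)
    nSync <- nSync + r@anySync
  }
  expect_lte(nSync, 1)
})

test_that("lick generator respects rates and degenerate settings", {
  cfg <- simConfig(nTrials = 60, seed = 87)
  tr <- simulateTrials(cfg)
  lk <- simulateLicks(tr, cfg$lick, seed = 88)
  expect_true(all(diff(lk) > 0))
  # zero rates -> empty train
  lk0 <- simulateLicks(tr, list(baselineHz = 0, anticipatoryRewardHz = 0,
                                anticipatoryPunishHz = 0, consumptionHz = 0,
                                consumptionDurS = 1), seed = 88)
  expect_length(lk0, 0)
  expect_error(simConfig(seed = 1, lick = list(baselineHz = 1,
                                               anticipatoryRewardHz = 0.5,
                                               anticipatoryPunishHz = 2,
                                               consumptionHz = 8,
                                               consumptionDurS = 1)),
               "config error")
})

test_that("sessions are reproducible and validate end to end", {
  p1 <- withr::local_tempdir(); p2 <- withr::local_tempdir()
  cfg <- simConfig(nTrials = 30, seed = 89,
                   units = list(unitSpec("poisson", baselineHz = 8),
                                unitSpec("bursting", baselineHz = 0)),
                   pairs = list(pairSpec("common_input")))
  simulateSession(cfg, path = p1)
  simulateSession(cfg, path = p2)
  for (f in c("spikes.csv", "trials.csv", "licks.csv", "units.csv",
              "meta.json", "ground_truth.json")) {
    expect_true(file.exists(file.path(p1, f)))
    expect_identical(unname(tools::md5sum(file.path(p1, f))),
                     unname(tools::md5sum(file.path(p2, f))))
  }
  sess <- readSessionBundle(p1)
  expect_equal(nrow(validateSession(sess)), 0)
  expect_length(spikeTrains(sess), 4)  # 2 units + 1 pair
  # seed is mandatory
  expect_error(simConfig(), "seed")
})
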