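test_that("PETH recovers a constant rate and integrates to the spike count", {
  set.seed(51)
  events <- seq(10, 10 + 199 * 5, by = 5)
  T <- max(events) + 5
  tt <- sort(runif(rpois(1, 10 * T), 0, T))
  p <- computePeth(tt, events, window = c(-1, 1), binS = 0.02)
  expect_equal(mean(p@rate), 10, tolerance = 0.05)
  # exact integration identity
  inWin <- sum(vapply(events, function(e)
    sum(tt >= e - 1 & tt < e + 1), 0))
  expect_equal(sum(p@rate) * 0.02, inWin / length(events))
})

test_that("a spike at every event gives a single-bin peak of 1/binS", {
  events <- seq(5, 100, by = 5)
  p <- computePeth(events + 0.001, events, window = c(-0.1, 0.1),
                   binS = 0.02)
  expect_equal(max(p@rate), 1 / 0.02)
  expect_equal(sum(p@rate > 0), 1)
  expect_equal(p@binCenters[which.max(p@rate)], 0.01)
  # no spikes: flat zero
  p0 <- computePeth(numeric(0), events)
  expect_true(all(p0@rate == 0))
  expect_error(computePeth(events, numeric(0)), "insufficient")
})

test_that("Z-scoring standardizes the baseline bins exactly", {
  set.seed(52)
  events <- seq(10, 500, by = 5)
  tt <- sort(runif(5000, 0, 510))
  p <- computePeth(tt, events)
  z <- zscorePeth(p, baseline = c(-0.5, 0))
  idx <- p@binCenters >= -0.5 & p@binCenters < 0
  expect_equal(mean(z@z[idx]), 0, tolerance = 1e-12)
  expect_equal(sd(z@z[idx]), 1, tolerance = 1e-12)
  # constant PETH has zero baseline SD: degenerate
  pc <- computePeth(events + 0.3, events, window = c(-1, 1), binS = 0.5)
  expect_error(zscorePeth(pc), class = "degenerateBaseline")
})

test_that("response test is two-sided, directional, and honest on nulls", {
  set.seed(53)
  events <- seq(10, 10 + 59 * 8, by = 8)
  T <- max(events) + 5
  # response window identical to baseline by construction
  tt <- sort(runif(3000, 0, T))
  r <- testEventResponse(tt, events, baselineWin = c(-0.5, 0),
                         responseWin = c(-0.5, 0))
  expect_equal(r$direction, "none")

  # activated unit
  spec <- unitSpec("poisson", baselineHz = 20,
                   responses = list(reward = list(sign = 1, amplitude = 1.5,
                                                  latencyS = 0,
                                                  decayS = 0.08)))
  trialsDf <- makeTrials(events - 1)  # reinforcement lands on `events`
  u <- simulateUnit(spec, trialsDf, durationS = T, seed = 54)$spikes
  ra <- testEventResponse(u, eventTimes(trialsDf, "reward"))
  expect_equal(ra$direction, "activated")
  expect_gt(ra$effect_hz, 0)

  # inhibited unit: rate roughly halved for ~300 ms
  speci <- unitSpec("poisson", baselineHz = 20,
                    responses = list(reward = list(sign = -1,
                                                   amplitude = 0.6,
                                                   latencyS = 0,
                                                   decayS = 0.12)))
  okInh <- sum(vapply(1:5, function(s) {
    ui <- simulateUnit(speci, trialsDf, durationS = T,
                       seed = 540 + s)$spikes
    testEventResponse(ui, eventTimes(trialsDf, "reward"))$direction ==
      "inhibited"
  }, TRUE))
  expect_gte(okInh, 4)
  expect_error(testEventResponse(u, events[1]), "insufficient")
})

test_that("latency picks the |z| extremum and recovers injected kernels", {
  # symmetric constructed z: exact bin-center recovery
  p <- computePeth(sort(runif(2000, 0, 100)), seq(5, 95, by = 5))
  p@z <- dnorm(p@binCenters, mean = 0.31, sd = 0.05)
  expect_equal(responseLatency(p, direction = "activated"), 0.31)
  p@z <- -p@z
  expect_equal(responseLatency(p, direction = "inhibited"), 0.31)

  # injected activation peaking 80 ms after the event
  events <- seq(10, 10 + 59 * 8, by = 8)
  trialsDf <- makeTrials(events - 1)
  spec <- unitSpec("poisson", baselineHz = 20,
                   responses = list(reward = list(sign = 1, amplitude = 1.5,
                                                  latencyS = 0,
                                                  decayS = 0.08)))
  lat <- vapply(1:5, function(s) {
    u <- simulateUnit(spec, trialsDf, durationS = max(events) + 5,
                      seed = 560 + s)$spikes
    zp <- zscorePeth(computePeth(u, events, smoothSdS = 0.02))
    responseLatency(zp, direction = "activated")
  }, 0)
  expect_lte(median(abs(lat - 0.08)), 0.02)
})

test_that("outcome-condition contrast excludes short conditions and is calibrated", {
  set.seed(57)
  evA <- seq(10, 10 + 39 * 8, by = 8)
  evB <- evA + 4
  units <- lapply(1:12, function(i)
    SpikeTrain(sort(runif(3000, 0, max(evB) + 5)),
               unitId = sprintf("u%02d", i)))
  r <- compareOutcomeConditions(units, evA, evB)
  expect_equal(r$nIncluded, 12)
  expect_gt(r$p, 0.001)  # same generator on both sides

  rEx <- compareOutcomeConditions(units, evA, evB[1:4])
  expect_true(all(rEx$perUnit$excluded))
  expect_equal(rEx$nIncluded, 0)

  # a real difference is detected
  unitsUp <- lapply(1:12, function(i) {
    base <- sort(runif(3000, 0, max(evB) + 5))
    extra <- unlist(lapply(evA, function(e) runif(3, e, e + 0.4)))
    SpikeTrain(sort(c(base, extra)), unitId = sprintf("v%02d", i))
  })
  r2 <- compareOutcomeConditions(unitsUp, evA, evB)
  expect_lt(r2$p, 0.05)
  expect_gt(median(r2$perUnit$delta), 0)
})

test_that("combination table counts all 27 sign patterns with exact marginals", {
  dirs <- c("activated", "none", "inhibited")
  set.seed(58)
  rows <- do.call(rbind, lapply(1:40, function(i)
    data.frame(unit_id = sprintf("u%02d", i),
               event_label = c("cue", "reward", "punishment"),
               direction = sample(dirs, 3, replace = TRUE),
               stringsAsFactors = FALSE)))
  tab <- responseCombinationTable(rows,
                                  c("cue", "reward", "punishment"))
  expect_equal(sum(tab), 40)
  # marginals equal the per-event sign counts
  cueSigns <- table(factor(c(activated = "+", none = "0",
                             inhibited = "-")[
    rows$direction[rows$event_label == "cue"]], levels = c("+", "0", "-")))
  expect_equal(as.vector(apply(tab, 1, sum)), as.vector(cueSigns))
  # all-unresponsive cohort: all mass at (0,0,0)
  rows0 <- rows; rows0$direction <- "none"
  tab0 <- responseCombinationTable(rows0, c("cue", "reward", "punishment"))
  expect_equal(tab0["0", "0", "0"], 40)
  expect_equal(sum(tab0), 40)
  # unit missing one event is dropped with a warning
  expect_warning(
    t2 <- responseCombinationTable(rows[-1, ],
                                   c("cue", "reward", "punishment")),
    "dropped")
  expect_equal(sum(t2), 39)
})

test_that("group-fraction chi-square matches the closed form", {
  r <- compareGroupFractions(30, 100, 10, 100)
  expect_equal(r$chi2, 12.5)
  expect_equal(r$p, stats::pchisq(12.5, 1, lower.tail = FALSE))
  same <- compareGroupFractions(20, 50, 40, 100)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(compareGroupFractions(0, 100, 0, 100), "degenerate")
  expect_error(compareGroupFractions(5, 4, 1, 10), "counts")
})

test_that("response testing is invariant to a global time shift", {
  set.seed(59)
  events <- seq(10, 400, by = 8)
  tt <- sort(runif(4000, 0, 410))
  r1 <- testEventResponse(tt, events)
  r2 <- testEventResponse(tt + 1234.5, events + 1234.5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$direction, r2$direction)
})
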