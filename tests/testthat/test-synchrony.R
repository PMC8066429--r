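# CCG with hand-set counts and flat bands for rule-level tests.
syntheticCcg <- function(cts, upper, binMs = 0.5) {
  n <- (length(cts) - 1) / 2
  new("Correlogram", lags = seq(-n, n) * binMs, counts = cts,
      binMs = binMs, windowMs = n * binMs, nRefSpikes = 100L,
      kind = "cross", normalization = "raw_counts",
      ciLower = rep(0, length(cts)), ciUpper = rep(upper, length(cts)))
}

test_that("surrogate bands collapse onto the observed CCG at zero jitter", {
  set.seed(71)
  a <- sort(runif(400, 0, 100)); b <- sort(runif(400, 0, 100))
  cg <- jitterSurrogateCi(a, b, nSurrogates = 100, jitterMs = 0, seed = 1)
  expect_equal(cg@ciLower, counts(cg))
  expect_equal(cg@ciUpper, counts(cg))
})

test_that("surrogate bands are deterministic given the seed", {
  set.seed(72)
  a <- sort(runif(300, 0, 60)); b <- sort(runif(300, 0, 60))
  c1 <- jitterSurrogateCi(a, b, nSurrogates = 150, seed = 9)
  c2 <- jitterSurrogateCi(a, b, nSurrogates = 150, seed = 9)
  expect_identical(c1@ciUpper, c2@ciUpper)
  c3 <- jitterSurrogateCi(a, b, nSurrogates = 150, seed = 10)
  expect_false(identical(c3@ciUpper, c1@ciUpper))
  expect_error(jitterSurrogateCi(a, b, nSurrogates = 50), "nSurrogates")
  expect_warning(z <- jitterSurrogateCi(numeric(0), b), "empty")
  expect_true(all(z@ciUpper == 0))
})

test_that("pointwise band exceedance is calibrated on independent pairs", {
  set.seed(73)
  exceed <- 0; nbins <- 0
  for (i in 1:10) {
    a <- sort(runif(1500, 0, 300)); b <- sort(runif(1500, 0, 300))
    cg <- jitterSurrogateCi(a, b, nSurrogates = 200, seed = 100 + i)
    exceed <- exceed + sum(counts(cg) > cg@ciUpper)
    nbins <- nbins + length(counts(cg))
  }
  # pointwise upper tail ~2.5%
  expect_lt(exceed / nbins, 0.06)
  expect_gt(exceed / nbins, 0.005)
})

test_that("classification rules resolve width, center and zero-lag correctly", {
  n <- 100  # 201 bins of 0.5 ms, lags -50..50
  base <- rep(10, 2 * n + 1)
  # 2-bin run containing lag 0, width 1 ms -> narrow
  cts <- base; cts[n + 1] <- 30; cts[n + 2] <- 25
  pr <- classifyPair(syntheticCcg(cts, 20))
  expect_equal(pr@features$class, "narrow_sync")
  expect_true(pr@anySync)
  # 7-bin run containing 0, width 3.5 ms -> broad
  cts <- base; cts[(n - 2):(n + 4)] <- 30
  prB <- classifyPair(syntheticCcg(cts, 20))
  expect_equal(prB@features$class, "broad_sync")
  # 3-bin run centered at +2 ms, width 1.5 -> monosynaptic excitation
  cts <- base; cts[n + 1 + (3:5)] <- 40
  prM <- classifyPair(syntheticCcg(cts, 20))
  expect_equal(prM@features$class, "mono_excitation")
  expect_equal(prM@features$center_ms, 2)
  expect_false(prM@anySync)
  # same peak at +10 ms: outside 1-4 ms -> unclassified
  cts <- base; cts[n + 1 + (19:21)] <- 40
  expect_equal(classifyPair(syntheticCcg(cts, 20))@features$class,
               "unclassified")
  # single-bin excursions are ignored
  cts <- base; cts[n + 1] <- 100
  expect_equal(nrow(classifyPair(syntheticCcg(cts, 20))@features), 0)
  # bands required
  ccg <- crosscorrelogram(c(1, 2), c(1.5))
  expect_error(classifyPair(ccg), "bands")
})

test_that("zero-lag class labels are symmetric under pair order", {
  set.seed(74)
  pr <- simulatePair(pairSpec("common_input", copyJitterSdMs = 0.5),
                     600, seed = 75)
  ab <- analyzePair(pr$a, pr$b, nSurrogates = 300, seed = 5)
  ba <- analyzePair(pr$b, pr$a, nSurrogates = 300, seed = 5)
  expect_equal(sort(ab@features$class[ab@features$class != "unclassified"]),
               sort(ba@features$class[ba@features$class != "unclassified"]))
  expect_equal(ab@anySync, ba@anySync)
})

test_that("generative coupling classes are recovered", {
  okN <- 0; okM <- 0; okB <- 0
  for (s in 1:5) {
    pn <- simulatePair(pairSpec("common_input", copyJitterSdMs = 0.5),
                       1200, seed = 760 + s)
    rn <- analyzePair(pn$a, pn$b, nSurrogates = 300, seed = s)
    okN <- okN + any(rn@features$class == "narrow_sync")
    pm <- simulatePair(pairSpec("synaptic"), 1200, seed = 770 + s)
    rm <- analyzePair(pm$a, pm$b, nSurrogates = 300, seed = s)
    okM <- okM + any(rm@features$class == "mono_excitation")
    pb <- simulatePair(pairSpec("common_input", copyProb = 0.5,
                                copyJitterSdMs = 3), 1200, seed = 780 + s)
    rb <- analyzePair(pb$a, pb$b, nSurrogates = 300, seed = s)
    okB <- okB + any(rb@features$class == "broad_sync")
  }
  expect_gte(okN, 4)
  expect_gte(okM, 4)
  expect_gte(okB, 4)
})

test_that("assembly graph groups sync edges into components", {
  mk <- function(a, b, cls) {
    f <- data.frame(run_start_ms = 0, run_end_ms = 1, width_ms = 1,
                    center_ms = 0, class = cls, stringsAsFactors = FALSE)
    new("PairResult", unitA = a, unitB = b,
        ccg = syntheticCcg(rep(0, 7), 1), features = f,
        anySync = cls %in% c("narrow_sync", "broad_sync"))
  }
  units <- c("a", "b", "c", "d", "e")
  g0 <- buildAssemblyGraph(list(), units)
  expect_length(g0@assemblies, 0)
  expect_true(all(g0@membership == "asynchronous"))

  g <- buildAssemblyGraph(list(mk("a", "b", "narrow_sync"),
                               mk("b", "c", "broad_sync"),
                               mk("d", "e", "mono_excitation")), units)
  expect_length(g@assemblies, 1)
  expect_setequal(g@assemblies[[1]], c("a", "b", "c"))
  expect_equal(unname(g@membership[c("a", "b", "c")]),
               rep("synchronous", 3))
  # mono edges do not confer synchrony
  expect_equal(unname(g@membership[c("d", "e")]), rep("asynchronous", 2))
})

test_that("sync vs async responsiveness comparison uses the 2x2 chi-square", {
  membership <- setNames(rep(c("synchronous", "asynchronous"), c(40, 60)),
                         sprintf("u%03d", 1:100))
  dirs <- c(rep("activated", 30), rep("none", 10),   # 75% responsive sync
            rep("activated", 15), rep("none", 45))   # 25% responsive async
  responses <- data.frame(unit_id = names(membership),
                          event_label = "reward", direction = dirs,
                          stringsAsFactors = FALSE)
  tab <- compareSyncResponsiveness(membership, responses)
  expect_equal(tab$n_sync_resp, 30)
  expect_equal(tab$n_async_resp, 15)
  expect_gt(tab$frac_sync, tab$frac_async)
  expect_lt(tab$p, 0.001)
  expect_equal(tab$chi2,
               compareGroupFractions(30, 40, 15, 60)$chi2)
  allAsync <- setNames(rep("asynchronous", 100), names(membership))
  expect_error(compareSyncResponsiveness(allAsync, responses), "degenerate")
})
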