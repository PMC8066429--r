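# Seeded generators for complete synthetic Pavlovian sessions with ground
# truth: the test harness for every analysis stage. All generators are pure
# functions of (config, seed).

#' Build a simulation configuration
#'
#' Default task parameters follow the probabilistic Pavlovian design:
#' two cues drawn equiprobably, outcome contingencies 80/10/10
#' (reward/punishment/omission) after the likely-reward cue and 25/65/10
#' after the likely-punishment cue, and a reinforcement delay uniform on
#' 400--600 ms after cue offset. Cue duration defaults to 0.5 s and the
#' inter-trial interval to Uniform(3, 6) s.
#'
#' @param nTrials number of trials.
#' @param contingencies named list mapping each cue to a probability vector
#'   over \code{c(reward, punishment, omission)}; each must sum to 1.
#' @param cueDurationS cue duration, seconds.
#' @param reinforcementDelayS uniform bounds of the reinforcement delay
#'   after cue offset, seconds.
#' @param itiS uniform bounds of the inter-trial interval, seconds.
#' @param postTrialS consumption buffer appended after each trial, seconds.
#' @param units list of unit specs (\code{\link{unitSpec}}).
#' @param pairs list of pair specs (\code{\link{pairSpec}}).
#' @param lick lick-generator parameters: baselineHz,
#'   anticipatoryRewardHz, anticipatoryPunishHz, consumptionHz,
#'   consumptionDurS.
#' @param seed RNG seed (mandatory).
#' @param subject subject identifier.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nTrials = 300,
                      contingencies = list(
                        likely_reward = c(reward = 0.80, punishment = 0.10,
                                          omission = 0.10),
                        likely_punishment = c(reward = 0.25,
                                              punishment = 0.65,
                                              omission = 0.10)),
                      cueDurationS = 0.5, reinforcementDelayS = c(0.4, 0.6),
                      itiS = c(3, 6), postTrialS = 2,
                      units = list(), pairs = list(),
                      lick = list(baselineHz = 0.5, anticipatoryRewardHz = 6,
                                  anticipatoryPunishHz = 2,
                                  consumptionHz = 8, consumptionDurS = 1),
                      seed = NULL, subject = "sim_subject") {
  if (is.null(seed)) .stopf("config error: a seed is mandatory")
  for (cue in names(contingencies)) {
    p <- contingencies[[cue]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      .stopf("config error: contingencies for '%s' must be a probability vector summing to 1",
             cue)
  }
  if (lick$baselineHz < 0 ||
      lick$anticipatoryRewardHz < lick$baselineHz ||
      lick$anticipatoryPunishHz < lick$baselineHz)
    .stopf("config error: anticipatory lick rates must be >= baseline >= 0")
  structure(list(nTrials = nTrials, contingencies = contingencies,
                 cueDurationS = cueDurationS,
                 reinforcementDelayS = reinforcementDelayS, itiS = itiS,
                 postTrialS = postTrialS, units = units, pairs = pairs,
                 lick = lick, seed = seed, subject = subject),
            class = "SimConfig")
}

#' Specify one synthetic unit
#'
#' E-types: \code{"poisson"} (homogeneous Poisson at \code{baselineHz}),
#' \code{"bursting"} (a Poisson burst-initiation process at
#' \code{burst$rbHz}, each initiation emitting 1 + Poisson(\code{burst$mu})
#' extra spikes with intra-burst ISIs uniform in \code{burst$isiRangeMs},
#' superposed on sparse Poisson singles at \code{burst$singlesHz}), and
#' \code{"rhythmic"} (inhomogeneous Poisson with rate
#' \code{baselineHz * (1 + depth * cos(2 pi f t))}).
#'
#' Event responses are multiplicative rate kernels: after each event of the
#' matching label the rate is multiplied by
#' \code{1 + sign * amplitude * g(t)}, with \code{g} an alpha function
#' rising after \code{latencyS} and peaking \code{decayS} later
#' (multiplicative, so inhibition can never drive the rate negative; the
#' amplitude of an inhibitory kernel must stay below 1). For bursting
#' units, kernels in \code{burstResponses}/\code{singleResponses} modulate
#' the burst-initiation and single-spike processes separately (default:
#' \code{responses} applies to both).
#'
#' @param etype one of \code{"poisson"}, \code{"bursting"},
#'   \code{"rhythmic"}.
#' @param baselineHz baseline rate, Hz.
#' @param burst list(rbHz, mu, singlesHz, isiRangeMs).
#' @param rhythm list(freqHz, depth) with depth in [0, 1].
#' @param responses named list of kernels by event label
#'   (\code{cue_reward}, \code{cue_punish}, \code{reward},
#'   \code{punishment}), each list(sign, amplitude, latencyS, decayS).
#' @param burstResponses,singleResponses optional kernel overrides for the
#'   two processes of a bursting unit.
#' @param dvUm dorsoventral position, micrometers (NA when absent).
#' @param unitId optional fixed id.
#' @return a unit spec list.
#' @export
unitSpec <- function(etype = c("poisson", "bursting", "rhythmic"),
                     baselineHz = 10,
                     burst = list(rbHz = 2, mu = 2, singlesHz = 2,
                                  isiRangeMs = c(3, 8)),
                     rhythm = list(freqHz = 40, depth = 0.8),
                     responses = list(), burstResponses = NULL,
                     singleResponses = NULL, dvUm = NA_real_,
                     unitId = NULL) {
  etype <- match.arg(etype)
  if (baselineHz < 0) .stopf("config error: negative rate")
  if (etype == "rhythmic" &&
      (rhythm$depth < 0 || rhythm$depth > 1))
    .stopf("config error: rhythm depth must lie in [0, 1]")
  for (k in c(responses, burstResponses, singleResponses))
    if (k$sign < 0 && k$amplitude >= 1)
      .stopf("config error: inhibitory amplitude must be < 1")
  list(etype = etype, baselineHz = baselineHz, burst = burst,
       rhythm = rhythm, responses = responses,
       burstResponses = burstResponses, singleResponses = singleResponses,
       dvUm = dvUm, unitId = unitId)
}

#' Specify one synthetic pair
#'
#' \code{"common_input"}: a shared Poisson event train at \code{rateHz};
#' each unit copies each shared event with probability \code{copyProb} and
#' independent Gaussian timing jitter (SD \code{copyJitterSdMs}), on top of
#' an independent Poisson background. \code{"synaptic"}: the postsynaptic
#' unit emits an extra spike for each presynaptic spike with probability
#' \code{pSyn} at a Normal(\code{delayMs}, \code{delaySdMs}) latency.
#'
#' @param type \code{"common_input"} or \code{"synaptic"}.
#' @param rateHz shared-event rate (common input), Hz.
#' @param copyProb per-event copy probability in [0, 1].
#' @param copyJitterSdMs copy jitter SD, ms.
#' @param backgroundHz independent background rate of each unit, Hz.
#' @param pSyn per-presynaptic-spike transmission probability in [0, 1].
#' @param delayMs,delaySdMs synaptic delay mean and SD, ms.
#' @param responses optional response kernels applied to both units'
#'   backgrounds (as in \code{\link{unitSpec}}).
#' @return a pair spec list.
#' @export
pairSpec <- function(type = c("common_input", "synaptic"), rateHz = 2,
                     copyProb = 0.3, copyJitterSdMs = 0.5, backgroundHz = 5,
                     pSyn = 0.15, delayMs = 2, delaySdMs = 0.3,
                     responses = list()) {
  type <- match.arg(type)
  if (copyProb < 0 || copyProb > 1 || pSyn < 0 || pSyn > 1)
    .stopf("config error: probabilities must lie in [0, 1]")
  list(type = type, rateHz = rateHz, copyProb = copyProb,
       copyJitterSdMs = copyJitterSdMs, backgroundHz = backgroundHz,
       pSyn = pSyn, delayMs = delayMs, delaySdMs = delaySdMs,
       responses = responses)
}

#' Simulate the Pavlovian trial table
#'
#' Cues are drawn equiprobably; outcomes follow the per-cue contingency
#' table; the reinforcement delay is uniform on the configured 400--600 ms
#' after cue offset; omission trials carry no reinforcement time. Trials
#' are laid out sequentially with Uniform(itiS) inter-trial intervals.
#' Deterministic given the seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed RNG seed (defaults to the config seed).
#' @return a trial table data.frame (see \linkS4class{Session}).
#' @export
simulateTrials <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$nTrials
  cues <- sample(names(config$contingencies), n, replace = TRUE)
  outcomes <- vapply(cues, function(cue) {
    p <- config$contingencies[[cue]]
    sample(c("reward", "punishment", "omission"), 1L, prob = p)
  }, "")
  t0 <- 0
  on <- off <- reinf <- numeric(n)
  for (i in seq_len(n)) {
    on[i] <- t0 + stats::runif(1, config$itiS[1], config$itiS[2])
    off[i] <- on[i] + config$cueDurationS
    reinf[i] <- if (outcomes[i] == "omission") NA_real_ else
      off[i] + stats::runif(1, config$reinforcementDelayS[1],
                            config$reinforcementDelayS[2])
    t0 <- max(off[i], reinf[i], off[i] + config$reinforcementDelayS[2],
              na.rm = TRUE) + config$postTrialS
  }
  data.frame(trial_id = seq_len(n), cue = unname(cues),
             outcome = unname(outcomes), t_cue_on_s = on, t_cue_off_s = off,
             t_reinforcement_s = reinf, stringsAsFactors = FALSE)
}

# Alpha-function response kernel, unit peak at latencyS + decayS after the
# event.
.alphaKernel <- function(x, latencyS, decayS) {
  y <- (x - latencyS) / decayS
  out <- numeric(length(x))
  pos <- !is.na(y) & y > 0
  out[pos] <- y[pos] * exp(1 - y[pos])
  out
}

# Multiplicative modulation factor at times t from one kernel attached to
# `events` (sorted). Assumes event effects do not overlap (trial spacing
# exceeds the kernel support).
.kernelFactor <- function(t, events, kernel) {
  if (!length(events)) return(rep(1, length(t)))
  idx <- findInterval(t, events)
  x <- ifelse(idx >= 1L, t - events[pmax(idx, 1L)], NA_real_)
  g <- .alphaKernel(x, kernel$latencyS, kernel$decayS)
  pmax(0, 1 + kernel$sign * kernel$amplitude * g)
}

# Rate-modulation function from a named kernel list and a trial table.
.modulationFn <- function(kernels, trialsDf) {
  if (is.null(trialsDf) || !length(kernels)) return(function(t) rep(1, length(t)))
  evs <- lapply(names(kernels), function(lbl) sort(eventTimes(trialsDf, lbl)))
  function(t) {
    f <- rep(1, length(t))
    for (i in seq_along(kernels))
      f <- f * .kernelFactor(t, evs[[i]], kernels[[i]])
    f
  }
}

.kernelHeadroom <- function(kernels) {
  h <- 1
  for (k in kernels) if (k$sign > 0) h <- h * (1 + k$amplitude)
  h
}

# Thinned inhomogeneous Poisson draw on [0, durationS).
.inhomPoisson <- function(rateFn, rMax, durationS) {
  cand <- .homPoisson(rMax, 0, durationS)
  if (!length(cand)) return(numeric(0))
  cand[stats::runif(length(cand)) < rateFn(cand) / rMax]
}

#' Simulate one unit
#'
#' Generates the spike train described by a \code{\link{unitSpec}} over
#' \code{[0, durationS)}, with event-response modulation taken from the
#' trial table (omit it for a task-free train). Deterministic given seed.
#'
#' @param spec a \code{\link{unitSpec}}.
#' @param trials trial table or NULL.
#' @param durationS session duration, seconds (default: spans the trials).
#' @param seed RNG seed.
#' @param unitId id of the emitted train.
#' @return list with \code{spikes} (\linkS4class{SpikeTrain}) and
#'   \code{truth} (ground-truth entry).
#' @export
simulateUnit <- function(spec, trials = NULL, durationS = NULL, seed = 1,
                         unitId = spec$unitId) {
  set.seed(seed)
  if (is.null(durationS)) {
    if (is.null(trials)) .stopf("either trials or durationS is required")
    durationS <- max(virtualReinforcementTimes(trials)) + 2
  }
  if (is.null(unitId)) unitId <- "unit"
  base <- spec$baselineHz
  if (spec$etype %in% c("poisson", "rhythmic")) {
    m <- if (spec$etype == "rhythmic") spec$rhythm$depth else 0
    f <- if (spec$etype == "rhythmic") spec$rhythm$freqHz else 0
    mod <- .modulationFn(spec$responses, trials)
    rateFn <- function(t) base * (1 + m * cos(2 * pi * f * t)) * mod(t)
    rMax <- base * (1 + m) * .kernelHeadroom(spec$responses)
    tt <- .inhomPoisson(rateFn, rMax, durationS)
  } else {
    bResp <- if (!is.null(spec$burstResponses)) spec$burstResponses
             else spec$responses
    sResp <- if (!is.null(spec$singleResponses)) spec$singleResponses
             else spec$responses
    bMod <- .modulationFn(bResp, trials)
    sMod <- .modulationFn(sResp, trials)
    onsets <- .inhomPoisson(function(t) spec$burst$rbHz * bMod(t),
                            spec$burst$rbHz * .kernelHeadroom(bResp),
                            durationS)
    burstSpikes <- unlist(lapply(onsets, function(t0) {
      nExtra <- 1L + stats::rpois(1L, spec$burst$mu)
      isis <- stats::runif(nExtra, spec$burst$isiRangeMs[1],
                           spec$burst$isiRangeMs[2]) / 1000
      t0 + cumsum(c(0, isis))
    }))
    singles <- .inhomPoisson(function(t) spec$burst$singlesHz * sMod(t),
                             spec$burst$singlesHz * .kernelHeadroom(sResp),
                             durationS)
    tt <- c(burstSpikes, singles)
  }
  tt <- .strictSort(tt)
  tt <- tt[tt >= 0 & tt < durationS]
  truth <- list(unit_id = unitId, etype = spec$etype,
                baseline_hz = base,
                rhythm = if (spec$etype == "rhythmic") spec$rhythm else NULL,
                burst = if (spec$etype == "bursting") spec$burst else NULL,
                responses = spec$responses, dv_um = spec$dvUm, seed = seed)
  list(spikes = SpikeTrain(tt, unitId = unitId, dvPosition = spec$dvUm),
       truth = truth)
}

#' Simulate one coupled pair
#'
#' @param spec a \code{\link{pairSpec}}.
#' @param durationS duration, seconds.
#' @param seed RNG seed.
#' @param ids character(2) of unit ids.
#' @param trials optional trial table for response kernels on the
#'   backgrounds.
#' @return list with \code{a}, \code{b} (\linkS4class{SpikeTrain}s) and
#'   \code{truth}.
#' @export
simulatePair <- function(spec, durationS, seed = 1, ids = c("a", "b"),
                         trials = NULL) {
  set.seed(seed)
  mod <- .modulationFn(spec$responses, trials)
  head <- .kernelHeadroom(spec$responses)
  bg <- function() .inhomPoisson(function(t) spec$backgroundHz * mod(t),
                                 spec$backgroundHz * head, durationS)
  if (spec$type == "common_input") {
    shared <- .homPoisson(spec$rateHz, 0, durationS)
    copy <- function() {
      keep <- shared[stats::runif(length(shared)) < spec$copyProb]
      keep + stats::rnorm(length(keep), 0, spec$copyJitterSdMs / 1000)
    }
    ta <- c(bg(), copy()); tb <- c(bg(), copy())
  } else {
    ta <- bg()
    tb <- bg()
    hit <- ta[stats::runif(length(ta)) < spec$pSyn]
    tb <- c(tb, hit + stats::rnorm(length(hit), spec$delayMs / 1000,
                                   spec$delaySdMs / 1000))
  }
  clean <- function(x) {
    x <- .strictSort(x); x[x >= 0 & x < durationS]
  }
  list(a = SpikeTrain(clean(ta), unitId = ids[1]),
       b = SpikeTrain(clean(tb), unitId = ids[2]),
       truth = list(unit_a = ids[1], unit_b = ids[2], class = spec$type,
                    params = spec, seed = seed))
}

#' Simulate licking activity
#'
#' Inhomogeneous Poisson licking: baseline rate between trials,
#' cue-dependent anticipatory rate from cue onset to reinforcement (virtual
#' reinforcement on omission trials), and a consumption burst after
#' reward delivery.
#'
#' @param trials trial table.
#' @param lickParams list(baselineHz, anticipatoryRewardHz,
#'   anticipatoryPunishHz, consumptionHz, consumptionDurS).
#' @param seed RNG seed.
#' @return numeric vector of lick times, seconds.
#' @export
simulateLicks <- function(trials, lickParams, seed = 1) {
  set.seed(seed)
  reinf <- virtualReinforcementTimes(trials)
  T <- max(reinf) + 2
  base <- .homPoisson(lickParams$baselineHz, 0, T)
  segs <- data.frame(lo = trials$t_cue_on_s, hi = reinf)
  consume <- trials$outcome == "reward"
  segs <- rbind(segs, data.frame(lo = reinf[consume],
                                 hi = reinf[consume] +
                                   lickParams$consumptionDurS))
  inSeg <- rep(FALSE, length(base))
  for (i in seq_len(nrow(segs)))
    inSeg <- inSeg | (base >= segs$lo[i] & base < segs$hi[i])
  out <- base[!inSeg]
  for (i in seq_len(nrow(trials))) {
    r <- if (trials$cue[i] == "likely_reward") lickParams$anticipatoryRewardHz
         else lickParams$anticipatoryPunishHz
    out <- c(out, .homPoisson(r, trials$t_cue_on_s[i], reinf[i]))
    if (consume[i])
      out <- c(out, .homPoisson(lickParams$consumptionHz, reinf[i],
                                reinf[i] + lickParams$consumptionDurS))
  }
  .strictSort(out)
}

#' Simulate a complete session
#'
#' Composes the trial, unit, pair and lick generators into a full
#' \linkS4class{Session} with ground truth; optionally writes the bundle
#' and \code{ground_truth.json} to disk. Fully reproducible from
#' (config, seed).
#'
#' @param config a \code{\link{simConfig}} with unit/pair specs.
#' @param path optional bundle directory to write.
#' @return invisibly, list with \code{session} and \code{truth}.
#' @export
simulateSession <- function(config, path = NULL) {
  set.seed(config$seed)
  nU <- length(config$units); nP <- length(config$pairs)
  seeds <- sample.int(.Machine$integer.max - 1L, nU + nP + 2L)
  trialsDf <- simulateTrials(config, seed = seeds[1])
  durationS <- max(virtualReinforcementTimes(trialsDf)) + 2
  sts <- list(); unitTruth <- list(); pairTruth <- list()
  for (i in seq_len(nU)) {
    id <- config$units[[i]]$unitId
    if (is.null(id)) id <- sprintf("u%03d", i)
    r <- simulateUnit(config$units[[i]], trialsDf, durationS,
                      seed = seeds[1 + i], unitId = id)
    sts[[length(sts) + 1L]] <- r$spikes
    unitTruth[[id]] <- r$truth
  }
  for (j in seq_len(nP)) {
    ids <- sprintf("p%03d%s", j, c("a", "b"))
    r <- simulatePair(config$pairs[[j]], durationS, seed = seeds[1 + nU + j],
                      ids = ids, trials = trialsDf)
    sts[[length(sts) + 1L]] <- r$a
    sts[[length(sts) + 1L]] <- r$b
    pairTruth[[sprintf("p%03d", j)]] <- r$truth
  }
  lk <- simulateLicks(trialsDf, config$lick, seed = seeds[nU + nP + 2L])
  meta <- list(subject = config$subject,
               contingencies = config$contingencies, seed = config$seed,
               synthetic = TRUE,
               generator = list(nTrials = config$nTrials,
                                cueDurationS = config$cueDurationS,
                                reinforcementDelayS = config$reinforcementDelayS,
                                itiS = config$itiS, lick = config$lick))
  sess <- Session(spikeTrains = sts, trials = trialsDf, licks = lk,
                  meta = meta)
  truth <- list(seed = config$seed, units = unitTruth, pairs = pairTruth)
  if (!is.null(path)) {
    writeSessionBundle(sess, path)
    jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(session = sess, truth = truth))
}
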