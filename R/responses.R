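.asTimes <- function(x) {
  if (is(x, "SpikeTrain")) spikeTimes(x) else as.numeric(x)
}

#' Peri-event time histogram
#'
#' Trial-averaged rate aligned to events: for each bin,
#' (spike count in the bin pooled over events) / (n_events * binS). Bins are
#' half-open \code{[lo, hi)}. Optional mass-conserving Gaussian smoothing of
#' the rate.
#'
#' @param spikes \linkS4class{SpikeTrain} or numeric times, seconds (also
#'   used for lick trains).
#' @param events event timestamps, seconds (>= 1 required).
#' @param window time window around the event, seconds.
#' @param binS bin width, seconds.
#' @param smoothSdS Gaussian smoothing SD in seconds (0 = none).
#' @param eventLabel label stored with the result.
#' @return a \linkS4class{Peth}.
#' @export
computePeth <- function(spikes, events, window = c(-1, 1), binS = 0.02,
                        smoothSdS = 0, eventLabel = "") {
  if (!length(events)) .stopf("insufficient data: no events")
  tt <- .asTimes(spikes)
  nb <- round((window[2] - window[1]) / binS)
  if (nb < 1L || abs(nb * binS - (window[2] - window[1])) > 1e-9)
    .stopf("window must be an integer number of bins")
  edges <- window[1] + seq(0, nb) * binS
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  cts <- rep(0, nb)
  for (e in events) {
    rel <- tt[tt >= e + window[1] & tt < e + window[2]] - e
    if (length(rel)) {
      idx <- floor((rel - window[1]) / binS) + 1
      idx[idx > nb] <- nb
      cts <- cts + tabulate(idx, nbins = nb)
    }
  }
  rate <- cts / (length(events) * binS)
  if (smoothSdS > 0) rate <- .gaussSmooth(rate, smoothSdS / binS)
  new("Peth", binCenters = centers, rate = rate, z = numeric(0),
      nTrials = length(events), eventLabel = as.character(eventLabel),
      binS = binS, smoothingSdS = smoothSdS)
}

#' Z-score a PETH against its baseline window
#'
#' z = (rate - baseline mean) / baseline SD per bin, with mean and SD taken
#' over the bins whose centers fall in the baseline window. By construction
#' the baseline bins of the result have mean 0 and SD 1.
#'
#' @param peth a \linkS4class{Peth}.
#' @param baseline baseline window, seconds (must lie inside the PETH
#'   window).
#' @return the \linkS4class{Peth} with its \code{z} slot filled.
#' @export
zscorePeth <- function(peth, baseline = c(-0.5, 0)) {
  idx <- peth@binCenters >= baseline[1] & peth@binCenters < baseline[2]
  if (!any(idx)) .stopf("baseline window outside the PETH window")
  mb <- mean(peth@rate[idx])
  sb <- stats::sd(peth@rate[idx])
  if (is.na(sb) || sb == 0) {
    cond <- simpleError("degenerate baseline: zero SD, cannot Z-score")
    class(cond) <- c("degenerateBaseline", class(cond))
    stop(cond)
  }
  initialize(peth, z = (peth@rate - mb) / sb)
}

#' Test a unit's response to an event
#'
#' Per-event spike counts in the baseline and response windows are compared
#' with a two-sided Mann-Whitney U (rank-sum) test. When p < alpha the
#' direction is taken from the sign of the median (fallback mean) rate
#' difference; otherwise the unit is unresponsive to this event. Counts are
#' converted to rates so baseline and response windows of different lengths
#' remain comparable.
#'
#' @param spikes \linkS4class{SpikeTrain} or numeric times, seconds.
#' @param events event timestamps (>= 2 required).
#' @param baselineWin,responseWin half-open windows relative to the event,
#'   seconds.
#' @param alpha significance level (default 0.001).
#' @param eventLabel label stored with the result.
#' @return one-row data.frame: unit_id, event_label, direction
#'   ("activated", "inhibited" or "none"), p_value, effect_hz (mean
#'   response-window rate minus mean baseline rate), n_trials.
#' @export
testEventResponse <- function(spikes, events, baselineWin = c(-0.5, 0),
                              responseWin = c(0, 0.5), alpha = 0.001,
                              eventLabel = "") {
  if (length(events) < 2L) .stopf("insufficient data: need >= 2 events")
  tt <- .asTimes(spikes)
  uid <- if (is(spikes, "SpikeTrain")) unitId(spikes) else ""
  durB <- diff(baselineWin); durR <- diff(responseWin)
  b <- .eventCounts(tt, events, baselineWin) / durB
  r <- .eventCounts(tt, events, responseWin) / durR
  if (all(b == b[1]) && all(r == r[1]) && b[1] == r[1]) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(r, b, exact = FALSE)$p.value)
    if (is.na(p)) p <- 1
  }
  dirn <- "none"
  if (p < alpha) {
    d <- stats::median(r) - stats::median(b)
    if (d == 0) d <- mean(r) - mean(b)
    dirn <- if (d > 0) "activated" else if (d < 0) "inhibited" else "none"
  }
  data.frame(unit_id = uid, event_label = as.character(eventLabel),
             direction = dirn, p_value = p,
             effect_hz = mean(r) - mean(b), n_trials = length(events),
             stringsAsFactors = FALSE)
}

#' Response latency from a Z-scored PETH
#'
#' The latency is the bin center at which |z| is extremal within the
#' response window: the maximum of z for activated units, the minimum for
#' inhibited units.
#'
#' @param zpeth a Z-scored \linkS4class{Peth} (see \code{\link{zscorePeth}}).
#' @param responseWin search window, seconds.
#' @param direction \code{"activated"} or \code{"inhibited"}.
#' @return latency in seconds.
#' @export
responseLatency <- function(zpeth, responseWin = c(0, 0.6),
                            direction = c("activated", "inhibited")) {
  direction <- match.arg(direction)
  if (!length(zpeth@z)) .stopf("PETH has not been Z-scored")
  idx <- which(zpeth@binCenters >= responseWin[1] &
               zpeth@binCenters < responseWin[2])
  if (!length(idx)) .stopf("response window outside the PETH window")
  z <- zpeth@z[idx]
  pick <- if (direction == "activated") which.max(z) else which.min(z)
  zpeth@binCenters[idx[pick]]
}

#' Compare response strength between two outcome conditions
#'
#' For each unit, the difference in mean response-window spike count between
#' condition A and condition B events; units with fewer than
#' \code{minTrials} trials in either condition are excluded (recorded, not
#' fatal). The per-unit differences are tested against zero with a
#' two-sided Wilcoxon signed-rank test.
#'
#' @param units list of \linkS4class{SpikeTrain}s (or a single one).
#' @param eventsA,eventsB event timestamps of the two conditions, seconds.
#' @param responseWin response window relative to the event, seconds.
#' @param minTrials minimal trials per condition (default 5).
#' @return list with \code{perUnit} (unit_id, delta, excluded), \code{p},
#'   \code{statistic} and \code{nIncluded}.
#' @export
compareOutcomeConditions <- function(units, eventsA, eventsB,
                                     responseWin = c(0, 0.5),
                                     minTrials = 5) {
  if (is(units, "SpikeTrain")) units <- list(units)
  excluded <- length(eventsA) < minTrials || length(eventsB) < minTrials
  rows <- lapply(units, function(u) {
    if (excluded)
      return(data.frame(unit_id = unitId(u), delta = NA_real_,
                        excluded = TRUE, stringsAsFactors = FALSE))
    tt <- spikeTimes(u)
    data.frame(unit_id = unitId(u),
               delta = mean(.eventCounts(tt, eventsA, responseWin)) -
                       mean(.eventCounts(tt, eventsB, responseWin)),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  perUnit <- do.call(rbind, rows)
  d <- perUnit$delta[!perUnit$excluded]
  if (length(d) < 2L || all(d == 0)) {
    p <- NA_real_; stat <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE))
    p <- wt$p.value; stat <- unname(wt$statistic)
  }
  list(perUnit = perUnit, p = p, statistic = stat,
       nIncluded = sum(!perUnit$excluded))
}

#' Three-way response-combination table
#'
#' Cross-tabulates per-unit response signs (+/0/-) over three events into
#' the 27 possible combinations. Units missing a test for any of the three
#' events are dropped with a warning. Marginal sums equal the per-event
#' sign counts by construction.
#'
#' @param results data.frame of \code{\link{testEventResponse}} rows
#'   (columns unit_id, event_label, direction) covering three events.
#' @param events the three event labels (default: the unique labels
#'   present, which must number three).
#' @return a 3 x 3 x 3 table with dimnames \code{c("+", "0", "-")} per
#'   event.
#' @export
responseCombinationTable <- function(results, events = NULL) {
  if (is.null(events)) events <- unique(results$event_label)
  if (length(events) != 3L) .stopf("exactly three events are required")
  sgn <- c(activated = "+", none = "0", inhibited = "-")
  wide <- lapply(events, function(e) {
    sub <- results[results$event_label == e, ]
    stats::setNames(sgn[sub$direction], sub$unit_id)
  })
  units <- Reduce(intersect, lapply(wide, names))
  all_units <- unique(results$unit_id)
  if (length(units) < length(all_units))
    warning(sprintf("%d unit(s) missing an event test were dropped",
                    length(all_units) - length(units)))
  lv <- c("+", "0", "-")
  table(factor(wide[[1]][units], levels = lv),
        factor(wide[[2]][units], levels = lv),
        factor(wide[[3]][units], levels = lv),
        dnn = events)
}

#' Chi-square comparison of responsive fractions between two groups
#'
#' 2x2 chi-square test without continuity correction on responsive vs
#' non-responsive counts of two unit groups.
#'
#' @param nRespA,nA responsive and total counts in group A.
#' @param nRespB,nB responsive and total counts in group B.
#' @return list with \code{chi2} and \code{p}.
#' @export
compareGroupFractions <- function(nRespA, nA, nRespB, nB) {
  if (any(c(nRespA, nA, nRespB, nB) < 0) || nRespA > nA || nRespB > nB)
    .stopf("counts must be non-negative with n_resp <= n")
  m <- matrix(c(nRespA, nA - nRespA, nRespB, nB - nRespB), nrow = 2,
              byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    .stopf("degenerate table: an expected cell count is zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}
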