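#' Parse a spike train into bursts and single spikes
#'
#' Left-to-right ISI scan: a burst starts at spike i when the ISI to the
#' next spike is below \code{firstIsiMaxMs} (default 10 ms) and extends
#' while subsequent ISIs stay below \code{intraIsiMaxMs} (default 15 ms);
#' a spike already inside a burst cannot start a new one. All other spikes
#' are singles. Inequalities are strict.
#'
#' @param spikes \linkS4class{SpikeTrain} or sorted numeric vector, seconds.
#' @param firstIsiMaxMs burst-initiating ISI bound, ms (> 0).
#' @param intraIsiMaxMs burst-continuation ISI bound, ms (> 0).
#' @return a \linkS4class{BurstParse}.
#' @examples
#' bp <- parseBursts(SpikeTrain(c(0, 0.008, 0.020, 0.100)))
#' bp@labels  # burst_first, burst_member, burst_member, single
#' @export
parseBursts <- function(spikes, firstIsiMaxMs = 10, intraIsiMaxMs = 15) {
  if (firstIsiMaxMs <= 0 || intraIsiMaxMs <= 0)
    .stopf("ISI thresholds must be positive")
  uid <- if (is(spikes, "SpikeTrain")) unitId(spikes) else "unit"
  tt <- if (is(spikes, "SpikeTrain")) spikeTimes(spikes) else as.numeric(spikes)
  n <- length(tt)
  labels <- rep("single", n)
  sizes <- integer(0)
  if (n >= 2L) {
    isi <- diff(tt) * 1000
    i <- 1L
    while (i <= n - 1L) {
      if (isi[i] < firstIsiMaxMs) {
        j <- i + 1L
        while (j <= n - 1L && isi[j] < intraIsiMaxMs) j <- j + 1L
        labels[i] <- "burst_first"
        labels[(i + 1L):j] <- "burst_member"
        sizes <- c(sizes, j - i + 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  new("BurstParse", unitId = uid, times = tt, labels = labels,
      burstOnsets = tt[labels == "burst_first"],
      singleTimes = tt[labels == "single"], burstSizes = sizes)
}

#' Burst parse as a per-spike data.frame
#'
#' @param parse a \linkS4class{BurstParse}.
#' @return data.frame: unit_id, spike_time_s, label.
#' @export
burstParseTable <- function(parse) {
  data.frame(unit_id = parse@unitId, spike_time_s = parse@times,
             label = parse@labels, stringsAsFactors = FALSE)
}

#' Test for dissociated burst vs single-spike event coding
#'
#' Runs the event-response test separately on the unit's burst event train
#' and its single-spike train, then reports the joint category. By default
#' each burst is represented by its first spike ("onsets" mode), one event
#' per physiological burst; \code{mode = "all_spikes"} aligns every spike
#' inside bursts instead.
#'
#' @param parse a \linkS4class{BurstParse}.
#' @param events event timestamps, seconds (>= 2 required).
#' @param baselineWin,responseWin windows relative to the event, seconds.
#' @param alpha significance level for each train's test (default 0.01).
#' @param mode \code{"onsets"} or \code{"all_spikes"}.
#' @return list with \code{category} ("concordant", "opposite",
#'   "burst_only", "single_only" or "neither") and the two per-train
#'   response rows (\code{burst}, \code{single}).
#' @export
detectRateDissociation <- function(parse, events, baselineWin = c(-0.5, 0),
                                   responseWin = c(0, 0.5), alpha = 0.01,
                                   mode = c("onsets", "all_spikes")) {
  mode <- match.arg(mode)
  if (length(events) < 2L)
    .stopf("insufficient data: need >= 2 events")
  bt <- if (mode == "onsets") parse@burstOnsets
        else parse@times[parse@labels != "single"]
  rb <- testEventResponse(bt, events, baselineWin, responseWin, alpha,
                          eventLabel = "burst_train")
  rs <- testEventResponse(parse@singleTimes, events, baselineWin,
                          responseWin, alpha, eventLabel = "single_train")
  db <- rb$direction; ds <- rs$direction
  category <-
    if (db != "none" && ds != "none") {
      if (db == ds) "concordant" else "opposite"
    } else if (db != "none") "burst_only"
    else if (ds != "none") "single_only"
    else "neither"
  list(category = category, burst = rb, single = rs)
}
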