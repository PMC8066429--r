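#' @useDynLib spikeEtypes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SpikeTrain: one unit's sorted spike timestamps
#'
#' Holds the event times of a single unit on the session clock, in seconds,
#' together with its identity and an optional dorsoventral recording depth.
#' Times must be strictly increasing and non-negative.
#'
#' @slot unitId single string identifying the unit within its session.
#' @slot times numeric vector of spike times in seconds, strictly increasing.
#' @slot dvPosition dorsoventral depth of the recording site in micrometers,
#'   or \code{NA} when unknown.
#' @slot sessionId identifier of the session the unit was recorded in.
#' @export
setClass("SpikeTrain",
  slots = c(unitId = "character", times = "numeric",
            dvPosition = "numeric", sessionId = "character"))

setValidity("SpikeTrain", function(object) {
  msgs <- character(0)
  if (length(object@unitId) != 1L || is.na(object@unitId))
    msgs <- c(msgs, "unitId must be a single non-NA string")
  tt <- object@times
  if (anyNA(tt)) msgs <- c(msgs, "times must not contain NA")
  else {
    if (length(tt) && any(tt < 0)) msgs <- c(msgs, "times must be >= 0")
    if (length(tt) > 1L && any(diff(tt) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
  }
  if (length(object@dvPosition) != 1L)
    msgs <- c(msgs, "dvPosition must be a single value (NA allowed)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times numeric vector of spike times in seconds, strictly increasing.
#' @param unitId unit identifier.
#' @param dvPosition optional dorsoventral depth, micrometers.
#' @param sessionId optional session identifier.
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' st <- SpikeTrain(c(0.1, 0.5, 0.9), unitId = "u1")
#' nSpikes(st)
#' @export
SpikeTrain <- function(times, unitId = "unit", dvPosition = NA_real_,
                       sessionId = "") {
  new("SpikeTrain", unitId = as.character(unitId),
      times = as.numeric(times),
      dvPosition = as.numeric(dvPosition),
      sessionId = as.character(sessionId))
}

#' Session: spike trains, trial table and licks on one clock
#'
#' A complete recording session: a list of \linkS4class{SpikeTrain} objects,
#' the Pavlovian trial table, lick timestamps, and free-form metadata (subject
#' id, contingency table, generator parameters for synthetic sessions).
#'
#' The trial table is a data.frame with columns \code{trial_id}, \code{cue}
#' (\code{"likely_reward"} or \code{"likely_punishment"}), \code{outcome}
#' (\code{"reward"}, \code{"punishment"} or \code{"omission"}),
#' \code{t_cue_on_s}, \code{t_cue_off_s} and \code{t_reinforcement_s}
#' (\code{NA} exactly for omission trials).
#'
#' @slot spikeTrains list of \linkS4class{SpikeTrain}, unique unit ids.
#' @slot trials trial table data.frame (schema above).
#' @slot licks numeric vector of lick times, seconds, strictly increasing.
#' @slot meta named list of metadata.
#' @export
setClass("Session",
  slots = c(spikeTrains = "list", trials = "data.frame",
            licks = "numeric", meta = "list"))

#' Construct a Session
#'
#' @param spikeTrains list of \linkS4class{SpikeTrain}.
#' @param trials trial table data.frame (see \linkS4class{Session}).
#' @param licks numeric lick times, seconds.
#' @param meta named list of metadata.
#' @return A \linkS4class{Session}.
#' @export
Session <- function(spikeTrains = list(), trials = emptyTrialTable(),
                    licks = numeric(0), meta = list()) {
  new("Session", spikeTrains = spikeTrains, trials = trials,
      licks = as.numeric(licks), meta = meta)
}

#' An empty trial table with the canonical schema
#' @return zero-row data.frame with the trial-table columns.
#' @export
emptyTrialTable <- function() {
  data.frame(trial_id = integer(0), cue = character(0),
             outcome = character(0), t_cue_on_s = numeric(0),
             t_cue_off_s = numeric(0), t_reinforcement_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Correlogram: binned auto- or cross-correlation of spike trains
#'
#' Lag histogram of spike pairs. Lags are bin centers in milliseconds,
#' symmetric about zero; counts are coincidences per bin. For
#' autocorrelograms the zero-lag bin is excluded (set to 0) and counts are
#' symmetric. Optional pointwise confidence bands come from jitter
#' surrogates (\code{\link{jitterSurrogateCi}}).
#'
#' @slot lags bin centers, milliseconds.
#' @slot counts coincidences per bin.
#' @slot binMs bin width, milliseconds.
#' @slot windowMs half-window, milliseconds.
#' @slot nRefSpikes number of reference spikes.
#' @slot kind \code{"auto"} or \code{"cross"}.
#' @slot normalization \code{"raw_counts"} or \code{"per_ref_spike"}.
#' @slot ciLower,ciUpper per-bin confidence bands (length 0 when absent).
#' @export
setClass("Correlogram",
  slots = c(lags = "numeric", counts = "numeric", binMs = "numeric",
            windowMs = "numeric", nRefSpikes = "integer", kind = "character",
            normalization = "character", ciLower = "numeric",
            ciUpper = "numeric"))

setValidity("Correlogram", function(object) {
  msgs <- character(0)
  if (length(object@lags) != length(object@counts))
    msgs <- c(msgs, "lags and counts must have equal length")
  if (length(object@lags) &&
      max(abs(object@lags + rev(object@lags))) > 1e-9)
    msgs <- c(msgs, "lags must be symmetric about 0")
  if (!object@kind %in% c("auto", "cross"))
    msgs <- c(msgs, "kind must be 'auto' or 'cross'")
  if (object@kind == "auto" && length(object@counts)) {
    z <- which(abs(object@lags) < 1e-9)
    if (length(z) && object@counts[z] != 0)
      msgs <- c(msgs, "autocorrelogram zero-lag bin must be 0")
    if (max(abs(object@counts - rev(object@counts))) > 1e-6)
      msgs <- c(msgs, "autocorrelogram counts must be symmetric")
  }
  if (length(object@ciLower) &&
      length(object@ciLower) != length(object@counts))
    msgs <- c(msgs, "ciLower length must match counts")
  if (length(object@ciUpper) &&
      length(object@ciUpper) != length(object@counts))
    msgs <- c(msgs, "ciUpper length must match counts")
  if (length(msgs)) msgs else TRUE
})

#' Peth: peri-event time histogram
#'
#' Trial-averaged firing (or licking) rate aligned to a behavioral event,
#' with optional Z-scored rate relative to a baseline window.
#'
#' @slot binCenters seconds relative to the event.
#' @slot rate Hz per bin.
#' @slot z Z-scored rate (length 0 until \code{\link{zscorePeth}}).
#' @slot nTrials number of aligning events.
#' @slot eventLabel label of the aligning event.
#' @slot binS bin width, seconds.
#' @slot smoothingSdS Gaussian smoothing SD applied to the rate, seconds.
#' @export
setClass("Peth",
  slots = c(binCenters = "numeric", rate = "numeric", z = "numeric",
            nTrials = "integer", eventLabel = "character", binS = "numeric",
            smoothingSdS = "numeric"))

#' BurstParse: ISI-rule partition of a spike train
#'
#' Every spike is labeled exactly once as \code{burst_first},
#' \code{burst_member} or \code{single}; burst onsets, single-spike times and
#' burst sizes are carried alongside. Produced by \code{\link{parseBursts}}.
#'
#' @slot unitId unit identifier.
#' @slot times all spike times, seconds.
#' @slot labels per-spike label.
#' @slot burstOnsets times of burst-initiating spikes.
#' @slot singleTimes times of single spikes.
#' @slot burstSizes spikes per burst (all >= 2).
#' @export
setClass("BurstParse",
  slots = c(unitId = "character", times = "numeric", labels = "character",
            burstOnsets = "numeric", singleTimes = "numeric",
            burstSizes = "integer"))

setValidity("BurstParse", function(object) {
  msgs <- character(0)
  if (length(object@labels) != length(object@times))
    msgs <- c(msgs, "one label per spike required")
  if (!all(object@labels %in% c("burst_first", "burst_member", "single")))
    msgs <- c(msgs, "unknown spike label")
  if (length(object@burstSizes) && any(object@burstSizes < 2L))
    msgs <- c(msgs, "burst sizes must all be >= 2")
  nb <- sum(object@labels != "single")
  if (sum(object@burstSizes) != nb)
    msgs <- c(msgs, "burst sizes must sum to the number of burst spikes")
  if (length(msgs)) msgs else TRUE
})

#' PairResult: classified cross-correlogram features of one pair
#'
#' Supra-band runs of the pair's cross-correlogram, each classified as
#' narrow zero-lag synchrony, broad zero-lag synchrony, putative
#' monosynaptic excitation, or left unclassified.
#'
#' @slot unitA,unitB unit identifiers (CCG reference and target).
#' @slot ccg \linkS4class{Correlogram} with confidence bands.
#' @slot features data.frame: run_start_ms, run_end_ms, width_ms, center_ms,
#'   class.
#' @slot anySync TRUE iff some feature is narrow or broad zero-lag synchrony.
#' @export
setClass("PairResult",
  slots = c(unitA = "character", unitB = "character", ccg = "Correlogram",
            features = "data.frame", anySync = "logical"))

#' AssemblyGraph: co-firing graph induced by pair classification
#'
#' Nodes are units; edges are significant pairwise features; assemblies are
#' connected components of the synchrony (narrow/broad) subgraph with at
#' least two members. A unit is "synchronous" iff it has at least one
#' synchrony edge.
#'
#' @slot nodes unit ids.
#' @slot edges data.frame: unit_a, unit_b, class.
#' @slot assemblies list of character vectors (component memberships).
#' @slot membership named character vector, "synchronous"/"asynchronous".
#' @export
setClass("AssemblyGraph",
  slots = c(nodes = "character", edges = "data.frame", assemblies = "list",
            membership = "character"))
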