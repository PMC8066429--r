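#' @rdname SpikeTrain-class
#' @param object,x a \linkS4class{SpikeTrain}.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname SpikeTrain-class
#' @export
setGeneric("dvPosition", function(x) standardGeneric("dvPosition"))

#' @rdname SpikeTrain-class
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname SpikeTrain-class
#' @export
setMethod("unitId", "SpikeTrain", function(x) x@unitId)

#' @rdname SpikeTrain-class
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @rdname SpikeTrain-class
#' @export
setMethod("dvPosition", "SpikeTrain", function(x) x@dvPosition)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes", object@unitId,
              length(object@times)))
  if (length(object@times))
    cat(sprintf(" over %.1f s", diff(range(object@times))))
  if (!is.na(object@dvPosition))
    cat(sprintf(", dv = %g um", object@dvPosition))
  cat("\n")
})

#' @rdname Session-class
#' @param x,object a \linkS4class{Session}.
#' @export
setGeneric("spikeTrains", function(x) standardGeneric("spikeTrains"))

#' @rdname Session-class
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname Session-class
#' @export
setGeneric("licks", function(x) standardGeneric("licks"))

#' @rdname Session-class
#' @export
setGeneric("sessionMeta", function(x) standardGeneric("sessionMeta"))

#' @rdname Session-class
#' @export
setMethod("spikeTrains", "Session", function(x) x@spikeTrains)

#' @rdname Session-class
#' @export
setMethod("trials", "Session", function(x) x@trials)

#' @rdname Session-class
#' @export
setMethod("licks", "Session", function(x) x@licks)

#' @rdname Session-class
#' @export
setMethod("sessionMeta", "Session", function(x) x@meta)

setMethod("show", "Session", function(object) {
  cat(sprintf("Session: %d units, %d trials, %d licks\n",
              length(object@spikeTrains), nrow(object@trials),
              length(object@licks)))
})

#' @rdname Correlogram-class
#' @param x,object a \linkS4class{Correlogram}.
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' @rdname Correlogram-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname Correlogram-class
#' @export
setMethod("lags", "Correlogram", function(x) x@lags)

#' @rdname Correlogram-class
#' @export
setMethod("counts", "Correlogram", function(x) x@counts)

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("%s-correlogram: bin %.2g ms, window +/-%g ms, %d ref spikes",
              object@kind, object@binMs, object@windowMs,
              object@nRefSpikes))
  if (length(object@ciUpper)) cat(", with CI bands")
  cat("\n")
})

#' Correlogram as a data.frame
#'
#' @param x a \linkS4class{Correlogram}.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with lag_ms, count and (when present) ci_lower,
#'   ci_upper columns.
#' @export
as.data.frame.Correlogram <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  df <- data.frame(lag_ms = x@lags, count = x@counts)
  if (length(x@ciLower)) df$ci_lower <- x@ciLower
  if (length(x@ciUpper)) df$ci_upper <- x@ciUpper
  df
}

setMethod("show", "Peth", function(object) {
  cat(sprintf("PETH '%s': %d bins of %g s, %d trials%s\n",
              object@eventLabel, length(object@binCenters), object@binS,
              object@nTrials,
              if (length(object@z)) ", Z-scored" else ""))
})

setMethod("show", "BurstParse", function(object) {
  cat(sprintf("BurstParse '%s': %d spikes, %d bursts, %d singles\n",
              object@unitId, length(object@times),
              length(object@burstSizes), length(object@singleTimes)))
})

setMethod("show", "PairResult", function(object) {
  cat(sprintf("PairResult %s-%s: %d feature(s)%s\n", object@unitA,
              object@unitB, nrow(object@features),
              if (object@anySync) ", synchronous" else ""))
})

setMethod("show", "AssemblyGraph", function(object) {
  cat(sprintf("AssemblyGraph: %d units, %d edges, %d assemblies, %d synchronous\n",
              length(object@nodes), nrow(object@edges),
              length(object@assemblies),
              sum(object@membership == "synchronous")))
})
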