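#' Jitter-surrogate confidence bands for a cross-correlogram
#'
#' Computes the observed CCG and pointwise confidence bands from spike-time
#' jitter surrogates: each surrogate displaces every target spike
#' independently by Uniform(-jitterMs, +jitterMs) and recomputes the CCG;
#' the bands are per-bin percentiles of the surrogate counts at
#' \code{(1 - ci)/2} and \code{1 - (1 - ci)/2}. The +/-25 ms default
#' destroys co-firing structure at the few-ms synchrony scale while
#' preserving slower rate comodulation, so excursions above the upper band
#' flag fine-timescale coupling. Deterministic given \code{seed}.
#'
#' @param ref,target \linkS4class{SpikeTrain}s or sorted numeric vectors,
#'   seconds.
#' @param binMs,windowMs CCG binning (defaults 0.5 and 50 ms).
#' @param jitterMs jitter half-width, ms.
#' @param nSurrogates number of surrogates (>= 100).
#' @param ci two-sided band coverage (default 0.95).
#' @param smoothMs Gaussian SD (ms) applied identically to the observed CCG
#'   and to every surrogate before taking percentiles (default one bin,
#'   0.5 ms). The comparison stays exchangeable under the surrogate null,
#'   while single-bin counting noise no longer fragments wide peaks into
#'   spurious sub-features.
#' @param seed optional RNG seed for reproducible bands.
#' @return a \linkS4class{Correlogram} of kind \code{"cross"} with
#'   \code{ciLower}/\code{ciUpper} filled; counts are the smoothed CCG.
#' @export
jitterSurrogateCi <- function(ref, target, binMs = 0.5, windowMs = 50,
                              jitterMs = 25, nSurrogates = 1000, ci = 0.95,
                              smoothMs = 0.5, seed = NULL) {
  if (nSurrogates < 100L) .stopf("need nSurrogates >= 100")
  tr <- .asTimes(ref); tt <- .asTimes(target)
  obs <- crosscorrelogram(tr, tt, binMs, windowMs)
  if (!length(tr) || !length(tt)) {
    warning("empty spike train: degenerate (all-zero) bands")
    return(initialize(obs, ciLower = rep(0, length(obs@lags)),
                      ciUpper = rep(0, length(obs@lags))))
  }
  if (!is.null(seed)) set.seed(seed)
  surr <- .cppJitterSurrogates(tr, tt, binMs, windowMs, jitterMs,
                               as.integer(nSurrogates))
  if (smoothMs > 0) {
    obs <- initialize(obs, counts = .gaussSmooth(obs@counts,
                                                 smoothMs / binMs))
    surr <- .gaussSmoothRows(surr, smoothMs / binMs)
  }
  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  qs <- apply(surr, 2, stats::quantile, probs = probs, names = FALSE)
  initialize(obs, ciLower = qs[1, ], ciUpper = qs[2, ])
}

#' Classify the supra-band features of a pair's cross-correlogram
#'
#' Finds maximal runs of at least \code{minRunBins} consecutive bins above
#' the upper confidence band (the run-length requirement is an implicit
#' multiple-comparison guard across the ~200 bins). Each run gets a
#' count-weighted mean lag (center) and a width measured as the full width
#' at half maximum (FWHM) of the excess above the band midline around the
#' run's peak bin -- unlike the raw run length, the FWHM of a peak does not
#' grow with its amplitude, so the narrow/broad boundary reflects peak
#' shape alone. Classification: a run containing lag 0 is narrow zero-lag
#' synchrony when narrower than \code{narrowMaxMs} (3 ms) and broad
#' synchrony otherwise; a run not containing 0, at most
#' \code{monoMaxWidthMs} (2 ms) wide with |center| in \code{monoCenterMs}
#' (1--4 ms), is putative monosynaptic excitation; anything else is left
#' unclassified.
#'
#' @param ccg \linkS4class{Correlogram} with confidence bands
#'   (\code{\link{jitterSurrogateCi}}).
#' @param unitA,unitB unit ids recorded in the result.
#' @param minRunBins minimal run length in bins.
#' @param narrowMaxMs narrow/broad width boundary, ms.
#' @param monoMaxWidthMs maximal width of a monosynaptic peak, ms.
#' @param monoCenterMs |center| range of a monosynaptic peak, ms.
#' @return a \linkS4class{PairResult}.
#' @export
classifyPair <- function(ccg, unitA = "a", unitB = "b", minRunBins = 2L,
                         narrowMaxMs = 3, monoMaxWidthMs = 2,
                         monoCenterMs = c(1, 4)) {
  if (!length(ccg@ciUpper)) .stopf("confidence bands are required")
  above <- ccg@counts > ccg@ciUpper
  base <- (ccg@ciLower + ccg@ciUpper) / 2   # ~ surrogate median per bin
  excess <- ccg@counts - base
  nb <- length(excess)
  rl <- rle(above)
  stops <- cumsum(rl$lengths)
  starts <- stops - rl$lengths + 1L
  feat <- list()
  for (k in which(rl$values & rl$lengths >= minRunBins)) {
    idx <- starts[k]:stops[k]
    pk <- idx[which.max(excess[idx])]
    half <- excess[pk] / 2
    lo <- pk; hi <- pk
    while (lo > 1L && excess[lo - 1L] >= half) lo <- lo - 1L
    while (hi < nb && excess[hi + 1L] >= half) hi <- hi + 1L
    width <- (hi - lo + 1L) * ccg@binMs
    center <- stats::weighted.mean(ccg@lags[idx], ccg@counts[idx])
    hasZero <- any(abs(ccg@lags[idx]) < 1e-9)
    cls <- if (hasZero) {
      if (width < narrowMaxMs) "narrow_sync" else "broad_sync"
    } else if (width <= monoMaxWidthMs &&
               abs(center) >= monoCenterMs[1] &&
               abs(center) <= monoCenterMs[2]) {
      "mono_excitation"
    } else "unclassified"
    feat[[length(feat) + 1L]] <- data.frame(
      run_start_ms = ccg@lags[idx[1]] - ccg@binMs / 2,
      run_end_ms = ccg@lags[idx[length(idx)]] + ccg@binMs / 2,
      width_ms = width, center_ms = center, class = cls,
      stringsAsFactors = FALSE)
  }
  features <- if (length(feat)) do.call(rbind, feat)
    else data.frame(run_start_ms = numeric(0), run_end_ms = numeric(0),
                    width_ms = numeric(0), center_ms = numeric(0),
                    class = character(0), stringsAsFactors = FALSE)
  new("PairResult", unitA = as.character(unitA), unitB = as.character(unitB),
      ccg = ccg, features = features,
      anySync = any(features$class %in% c("narrow_sync", "broad_sync")))
}

#' Classify one pair end-to-end
#'
#' Convenience wrapper: surrogate bands then feature classification.
#'
#' @param ref,target \linkS4class{SpikeTrain}s.
#' @param ... passed to \code{\link{jitterSurrogateCi}}.
#' @return a \linkS4class{PairResult}.
#' @export
analyzePair <- function(ref, target, ...) {
  ccg <- jitterSurrogateCi(ref, target, ...)
  classifyPair(ccg,
               unitA = if (is(ref, "SpikeTrain")) unitId(ref) else "a",
               unitB = if (is(target, "SpikeTrain")) unitId(target) else "b")
}

#' Build the assembly graph from classified pairs
#'
#' Synchrony edges come from pairs with a narrow or broad zero-lag feature;
#' assemblies are connected components (size >= 2) of the synchrony
#' subgraph; a unit is synchronous iff it has at least one synchrony edge.
#'
#' @param pairResults list of \linkS4class{PairResult}s from one session.
#' @param units character vector of all unit ids under consideration.
#' @return an \linkS4class{AssemblyGraph}.
#' @export
buildAssemblyGraph <- function(pairResults, units) {
  units <- as.character(units)
  edges <- do.call(rbind, c(list(
    data.frame(unit_a = character(0), unit_b = character(0),
               class = character(0), stringsAsFactors = FALSE)),
    lapply(pairResults, function(pr) {
      if (!nrow(pr@features)) return(NULL)
      cls <- pr@features$class[pr@features$class != "unclassified"]
      if (!length(cls)) return(NULL)
      data.frame(unit_a = pr@unitA, unit_b = pr@unitB, class = unique(cls),
                 stringsAsFactors = FALSE)
    })))
  syncEdges <- edges[edges$class %in% c("narrow_sync", "broad_sync"), ,
                     drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(units), name = units)
  if (nrow(syncEdges))
    g <- igraph::add_edges(g, rbind(match(syncEdges$unit_a, units),
                                    match(syncEdges$unit_b, units)))
  comp <- igraph::components(g)
  assemblies <- lapply(which(comp$csize >= 2),
                       function(k) units[comp$membership == k])
  deg <- igraph::degree(g)
  membership <- stats::setNames(
    ifelse(deg >= 1, "synchronous", "asynchronous"), units)
  new("AssemblyGraph", nodes = units, edges = edges,
      assemblies = assemblies, membership = membership)
}

#' Responsiveness of synchronous vs asynchronous units
#'
#' For each tested event, compares the responsive fraction among
#' synchronous units with that among asynchronous units by a 2x2
#' chi-square test (no continuity correction).
#'
#' @param membership named character vector
#'   ("synchronous"/"asynchronous"), e.g. from
#'   \code{\link{buildAssemblyGraph}}.
#' @param responses data.frame of \code{\link{testEventResponse}} rows for
#'   the same units.
#' @return data.frame: event_label, n_sync, n_sync_resp, n_async,
#'   n_async_resp, frac_sync, frac_async, chi2, p.
#' @export
compareSyncResponsiveness <- function(membership, responses) {
  if (!any(membership == "synchronous") ||
      !any(membership == "asynchronous"))
    .stopf("degenerate table: both membership groups must be non-empty")
  responses <- responses[responses$unit_id %in% names(membership), ]
  out <- lapply(unique(responses$event_label), function(e) {
    sub <- responses[responses$event_label == e, ]
    resp <- sub$direction != "none"
    sync <- membership[sub$unit_id] == "synchronous"
    cg <- compareGroupFractions(sum(resp & sync), sum(sync),
                                sum(resp & !sync), sum(!sync))
    data.frame(event_label = e, n_sync = sum(sync),
               n_sync_resp = sum(resp & sync), n_async = sum(!sync),
               n_async_resp = sum(resp & !sync),
               frac_sync = mean(resp[sync]), frac_async = mean(resp[!sync]),
               chi2 = cg$chi2, p = cg$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
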