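# Band definitions (lag ranges, ms) for rhythmicity analysis. Conventional
# frequency bands: beta 13-30 Hz, gamma 30-100 Hz.
.bandLagRange <- function(band) {
  switch(band,
    beta = c(1000 / 30, 1000 / 13),    # 33.3 - 76.9 ms
    gamma = c(10, 1000 / 30),          # 10 - 33.3 ms
    .stopf("unknown band '%s' (use 'beta' or 'gamma')", band))
}

.smoothedAcgCounts <- function(acg, smoothSdMs) {
  if (acg@kind != "auto") .stopf("an autocorrelogram is required")
  smoothCorrelogram(acg, smoothSdMs)@counts
}

#' Burst index of an autocorrelogram
#'
#' Contrast of the short-latency (1--10 ms) autocorrelogram peak against a
#' long-lag baseline (mean over 180--200 ms):
#' \deqn{BI = (P - B) / max(P, B)}
#' where \eqn{P} is the maximum smoothed count over 1--10 ms lags and
#' \eqn{B} the mean smoothed count over 180--200 ms. Bounded in [-1, 1],
#' scale-free (invariant to uniform count rescaling), 0 when the
#' autocorrelogram is empty. Positive values flag preferential short-ISI
#' (burst) firing.
#'
#' @param acg autocorrelogram with window >= 200 ms.
#' @param peakMs lag range of the burst peak, ms.
#' @param baselineMs lag range of the baseline, ms.
#' @param smoothSdMs Gaussian smoothing SD applied before taking peak and
#'   baseline, ms.
#' @return burst index, dimensionless in [-1, 1].
#' @export
burstIndex <- function(acg, peakMs = c(1, 10), baselineMs = c(180, 200),
                       smoothSdMs = 1) {
  if (acg@windowMs < baselineMs[2])
    .stopf("autocorrelogram window (%g ms) shorter than baseline end (%g ms)",
           acg@windowMs, baselineMs[2])
  sm <- .smoothedAcgCounts(acg, smoothSdMs)
  pk <- acg@lags >= peakMs[1] & acg@lags <= peakMs[2]
  bl <- acg@lags >= baselineMs[1] & acg@lags <= baselineMs[2]
  P <- max(sm[pk])
  B <- mean(sm[bl])
  if (max(P, B) == 0) return(0)
  (P - B) / max(P, B)
}

#' Classify a unit as bursting or non-bursting
#'
#' Units with fewer than 100 spikes are excluded from the classification;
#' otherwise the unit is bursting iff its burst index reaches
#' \code{biThreshold}. The default of 0.5 demands a short-lag peak at least
#' double the long-lag baseline: genuine burst firing drives the index
#' toward 0.9, while the mild short-lag elevation of a strongly
#' rate-modulated (e.g. rhythmic) unit stays near 0.3 and a Poisson unit
#' near 0.1.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param biThreshold burst-index threshold.
#' @param binMs,windowMs autocorrelogram parameters.
#' @param smoothSdMs smoothing SD for the index, ms.
#' @return list with \code{status} ("bursting", "non_bursting" or
#'   "excluded") and \code{burstIndex} (NA when excluded).
#' @export
classifyBursting <- function(spikes, biThreshold = 0.5, binMs = 1,
                             windowMs = 500, smoothSdMs = 1) {
  if (nSpikes(spikes) < 100L)
    return(list(status = "excluded", burstIndex = NA_real_))
  bi <- burstIndex(autocorrelogram(spikes, binMs, windowMs),
                   smoothSdMs = smoothSdMs)
  list(status = if (bi >= biThreshold) "bursting" else "non_bursting",
       burstIndex = bi)
}

#' Band rhythmicity index of an autocorrelogram
#'
#' In-band peak-to-trough contrast of the smoothed autocorrelogram:
#' \deqn{RI = (P - T) / max(P, T)}
#' with \eqn{P} and \eqn{T} the maximum and minimum smoothed count over the
#' band's lag range (beta: 33.3--76.9 ms, i.e. 13--30 Hz; gamma: 10--33.3
#' ms, i.e. 30--100 Hz). A flat autocorrelogram gives 0; a strong in-band
#' oscillation, whose correlogram swings between peak and trough within the
#' band, gives values approaching 1. Bounded in [-1, 1] and invariant to
#' uniform rescaling of the counts.
#'
#' @param acg autocorrelogram covering the band lag range.
#' @param band \code{"beta"} or \code{"gamma"}.
#' @param smoothSdMs smoothing SD, ms.
#' @return rhythmicity index, dimensionless.
#' @export
rhythmicityIndex <- function(acg, band = c("beta", "gamma"), smoothSdMs = 1) {
  band <- match.arg(band)
  rng <- .bandLagRange(band)
  if (acg@windowMs < rng[2])
    .stopf("autocorrelogram window too short for band '%s'", band)
  sm <- .smoothedAcgCounts(acg, smoothSdMs)
  inb <- acg@lags >= rng[1] & acg@lags <= rng[2]
  P <- max(sm[inb]); Tr <- min(sm[inb])
  if (max(P, Tr) == 0) return(0)
  (P - Tr) / max(P, Tr)
}

# Z-score of the in-band peak-to-trough swing against Poisson counting
# noise. Smoothing with kernel weights k scales the count variance by
# sum(k^2); a genuine oscillation must swing the smoothed ACG by several
# of those noise SDs, otherwise a low-rate unit's band extrema are just
# the tails of flat noise.
.bandSwingZ <- function(acg, rng, smoothSdMs) {
  sm <- .smoothedAcgCounts(acg, smoothSdMs)
  inb <- acg@lags >= rng[1] & acg@lags <= rng[2]
  P <- max(sm[inb]); Tr <- min(sm[inb])
  sdBins <- smoothSdMs / acg@binMs
  varFactor <- if (sdBins > 0) {
    h <- max(1L, ceiling(4 * sdBins))
    k <- exp(-(seq.int(-h, h))^2 / (2 * sdBins^2))
    k <- k / sum(k)
    sum(k^2)
  } else 1
  (P - Tr) / sqrt(varFactor * max(Tr, 1))
}

# Earliest prominent local maximum of the smoothed ACG in [lo, hi] ms.
# Prominence: at least halfway from the in-range minimum to the in-range
# maximum; boundary bins never qualify. Peak finding uses a wider kernel
# (>= 2 ms SD) than the indices: single-bin noise bumps on a rising flank
# must not masquerade as the fundamental. Returns the lag in ms, or NA when
# the range has no interior peak.
.firstRhythmPeakLag <- function(acg, lo, hi, smoothSdMs) {
  sm <- .smoothedAcgCounts(acg, max(smoothSdMs, 2))
  idx <- which(acg@lags >= lo & acg@lags <= hi)
  v <- sm[idx]
  if (length(v) < 3L || max(v) <= min(v)) return(NA_real_)
  thr <- min(v) + 0.5 * (max(v) - min(v))
  n <- length(v)
  interior <- 2:(n - 1)
  locmax <- interior[v[interior] >= v[interior - 1] &
                     v[interior] > v[interior + 1] & v[interior] >= thr]
  if (!length(locmax)) return(NA_real_)
  acg@lags[idx[locmax[1]]]
}

#' Estimate the rhythm frequency from the autocorrelogram peak location
#'
#' The frequency is the reciprocal of the lag of the first prominent
#' autocorrelogram peak within the band's lag range: \eqn{f = 1000 / lag}.
#' Using the earliest peak pins the fundamental rather than a harmonic
#' (an f Hz oscillation also produces peaks at 2/f, 3/f, ... seconds lag).
#' Requires a supra-threshold rhythmicity index in the band.
#'
#' @param acg autocorrelogram.
#' @param band \code{"beta"} or \code{"gamma"}.
#' @param riThreshold minimal rhythmicity index.
#' @param smoothSdMs smoothing SD, ms.
#' @return frequency in Hz.
#' @export
estimateRhythmFrequency <- function(acg, band = c("beta", "gamma"),
                                    riThreshold = 0.35, smoothSdMs = 1) {
  band <- match.arg(band)
  if (rhythmicityIndex(acg, band, smoothSdMs) < riThreshold)
    .stopf("no supra-threshold rhythmicity in band '%s'", band)
  rng <- .bandLagRange(band)
  lag <- .firstRhythmPeakLag(acg, rng[1], rng[2], smoothSdMs)
  if (is.na(lag) || lag <= 0)
    .stopf("no identifiable peak in band '%s'", band)
  1000 / lag
}

#' Full e-type profile of a unit
#'
#' Computes the burst index, both band rhythmicity indices, the bursting and
#' rhythmic labels, and (for rhythmic units) the rhythm band and frequency.
#' A unit is rhythmic when its larger band index reaches
#' \code{riThreshold}; the band is then assigned from the frequency of the
#' first prominent autocorrelogram peak in the combined 10--76.9 ms lag
#' range (beta when below 30 Hz, gamma at or above), so that harmonic peaks
#' in the slower band cannot steal a fast unit. Bursting and rhythmic
#' labels are independent: a unit may be both. Units with fewer than 100
#' spikes have \code{is_bursting = NA} (excluded).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param binMs,windowMs autocorrelogram parameters.
#' @param biThreshold bursting threshold on the burst index.
#' @param riThreshold rhythmicity threshold on the band indices.
#' @param smoothSdMs smoothing SD for all indices, ms.
#' @return one-row data.frame: unit_id, n_spikes, rate_hz, burst_index,
#'   is_bursting, beta_index, gamma_index, is_rhythmic, rhythm_band,
#'   rhythm_freq_hz, dv_um.
#' @export
classifyEtype <- function(spikes, binMs = 1, windowMs = 500,
                          biThreshold = 0.5, riThreshold = 0.35,
                          smoothSdMs = 1) {
  tt <- spikeTimes(spikes)
  n <- length(tt)
  rate <- if (n >= 2L) n / diff(range(tt)) else 0
  acg <- autocorrelogram(spikes, binMs, windowMs)
  bi <- burstIndex(acg, smoothSdMs = smoothSdMs)
  betaI <- rhythmicityIndex(acg, "beta", smoothSdMs)
  gammaI <- rhythmicityIndex(acg, "gamma", smoothSdMs)
  isRhythmic <- max(betaI, gammaI) >= riThreshold
  band <- "none"; freq <- NA_real_
  if (isRhythmic) {
    lag <- .firstRhythmPeakLag(acg, 10, 1000 / 13, smoothSdMs)
    if (is.na(lag)) {
      isRhythmic <- FALSE
    } else {
      freq <- 1000 / lag
      band <- if (freq < 30) "beta" else "gamma"
      # the in-band swing must clear Poisson counting noise (8 SD): for
      # low-rate or short recordings the band extrema of a flat ACG alone
      # can push the bounded index past the threshold
      if (.bandSwingZ(acg, .bandLagRange(band), smoothSdMs) < 8) {
        isRhythmic <- FALSE; band <- "none"; freq <- NA_real_
      }
    }
  }
  data.frame(unit_id = unitId(spikes), n_spikes = n, rate_hz = rate,
             burst_index = if (n >= 100L) bi else NA_real_,
             is_bursting = if (n >= 100L) bi >= biThreshold else NA,
             beta_index = betaI, gamma_index = gammaI,
             is_rhythmic = isRhythmic, rhythm_band = band,
             rhythm_freq_hz = freq, dv_um = dvPosition(spikes),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of a per-unit index with recording depth
#'
#' Units with missing depth are dropped; at least 3 complete pairs are
#' required.
#'
#' @param values per-unit index values.
#' @param dv per-unit dorsoventral positions, micrometers.
#' @return list with \code{r}, \code{p} (two-sided) and \code{n}.
#' @export
correlateIndexWithPosition <- function(values, dv) {
  keep <- !is.na(values) & !is.na(dv)
  if (sum(keep) < 3L)
    .stopf("insufficient data: need >= 3 units with index and position")
  ct <- stats::cor.test(values[keep], dv[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
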