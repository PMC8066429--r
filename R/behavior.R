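#' Lick PETH
#'
#' Peri-event time histogram of licking activity; identical to
#' \code{\link{computePeth}} applied to lick timestamps.
#'
#' @param licks numeric lick times, seconds.
#' @param events event timestamps, seconds.
#' @param window,binS,smoothSdS,eventLabel as in \code{\link{computePeth}}.
#' @return a \linkS4class{Peth}.
#' @export
lickPeth <- function(licks, events, window = c(-1, 2), binS = 0.05,
                     smoothSdS = 0, eventLabel = "licks") {
  computePeth(licks, events, window, binS, smoothSdS, eventLabel)
}

#' Anticipatory-lick discrimination test
#'
#' Per trial, licks are counted in the anticipatory window from cue onset
#' to reinforcement (virtual reinforcement, cue offset + 0.5 s, on omission
#' trials) and normalized by the window length, so each trial contributes
#' an anticipatory lick rate in Hz. Rates are compared across the two cue
#' types. Trials are unpaired across cues, so the default test is the
#' two-sided rank-sum (Mann-Whitney) test; \code{paired = TRUE} pairs
#' trials by within-cue order (session blocks) and applies the Wilcoxon
#' signed-rank test instead.
#'
#' @param licks numeric lick times, seconds.
#' @param trials trial table (see \linkS4class{Session}).
#' @param minTrials minimal trials per cue (default 5).
#' @param paired use the paired session-block mode.
#' @param subjectId identifier stored in the output.
#' @return one-row data.frame: subject_id, n_trials_reward_cue,
#'   n_trials_punish_cue, lick_rate_reward_cue, lick_rate_punish_cue
#'   (Hz over the anticipatory window), discrimination_delta (Hz),
#'   p_discrimination (NA when degenerate, e.g. no licks at all).
#' @export
anticipatoryLickTest <- function(licks, trials, minTrials = 5,
                                 paired = FALSE, subjectId = "") {
  licks <- as.numeric(licks)
  reinf <- virtualReinforcementTimes(trials)
  len <- reinf - trials$t_cue_on_s
  stopifnot(all(len > 0))
  nLick <- .nBefore(reinf, licks) - .nBefore(trials$t_cue_on_s, licks)
  rate <- nLick / len
  isR <- trials$cue == "likely_reward"
  rr <- rate[isR]; rp <- rate[!isR]
  if (length(rr) < minTrials || length(rp) < minTrials)
    .stopf("insufficient data: need >= %d trials per cue", minTrials)
  delta <- mean(rr) - mean(rp)
  if (all(c(rr, rp) == c(rr, rp)[1])) {
    p <- NA_real_
  } else if (paired) {
    k <- min(length(rr), length(rp))
    p <- suppressWarnings(stats::wilcox.test(rr[seq_len(k)], rp[seq_len(k)],
                                             paired = TRUE,
                                             exact = FALSE)$p.value)
  } else {
    p <- suppressWarnings(stats::wilcox.test(rr, rp, exact = FALSE)$p.value)
  }
  data.frame(subject_id = subjectId, n_trials_reward_cue = length(rr),
             n_trials_punish_cue = length(rp),
             lick_rate_reward_cue = mean(rr),
             lick_rate_punish_cue = mean(rp),
             discrimination_delta = delta, p_discrimination = p,
             stringsAsFactors = FALSE)
}

#' Correlate behavioral discrimination with neural responsiveness
#'
#' Spearman rank correlation between per-subject anticipatory lick-rate
#' differences and per-subject responsive-unit fractions.
#'
#' @param delta per-subject discrimination deltas (Hz).
#' @param fraction per-subject responsive fractions.
#' @return list with \code{rho}, \code{p} and \code{n}. When either input
#'   is constant the correlation is undefined: \code{rho} and \code{p} are
#'   NA with a warning.
#' @export
correlateDiscriminationWithResponsiveness <- function(delta, fraction) {
  keep <- !is.na(delta) & !is.na(fraction)
  if (sum(keep) < 3L)
    .stopf("insufficient data: need >= 3 subjects")
  d <- delta[keep]; f <- fraction[keep]
  if (stats::sd(d) == 0 || stats::sd(f) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = sum(keep)))
  }
  ct <- suppressWarnings(stats::cor.test(d, f, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
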