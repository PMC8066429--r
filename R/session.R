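#' Read a session bundle from disk
#'
#' A bundle directory holds \code{spikes.csv} (unit_id, time_s),
#' \code{trials.csv}, \code{licks.csv} (time_s), \code{units.csv}
#' (unit_id, dv_um) and \code{meta.json}. All tables are UTF-8 CSV with one
#' header row; enum columns use the lower-case strings documented in
#' \linkS4class{Session}. The returned session has been validated; any
#' invariant violation is an error naming the offending entity.
#'
#' @param path bundle directory.
#' @return a validated \linkS4class{Session}.
#' @seealso \code{\link{writeSessionBundle}}, \code{\link{validateSession}}
#' @export
readSessionBundle <- function(path) {
  need <- c("spikes.csv", "trials.csv", "licks.csv", "units.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    .stopf("format error: bundle at '%s' is missing %s", path,
           paste(missing, collapse = ", "))
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c(unit_id = "character",
                                           time_s = "numeric"))
  trialsDf <- utils::read.csv(file.path(path, "trials.csv"),
                              colClasses = c(trial_id = "integer",
                                             cue = "character",
                                             outcome = "character",
                                             t_cue_on_s = "numeric",
                                             t_cue_off_s = "numeric",
                                             t_reinforcement_s = "numeric"))
  lickDf <- utils::read.csv(file.path(path, "licks.csv"),
                            colClasses = c(time_s = "numeric"))
  unitsDf <- utils::read.csv(file.path(path, "units.csv"),
                             colClasses = c(unit_id = "character",
                                            dv_um = "numeric"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sid <- if (!is.null(meta$subject)) as.character(meta$subject) else ""
  sts <- lapply(seq_len(nrow(unitsDf)), function(i) {
    uid <- unitsDf$unit_id[i]
    tt <- spikes$time_s[spikes$unit_id == uid]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      .stopf("validation error: unit '%s' has unsorted or duplicate spike times",
             uid)
    SpikeTrain(tt, unitId = uid, dvPosition = unitsDf$dv_um[i],
               sessionId = sid)
  })
  orphan <- setdiff(unique(spikes$unit_id), unitsDf$unit_id)
  if (length(orphan))
    .stopf("format error: spikes reference unknown unit(s): %s",
           paste(orphan, collapse = ", "))
  sess <- Session(spikeTrains = sts, trials = trialsDf,
                  licks = lickDf$time_s, meta = as.list(meta))
  v <- validateSession(sess)
  if (nrow(v))
    .stopf("validation error: %s", paste(v$entity, v$rule, sep = ": ",
                                         collapse = "; "))
  sess
}

#' Write a session bundle to disk
#'
#' Inverse of \code{\link{readSessionBundle}}. Timestamps are written with
#' 0.1 microsecond precision, so a write/read round trip reproduces the
#' session to well under 1 microsecond.
#'
#' @param session a \linkS4class{Session}.
#' @param path directory to create/write into.
#' @return invisibly, the bundle path.
#' @export
writeSessionBundle <- function(session, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || !dir.exists(path)) .stopf("I/O error: cannot write to '%s'", path)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.7f", x))
  sts <- session@spikeTrains
  spikes <- data.frame(
    unit_id = rep(vapply(sts, unitId, ""),
                  vapply(sts, nSpikes, 0L)),
    time_s = fmt(unlist(lapply(sts, spikeTimes))),
    stringsAsFactors = FALSE)
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- session@trials
  trOut <- data.frame(trial_id = tr$trial_id, cue = tr$cue,
                      outcome = tr$outcome,
                      t_cue_on_s = fmt(tr$t_cue_on_s),
                      t_cue_off_s = fmt(tr$t_cue_off_s),
                      t_reinforcement_s = fmt(tr$t_reinforcement_s),
                      stringsAsFactors = FALSE)
  utils::write.csv(trOut, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(time_s = fmt(session@licks)),
                   file.path(path, "licks.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(unit_id = vapply(sts, unitId, ""),
                              dv_um = fmt(vapply(sts, dvPosition, 0))),
                   file.path(path, "units.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(session@meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Validate a session against its type invariants
#'
#' Checks every documented invariant (sorted non-negative spike and lick
#' times, trial-table consistency, the omission/reinforcement rule, trial
#' ordering and non-overlap, unique unit ids). Violations are returned as
#' data, one row per violation naming the entity and the broken rule; an
#' empty result means the session is valid.
#'
#' For synthetic sessions (\code{meta$synthetic} is TRUE) the
#' reinforcement delay is additionally required to fall in the generator's
#' 400--600 ms window after cue offset.
#'
#' @param session a \linkS4class{Session}.
#' @return data.frame with columns \code{entity} and \code{rule}; zero rows
#'   when the session is valid.
#' @export
validateSession <- function(session) {
  out <- list()
  bad <- function(entity, rule)
    out[[length(out) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                           stringsAsFactors = FALSE)
  ids <- vapply(session@spikeTrains, unitId, "")
  if (anyDuplicated(ids))
    bad("session", "unit ids must be unique")
  for (st in session@spikeTrains) {
    tt <- spikeTimes(st)
    if (length(tt) && any(tt < 0))
      bad(unitId(st), "spike times must be >= 0")
    if (length(tt) > 1L && any(diff(tt) <= 0))
      bad(unitId(st), "spike times must be strictly increasing")
  }
  lk <- session@licks
  if (length(lk) > 1L && any(diff(lk) <= 0))
    bad("licks", "lick times must be strictly increasing")
  tr <- session@trials
  synth <- isTRUE(session@meta$synthetic)
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      id <- sprintf("trial %s", tr$trial_id[i])
      if (!tr$cue[i] %in% c("likely_reward", "likely_punishment"))
        bad(id, "unknown cue")
      if (!tr$outcome[i] %in% c("reward", "punishment", "omission"))
        bad(id, "unknown outcome")
      if (!(tr$t_cue_on_s[i] < tr$t_cue_off_s[i]))
        bad(id, "t_cue_on must precede t_cue_off")
      if (tr$outcome[i] == "omission") {
        if (!is.na(tr$t_reinforcement_s[i]))
          bad(id, "omission trial must not carry a reinforcement time")
      } else {
        if (is.na(tr$t_reinforcement_s[i]))
          bad(id, "non-omission trial must carry a reinforcement time")
        else {
          if (tr$t_reinforcement_s[i] <= tr$t_cue_off_s[i])
            bad(id, "reinforcement must follow cue offset")
          else if (synth) {
            d <- tr$t_reinforcement_s[i] - tr$t_cue_off_s[i]
            if (d < 0.4 - 1e-9 || d > 0.6 + 1e-9)
              bad(id, "reinforcement delay outside 400-600 ms")
          }
        }
      }
    }
    ends <- pmax(tr$t_cue_off_s, tr$t_reinforcement_s, na.rm = TRUE)
    if (nrow(tr) > 1L) {
      for (i in seq_len(nrow(tr) - 1L)) for (j in (i + 1L):nrow(tr)) {
        if (tr$t_cue_on_s[j] < ends[i] && tr$t_cue_on_s[i] < ends[j])
          bad(sprintf("trials %s/%s", tr$trial_id[i], tr$trial_id[j]),
              "trials must not overlap")
      }
      if (any(diff(tr$t_cue_on_s) <= 0))
        bad("trials", "trials must be time-ordered")
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(entity = character(0), rule = character(0),
                  stringsAsFactors = FALSE)
}

#' Reinforcement times with virtual omission events
#'
#' For reward/punishment trials returns the recorded reinforcement time; for
#' omission trials returns cue offset + 0.5 s, the midpoint of the 400--600
#' ms reinforcement delay, as a "virtual reinforcement" for omission-response
#' analyses.
#'
#' @param trials trial table (see \linkS4class{Session}).
#' @return numeric vector, one time per trial.
#' @export
virtualReinforcementTimes <- function(trials) {
  ifelse(is.na(trials$t_reinforcement_s), trials$t_cue_off_s + 0.5,
         trials$t_reinforcement_s)
}

#' Event times of a labeled task event
#'
#' Maps the canonical event labels onto a trial table: cue onsets split by
#' cue identity, reinforcement times split by outcome, and virtual omission
#' events (cue offset + 0.5 s on omission trials).
#'
#' @param trials trial table.
#' @param label one of \code{"cue_reward"}, \code{"cue_punish"},
#'   \code{"reward"}, \code{"punishment"}, \code{"omission_virtual"}.
#' @return numeric vector of event times, seconds.
#' @export
eventTimes <- function(trials, label) {
  switch(label,
    cue_reward = trials$t_cue_on_s[trials$cue == "likely_reward"],
    cue_punish = trials$t_cue_on_s[trials$cue == "likely_punishment"],
    reward = trials$t_reinforcement_s[trials$outcome == "reward"],
    punishment = trials$t_reinforcement_s[trials$outcome == "punishment"],
    omission_virtual =
      trials$t_cue_off_s[trials$outcome == "omission"] + 0.5,
    .stopf("unknown event label '%s'", label))
}
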