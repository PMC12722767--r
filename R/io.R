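# Long-format observation table I/O (CSV/TSV via data.table).

#' Write / read a cohort as long-format observation + statics tables
#'
#' Observations: columns `patientid`, `datetime` (minutes since cohort
#' origin), `variableid`, `value`. Statics: one row per stay with
#' admission/discharge times, demographics and flags. The cohort origin is
#' stored as an ISO timestamp column on the statics table.
#'
#' @param stays List of [stay_record]s.
#' @param obs_path,statics_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(stays, obs_path, statics_path) {
  obs <- data.table::rbindlist(lapply(stays, function(s) {
    data.table::rbindlist(lapply(names(s$observations), function(v) {
      o <- s$observations[[v]]
      data.table::data.table(patientid = s$patient_id, datetime = o$time,
                             variableid = v, value = o$value)
    }))
  }))
  st <- data.table::rbindlist(lapply(stays, function(s) {
    data.table::data.table(
      patientid = s$patient_id, admission = s$admission_time,
      discharge = s$discharge_time, age = s$statics$age, sex = s$statics$sex,
      height = s$statics$height, apache_group = s$statics$apache_group,
      emergency = s$statics$emergency, surgical = s$statics$surgical,
      elective = s$statics$elective, era_pre2009 = s$statics$era_pre2009,
      era_pre2010 = s$statics$era_pre2010, death = s$death_time,
      origin = if (!is.null(s$origin)) format(s$origin, "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC") else NA_character_)
  }))
  data.table::fwrite(obs, obs_path)
  data.table::fwrite(st, statics_path)
  invisible(c(obs_path, statics_path))
}

#' @rdname write_cohort_csv
#' @return `read_cohort_csv()`: a list of [stay_record]s.
#' @export
read_cohort_csv <- function(obs_path, statics_path) {
  obs <- data.table::fread(obs_path)
  st <- data.table::fread(statics_path)
  lapply(seq_len(nrow(st)), function(i) {
    r <- st[i]
    po <- obs[obs$patientid == r$patientid]
    po <- po[order(po$datetime)]
    observations <- lapply(split(po, po$variableid), function(d) {
      data.frame(time = d$datetime, value = d$value)
    })
    stay_record(
      patient_id = r$patientid, admission_time = r$admission,
      discharge_time = r$discharge, observations = observations,
      age = r$age, sex = r$sex, height = r$height,
      apache_group = r$apache_group, emergency = isTRUE(r$emergency),
      surgical = isTRUE(r$surgical), elective = isTRUE(r$elective),
      era_pre2009 = isTRUE(r$era_pre2009), era_pre2010 = isTRUE(r$era_pre2010),
      death_time = if (is.na(r$death)) NA_real_ else r$death,
      origin = if (!is.na(r$origin)) as.POSIXct(r$origin, tz = "UTC",
                                                format = "%Y-%m-%dT%H:%M:%SZ")
               else NULL)
  })
}

#' Export endpoint events as a BED-like interval table
#'
#' @param events Named list (by stay) of event data.frames with `start`,
#'   `end` and optionally `severity`.
#' @param path Output TSV path.
#' @export
write_events_bed <- function(events, path) {
  dt <- data.table::rbindlist(lapply(names(events), function(id) {
    ev <- events[[id]]
    if (!nrow(ev)) return(NULL)
    data.table::data.table(stay = id, start_bin = ev$start, end_bin = ev$end,
                           status = if ("severity" %in% names(ev))
                             ev$severity else "event")
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
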