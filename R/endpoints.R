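# Rule-based endpoint annotation: hypoxemic respiratory failure severity,
# mechanical ventilation status, readiness to extubate.

RF_THRESHOLDS <- c(severe = 100, moderate = 200, mild = 300)
RF_WINDOW_BINS <- 12L    # forward-facing 1 h
RF_SANDWICH_BINS <- 48L  # 4 h
VENT_SCORE_CUTOFF <- 4L
REXT_WINDOW_BINS <- 12L  # trailing 1 h
REXT_CUTOFF <- 9L

# run-length intervals of a vector: data.frame(start, end, value) with
# half-open 1-based [start, end] inclusive bins
status_runs <- function(x) {
  r <- rle(as.vector(x))
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Annotate respiratory-failure severity
#'
#' Per grid point a forward-facing 1-h window (12 bins) is scanned. The bin
#' is labeled `severe` if at least two thirds of the window bins have an
#' estimated P/F ratio below 100 mmHg, else `moderate` below 200, else
#' `mild` below 300, else `stable`; `unknown` when two thirds of the window
#' have no P/F estimate. A window bin only qualifies for a severity count if
#' the patient is in a consistent ventilation state there: not ventilated,
#' or ventilated with PEEP not densely available, or ventilated with dense
#' PEEP >= 4 cmH2O. Two-thirds thresholds use `ceil(2/3 * window length)`
#' with windows truncated at the end of stay. Alternative P/F cutoffs (e.g.
#' the 150-mmHg sensitivity configuration or an S/F-ratio input) are
#' supported via `thresholds`.
#'
#' @param pf Estimated (dense) P/F track, `NA` where no estimate exists.
#' @param vent Logical ventilation track.
#' @param peep Dense PEEP track.
#' @param peep_avail Logical; `TRUE` where the dense PEEP value is backed by
#'   a real measurement (forward fill), `FALSE` where it is a normal-value
#'   placeholder.
#' @param thresholds Named severity cutoffs, default `c(severe = 100,
#'   moderate = 200, mild = 300)`.
#' @return Character track with levels stable/mild/moderate/severe/unknown.
#' @export
annotate_rf <- function(pf, vent, peep = NULL, peep_avail = NULL,
                        thresholds = RF_THRESHOLDS) {
  n <- length(pf)
  if (is.null(peep)) peep <- rep(NA_real_, n)
  if (is.null(peep_avail)) peep_avail <- rep(FALSE, n)
  consistent <- !vent | (vent & (!peep_avail | (!is.na(peep) & peep >= 4)))
  qual <- function(thr) !is.na(pf) & pf < thr & consistent
  ind <- cbind(sev = qual(thresholds[["severe"]]),
               mod = qual(thresholds[["moderate"]]),
               mild = qual(thresholds[["mild"]]),
               na = is.na(pf))
  cs <- rbind(0, apply(ind, 2, cumsum))
  out <- character(n)
  for (t in seq_len(n)) {
    hi <- min(n, t + RF_WINDOW_BINS - 1L)
    len <- hi - t + 1L
    need <- ceiling(2 / 3 * len)
    cnt <- cs[hi + 1L, ] - cs[t, ]
    out[t] <- if (cnt[["na"]] >= need) "unknown"
      else if (cnt[["sev"]] >= need) "severe"
      else if (cnt[["mod"]] >= need) "moderate"
      else if (cnt[["mild"]] >= need) "mild"
      else "stable"
  }
  out
}

#' Right-edge correction of respiratory-failure events
#'
#' The forward-facing window mislabels the right boundary of events. For
#' each failure event, bins immediately after its tentative right edge whose
#' instantaneous P/F ratio still satisfies the event's severity criterion
#' are relabeled to that severity; the scan stops at the first
#' non-satisfying bin and never crosses a bin with missing P/F.
#'
#' @param rf_status Tentative status track from [annotate_rf()].
#' @param pf The same P/F track.
#' @param thresholds As in [annotate_rf()].
#' @return Corrected status track.
#' @export
correct_right_edges <- function(rf_status, pf, thresholds = RF_THRESHOLDS) {
  n <- length(rf_status)
  runs <- status_runs(rf_status)
  for (i in seq_len(nrow(runs))) {
    sev <- runs$value[i]
    if (!sev %in% names(thresholds)) next
    thr <- thresholds[[sev]]
    t <- runs$end[i] + 1L
    while (t <= n && !is.na(pf[t]) && pf[t] < thr &&
           !rf_status[t] %in% names(thresholds)) {
      rf_status[t] <- sev
      t <- t + 1L
    }
  }
  rf_status
}

#' Sandwich post-processing of the respiratory-failure track
#'
#' A run of at most 4 h sandwiched between two runs of equal status, at
#' least one of which is longer than the sandwiched run, is relabeled to the
#' surrounding status. This single symmetric rule both deletes spuriously
#' short failure events (a short event between two stable runs) and merges
#' short gaps between failure events. Applied to a fixpoint; idempotent.
#'
#' @param rf_status Edge-corrected status track.
#' @return Post-processed status track.
#' @export
postprocess_rf <- function(rf_status) {
  repeat {
    runs <- status_runs(rf_status)
    changed <- FALSE
    if (nrow(runs) >= 3) {
      for (i in 2:(nrow(runs) - 1L)) {
        if (runs$length[i] <= RF_SANDWICH_BINS &&
            runs$value[i - 1L] == runs$value[i + 1L] &&
            max(runs$length[i - 1L], runs$length[i + 1L]) > runs$length[i]) {
          rf_status[runs$start[i]:runs$end[i]] <- runs$value[i - 1L]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(rf_status)
  }
}

#' Extract failure events from a status track
#'
#' Maximal runs of the given statuses as `[start, end]` bin intervals.
#'
#' @param rf_status Status track.
#' @param statuses Which statuses form an event (default moderate/severe,
#'   the prediction-task definition).
#' @return data.frame with columns `start`, `end`, `severity` (the most
#'   severe status in the run).
#' @export
rf_events <- function(rf_status, statuses = c("moderate", "severe")) {
  ev <- status_runs(rf_status %in% statuses)
  ev <- ev[ev$value, c("start", "end"), drop = FALSE]
  if (nrow(ev)) {
    ev$severity <- vapply(seq_len(nrow(ev)), function(i) {
      s <- rf_status[ev$start[i]:ev$end[i]]
      if ("severe" %in% s) "severe" else if ("moderate" %in% s) "moderate"
      else "mild"
    }, "")
  } else ev$severity <- character(0)
  rownames(ev) <- NULL
  ev
}

#' Ventilation-presence voting score
#'
#' Point-based vote evaluated per grid point: +1 for the pre-2009-12-06
#' recording era, +2 when at least one EtCO2 measurement above 0.5 mmHg
#' falls in a centered 30-min window, +1 for ventilator mode 2
#' (controlled) or 3 (spontaneous), -1 for mode 1 (standby), -2 for modes 4
#' (NIV) / 5 (high flow) / 6 (CPAP), +1 for tidal volume > 0 mL, +2 for an
#' intubation/tracheostomy indicator, -1 for a non-invasive airway (mask,
#' helmet, mouthpiece, nasal interface). A grid point is ventilated when the
#' combined score is at least 4. Unknown mode codes contribute 0.
#'
#' @param era_pre2009 Logical scalar or track.
#' @param etco2_window Logical track: EtCO2 > 0.5 observed within +-15 min.
#' @param mode Current ventilator mode code (1-6), `NA` if unknown.
#' @param tv Current tidal volume (mL), `NA` allowed.
#' @param invasive_airway Logical track: intubated or tracheostomy.
#' @param noninvasive_airway Logical track: mask/helmet/mouthpiece/nasal.
#' @return List with integer `score` and logical `vent` tracks.
#' @export
vote_ventilation <- function(era_pre2009, etco2_window, mode, tv,
                             invasive_airway, noninvasive_airway) {
  score <- rep(0L, length(etco2_window)) +
    1L * (rep_len(era_pre2009, length(etco2_window))) +
    2L * etco2_window +
    1L * (!is.na(mode) & mode %in% c(2, 3)) -
    1L * (!is.na(mode) & mode == 1) -
    2L * (!is.na(mode) & mode %in% c(4, 5, 6)) +
    1L * (!is.na(tv) & tv > 0) +
    2L * invasive_airway -
    1L * noninvasive_airway
  list(score = as.integer(score), vent = score >= VENT_SCORE_CUTOFF)
}

#' Post-process the voted ventilation track
#'
#' In order: (1) gaps between ventilation episodes during which the patient
#' was likely off-unit (fewer than 50% of gap bins have a heart-rate
#' observation within 10 min) are closed; (2) gaps shorter than 15 min are
#' closed; (3) gaps shorter than 24 h flanked by tracheostomy indicators are
#' closed (normal tracheostomy weaning); (4) ventilation events shorter than
#' 45 min are deleted unless they occur at the very beginning of the stay
#' (no heart-rate observation before the event).
#'
#' @param vent Logical voted track.
#' @param hr_near Logical track: >= 1 raw HR observation within 10 min of
#'   the bin start.
#' @param trach_active Logical tracheostomy-indicator track.
#' @param hr_before Logical track: >= 1 raw HR observation strictly before
#'   the bin start.
#' @return Post-processed logical track; idempotent.
#' @export
postprocess_ventilation <- function(vent, hr_near, trach_active, hr_before) {
  n <- length(vent)
  close_gaps <- function(vent, cond) {
    runs <- status_runs(vent)
    if (nrow(runs) >= 3) {
      for (i in 2:(nrow(runs) - 1L)) {
        if (!runs$value[i] && runs$value[i - 1L] && runs$value[i + 1L] &&
            cond(runs$start[i], runs$end[i], runs$length[i])) {
          vent[runs$start[i]:runs$end[i]] <- TRUE
        }
      }
    }
    vent
  }
  # (1) off-unit gaps
  vent <- close_gaps(vent, function(s, e, len)
    mean(hr_near[s:e]) < 0.5)
  # (2) micro-gaps < 15 min
  vent <- close_gaps(vent, function(s, e, len) len * GRID_STEP_MIN < 15)
  # (3) tracheostomy weaning gaps < 24 h
  vent <- close_gaps(vent, function(s, e, len)
    len * GRID_STEP_MIN < 24 * 60 &&
      trach_active[max(1L, s - 1L)] && trach_active[min(n, e + 1L)])
  # (4) spurious short events
  runs <- status_runs(vent)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] && runs$length[i] * GRID_STEP_MIN < 45 &&
        hr_before[runs$start[i]]) {
      vent[runs$start[i]:runs$end[i]] <- FALSE
    }
  }
  vent
}

#' Readiness-to-extubate violation score
#'
#' Counts violations of commonly accepted extubation criteria at a
#' (ventilated) grid point: ventilator mode not spontaneous (code 3) -> +9
#' (skipped for pre-2010 data where mode recording was unreliable);
#' PEEP > 7 -> +3; pressure support > 10 -> +3; FIO2 > 0.4 -> +3;
#' RSBI = 1000 * RR / TV >= 105 -> +3; RR >= 35 -> +3; minute volume >= 10
#' -> +3; P/F <= 150 -> +3; PaCO2 >= 50 -> +3; GCS <= 8 -> +1; MAP <= 60 ->
#' +1; norepinephrine > 0.05 ug/kg/h or any inotrope -> +1; lactate >= 2.5
#' -> +1. Missing inputs contribute 0.
#'
#' @param state List (or data.frame) of current dense tracks: `mode`,
#'   `peep`, `pressure_support`, `fio2`, `rr`, `tv`, `minute_volume`, `pf`,
#'   `paco2`, `gcs`, `map`, `norepinephrine`, `inotrope`, `lactate`.
#' @param era_pre2010 Logical scalar.
#' @return Integer violation-score track.
#' @export
rext_violation_score <- function(state, era_pre2010 = FALSE) {
  v <- function(x) if (is.null(x)) NA_real_ else x
  chk <- function(x, cond) !is.na(x) & cond
  mode <- v(state$mode)
  rsbi <- 1000 * v(state$rr) / v(state$tv)
  score <- 0L +
    (if (era_pre2010) 0L else 9L * chk(mode, mode != 3)) +
    3L * chk(v(state$peep), v(state$peep) > 7) +
    3L * chk(v(state$pressure_support), v(state$pressure_support) > 10) +
    3L * chk(v(state$fio2), v(state$fio2) > 0.4) +
    3L * chk(rsbi, rsbi >= 105) +
    3L * chk(v(state$rr), v(state$rr) >= 35) +
    3L * chk(v(state$minute_volume), v(state$minute_volume) >= 10) +
    3L * chk(v(state$pf), v(state$pf) <= 150) +
    3L * chk(v(state$paco2), v(state$paco2) >= 50) +
    1L * chk(v(state$gcs), v(state$gcs) <= 8) +
    1L * (chk(v(state$norepinephrine), v(state$norepinephrine) > 0.05) |
            chk(v(state$inotrope), v(state$inotrope) > 0)) +
    1L * chk(v(state$map), v(state$map) <= 60) +
    1L * chk(v(state$lactate), v(state$lactate) >= 2.5)
  as.integer(score)
}

#' Readiness-to-extubate track
#'
#' A ventilated grid point is ready to extubate when at least two thirds of
#' the bins in the trailing 1-h window (12 bins, inclusive of the current
#' one) are ventilated with a violation score below 9. The window count
#' threshold is fixed at 8 of 12, and a full trailing hour of track must
#' exist: the first 11 bins of a stay are never ready (conservative
#' start-up, so a fully passing run turns ready at its 12th bin when the
#' stay begins ventilated).
#'
#' @param scores Violation-score track (defined on ventilated bins).
#' @param vent Logical ventilation track.
#' @return Logical readiness track.
#' @export
annotate_rext <- function(scores, vent) {
  n <- length(scores)
  pass <- as.numeric(vent & !is.na(scores) & scores < REXT_CUTOFF)
  cp <- c(0, cumsum(pass))
  out <- logical(n)
  for (t in seq_len(n)) {
    if (t < REXT_WINDOW_BINS) next
    lo <- t - REXT_WINDOW_BINS + 1L
    out[t] <- vent[t] && (cp[t + 1L] - cp[lo]) >= ceiling(2 / 3 * REXT_WINDOW_BINS)
  }
  out
}

#' Full endpoint annotation of one stay
#'
#' Convenience wrapper running, in order: ventilation voting +
#' post-processing (no FIO2 dependency), FIO2 estimation, PaO2 estimation,
#' P/F smoothing, respiratory-failure annotation with right-edge correction
#' and sandwich post-processing, and readiness-to-extubate scoring.
#'
#' @param grid_raw Raw `gridded_stay` from [build_grid()].
#' @param grid_dense Dense-imputed copy from [impute_grid()].
#' @param pao2_estimator Optional `pao2_estimator` (Ellis fallback if
#'   `NULL`).
#' @param schema,stats Schema and training statistics.
#' @param rf_thresholds Severity cutoffs for [annotate_rf()].
#' @return List of tracks: `vent`, `vent_score`, `fio2_est`, `pao2_est`,
#'   `pao2_source`, `pf`, `rf_status`, `rext`, `rext_score`, and event
#'   tables `rf_events`, `vent_events`.
#' @export
annotate_endpoints <- function(grid_raw, grid_dense, pao2_estimator = NULL,
                               schema = default_schema(), stats = NULL,
                               rf_thresholds = RF_THRESHOLDS) {
  n <- grid_raw$n_steps
  # EtCO2 > 0.5 within centered 30-min window
  et_meas <- grid_raw$measured$etco2 == 1L & !is.na(grid_raw$values$etco2) &
    grid_raw$values$etco2 > 0.5
  cw <- c(0, cumsum(as.numeric(et_meas)))
  et_win <- vapply(seq_len(n), function(t) {
    lo <- max(1L, t - 3L); hi <- min(n, t + 3L)
    (cw[hi + 1L] - cw[lo]) > 0
  }, TRUE)
  mode_now <- grid_dense$values$vent_mode
  mode_now[grid_raw$tsm$vent_mode < 0] <- NA  # never measured -> unknown
  beyond <- grid_raw$tsm$vent_mode > ffill_horizon_minutes(schema$vent_mode, stats)
  mode_now[beyond] <- NA
  tv_now <- grid_dense$values$tv
  tv_now[grid_raw$tsm$tv < 0] <- NA
  invasive <- (grid_dense$values$trach > 0 & grid_raw$tsm$trach >= 0) |
    (grid_dense$values$intub > 0 & grid_raw$tsm$intub >= 0) |
    (grid_raw$tsm$airway >= 0 & grid_dense$values$airway %in% AIRWAY_INVASIVE)
  noninv <- grid_raw$tsm$airway >= 0 &
    grid_dense$values$airway %in% AIRWAY_NONINVASIVE
  vote <- vote_ventilation(isTRUE(grid_raw$statics$era_pre2009), et_win,
                           mode_now, tv_now, invasive, noninv)
  hr_times <- grid_raw$raw_obs_times$hr
  bin_starts <- grid_raw$grid_start + GRID_STEP_MIN * (seq_len(n) - 1)
  hr_near <- near_observation(bin_starts, hr_times, 10)
  hr_before <- findInterval(bin_starts - 1e-9, hr_times) >= 1
  trach_active <- grid_dense$values$trach > 0 & grid_raw$tsm$trach >= 0
  vent <- postprocess_ventilation(vote$vent, hr_near, trach_active, hr_before)

  fio2_est <- estimate_fio2_track(grid_raw, vent)
  pa <- estimate_pao2_track(grid_raw, pao2_estimator, schema, stats)
  pf <- pf_track(pa$pao2_est, fio2_est)
  peep_avail <- grid_raw$tsm$peep >= 0 &
    grid_raw$tsm$peep <= ffill_horizon_minutes(schema$peep, stats)
  rf <- annotate_rf(pf, vent, grid_dense$values$peep, peep_avail,
                    rf_thresholds)
  rf <- correct_right_edges(rf, pf, rf_thresholds)
  rf <- postprocess_rf(rf)

  rext_sc <- rext_violation_score(list(
    mode = mode_now, peep = grid_dense$values$peep,
    pressure_support = grid_dense$values$pressure_support, fio2 = fio2_est,
    rr = grid_dense$values$rr, tv = grid_dense$values$tv,
    minute_volume = grid_dense$values$minute_volume, pf = pf,
    paco2 = grid_dense$values$paco2, gcs = grid_dense$values$gcs,
    map = grid_dense$values$map,
    norepinephrine = grid_dense$values$norepinephrine,
    inotrope = grid_dense$values$inotrope,
    lactate = grid_dense$values$lactate
  ), era_pre2010 = isTRUE(grid_raw$statics$era_pre2010))
  rext <- annotate_rext(rext_sc, vent)

  vr <- status_runs(vent)
  vent_events <- vr[vr$value, c("start", "end"), drop = FALSE]
  rownames(vent_events) <- NULL
  list(vent = vent, vent_score = vote$score, fio2_est = fio2_est,
       pao2_est = pa$pao2_est, pao2_source = pa$source, pf = pf,
       rf_status = rf, rext = rext, rext_score = rext_sc,
       rf_events = rf_events(rf), vent_events = vent_events,
       hr_near = hr_near, hr_before = hr_before, trach_active = trach_active,
       vent_mode_now = mode_now)
}

# TRUE where any observation time lies within +-tol minutes of each anchor
near_observation <- function(anchors, obs_times, tol) {
  if (is.null(obs_times) || length(obs_times) == 0) {
    return(rep(FALSE, length(anchors)))
  }
  i <- findInterval(anchors, obs_times)
  prev_ok <- i >= 1 & (anchors - obs_times[pmax(i, 1)]) <= tol
  nxt <- pmin(i + 1, length(obs_times))
  next_ok <- i < length(obs_times) & (obs_times[nxt] - anchors) <= tol
  prev_ok | next_ok
}
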