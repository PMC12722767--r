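# Machine-learning label construction for the four prediction tasks.
# Labels live on the 5-min grid with values "positive"/"negative"/
# "undefined"; the 24-h horizon is 288 bins, the extubation-failure horizon
# 48 h = 576 bins, the pre-onset/pre-extubation augmentation window 30 min =
# 6 bins.

TASK_HORIZON_BINS <- 288L
EF_HORIZON_BINS <- 576L
AUGMENT_BINS <- 6L

# any TRUE within (t, t+h] for each t, vectorized
future_any <- function(flag, h) {
  n <- length(flag)
  cf <- c(0, cumsum(as.numeric(flag)))
  hi <- pmin(n, seq_len(n) + h)
  (cf[hi + 1L] - cf[seq_len(n) + 1L]) > 0
}

# all TRUE within (t, t+h] (empty window counts as all-TRUE)
future_all <- function(flag, h) {
  n <- length(flag)
  cf <- c(0, cumsum(as.numeric(flag)))
  hi <- pmin(n, seq_len(n) + h)
  cnt <- cf[hi + 1L] - cf[seq_len(n) + 1L]
  cnt == (hi - seq_len(n))
}

#' Respiratory-failure onset labels
#'
#' Defined only where the patient is currently stable or in mild failure:
#' positive if moderate or severe failure occurs within the next 24 h,
#' negative otherwise; undefined where the current status is unknown,
#' moderate/severe, or the entire next 24 h is unknown. If the remaining
#' stay is shorter than 24 h and the status is known to stay end without an
#' event, the label is negative (horizon truncation at discharge).
#'
#' @param rf_status Status track from the respiratory-failure annotator.
#' @return Character label track.
#' @export
label_rf_onset <- function(rf_status) {
  n <- length(rf_status)
  in_rf <- rf_status %in% c("moderate", "severe")
  unknown <- rf_status == "unknown"
  lab <- rep("undefined", n)
  eligible <- rf_status %in% c("stable", "mild")
  pos <- future_any(in_rf, TASK_HORIZON_BINS)
  all_unknown <- future_all(unknown, TASK_HORIZON_BINS) &
    seq_len(n) < n  # empty window at the last bin is not "all unknown"
  lab[eligible & pos] <- "positive"
  lab[eligible & !pos] <- "negative"
  lab[eligible & !pos & all_unknown] <- "undefined"
  lab
}

#' Ventilation-onset labels
#'
#' Defined only at non-ventilated bins: positive if mechanical ventilation
#' starts within the next 24 h, negative otherwise. The 30 min just before
#' each ventilation onset are set undefined to prevent leakage from the
#' future.
#'
#' @param vent Logical ventilation track.
#' @return Character label track.
#' @export
label_mv_start <- function(vent) {
  n <- length(vent)
  lab <- rep("undefined", n)
  eligible <- !vent
  pos <- future_any(vent, TASK_HORIZON_BINS)
  lab[eligible & pos] <- "positive"
  lab[eligible & !pos] <- "negative"
  onsets <- which(vent & !c(FALSE, vent[-n]))
  for (o in onsets) {
    lo <- max(1L, o - AUGMENT_BINS)
    if (lo <= o - 1L) lab[lo:(o - 1L)] <- "undefined"
  }
  lab
}

#' Readiness-to-extubate onset labels
#'
#' Defined only where the patient is ventilated and not yet ready to
#' extubate: positive if readiness occurs within the next 24 h, negative
#' otherwise.
#'
#' @param vent,rext Logical tracks.
#' @return Character label track.
#' @export
label_mv_end <- function(vent, rext) {
  n <- length(vent)
  lab <- rep("undefined", n)
  eligible <- vent & !rext
  pos <- future_any(rext, TASK_HORIZON_BINS)
  lab[eligible & pos] <- "positive"
  lab[eligible & !pos] <- "negative"
  lab
}

#' Extubation events and extubation-failure labels
#'
#' An extubation is a ventilated-to-not-ventilated transition that is not a
#' tracheostomy decannulation (tracheostomy indicator active at the
#' transition). The event fails if a valid re-intubation (a later
#' not-ventilated-to-ventilated transition) occurs within 48 h; a
#' re-intubation is invalid when the patient was away from the unit in the
#' hour immediately before it (more than two thirds of that hour without a
#' heart-rate observation within 10 min), indicating a procedural
#' re-intubation. With no valid re-intubation, death within 48 h makes the
#' label uncertain; otherwise the extubation is a success (truncated
#' follow-up counts as success). The 30 min before the extubation share its
#' label; uncertain events yield no defined labels.
#'
#' @param vent Logical ventilation track.
#' @param hr_near Logical track: HR observation within 10 min of bin start.
#' @param trach_active Logical tracheostomy track.
#' @param death_bin Bin index of death, or `NA`.
#' @return List with `events` (data.frame: `bin`, `label` in
#'   failure/success/uncertain) and the augmented `label` track.
#' @export
label_extubations <- function(vent, hr_near, trach_active, death_bin = NA) {
  n <- length(vent)
  lab <- rep("undefined", n)
  offs <- which(!vent & c(FALSE, vent[-n]))   # first non-ventilated bin
  ons <- which(vent & !c(FALSE, vent[-n]))    # ventilation onsets
  events <- data.frame(bin = integer(), label = character(),
                       stringsAsFactors = FALSE)
  for (b in offs) {
    if (trach_active[max(1L, b - 1L)]) next  # decannulation, not extubation
    reint <- ons[ons > b & ons <= b + EF_HORIZON_BINS]
    valid <- reint[vapply(reint, function(r) {
      lo <- max(1L, r - 12L); hi <- r - 1L
      if (hi < lo) return(TRUE)
      mean(!hr_near[lo:hi]) <= 2 / 3  # off-unit > 2/3 of the hour -> invalid
    }, TRUE)]
    ev_lab <- if (length(valid)) {
      "failure"
    } else if (!is.na(death_bin) && death_bin > b &&
               death_bin <= b + EF_HORIZON_BINS) {
      "uncertain"
    } else "success"
    events <- rbind(events, data.frame(bin = b, label = ev_lab,
                                       stringsAsFactors = FALSE))
    if (ev_lab != "uncertain") {
      lo <- max(1L, b - AUGMENT_BINS)
      lab[lo:b] <- if (ev_lab == "failure") "positive" else "negative"
    }
  }
  list(events = events, label = lab)
}

#' All four task label tracks for one annotated stay
#'
#' @param endpoints Output of [annotate_endpoints()].
#' @param grid The underlying `gridded_stay` (for death time).
#' @return Named list of label tracks `RF`, `MVStart`, `MVEnd`, `EF` plus
#'   `ef_events`.
#' @export
label_tasks <- function(endpoints, grid) {
  death_bin <- if (is.finite(grid$death_time)) {
    floor((grid$death_time - grid$grid_start) / GRID_STEP_MIN) + 1L
  } else NA
  ef <- label_extubations(endpoints$vent, endpoints$hr_near,
                          endpoints$trach_active, death_bin)
  list(RF = label_rf_onset(endpoints$rf_status),
       MVStart = label_mv_start(endpoints$vent),
       MVEnd = label_mv_end(endpoints$vent, endpoints$rext),
       EF = ef$label, ef_events = ef$events)
}
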