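# Alarm generation policy and event-based evaluation.
#
# Alarm traces and event metrics work on per-stay score/status tracks. An
# "evaluation set" is a list of stays, each a list with `scores` (numeric
# track) and `rf_status` (character track), or more generally `event_flag`
# (logical in-event track) for non-RF tasks.

ALARM_SILENCE_BINS <- 48L   # 4 h
ALARM_RESET_BINS <- 6L      # 30 min after event recovery
EVENT_HORIZON_BINS <- 288L  # 24 h matching horizon

#' Generate alarms from a score track
#'
#' Scans bins where the patient is not currently in an event: an alarm
#' fires when the score meets the threshold and the system is not silenced;
#' each alarm silences the system for 4 h. When the patient recovers from
#' an event the silencing state is reset and the system may fire again from
#' 30 min after recovery.
#'
#' @param scores Numeric score track (`NA` = no score, never fires).
#' @param in_event Logical track: currently in an event (no alarms there).
#' @param threshold Alarm threshold (fires at `score >= threshold`).
#' @return Integer vector of alarm bins.
#' @export
generate_alarms <- function(scores, in_event, threshold) {
  n <- length(scores)
  alarms <- integer(0)
  allowed_from <- 1L  # first bin allowed to fire
  for (t in seq_len(n)) {
    if (in_event[t]) next
    if (t > 1L && in_event[t - 1L]) {
      # recovery: reset silencing, reactivation 30 min later
      allowed_from <- t + ALARM_RESET_BINS
    }
    if (t >= allowed_from && !is.na(scores[t]) && scores[t] >= threshold) {
      alarms <- c(alarms, t)
      allowed_from <- t + ALARM_SILENCE_BINS
    }
  }
  alarms
}

#' Event-based precision and recall
#'
#' An alarm is true iff an event onset occurs within the horizon after it;
#' an event is caught iff at least one alarm fires in the horizon preceding
#' its onset. Recall = caught events / all events; precision = true alarms
#' / all alarms (missing when no alarms fired).
#'
#' @param alarm_list List (per stay) of alarm-bin vectors.
#' @param event_list List (per stay) of event data.frames with a `start`
#'   column (onset bins).
#' @param horizon Matching horizon in bins.
#' @return List with `recall`, `precision`, `tp`, `fp`, `fn`, `n_events`,
#'   `n_alarms`.
#' @export
event_metrics <- function(alarm_list, event_list,
                          horizon = EVENT_HORIZON_BINS) {
  tp <- fp <- caught <- n_events <- 0L
  for (i in seq_along(alarm_list)) {
    alarms <- alarm_list[[i]]
    onsets <- event_list[[i]]$start
    n_events <- n_events + length(onsets)
    for (a in alarms) {
      if (any(onsets > a & onsets <= a + horizon)) tp <- tp + 1L
      else fp <- fp + 1L
    }
    for (o in onsets) {
      if (any(alarms >= o - horizon & alarms < o)) caught <- caught + 1L
    }
  }
  n_alarms <- tp + fp
  list(recall = if (n_events > 0) caught / n_events else NA_real_,
       precision = if (n_alarms > 0) tp / n_alarms else NA_real_,
       tp = tp, fp = fp, fn = n_events - caught,
       n_events = n_events, n_alarms = n_alarms)
}

#' Event-based precision-recall curve
#'
#' Sweeps thresholds over the alarm policy; the area under the curve uses
#' interpolation-free step integration over recall (curve sorted by
#' increasing recall, precision carried at each step).
#'
#' @param stays List of stays, each with `scores` and `in_event` (logical)
#'   and `events` (data.frame with `start`).
#' @param thresholds Numeric thresholds; default 40 quantiles of the
#'   pooled scores.
#' @param horizon Matching horizon in bins.
#' @return List with `curve` (data.frame threshold/recall/precision/tp/fp)
#'   and `auprc`.
#' @export
event_pr_curve <- function(stays, thresholds = NULL,
                           horizon = EVENT_HORIZON_BINS) {
  if (is.null(thresholds)) {
    pooled <- unlist(lapply(stays, function(s) s$scores[!s$in_event]))
    pooled <- pooled[!is.na(pooled)]
    thresholds <- unique(stats::quantile(pooled, seq(0.01, 0.995, length.out = 40),
                                         names = FALSE, type = 7))
  }
  rows <- lapply(thresholds, function(th) {
    al <- lapply(stays, function(s) generate_alarms(s$scores, s$in_event, th))
    ev <- lapply(stays, function(s) s$events)
    m <- event_metrics(al, ev, horizon)
    data.frame(threshold = th, recall = m$recall, precision = m$precision,
               tp = m$tp, fp = m$fp)
  })
  curve <- do.call(rbind, rows)
  list(curve = curve, auprc = event_auprc(curve))
}

event_auprc <- function(curve) {
  ok <- !is.na(curve$recall) & !is.na(curve$precision)
  if (!any(ok)) return(NA_real_)
  cv <- curve[ok, ]
  cv <- cv[order(cv$recall, -cv$precision), ]
  sum(diff(c(0, cv$recall)) * cv$precision)
}

#' Alarm earliness fractions
#'
#' For events preceded by at least `stability_min` minutes of stable time,
#' the fraction whose earliest in-horizon alarm precedes onset by at least
#' each cutoff. Fractions are non-increasing in the cutoff.
#'
#' @param alarm_list,event_list As in [event_metrics()]; events need
#'   `start` and a `stable_before` column in minutes (or pass
#'   `stability_min = 0`).
#' @param cutoffs_hours Earliness cutoffs (hours).
#' @param stability_min Required prior stability (minutes).
#' @param horizon Matching horizon in bins.
#' @return Named numeric vector of fractions per cutoff.
#' @export
earliness <- function(alarm_list, event_list, cutoffs_hours = c(0, 2, 5, 10),
                      stability_min = 24 * 60, horizon = EVENT_HORIZON_BINS) {
  lead_times <- numeric(0)  # minutes of earliest warning per qualifying event
  for (i in seq_along(alarm_list)) {
    ev <- event_list[[i]]
    if (!nrow(ev)) next
    stable_before <- if ("stable_before" %in% names(ev)) ev$stable_before
      else rep(Inf, nrow(ev))
    for (j in seq_len(nrow(ev))) {
      if (stable_before[j] < stability_min) next
      o <- ev$start[j]
      a <- alarm_list[[i]]
      a <- a[a >= o - horizon & a < o]
      lead_times <- c(lead_times, if (length(a)) (o - min(a)) * GRID_STEP_MIN
                      else -1)
    }
  }
  out <- vapply(cutoffs_hours, function(h) {
    if (!length(lead_times)) return(NA_real_)
    mean(lead_times >= h * 60)
  }, 0)
  names(out) <- sprintf(">=%gh", cutoffs_hours)
  out
}

#' Detectable event prevalence
#'
#' The chance floor of the event-based PR curve: the expected event AUPRC
#' of a random classifier, estimated by Monte-Carlo with uniform random
#' scores.
#'
#' @param stays As in [event_pr_curve()] (scores are ignored).
#' @param n_sim Monte-Carlo replicates.
#' @param seed Seed.
#' @return Mean event AUPRC under random scoring.
#' @export
detectable_prevalence <- function(stays, n_sim = 50, seed = 1) {
  if (!any(vapply(stays, function(s) nrow(s$events) > 0, TRUE))) return(0)
  set.seed(seed)
  vals <- vapply(seq_len(n_sim), function(k) {
    rs <- lapply(stays, function(s) {
      s$scores <- stats::runif(length(s$scores))
      s
    })
    event_pr_curve(rs, thresholds = seq(0.05, 0.95, by = 0.1))$auprc
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Prevalence correction of a PR curve
#'
#' Rescales false-alarm counts so precision is comparable across cohorts
#' with different detectable event prevalences: with scaling factor
#' `s = (1/prev_target - 1) / (1/prev_source - 1)`, precision becomes
#' `TP / (TP + s * FP)`; recall is unchanged. Applying the correction with
#' swapped prevalences undoes it.
#'
#' @param curve Curve data.frame with `tp`, `fp`, `recall` columns.
#' @param prev_source Prevalence of the cohort the curve was computed on.
#' @param prev_target Prevalence to correct to.
#' @return Corrected curve (precision recomputed) with the same columns.
#' @export
prevalence_correct <- function(curve, prev_source, prev_target) {
  if (!(prev_source > 0 && prev_source < 1 && prev_target > 0 &&
        prev_target < 1)) {
    stop("prevalences must lie strictly between 0 and 1")
  }
  s <- (1 / prev_target - 1) / (1 / prev_source - 1)
  curve$fp <- s * curve$fp
  curve$precision <- ifelse(curve$tp + curve$fp > 0,
                            curve$tp / (curve$tp + curve$fp), NA_real_)
  curve
}

#' Subgroup bootstrap fairness analysis
#'
#' Patient-level bootstrap (default 100 samples) of a per-group metric,
#' with per-group threshold recalibration to the target event recall; each
#' group is compared against its complement with a one-sided Mann-Whitney U
#' test at significance level 0.1%, Bonferroni-corrected over groups.
#'
#' @param stays Evaluation stays as in [event_pr_curve()].
#' @param groups Named character/factor vector: group per stay.
#' @param target_recall Event recall at which precision is evaluated.
#' @param n_boot Bootstrap samples.
#' @param alpha Significance level before Bonferroni correction.
#' @param seed Seed.
#' @return data.frame per group: median precision, p-value, worse-off flag.
#' @export
subgroup_bootstrap <- function(stays, groups, target_recall = 0.8,
                               n_boot = 100, alpha = 0.001, seed = 1) {
  set.seed(seed)
  groups <- as.character(groups)
  prec_at_recall <- function(sub) {
    if (!any(vapply(sub, function(s) nrow(s$events) > 0, TRUE))) return(NA_real_)
    cv <- event_pr_curve(sub)$curve
    ok <- !is.na(cv$recall) & !is.na(cv$precision) & cv$recall >= target_recall
    if (!any(ok)) return(NA_real_)
    max(cv$precision[ok])
  }
  boot_groups <- function(sel) {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample(sel, replace = TRUE)
      prec_at_recall(stays[idx])
    }, 0)
  }
  out <- lapply(unique(groups), function(g) {
    ing <- which(groups == g); outg <- which(groups != g)
    bi <- boot_groups(ing); bo <- boot_groups(outg)
    p <- if (all(is.na(bi)) || all(is.na(bo))) NA_real_ else
      stats::wilcox.test(bi, bo, alternative = "less", exact = FALSE)$p.value
    data.frame(group = g, n_stays = length(ing),
               median_precision = stats::median(bi, na.rm = TRUE),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  n_tests <- sum(!is.na(out$p_value))
  out$worse_off <- !is.na(out$p_value) & out$p_value * n_tests < alpha
  out
}
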