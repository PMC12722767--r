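# ICU-level ventilator-demand forecasting from per-patient risk scores.

RESOURCE_HORIZONS <- list(`4-8` = c(4, 8), `4-12` = c(4, 12),
                          `8-12` = c(8, 12), `8-16` = c(8, 16),
                          `16-24` = c(16, 24))

#' Hourly ICU census
#'
#' Reconstructs, per calendar hour, the number of patients present, the
#' number of ventilated non-elective patients, and the new (non-elective /
#' ventilated non-elective) admissions in the past hour, plus hour-of-day
#' and weekday calendar fields. Elective patients count toward presence but
#' are excluded from the ventilated prediction target (their resource use
#' is known in advance).
#'
#' @param stays List of [stay_record]s with admission/discharge minutes.
#' @param vent_tracks Named list (by patient id) of logical ventilation
#'   tracks on the stay grids.
#' @param grids Named list of `gridded_stay`s (for grid anchoring).
#' @return `data.table` census, one row per hour.
#' @export
build_census <- function(stays, vent_tracks, grids) {
  if (any(vapply(stays, function(s) is.na(s$admission_time), TRUE))) {
    stop("census requires admission times for all stays")
  }
  t0 <- floor(min(vapply(stays, `[[`, 0, "admission_time")) / 60)
  t1 <- ceiling(max(vapply(stays, `[[`, 0, "discharge_time")) / 60)
  hours <- t0:t1
  present <- vent_ne <- adm_new <- adm_vent <- numeric(length(hours))
  for (s in stays) {
    pid <- s$patient_id
    in_h <- hours * 60 >= s$admission_time & hours * 60 < s$discharge_time
    present[in_h] <- present[in_h] + 1
    if (!isTRUE(s$statics$elective)) {
      vt <- vent_tracks[[pid]]
      g <- grids[[pid]]
      if (!is.null(vt) && any(vt)) {
        # ventilated at hour h iff the grid bin covering that hour is TRUE
        hb <- floor((hours * 60 - g$grid_start) / GRID_STEP_MIN) + 1L
        okb <- hb >= 1 & hb <= g$n_steps
        vh <- in_h & okb
        vent_ne[vh] <- vent_ne[vh] + as.numeric(vt[hb[vh]])
        # a "ventilated admission" must need the ventilator near arrival
        # (within 16 h, the farthest supported horizon) -- later ventilation
        # is the admitted-patient sub-model's job, not the admission model's
        early_bins <- which(vt) * GRID_STEP_MIN + g$grid_start
        if (any(early_bins - s$admission_time <= 16 * 60)) {
          adm_in <- hours * 60 - 60 < s$admission_time &
            hours * 60 >= s$admission_time
          adm_vent[adm_in] <- adm_vent[adm_in] + 1
        }
      }
      adm_in <- hours * 60 - 60 < s$admission_time & hours * 60 >= s$admission_time
      adm_new[adm_in] <- adm_new[adm_in] + 1
    }
  }
  origin <- stays[[1]]$origin
  tod <- if (!is.null(origin)) {
    as.POSIXlt(origin + hours * 3600)
  } else NULL
  data.table::data.table(
    hour = hours, present = present, vent_nonelective = vent_ne,
    new_admissions = adm_new, new_vent_admissions = adm_vent,
    hour_of_day = if (!is.null(tod)) tod$hour else hours %% 24,
    weekday = if (!is.null(tod)) tod$wday else (hours %/% 24) %% 7
  )
}

#' Per-patient integration features at one hour
#'
#' The four task scores (carried forward up to 1 h), the current
#' ventilation flag, and the elapsed stay time: the fixed length-6 vector
#' the admitted-patient sub-model consumes.
#'
#' @param score_tracks Named list of per-stay lists with `RF`, `EF`,
#'   `MVStart`, `MVEnd` score tracks and `vent`.
#' @param grid The stay's `gridded_stay`.
#' @param hour_min Prediction time in minutes since origin.
#' @return Numeric vector of length 6 (NA where no recent score exists).
#' @export
patient_level_features <- function(score_tracks, grid, hour_min) {
  bin <- floor((hour_min - grid$grid_start) / GRID_STEP_MIN) + 1L
  pick <- function(x) {
    lo <- max(1L, bin - 12L)
    hi <- min(grid$n_steps, bin)
    if (hi < lo) return(NA_real_)
    v <- x[lo:hi]
    v <- v[!is.na(v)]
    if (length(v)) v[length(v)] else NA_real_
  }
  c(rf = pick(score_tracks$RF), ef = pick(score_tracks$EF),
    mvstart = pick(score_tracks$MVStart), mvend = pick(score_tracks$MVEnd),
    vent = as.numeric(score_tracks$vent[min(max(bin, 1L), grid$n_steps)]),
    elapsed_h = (hour_min - grid$grid_start) / 60)
}

horizon_target <- function(census, horizon) {
  # max ventilated non-elective count within (h + start, h + end] hours
  n <- nrow(census)
  vapply(seq_len(n), function(i) {
    lo <- i + horizon[1]; hi <- min(n, i + horizon[2])
    if (lo > n) NA_real_ else max(census$vent_nonelective[lo:hi])
  }, 0)
}

#' Train the ventilator-demand forecaster
#'
#' Two sub-models: (A) a per-admitted-patient gradient-boosted classifier
#' of "ventilated at some point within the horizon window", whose
#' probabilities are summed over admitted non-elective patients; (B) an
#' ICU-level gradient-boosted regressor predicting how many newly admitted
#' non-elective patients will be ventilated within the window, from
#' calendar and census features. The total forecast is A + B, clipped at
#' zero.
#'
#' @param census [build_census()] output.
#' @param patient_rows `data.table` with one row per (hour, admitted
#'   patient): columns `hour`, the 6 [patient_level_features()] columns and
#'   `future_vent` (0/1 target).
#' @param horizon One of the supported horizon windows, e.g. `c(8, 16)`.
#' @param train_hours Logical mask of census rows used for training.
#' @param ... Passed to [gbt_fit()].
#' @return A `resource_model`.
#' @export
train_resource_model <- function(census, patient_rows, horizon = c(8, 16),
                                 train_hours = NULL, ...) {
  if (!any(vapply(RESOURCE_HORIZONS, identical, TRUE, as.numeric(horizon)))) {
    stop("unsupported horizon window")
  }
  if (nrow(census) < 30 * 24) stop("need >= 30 days of census to train")
  if (is.null(train_hours)) train_hours <- rep(TRUE, nrow(census))
  # the last quarter of the training hours drives early stopping
  tr_idx <- which(train_hours)
  val_from <- tr_idx[floor(0.75 * length(tr_idx))]
  val_hours <- train_hours & seq_len(nrow(census)) > val_from
  fit_hours <- train_hours & !val_hours
  pcols <- c("rf", "ef", "mvstart", "mvend", "vent", "elapsed_h")
  pr_tr <- patient_rows[patient_rows$hour %in% census$hour[fit_hours], ]
  pr_va <- patient_rows[patient_rows$hour %in% census$hour[val_hours], ]
  model_a <- gbt_fit(as.matrix(pr_tr[, pcols, with = FALSE]),
                     pr_tr$future_vent,
                     as.matrix(pr_va[, pcols, with = FALSE]),
                     pr_va$future_vent,
                     objective = "binary", nrounds = 200L, max_depth = 3L,
                     min_leaf = 30L, early_stopping_rounds = 30L, ...)
  # sub-model B: new ventilated admissions in the window, ICU-level only
  n <- nrow(census)
  target_b <- vapply(seq_len(n), function(i) {
    lo <- i + horizon[1]; hi <- min(n, i + horizon[2])
    if (lo > n) NA_real_ else sum(census$new_vent_admissions[lo:hi])
  }, 0)
  bcols <- c("hour_of_day", "weekday", "present", "vent_nonelective",
             "new_admissions", "new_vent_admissions")
  okb <- fit_hours & !is.na(target_b)
  okv <- val_hours & !is.na(target_b)
  model_b <- gbt_fit(as.matrix(census[okb, bcols, with = FALSE]),
                     target_b[okb],
                     as.matrix(census[okv, bcols, with = FALSE]),
                     target_b[okv],
                     objective = "regression", nrounds = 200L,
                     max_depth = 3L, min_leaf = 30L,
                     early_stopping_rounds = 30L, ...)
  structure(list(model_a = model_a, model_b = model_b, horizon = horizon,
                 pcols = pcols, bcols = bcols), class = "resource_model")
}

#' @rdname train_resource_model
#' @param object A `resource_model`.
#' @param newdata List with `census` and `patient_rows` as in training.
#' @param ... Unused.
#' @return Numeric forecast per census hour.
#' @export
predict.resource_model <- function(object, newdata, ...) {
  census <- newdata$census; patient_rows <- newdata$patient_rows
  agg <- rep(0, nrow(census))
  if (nrow(patient_rows)) {
    p <- predict(object$model_a,
                 as.matrix(patient_rows[, object$pcols, with = FALSE]))
    s <- tapply(p, factor(patient_rows$hour, levels = census$hour), sum)
    agg <- ifelse(is.na(s), 0, as.numeric(s))
  }
  # no inner clipping: truncating B at zero would bias the sum upward
  # whenever few admissions are expected; only the total is clipped.
  # Ventilators come in integers and the loss is absolute error, so the
  # forecast is rounded toward the conditional median.
  b <- predict(object$model_b,
               as.matrix(census[, object$bcols, with = FALSE]))
  round(pmax(0, agg + b))
}

#' Persistence baseline
#'
#' Forecasts that the current ventilated non-elective count persists,
#' whatever the horizon.
#'
#' @param census [build_census()] output.
#' @return Numeric forecast per hour.
#' @export
persistence_baseline <- function(census) {
  census$vent_nonelective
}

#' Evaluate demand forecasts
#'
#' Mean absolute error against the realized maximum ventilated count in
#' the horizon window, overall and stratified by hour of day and by the
#' current-usage bin, plus a head-to-head table of |forecast - truth|
#' improvements over the baseline.
#'
#' @param forecast,baseline Hourly forecasts.
#' @param census Census table.
#' @param horizon Horizon window (hours).
#' @param usage_breaks Breaks for current-usage stratification.
#' @return List with `mae`, `mae_baseline`, `by_hour`, `by_usage`,
#'   `head_to_head`.
#' @export
evaluate_resource <- function(forecast, baseline, census, horizon = c(8, 16),
                              usage_breaks = c(-1, 2, 5, 8, Inf)) {
  truth <- horizon_target(census, horizon)
  ok <- !is.na(truth)
  err_f <- abs(forecast - truth)[ok]
  err_b <- abs(baseline - truth)[ok]
  hod <- census$hour_of_day[ok]
  usage <- cut(census$vent_nonelective[ok], usage_breaks)
  h2h <- vapply(1:4, function(k) {
    c(model = mean(err_b - err_f >= k), baseline = mean(err_f - err_b >= k))
  }, c(model = 0, baseline = 0))
  list(mae = mean(err_f), mae_baseline = mean(err_b),
       by_hour = tapply(err_f, hod, mean),
       by_usage = tapply(err_f, usage, mean),
       head_to_head = t(h2h))
}
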