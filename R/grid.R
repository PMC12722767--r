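# 5-minute gridding of irregular ICU observations.
#
# Internally, time is measured in minutes relative to a cohort origin; the
# origin (a POSIXct) travels with the StayRecord so calendar features can be
# reconstructed for census building.

GRID_STEP_MIN <- 5
MAX_GRID_DAYS <- 28
MAX_GRID_STEPS <- MAX_GRID_DAYS * 24 * 60 / GRID_STEP_MIN  # 8064

#' Construct a stay record
#'
#' Holds static admission data and the per-variable irregular observations of
#' one ICU stay. Observation timestamps are minutes relative to the cohort
#' origin and must be non-decreasing per variable.
#'
#' @param patient_id Stay identifier.
#' @param admission_time,discharge_time Minutes since cohort origin,
#'   `admission_time < discharge_time`.
#' @param observations Named list (by variable id) of data.frames with
#'   columns `time` (minutes) and `value`.
#' @param age,sex,height,apache_group,emergency,surgical,elective Statics.
#' @param era_pre2009,era_pre2010 Recording-era flags driving the
#'   ventilation-vote bonus and the readiness-to-extubate mode-criterion
#'   skip.
#' @param death_time Minutes since origin, or `NA` if the patient survived.
#' @param origin POSIXct cohort origin (calendar anchor), optional.
#' @return A `stay_record`.
#' @export
stay_record <- function(patient_id, admission_time, discharge_time,
                        observations, age = NA_real_, sex = NA_character_,
                        height = NA_real_, apache_group = NA_character_,
                        emergency = FALSE, surgical = FALSE, elective = FALSE,
                        era_pre2009 = FALSE, era_pre2010 = FALSE,
                        death_time = NA_real_, origin = NULL) {
  stopifnot(admission_time < discharge_time)
  for (v in names(observations)) {
    tt <- observations[[v]]$time
    if (is.unsorted(tt)) stop("timestamps of ", v, " are not non-decreasing")
  }
  structure(list(
    patient_id = as.character(patient_id),
    admission_time = admission_time, discharge_time = discharge_time,
    observations = observations,
    statics = list(age = age, sex = sex, height = height,
                   apache_group = apache_group, emergency = emergency,
                   surgical = surgical, elective = elective,
                   era_pre2009 = era_pre2009, era_pre2010 = era_pre2010),
    death_time = death_time, origin = origin
  ), class = "stay_record")
}

#' @export
print.stay_record <- function(x, ...) {
  cat(sprintf("<stay_record %s: %d variables, %.0f-%.0f min>\n", x$patient_id,
              length(x$observations), x$admission_time, x$discharge_time))
  invisible(x)
}

#' Grid one stay onto the 5-minute time grid
#'
#' The grid spans the first to the last heart-rate observation (the admitted
#' time period), truncated at 28 days. Bin `t` (0-based) covers the half-open
#' interval `[grid_start + 5t, grid_start + 5(t+1))` minutes. Observations
#' sharing a timestamp are averaged first; when several observations fall in
#' one bin the latest wins (current-value semantics). Each variable gets a
#' `measured` indicator track (1 iff >= 1 raw observation in the bin) and a
#' time-since-last-measurement track in minutes (-1 before the first
#' observation; 0 at a bin whose latest observation is in-bin).
#'
#' @param stay A [stay_record]; must contain at least one `hr` observation.
#' @param schema An `icu_schema`; observations of unknown variables are a
#'   schema error.
#' @return A `gridded_stay`: list with `grid_start`, `n_steps`, and named
#'   lists `values`, `measured`, `tsm` over schema variables, plus statics.
#' @export
build_grid <- function(stay, schema) {
  unknown <- setdiff(names(stay$observations), names(schema))
  if (length(unknown)) {
    stop("observations for variables not in schema: ",
         paste(unknown, collapse = ", "))
  }
  hr <- stay$observations[["hr"]]
  if (is.null(hr) || nrow(hr) == 0) stop("stay without heart-rate data rejected")
  grid_start <- hr$time[1]
  grid_end <- hr$time[nrow(hr)]
  n_steps <- floor((grid_end - grid_start) / GRID_STEP_MIN) + 1
  n_steps <- max(1L, min(as.integer(n_steps), MAX_GRID_STEPS))

  values <- measured <- tsm <- vector("list", length(schema))
  names(values) <- names(measured) <- names(tsm) <- names(schema)
  bin_starts <- grid_start + GRID_STEP_MIN * (seq_len(n_steps) - 1)
  for (v in names(schema)) {
    obs <- stay$observations[[v]]
    val <- rep(NA_real_, n_steps)
    mea <- integer(n_steps)
    ts <- rep(-1, n_steps)
    if (!is.null(obs) && nrow(obs) > 0) {
      # same-timestamp duplicates -> mean
      if (anyDuplicated(obs$time)) {
        agg <- tapply(obs$value, obs$time, mean)
        obs <- data.frame(time = as.numeric(names(agg)), value = as.numeric(agg))
        obs <- obs[order(obs$time), , drop = FALSE]
      }
      bin <- floor((obs$time - grid_start) / GRID_STEP_MIN)
      keep <- bin >= 0 & bin < n_steps
      if (any(keep)) {
        b <- bin[keep]
        mea[unique(b) + 1L] <- 1L
        # latest observation in bin wins (obs sorted by time)
        val[b + 1L] <- obs$value[keep]
      }
      # time since last raw observation (relative to bin start, floored at 0)
      idx <- findInterval(bin_starts + GRID_STEP_MIN - 1e-9, obs$time)
      has_prior <- idx >= 1
      ts[has_prior] <- pmax(0, bin_starts[has_prior] - obs$time[idx[has_prior]])
    }
    values[[v]] <- val; measured[[v]] <- mea; tsm[[v]] <- ts
  }
  structure(list(
    patient_id = stay$patient_id, grid_start = grid_start, n_steps = n_steps,
    step = GRID_STEP_MIN, values = values, measured = measured, tsm = tsm,
    statics = stay$statics, admission_time = stay$admission_time,
    discharge_time = stay$discharge_time, death_time = stay$death_time,
    origin = stay$origin,
    raw_obs_times = lapply(stay$observations, function(o) o$time)
  ), class = "gridded_stay")
}

#' @export
print.gridded_stay <- function(x, ...) {
  cat(sprintf("<gridded_stay %s: %d bins x %d variables (%.1f h)>\n",
              x$patient_id, x$n_steps, length(x$values),
              x$n_steps * x$step / 60))
  invisible(x)
}

#' Data-adaptive forward-fill horizon
#'
#' For variables whose forward-fill horizon cannot be specified from clinical
#' concepts, the horizon is estimated from the training-set distribution of
#' observation intervals as `2 * median(interval) + IQR(interval)` (IQR =
#' 75th - 25th percentile, linear interpolation).
#'
#' @param intervals Numeric vector of observation intervals in minutes.
#' @return Horizon in minutes.
#' @export
adaptive_horizon <- function(intervals) {
  if (length(intervals) == 0) stop("adaptive_horizon requires >= 1 interval")
  q <- stats::quantile(intervals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  2 * q[2] + (q[3] - q[1])
}

#' Training-set gridding statistics
#'
#' Computes, from training stays only, the per-variable median observation
#' interval and adaptive forward-fill horizon, plus static medians/modes for
#' dense static imputation. Serialize with [saveRDS]-free JSON via
#' [write_grid_stats()] if needed.
#'
#' @param stays List of [stay_record]s (training set only, to avoid leakage).
#' @param schema An `icu_schema`.
#' @return A `grid_stats` list.
#' @export
grid_stats <- function(stays, schema) {
  med_int <- ada <- stats::setNames(rep(NA_real_, length(schema)), names(schema))
  for (v in names(schema)) {
    ints <- unlist(lapply(stays, function(s) {
      tt <- s$observations[[v]]$time
      if (length(tt) >= 2) diff(tt) else numeric()
    }), use.names = FALSE)
    if (length(ints)) {
      med_int[v] <- stats::median(ints)
      ada[v] <- adaptive_horizon(ints)
    }
  }
  num_med <- function(f) stats::median(unlist(lapply(stays, function(s)
    s$statics[[f]])), na.rm = TRUE)
  mode_of <- function(f) {
    x <- unlist(lapply(stays, function(s) s$statics[[f]]))
    x <- x[!is.na(x)]
    if (!length(x)) return(NA)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  structure(list(
    median_interval = med_int, adaptive_horizon = ada,
    static_median = list(age = num_med("age"), height = num_med("height")),
    static_mode = list(sex = mode_of("sex"),
                       apache_group = mode_of("apache_group"))
  ), class = "grid_stats")
}

#' @rdname grid_stats
#' @param stats A `grid_stats` object.
#' @param path JSON file path.
#' @export
write_grid_stats <- function(stats, path) {
  x <- unclass(stats)
  # named vectors must serialize as JSON objects, not bare arrays
  x$median_interval <- as.list(x$median_interval)
  x$adaptive_horizon <- as.list(x$adaptive_horizon)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname grid_stats
#' @export
read_grid_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_or_na <- function(l) vapply(l, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), 0)
  x$median_interval <- num_or_na(x$median_interval)
  x$adaptive_horizon <- num_or_na(x$adaptive_horizon)
  x$static_median <- lapply(x$static_median, function(v) v %||% NA_real_)
  x$static_mode <- lapply(x$static_mode, function(v) v %||% NA)
  structure(x, class = "grid_stats")
}

ffill_horizon_minutes <- function(spec, stats = NULL) {
  switch(spec$imputation_mode,
    indefinite_ffill = Inf,
    limited_ffill_fixed = spec$ffill_minutes,
    limited_ffill_adaptive = {
      h <- if (!is.null(stats)) stats$adaptive_horizon[[spec$variable_id]] else NA_real_
      if (is.null(h) || !is.finite(h)) Inf else h
    },
    exact_grid_point = 0
  )
}

#' Impute a gridded stay
#'
#' Applies each variable's forward-fill policy to the value tracks. In
#' `"dense"` mode every grid point ends up with a finite value: bins the
#' policy cannot fill (before the first observation, or beyond the
#' forward-fill horizon) receive the schema's clinically normal value, and
#' missing statics are filled with training-set medians/modes. In
#' `"feature"` mode those bins stay missing (`NA`), preserving the
#' missingness pattern for model features. `exact_grid_point` variables keep
#' values only at measured bins.
#'
#' @param grid A `gridded_stay` from [build_grid()].
#' @param schema An `icu_schema`.
#' @param mode `"dense"` or `"feature"`.
#' @param stats Optional [grid_stats()] object; required when the schema has
#'   `limited_ffill_adaptive` variables (falls back to indefinite filling
#'   with a warning otherwise) and for dense static imputation.
#' @return The imputed `gridded_stay` (with `$imputation` set).
#' @export
impute_grid <- function(grid, schema, mode = c("dense", "feature"),
                        stats = NULL) {
  mode <- match.arg(mode)
  has_adaptive <- any(vapply(schema, function(s)
    s$imputation_mode == "limited_ffill_adaptive", TRUE))
  if (is.null(stats) && has_adaptive) {
    warning("no grid_stats supplied; adaptive horizons fall back to indefinite filling")
  }
  for (v in names(schema)) {
    spec <- schema[[v]]
    if (mode == "dense" && !is.finite(spec$normal_value)) {
      stop("dense imputation requires a normal_value for ", v)
    }
    val <- grid$values[[v]]
    ts <- grid$tsm[[v]]
    mea <- grid$measured[[v]]
    horizon <- ffill_horizon_minutes(spec, stats)
    out <- rep(NA_real_, grid$n_steps)
    if (spec$imputation_mode == "exact_grid_point") {
      keep <- mea == 1L
    } else {
      keep <- ts >= 0 & ts <= horizon
    }
    # carry last observed value forward onto kept bins (vectorized ffill)
    li <- cummax(ifelse(mea == 1L, seq_len(grid$n_steps), 0L))
    fill <- keep & li > 0L
    out[fill] <- val[li[fill]]
    if (mode == "dense") out[is.na(out)] <- spec$normal_value
    grid$values[[v]] <- out
  }
  if (mode == "dense" && !is.null(stats)) {
    st <- grid$statics
    if (is.na(st$age)) st$age <- stats$static_median$age
    if (is.na(st$height)) st$height <- stats$static_median$height
    if (is.na(st$sex)) st$sex <- stats$static_mode$sex
    if (is.na(st$apache_group)) st$apache_group <- stats$static_mode$apache_group
    grid$statics <- st
  }
  grid$imputation <- mode
  grid
}
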