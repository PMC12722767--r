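# Feature matrix construction from feature-imputed gridded stays.
#
# Multi-resolution horizons: 10 / 26 / 63 / 156 h correspond to the
# 20/40/60/80 percentiles of the available history in the reference
# training population; they are fixed constants here, not recomputed.

MULTIRES_HORIZON_HOURS <- c(10, 26, 63, 156)
MULTIRES_HORIZON_BINS <- as.integer(MULTIRES_HORIZON_HOURS * 12)
INSTABILITY_WINDOW_BINS <- 96L  # 8 h
TSM_SENTINEL <- 1e6

#' Multi-resolution summary features for one variable track
#'
#' Trailing-window summaries over the admitted horizons (10/26/63/156 h,
#' clipped at admission). A horizon is admitted when the expected number of
#' measurements in it (horizon / training-set median observation interval)
#' is at least 5; important variables use all admitted horizons, others
#' only the shortest admitted one. Ordinal variables yield median, IQR and
#' trend (OLS slope of value against bin index, units value per 5-min bin);
#' binary variables the mean; categorical variables the mode. Bins whose
#' window holds no value yield missing features.
#'
#' @param values Feature-imputed value track (`NA` preserved).
#' @param kind Variable kind.
#' @param horizons_bins Integer vector of admitted horizons in bins.
#' @param bins Bins (1-based) at which to evaluate; default all.
#' @return Named list of feature vectors, one per horizon x summary.
#' @export
multires_summaries <- function(values, kind, horizons_bins,
                               bins = seq_along(values)) {
  out <- list()
  for (w in horizons_bins) {
    tag <- sprintf("h%d", as.integer(round(w / 12)))
    if (kind == "ordinal") {
      m <- .roll_summaries_cpp(as.numeric(values), as.integer(w),
                               as.integer(bins))
      out[[paste0("median_", tag)]] <- m[, 1]
      out[[paste0("iqr_", tag)]] <- m[, 2]
      out[[paste0("trend_", tag)]] <- m[, 3]
    } else if (kind == "binary") {
      out[[paste0("mean_", tag)]] <- roll_fun(values, w, bins, function(v)
        mean(v))
    } else {
      out[[paste0("mode_", tag)]] <- roll_fun(values, w, bins, function(v) {
        uv <- unique(v)
        uv[which.max(tabulate(match(v, uv)))]
      })
    }
  }
  out
}

roll_fun <- function(values, w, bins, fun) {
  vapply(bins, function(t) {
    v <- values[max(1L, t - w + 1L):t]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fun(v)
  }, 0)
}

#' Measurement-intensity features
#'
#' Time to the last real measurement (the tracked time-since-measurement,
#' with a large sentinel where the variable was never measured) plus the
#' per-horizon measurement density: observations in the horizon divided by
#' the horizon length in hours.
#'
#' @param measured 0/1 measurement-indicator track.
#' @param tsm Time-since-measurement track (minutes, -1 = never).
#' @param horizons_bins Admitted horizons in bins.
#' @param bins Evaluation bins.
#' @return Named list of feature vectors.
#' @export
intensity_features <- function(measured, tsm, horizons_bins,
                               bins = seq_along(measured)) {
  out <- list(time_since_meas = ifelse(tsm[bins] < 0, TSM_SENTINEL, tsm[bins]))
  cm <- c(0, cumsum(measured))
  for (w in horizons_bins) {
    lo <- pmax(1L, bins - w + 1L)
    cnt <- cm[bins + 1L] - cm[lo]
    out[[sprintf("density_h%d", as.integer(round(w / 12)))]] <-
      cnt / (w * GRID_STEP_MIN / 60)
  }
  out
}

#' Instability-history features
#'
#' For each declared severity level of a variable: the fraction of bins in
#' that level over the trailing 8 h (current bin included) and over the
#' whole stay so far. Computed on the dense-imputed track so the fractions
#' are well defined.
#'
#' @param values Dense value track.
#' @param severity_levels Ordered threshold predicates from the schema.
#' @param bins Evaluation bins.
#' @return Named list of feature vectors; empty when no levels declared.
#' @export
instability_history <- function(values, severity_levels,
                                bins = seq_along(values)) {
  out <- list()
  if (is.null(severity_levels) || !length(severity_levels)) return(out)
  for (k in seq_along(severity_levels)) {
    lv <- severity_levels[[k]]
    in_level <- severity_indicator(values, severity_levels, k)
    ci <- c(0, cumsum(as.numeric(in_level)))
    lo <- pmax(1L, bins - INSTABILITY_WINDOW_BINS + 1L)
    out[[sprintf("sev%d_frac8h", k)]] <-
      (ci[bins + 1L] - ci[lo]) / (bins - lo + 1L)
    out[[sprintf("sev%d_fracstay", k)]] <- ci[bins + 1L] / bins
  }
  out
}

# exclusive level membership: a bin sits in the most severe level whose
# predicate it satisfies
severity_indicator <- function(values, severity_levels, k) {
  sat <- function(lv) {
    switch(lv$op,
           "<" = values < lv$value, "<=" = values <= lv$value,
           ">" = values > lv$value, ">=" = values >= lv$value)
  }
  in_k <- sat(severity_levels[[k]])
  if (k < length(severity_levels)) {
    for (j in (k + 1):length(severity_levels)) in_k <- in_k & !sat(severity_levels[[j]])
  }
  in_k & !is.na(values)
}

admitted_horizons <- function(spec, stats) {
  med <- stats$median_interval[[spec$variable_id]]
  if (is.null(med) || !is.finite(med)) return(integer(0))
  expected <- MULTIRES_HORIZON_BINS * GRID_STEP_MIN / med
  ok <- MULTIRES_HORIZON_BINS[expected >= 5]
  if (!length(ok)) return(integer(0))
  if (spec$is_important) ok else ok[1]
}

#' Assemble the feature matrix of one stay
#'
#' Concatenates, per evaluation bin: current feature-imputed values,
#' time-since-admission, endpoint-derived inputs (current estimated FIO2
#' and ventilation status; the PaO2 estimate is deliberately excluded to
#' avoid leakage), multi-resolution summaries, measurement-intensity
#' features, instability history, and the statics (age, sex, height,
#' APACHE group, emergency, surgical). The column set is a pure function of
#' the schema and training statistics; rows are `(stay, bin)` ordered by
#' bin. Missing values are preserved for the tree models.
#'
#' @param grid_feat Feature-imputed `gridded_stay`.
#' @param grid_dense Dense-imputed `gridded_stay` (instability features).
#' @param endpoints Output of [annotate_endpoints()].
#' @param schema,stats Schema and training statistics.
#' @param bins Evaluation bins (default all); the pipeline typically uses a
#'   stride to bound cost.
#' @return `data.table` with columns `stay`, `bin`, then features; a column
#'   manifest (name, category, variable, horizon) is attached as attribute
#'   `"manifest"`.
#' @export
assemble_features <- function(grid_feat, grid_dense, endpoints, schema,
                              stats, bins = seq_len(grid_feat$n_steps)) {
  cols <- list()
  manifest <- list()
  add <- function(name, x, category, variable = NA, horizon = NA) {
    cols[[name]] <<- x
    manifest[[length(manifest) + 1L]] <<-
      data.frame(name = name, category = category, variable = variable,
                 horizon = horizon, stringsAsFactors = FALSE)
  }
  for (v in names(schema)) {
    spec <- schema[[v]]
    add(paste0(v, "_cur"), grid_feat$values[[v]][bins], "current", v)
  }
  add("time_since_admission", (bins - 1) * GRID_STEP_MIN,
      "time_since_admission")
  add("fio2_est", endpoints$fio2_est[bins], "endpoint_derived")
  add("vent_status", as.numeric(endpoints$vent[bins]), "endpoint_derived")
  for (v in names(schema)) {
    spec <- schema[[v]]
    hz <- admitted_horizons(spec, stats)
    if (length(hz)) {
      mr <- multires_summaries(grid_feat$values[[v]], spec$kind, hz, bins)
      for (nm in names(mr)) add(paste0(v, "_", nm), mr[[nm]], "multires", v,
                                sub(".*_h", "", nm))
    }
    it <- intensity_features(grid_feat$measured[[v]], grid_feat$tsm[[v]],
                             hz, bins)
    for (nm in names(it)) add(paste0(v, "_", nm), it[[nm]], "intensity", v)
    if (!is.null(spec$severity_levels)) {
      ih <- instability_history(grid_dense$values[[v]], spec$severity_levels,
                                bins)
      for (nm in names(ih)) add(paste0(v, "_", nm), ih[[nm]], "instability", v)
    }
  }
  st <- grid_feat$statics
  nbin <- length(bins)
  add("age", rep(as.numeric(st$age), nbin), "static")
  add("height", rep(as.numeric(st$height), nbin), "static")
  add("sex_male", rep(as.numeric(identical(st$sex, "M")), nbin), "static")
  add("emergency", rep(as.numeric(isTRUE(st$emergency)), nbin), "static")
  add("surgical", rep(as.numeric(isTRUE(st$surgical)), nbin), "static")
  add("apache_cardio", rep(as.numeric(identical(st$apache_group, "cardiovascular")),
                           nbin), "static")
  add("apache_resp", rep(as.numeric(identical(st$apache_group, "respiratory")),
                         nbin), "static")
  dt <- data.table::as.data.table(cols)
  dt <- cbind(data.table::data.table(stay = grid_feat$patient_id, bin = bins), dt)
  attr(dt, "manifest") <- do.call(rbind, manifest)
  dt
}
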