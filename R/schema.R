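#' Variable schema specification
#'
#' A `variable_spec` describes one meta-variable of the monitoring schema:
#' its measurement kind, unit, gridding/imputation policy, clinically normal
#' value and optional ordered severity thresholds used for instability
#' features.
#'
#' @param variable_id Token identifying the meta-variable (e.g. `"spo2"`).
#' @param kind One of `"ordinal"`, `"binary"`, `"categorical"`.
#' @param unit Free-text unit string.
#' @param imputation_mode One of `"indefinite_ffill"`,
#'   `"limited_ffill_fixed"`, `"limited_ffill_adaptive"`,
#'   `"exact_grid_point"`.
#' @param normal_value Clinically normal value in variable units; used by
#'   dense imputation before the first observation and beyond the
#'   forward-fill horizon.
#' @param ffill_minutes Positive horizon in minutes; required for
#'   `limited_ffill_fixed`, ignored otherwise.
#' @param severity_levels Optional list of up to 3 threshold predicates,
#'   ordered by increasing severity. Each element is
#'   `list(op = "<"|"<="|">"|">=", value = x)`.
#' @param is_medication,is_important Flags used by feature extraction and
#'   variable selection.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(variable_id, kind = c("ordinal", "binary", "categorical"),
                          unit = "", imputation_mode = "indefinite_ffill",
                          normal_value = NA_real_, ffill_minutes = NA_real_,
                          severity_levels = NULL, is_medication = FALSE,
                          is_important = FALSE) {
  kind <- match.arg(kind)
  imputation_mode <- match.arg(imputation_mode,
    c("indefinite_ffill", "limited_ffill_fixed", "limited_ffill_adaptive",
      "exact_grid_point"))
  if (imputation_mode == "limited_ffill_fixed" &&
      (!is.finite(ffill_minutes) || ffill_minutes <= 0)) {
    stop("limited_ffill_fixed requires a positive ffill_minutes for ",
         variable_id)
  }
  if (!is.null(severity_levels)) {
    if (length(severity_levels) > 3) {
      stop("at most 3 severity levels are supported (", variable_id, ")")
    }
    for (lv in severity_levels) {
      if (!all(c("op", "value") %in% names(lv)) ||
          !lv$op %in% c("<", "<=", ">", ">=")) {
        stop("malformed severity level for ", variable_id)
      }
    }
  }
  structure(list(
    variable_id = as.character(variable_id), kind = kind, unit = unit,
    imputation_mode = imputation_mode, normal_value = normal_value,
    ffill_minutes = ffill_minutes, severity_levels = severity_levels,
    is_medication = isTRUE(is_medication), is_important = isTRUE(is_important)
  ), class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec %s: %s [%s], %s, normal=%s>\n", x$variable_id,
              x$kind, x$unit, x$imputation_mode, format(x$normal_value)))
  invisible(x)
}

#' Default monitoring schema
#'
#' The meta-variables the pipeline (and the bundled cohort simulator) work
#' with: vitals, arterial blood-gas panel, ventilator channels, supplemental
#' oxygen, airway indicators and vasoactive medications. Units, forward-fill
#' policies and severity thresholds are documented defaults and fully
#' user-overridable; `fio2` (ventilator), `suppl_fio2` and `highflow_fio2`
#' are stored as fractions of inspired oxygen.
#'
#' @return A named list of [variable_spec] objects, class `icu_schema`.
#' @export
default_schema <- function() {
  sl <- function(...) list(...)
  lev <- function(op, value) list(op = op, value = value)
  specs <- list(
    variable_spec("hr", "ordinal", "bpm", "indefinite_ffill", 80,
                  is_important = TRUE,
                  severity_levels = sl(lev(">=", 110), lev(">=", 130),
                                       lev(">=", 150))),
    variable_spec("spo2", "ordinal", "fraction", "indefinite_ffill", 0.97,
                  is_important = TRUE,
                  severity_levels = sl(lev("<", 0.92), lev("<", 0.88),
                                       lev("<", 0.82))),
    variable_spec("rr", "ordinal", "breaths/min", "indefinite_ffill", 15,
                  is_important = TRUE,
                  severity_levels = sl(lev(">=", 25), lev(">=", 30),
                                       lev(">=", 35))),
    variable_spec("map", "ordinal", "mmHg", "indefinite_ffill", 80,
                  is_important = TRUE,
                  severity_levels = sl(lev("<=", 70), lev("<=", 60),
                                       lev("<=", 50))),
    variable_spec("gcs", "ordinal", "points", "limited_ffill_adaptive", 15),
    # arterial blood gas panel: episodic, data-adaptive horizons
    variable_spec("pao2", "ordinal", "mmHg", "limited_ffill_adaptive", 90,
                  is_important = TRUE),
    variable_spec("sao2", "ordinal", "fraction", "limited_ffill_adaptive",
                  0.975),
    variable_spec("paco2", "ordinal", "mmHg", "limited_ffill_adaptive", 40),
    variable_spec("ph", "ordinal", "pH", "limited_ffill_adaptive", 7.4),
    variable_spec("lactate", "ordinal", "mmol/L", "limited_ffill_adaptive",
                  1.0, severity_levels = sl(lev(">=", 2.0), lev(">=", 4.0))),
    # ventilator channels: meaningful only while a ventilator is attached
    variable_spec("vent_mode", "categorical", "code 1-6",
                  "limited_ffill_fixed", 1, ffill_minutes = 480),
    variable_spec("peep", "ordinal", "cmH2O", "limited_ffill_fixed", 5,
                  ffill_minutes = 480, is_important = TRUE),
    variable_spec("pressure_support", "ordinal", "cmH2O",
                  "limited_ffill_fixed", 8, ffill_minutes = 480),
    variable_spec("tv", "ordinal", "mL", "limited_ffill_fixed", 450,
                  ffill_minutes = 480),
    variable_spec("minute_volume", "ordinal", "L/min", "limited_ffill_fixed",
                  7, ffill_minutes = 480),
    variable_spec("etco2", "ordinal", "mmHg", "exact_grid_point", 0),
    variable_spec("ppeak", "ordinal", "cmH2O", "limited_ffill_fixed", 18,
                  ffill_minutes = 480),
    variable_spec("fio2", "ordinal", "fraction", "limited_ffill_fixed", 0.21,
                  ffill_minutes = 720, is_important = TRUE),
    variable_spec("suppl_fio2", "ordinal", "fraction", "limited_ffill_fixed",
                  0.21, ffill_minutes = 720),
    variable_spec("highflow_fio2", "ordinal", "fraction",
                  "limited_ffill_fixed", 0.21, ffill_minutes = 720),
    # airway indicators
    variable_spec("airway", "categorical", "code", "indefinite_ffill", 0),
    variable_spec("trach", "binary", "flag", "indefinite_ffill", 0),
    variable_spec("intub", "binary", "flag", "indefinite_ffill", 0),
    # medications (rates); zero when not running
    variable_spec("norepinephrine", "ordinal", "ug/kg/h",
                  "indefinite_ffill", 0, is_medication = TRUE,
                  is_important = TRUE),
    variable_spec("inotrope", "binary", "flag", "indefinite_ffill", 0,
                  is_medication = TRUE)
  )
  names(specs) <- vapply(specs, `[[`, "", "variable_id")
  structure(specs, class = "icu_schema")
}

#' Airway category codes used by the default schema
#'
#' 1 = intubated, 2 = tracheostomy, 3 = mask, 4 = helmet, 5 = mouthpiece,
#' 6 = nasal interface, 0 = none recorded.
#' @keywords internal
AIRWAY_INVASIVE <- c(1, 2)
#' @keywords internal
AIRWAY_NONINVASIVE <- c(3, 4, 5, 6)

#' Read / write a schema as JSON (or YAML)
#'
#' @param path File path; `.json` handled with jsonlite, `.yaml`/`.yml`
#'   require the optional yaml package.
#' @return `read_schema()`: an `icu_schema`; `write_schema()`: `path`,
#'   invisibly.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML schemas requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  specs <- lapply(raw, function(v) {
    variable_spec(v$variable_id, v$kind, v$unit %||% "",
                  v$imputation_mode %||% "indefinite_ffill",
                  v$normal_value %||% NA_real_,
                  v$ffill_minutes %||% NA_real_,
                  severity_levels = v$severity_levels,
                  is_medication = isTRUE(v$is_medication),
                  is_important = isTRUE(v$is_important))
  })
  names(specs) <- vapply(specs, `[[`, "", "variable_id")
  structure(specs, class = "icu_schema")
}

#' @rdname read_schema
#' @param schema An `icu_schema`.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(lapply(unname(schema), unclass), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
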