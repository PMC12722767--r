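# One seeded ventilator-demand forecasting experiment on a simulated unit.
# Rule-based clinical scores stand in for the four fitted task models so a
# whole run fits the CPU budget; the forecaster itself (sub-models A and B)
# is trained per run.

resource_experiment <- function(seed, n_stays = 157, horizon_days = 45,
                                horizon = c(8, 16)) {
  cfg <- sim_config(n_stays = n_stays, horizon_days = horizon_days,
                    admission_rate_per_day = 3.5)
  co <- simulate_cohort(cfg, seed = seed)
  sc <- default_schema()
  st <- grid_stats(co$stays, sc)
  grids <- vents <- eps <- list()
  for (s in co$stays) {
    g <- build_grid(s, sc)
    gd <- impute_grid(g, sc, "dense", st)
    ep <- annotate_endpoints(g, gd, schema = sc, stats = st)
    grids[[s$patient_id]] <- g
    vents[[s$patient_id]] <- ep$vent
    eps[[s$patient_id]] <- ep
  }
  census <- build_census(co$stays, vents, grids)
  # hour with the highest realized ventilated count inside each window:
  # per-patient membership there sums to the window-max target
  nK <- nrow(census)
  peak_h <- vapply(seq_len(nK), function(i) {
    lo <- i + horizon[1]; hi <- min(nK, i + horizon[2])
    if (lo > nK) return(NA_real_)
    census$hour[lo:hi][which.max(census$vent_nonelective[lo:hi])]
  }, 0)
  names(peak_h) <- as.character(census$hour)
  # per (hour, admitted non-elective patient) rows with rule-based scores
  rows <- list()
  for (s in co$stays) {
    if (isTRUE(s$statics$elective)) next  # excluded from target and forecast
    g <- grids[[s$patient_id]]; ep <- eps[[s$patient_id]]
    tracks <- list(
      RF = as.numeric(ep$rf_status %in% c("moderate", "severe")) +
        0.5 * (ep$rf_status == "mild"),
      EF = pmin(1, ep$rext_score / 9),
      MVStart = -pmin(ep$pf, 500) / 500,
      MVEnd = as.numeric(ep$rext),
      vent = ep$vent)
    hrs <- census$hour[census$hour * 60 >= s$admission_time &
                         census$hour * 60 < s$discharge_time]
    if (!length(hrs)) next
    fv <- t(vapply(hrs, function(h)
      patient_level_features(tracks, g, h * 60), numeric(6)))
    # per-patient event: ventilated at the window's peak-count hour
    fut <- vapply(hrs, function(h) {
      hp <- peak_h[[as.character(h)]]
      if (is.na(hp)) return(0)
      bm <- floor((hp * 60 - g$grid_start) / 5) + 1
      if (bm > g$n_steps || bm < 1) 0 else as.numeric(ep$vent[bm])
    }, 0)
    rows[[s$patient_id]] <- data.table::data.table(
      hour = hrs, rf = fv[, 1], ef = fv[, 2], mvstart = fv[, 3],
      mvend = fv[, 4], vent = fv[, 5], elapsed_h = fv[, 6],
      future_vent = fut)
  }
  patient_rows <- data.table::rbindlist(rows)
  # steady-state window: skip the fill-up ramp and the drain after the last
  # admission; split it 2:1 into train and evaluation hours
  adm_h <- vapply(co$stays, `[[`, 0, "admission_time") / 60
  steady <- census$hour >= min(adm_h) + 48 & census$hour <= max(adm_h)
  idx <- which(steady)
  cutoff <- idx[floor(2 / 3 * length(idx))]
  train_hours <- steady & census$hour <= census$hour[cutoff]
  eval_hours <- steady & census$hour > census$hour[cutoff]
  m <- train_resource_model(census, patient_rows, horizon = horizon,
                            train_hours = train_hours)
  fc <- predict(m, list(census = census, patient_rows = patient_rows))
  base <- persistence_baseline(census)
  ev <- evaluate_resource(fc[eval_hours], base[eval_hours],
                          census[eval_hours, ], horizon = horizon)
  list(mae = ev$mae, mae_baseline = ev$mae_baseline, census = census,
       model = m, eval = ev, forecast = fc, baseline = base,
       eval_hours = eval_hours, patient_rows = patient_rows)
}
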