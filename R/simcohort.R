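# Synthetic ICU cohort generator with known ground truth.
#
# Stays follow a latent respiratory state chain (stable -> deteriorating ->
# respiratory failure -> ventilated -> weaning -> ready -> extubated ->
# {reintubated, recovered}) on the 5-min step. The latent P/F trajectory is
# an Ornstein-Uhlenbeck-like walk around state-dependent means; SpO2 is
# emitted from latent PaO2 through the Severinghaus dissociation curve with
# a pH (Bohr) shift, clipped below 1. Observations are sampled at
# clinically plausible irregular rates; ventilator channels are only active
# during latent ventilation. Off-unit heart-rate gaps, tracheostomy
# weaning, non-invasive ventilation episodes, deaths and an
# elective/non-elective admission mix with calendar timestamps are built in
# so every downstream rule is exercised.

#' Simulation configuration
#'
#' Defaults describe a mid-sized mixed ICU: roughly half the stays ever
#' ventilated, an extubation-failure rate near 11%, ABGA panels every 2-6 h
#' depending on stability, and SpO2/HR at (near-)continuous 5-min
#' resolution.
#'
#' @param n_stays Number of stays.
#' @param horizon_days Calendar span of the admission process.
#' @param admission_rate_per_day Mean non-elective admissions per day (the
#'   nonhomogeneous Poisson intensity has a diurnal factor and a weekday
#'   uplift on top).
#' @param p_det,p_det_back,p_rf,p_rf_back,p_vent,p_wean,p_ready,p_setback,p_ext
#'   Per-5-min latent transition probabilities.
#' @param pf_means Named state-dependent P/F targets (mmHg).
#' @param pf_theta,pf_sigma OU mean-reversion rate and innovation sd.
#' @param bohr Dissociation-curve pH shift strength (per pH unit).
#' @param spo2_noise_sd SpO2 observation noise (fraction).
#' @param ef_coef Extubation-failure logistic coefficients
#'   `c(intercept, low_pf, high_support)`.
#' @param p_death_after_ext Death probability within 48 h of an extubation
#'   without re-intubation (yields uncertain labels).
#' @param p_trach Probability a long-ventilated stay converts to
#'   tracheostomy.
#' @param p_offunit Expected off-unit (HR gap) episodes per stay.
#' @param p_niv Probability a respiratory-failure episode gets a
#'   non-invasive ventilation trial.
#' @param frac_elective,frac_pre2009,frac_pre2010 Cohort mix fractions.
#' @param max_stay_days Hard stay cap.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_stays = 100, horizon_days = 30,
                       admission_rate_per_day = 6,
                       p_det = 0.005, p_det_back = 0.002, p_rf = 0.004,
                       p_rf_back = 0.006, p_vent = 0.012, p_wean = 0.010,
                       p_ready = 0.012, p_setback = 0.003, p_ext = 0.050,
                       pf_means = c(stable = 420, det = 280, rf = 140,
                                    vent = 170, wean = 240, ready = 310,
                                    post = 360),
                       pf_theta = 0.06, pf_sigma = 7, bohr = 2.5,
                       spo2_noise_sd = 0.006,
                       ef_coef = c(-2.7, 1.3, 0.9),
                       p_death_after_ext = 0.04, p_trach = 0.08,
                       p_offunit = 0.3, p_niv = 0.3,
                       frac_elective = 0.4, frac_pre2009 = 0.10,
                       frac_pre2010 = 0.15, max_stay_days = 10) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[grep("^p_", names(cfg))]) >= 0),
            all(unlist(cfg[grep("^p_", names(cfg))]) <= 1),
            all(pf_means > 0))
  structure(cfg, class = "sim_config")
}

# latent state codes
ST_STABLE <- 1L; ST_DET <- 2L; ST_RF <- 3L; ST_VENT <- 4L; ST_WEAN <- 5L
ST_READY <- 6L; ST_POST <- 7L

#' Simulate one stay
#'
#' Latent state, P/F trajectory and extubation outcomes co-evolve in one
#' pass: extubation failure is decided at each extubation with the
#' configured logistic model on the current latent covariates, and a failed
#' extubation schedules a re-intubation (return to the ventilated state)
#' within 48 h, so the emitted observations are consistent with the ground
#' truth.
#'
#' @param cfg A [sim_config()].
#' @param admission_min Admission time in minutes since cohort origin.
#' @param elective Elective admission flag.
#' @return List with the [stay_record] and its ground truth.
#' @keywords internal
sim_stay <- function(cfg, admission_min = 0, elective = FALSE,
                     patient_id = "sim1") {
  max_steps <- cfg$max_stay_days * 288L
  mu_of <- c(cfg$pf_means[["stable"]], cfg$pf_means[["det"]],
             cfg$pf_means[["rf"]], cfg$pf_means[["vent"]],
             cfg$pf_means[["wean"]], cfg$pf_means[["ready"]],
             cfg$pf_means[["post"]])
  state <- integer(max_steps)
  pf <- numeric(max_steps)
  s <- ST_STABLE
  pfv <- mu_of[ST_STABLE] + stats::rnorm(1, 0, 10)
  post_until <- reint_at <- -1L
  vent_since <- -1L
  trach_from <- NA_integer_
  ext_bins <- integer(); ext_fail <- logical(); ext_pfail <- numeric()
  death_bin <- NA_integer_
  min_steps <- 72L  # 6 h minimum stay
  t <- 0L
  while (t < max_steps) {
    t <- t + 1L
    state[t] <- s
    pfv <- max(40, pfv + cfg$pf_theta * (mu_of[s] - pfv) +
                 stats::rnorm(1, 0, cfg$pf_sigma))
    pf[t] <- pfv
    if (!is.na(death_bin) && t >= death_bin) break
    if (s %in% c(ST_VENT, ST_WEAN, ST_READY)) {
      if (vent_since < 0) vent_since <- t
      if (is.na(trach_from) && t - vent_since > 864L &&
          stats::runif(1) < cfg$p_trach / 100) {
        trach_from <- t  # tracheostomy conversion after > 72 h ventilation
      }
    } else {
      vent_since <- -1L
    }
    u <- stats::runif(1)
    if (s == ST_STABLE) {
      if (u < cfg$p_det) s <- ST_DET
      else if (t > min_steps && u < cfg$p_det + 0.003) break  # discharge
    } else if (s == ST_DET) {
      if (u < cfg$p_rf) s <- ST_RF
      else if (u < cfg$p_rf + cfg$p_det_back) s <- ST_STABLE
    } else if (s == ST_RF) {
      if (u < cfg$p_vent) s <- ST_VENT
      else if (u < cfg$p_vent + cfg$p_rf_back) s <- ST_DET
    } else if (s == ST_VENT) {
      if (u < cfg$p_wean) s <- ST_WEAN
    } else if (s == ST_WEAN) {
      if (u < cfg$p_ready) s <- ST_READY
      else if (u < cfg$p_ready + cfg$p_setback) s <- ST_VENT
    } else if (s == ST_READY) {
      # extubations concentrate in daytime hours (ward-round practice)
      clock <- ((admission_min + GRID_STEP_MIN * (t - 1)) / 60) %% 24
      p_ext_now <- cfg$p_ext * (if (clock >= 7 && clock < 19) 1.7 else 0.25)
      if (u < p_ext_now) {
        s <- ST_POST
        post_until <- t + 144L  # 12 h recovery
        reint_at <- -1L
        if (is.na(trach_from)) {
          ext_bins <- c(ext_bins, t + 1L)
          low_pf <- as.numeric(pfv < 250)
          high_support <- as.numeric(stats::runif(1) < 0.3)
          p_fail <- stats::plogis(cfg$ef_coef[1] + cfg$ef_coef[2] * low_pf +
                                    cfg$ef_coef[3] * high_support)
          fail <- stats::runif(1) < p_fail
          ext_fail <- c(ext_fail, fail)
          ext_pfail <- c(ext_pfail, p_fail)
          if (fail) {
            reint_at <- t + sample(24:540, 1)  # re-intubation within 48 h
          } else if (stats::runif(1) < cfg$p_death_after_ext) {
            death_bin <- t + sample(12:500, 1)
          }
        }
      }
    } else if (s == ST_POST) {
      if (reint_at > 0L && t >= reint_at) {
        s <- ST_VENT
        reint_at <- -1L
      } else if (reint_at < 0L && t >= post_until) {
        s <- ST_STABLE
      }
    }
  }
  n <- min(t, max_steps)
  st <- state[seq_len(n)]; pf <- pf[seq_len(n)]
  vent_true <- st %in% c(ST_VENT, ST_WEAN, ST_READY)
  if (!is.na(death_bin)) death_bin <- min(death_bin, n)
  ext_bins <- ext_bins[ext_bins <= n]
  ext_fail <- ext_fail[seq_along(ext_bins)]
  ext_pfail <- ext_pfail[seq_along(ext_bins)]

  # latent pH and FIO2
  ph <- numeric(n); ph[1] <- 7.4
  for (t in 2:max(n, 2)) {
    if (t > n) break
    ph[t] <- ph[t - 1] + 0.05 * (7.4 - 0.015 * (st[t] >= ST_RF) - ph[t - 1]) +
      stats::rnorm(1, 0, 0.006)
  }
  fio2_true <- rep(0.21, n)
  fio2_true[st == ST_DET] <- 0.35
  fio2_true[st == ST_RF] <- 0.5
  fio2_true[st == ST_VENT] <- 0.6
  fio2_true[st == ST_WEAN] <- 0.45
  fio2_true[st == ST_READY] <- 0.3
  fio2_true[st == ST_POST] <- 0.3
  pao2_true <- pf * fio2_true
  spo2_true <- severinghaus(pmax(pao2_true, 20) * exp(cfg$bohr * (ph - 7.4)))

  minutes <- (seq_len(n) - 1) * GRID_STEP_MIN
  obs <- list()
  emit <- function(var, times, values) {
    keep <- times >= 0 & times <= minutes[n]
    if (!any(keep)) return()
    o <- data.frame(time = admission_min + times[keep], value = values[keep])
    obs[[var]] <<- rbind(obs[[var]], o)
  }
  at_bins <- function(bins) minutes[bins]
  # vitals
  hr_t <- seq(0, minutes[n], by = 5) + stats::runif(length(seq(0, minutes[n], by = 5)), 0, 2)
  hr_bin <- pmin(n, floor(hr_t / 5) + 1)
  emit("hr", hr_t, 80 + 8 * (st[hr_bin] >= ST_DET) + 12 * (st[hr_bin] == ST_RF) +
         stats::rnorm(length(hr_t), 0, 4))
  spo2_t <- seq(0, minutes[n], by = 5)
  spo2_bin <- pmin(n, floor(spo2_t / 5) + 1)
  emit("spo2", spo2_t, pmin(0.999, pmax(0.5,
    spo2_true[spo2_bin] + stats::rnorm(length(spo2_t), 0, cfg$spo2_noise_sd))))
  rr_t <- seq(0, minutes[n], by = 30)
  rr_bin <- pmin(n, floor(rr_t / 5) + 1)
  emit("rr", rr_t, 14 + 8 * (st[rr_bin] == ST_RF) + 4 * (st[rr_bin] == ST_DET) +
         stats::rnorm(length(rr_t), 0, 2))
  map_t <- seq(0, minutes[n], by = 15)
  map_bin <- pmin(n, floor(map_t / 5) + 1)
  emit("map", map_t, 85 - 10 * (st[map_bin] >= ST_RF) +
         stats::rnorm(length(map_t), 0, 6))
  gcs_t <- seq(0, minutes[n], by = 240)
  gcs_bin <- pmin(n, floor(gcs_t / 5) + 1)
  emit("gcs", gcs_t, pmin(15, pmax(3, round(15 - 6 * (st[gcs_bin] %in%
    c(ST_VENT, ST_WEAN)) + stats::rnorm(length(gcs_t), 0, 0.5)))))
  # ABGA panels: event-driven, denser when unstable
  abga_t <- numeric(0)
  tcur <- stats::runif(1, 30, 120)
  while (tcur <= minutes[n]) {
    abga_t <- c(abga_t, tcur)
    b <- min(n, floor(tcur / 5) + 1)
    mean_gap <- if (st[b] >= ST_DET && st[b] <= ST_VENT) 120 else 360
    tcur <- tcur + stats::rgamma(1, shape = 4, scale = mean_gap / 4)
  }
  if (length(abga_t)) {
    ab <- pmin(n, floor(abga_t / 5) + 1)
    emit("pao2", abga_t, pao2_true[ab] + stats::rnorm(length(ab), 0, 4))
    emit("sao2", abga_t, pmin(0.999, spo2_true[ab] +
                                stats::rnorm(length(ab), 0, 0.004)))
    emit("paco2", abga_t, 40 + 6 * (st[ab] >= ST_RF) +
           stats::rnorm(length(ab), 0, 3))
    emit("ph", abga_t, ph[ab] + stats::rnorm(length(ab), 0, 0.01))
    emit("lactate", abga_t, pmax(0.4, 1 + 1.5 * (st[ab] == ST_RF) +
                                   stats::rnorm(length(ab), 0, 0.3)))
  }
  # ventilator channels during latent ventilation
  if (any(vent_true)) {
    vbins <- which(vent_true)
    vt <- at_bins(vbins[seq(1, length(vbins), by = 12)])  # hourly
    vb <- pmin(n, floor(vt / 5) + 1)
    mode_code <- ifelse(st[vb] == ST_VENT, 2, 3)
    emit("vent_mode", vt, mode_code)
    emit("peep", vt, ifelse(st[vb] == ST_VENT, 10, ifelse(st[vb] == ST_WEAN, 7, 5)) +
           stats::rnorm(length(vt), 0, 0.5))
    emit("pressure_support", vt,
         ifelse(st[vb] == ST_VENT, 14, ifelse(st[vb] == ST_WEAN, 10, 7)) +
           stats::rnorm(length(vt), 0, 1))
    emit("tv", vt, 450 + stats::rnorm(length(vt), 0, 30))
    emit("minute_volume", vt, ifelse(st[vb] == ST_VENT, 9.5, 7.5) +
           stats::rnorm(length(vt), 0, 0.8))
    emit("ppeak", vt, ifelse(st[vb] == ST_VENT, 26, 18) +
           stats::rnorm(length(vt), 0, 2))
    # ventilator FIO2 is a device channel: ~10-min resolution
    ft <- at_bins(vbins[seq(1, length(vbins), by = 2)])
    fb <- pmin(n, floor(ft / 5) + 1)
    emit("fio2", ft, pmin(1, pmax(0.21, fio2_true[fb] +
                                    stats::rnorm(length(ft), 0, 0.02))))
    et_t <- at_bins(vbins[seq(1, length(vbins), by = 6)])  # every 30 min
    eb <- pmin(n, floor(et_t / 5) + 1)
    emit("etco2", et_t, 35 + stats::rnorm(length(et_t), 0, 3))
    # airway indicators
    onsets <- vr2 <- status_runs(vent_true)
    for (i in which(vr2$value)) {
      s0 <- vr2$start[i]; e0 <- vr2$end[i]
      if (!is.na(trach_from) && e0 >= trach_from) {
        emit("intub", at_bins(s0), 1)
        emit("trach", at_bins(min(e0, max(s0, trach_from))), 1)
        emit("airway", at_bins(s0), 1)
        emit("airway", at_bins(min(e0, max(s0, trach_from))), 2)
      } else {
        emit("intub", c(at_bins(s0), at_bins(e0) + 2), c(1, 0))
        emit("airway", c(at_bins(s0), at_bins(e0) + 2), c(1, 0))
      }
    }
  }
  # NIV trial during a respiratory-failure episode (mask airway, mode 4)
  rfr <- status_runs(st == ST_RF)
  for (i in which(rfr$value)) {
    if (stats::runif(1) < cfg$p_niv && rfr$length[i] >= 24) {
      s0 <- rfr$start[i]; e0 <- min(rfr$end[i], rfr$start[i] + 72)
      tt <- at_bins(seq(s0, e0, by = 6))
      emit("vent_mode", tt, rep(4, length(tt)))
      emit("fio2", tt, rep(0.5, length(tt)))
      emit("airway", at_bins(s0), 3)
    }
  }
  # supplemental oxygen while deteriorated/failing but not ventilated
  so <- status_runs(st %in% c(ST_DET, ST_RF) & !vent_true)
  for (i in which(so$value)) {
    tt <- at_bins(seq(so$start[i], so$end[i], by = 48))  # every 4 h
    emit("suppl_fio2", tt, pmin(0.8, fio2_true[pmin(n, floor(tt / 5) + 1)] +
                                  stats::rnorm(length(tt), 0, 0.02)))
  }
  # medications
  med <- status_runs(st %in% c(ST_RF, ST_VENT))
  for (i in which(med$value)) {
    tt <- at_bins(seq(med$start[i], med$end[i], by = 12))
    emit("norepinephrine", tt, pmax(0, 0.1 + stats::rnorm(length(tt), 0, 0.04)))
    if (stats::runif(1) < 0.2) emit("inotrope", tt[1], 1)
  }
  # off-unit HR gaps
  n_gap <- stats::rpois(1, cfg$p_offunit)
  gap_iv <- NULL
  if (n_gap > 0 && minutes[n] > 360) {
    for (k in seq_len(n_gap)) {
      g0 <- stats::runif(1, 60, minutes[n] - 180)
      g1 <- g0 + stats::runif(1, 60, 120)
      gap_iv <- rbind(gap_iv, c(g0, g1))
      for (v in c("hr", "spo2", "map", "rr")) {
        if (!is.null(obs[[v]])) {
          rel <- obs[[v]]$time - admission_min
          obs[[v]] <- obs[[v]][!(rel >= g0 & rel <= g1), , drop = FALSE]
        }
      }
    }
  }
  era2009 <- stats::runif(1) < cfg$frac_pre2009
  era2010 <- era2009 || stats::runif(1) < (cfg$frac_pre2010 - cfg$frac_pre2009)
  stay <- stay_record(
    patient_id = patient_id,
    admission_time = admission_min,
    discharge_time = admission_min + minutes[n] + GRID_STEP_MIN,
    observations = lapply(obs, function(o) o[order(o$time), , drop = FALSE]),
    age = 5 * sample(6:18, 1), sex = sample(c("M", "F"), 1, prob = c(0.63, 0.37)),
    height = 5 * sample(30:38, 1),
    apache_group = sample(c("neurologic", "cardiovascular", "respiratory",
                            "gastrointestinal", "trauma", "other"), 1,
                          prob = c(0.25, 0.3, 0.1, 0.1, 0.06, 0.19)),
    emergency = !elective, surgical = stats::runif(1) < 0.4,
    elective = elective, era_pre2009 = era2009, era_pre2010 = era2010,
    death_time = if (is.finite(death_bin)) admission_min + at_bins(death_bin) else NA_real_
  )
  truth <- list(
    state = st, pf_true = pf, pao2_true = pao2_true, ph_true = ph,
    fio2_true = fio2_true, vent_true = vent_true,
    ext_bins = ext_bins, ext_fail = ext_fail, ext_pfail = ext_pfail,
    trach_from = trach_from, death_bin = death_bin, offunit = gap_iv
  )
  list(stay = stay, truth = truth)
}

#' Simulate a cohort
#'
#' Admission times follow a nonhomogeneous Poisson process with a diurnal
#' intensity peak in daytime hours and a weekday uplift; elective
#' admissions arrive on weekday mornings. The cohort origin is a fixed
#' calendar anchor so census construction has real timestamps.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all stochasticity flows from it.
#' @return List with `stays` (list of [stay_record]) and `truth` (parallel
#'   list of ground-truth objects).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  horizon_min <- cfg$horizon_days * 1440
  # thinning for the nonhomogeneous admission process
  lam_max <- cfg$admission_rate_per_day / 1440 * 2.5
  tt <- 0; adm <- numeric(0)
  while (length(adm) < cfg$n_stays * 3 && tt < horizon_min * 5) {
    tt <- tt + stats::rexp(1, lam_max)
    hour <- (tt / 60) %% 24
    wday <- floor(tt / 1440) %% 7
    lam <- cfg$admission_rate_per_day / 1440 *
      (1 + 0.5 * sin(2 * pi * (hour - 9) / 24)) *
      (if (wday < 5) 1.2 else 0.7)
    if (stats::runif(1) < lam / lam_max) adm <- c(adm, tt)
  }
  adm <- adm[seq_len(min(cfg$n_stays, length(adm)))]
  n_el <- round(cfg$frac_elective * length(adm))
  elective <- rep(FALSE, length(adm))
  if (n_el > 0) elective[sample(seq_along(adm), n_el)] <- TRUE
  # electives arrive weekday 08:00-12:00
  for (i in which(elective)) {
    day <- floor(adm[i] / 1440)
    adm[i] <- day * 1440 + stats::runif(1, 8 * 60, 12 * 60)
  }
  stays <- truth <- vector("list", length(adm))
  for (i in seq_along(adm)) {
    r <- sim_stay(cfg, adm[i], elective[i], sprintf("sim%04d", i))
    r$stay$origin <- origin
    stays[[i]] <- r$stay
    truth[[i]] <- r$truth
  }
  list(stays = stays, truth = truth, origin = origin, config = cfg,
       seed = seed)
}

#' Hand-designed rule fixtures with golden expected outputs
#'
#' Tiny deterministic track-level scenarios, each exercising exactly one
#' post-processing or labeling rule, with the hand-walked expected output
#' stored beside the inputs. Used by the golden-fixture acceptance tests.
#'
#' @param scenario One of `"sandwich-merge"`, `"short-event-delete"`,
#'   `"gap-too-long"`, `"right-edge"`, `"micro-gap"`, `"offunit-gap"`,
#'   `"trach-gap"`, `"short-vent-delete"`, `"trach-decannulation"`,
#'   `"procedural-reintubation"`, `"death-censored-ef"`,
#'   `"label-augmentation"`, `"pre2010-era"`.
#' @return List with `inputs` and `expected`.
#' @export
make_fixtures <- function(scenario) {
  switch(scenario,
    "sandwich-merge" = {
      x <- c(rep("moderate", 72), rep("stable", 24), rep("moderate", 60))
      list(inputs = list(rf_status = x),
           expected = list(rf_status = rep("moderate", 156)))
    },
    "short-event-delete" = {
      x <- c(rep("stable", 72), rep("moderate", 36), rep("stable", 72))
      list(inputs = list(rf_status = x),
           expected = list(rf_status = rep("stable", 180)))
    },
    "gap-too-long" = {
      x <- c(rep("moderate", 72), rep("stable", 60), rep("moderate", 72))
      list(inputs = list(rf_status = x), expected = list(rf_status = x))
    },
    "right-edge" = {
      status <- c(rep("moderate", 20), rep("stable", 10))
      pf <- c(rep(150, 24), rep(250, 6))
      list(inputs = list(rf_status = status, pf = pf),
           expected = list(rf_status = c(rep("moderate", 24),
                                         rep("stable", 6))))
    },
    "micro-gap" = {
      vent <- c(rep(TRUE, 24), rep(FALSE, 2), rep(TRUE, 24))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 50),
                         trach = rep(FALSE, 50), hr_before = rep(TRUE, 50)),
           expected = list(vent = rep(TRUE, 50)))
    },
    "offunit-gap" = {
      vent <- c(rep(TRUE, 24), rep(FALSE, 24), rep(TRUE, 24))
      hr <- c(rep(TRUE, 24), rep(FALSE, 24), rep(TRUE, 24))
      list(inputs = list(vent = vent, hr_near = hr,
                         trach = rep(FALSE, 72), hr_before = rep(TRUE, 72)),
           expected = list(vent = rep(TRUE, 72)))
    },
    "trach-gap" = {
      vent <- c(rep(TRUE, 24), rep(FALSE, 100), rep(TRUE, 24))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 148),
                         trach = rep(TRUE, 148), hr_before = rep(TRUE, 148)),
           expected = list(vent = rep(TRUE, 148)))
    },
    "short-vent-delete" = {
      vent <- c(rep(FALSE, 24), rep(TRUE, 6), rep(FALSE, 24))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 54),
                         trach = rep(FALSE, 54), hr_before = rep(TRUE, 54)),
           expected = list(vent = rep(FALSE, 54)))
    },
    "short-vent-start" = {
      vent <- c(rep(TRUE, 6), rep(FALSE, 48))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 54),
                         trach = rep(FALSE, 54),
                         hr_before = c(rep(FALSE, 6), rep(TRUE, 48))),
           expected = list(vent = vent))
    },
    "trach-decannulation" = {
      vent <- c(rep(TRUE, 100), rep(FALSE, 100))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 200),
                         trach = rep(TRUE, 200), death_bin = NA),
           expected = list(n_events = 0L))
    },
    "procedural-reintubation" = {
      vent <- c(rep(TRUE, 50), rep(FALSE, 60), rep(TRUE, 50))
      hr <- rep(TRUE, 160)
      hr[99:110] <- FALSE  # off-unit during the hour before re-intubation
      list(inputs = list(vent = vent, hr_near = hr,
                         trach = rep(FALSE, 160), death_bin = NA),
           expected = list(labels = "success", bins = 51L))
    },
    "death-censored-ef" = {
      vent <- c(rep(TRUE, 50), rep(FALSE, 150))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 200),
                         trach = rep(FALSE, 200), death_bin = 150L),
           expected = list(labels = "uncertain", bins = 51L))
    },
    "label-augmentation" = {
      vent <- c(rep(TRUE, 50), rep(FALSE, 30), rep(TRUE, 40))
      list(inputs = list(vent = vent, hr_near = rep(TRUE, 120),
                         trach = rep(FALSE, 120), death_bin = NA),
           expected = list(labels = "failure", bins = 51L,
                           positive_bins = 45:51))
    },
    "pre2010-era" = {
      state <- list(mode = 2, peep = 5, pressure_support = 8, fio2 = 0.3,
                    rr = 16, tv = 450, minute_volume = 7, pf = 300,
                    paco2 = 40, gcs = 15, map = 80, norepinephrine = 0,
                    inotrope = 0, lactate = 1)
      list(inputs = list(state = state),
           expected = list(score_pre2010 = 0L, score_post2010 = 9L))
    },
    stop("unknown fixture scenario: ", scenario)
  )
}
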