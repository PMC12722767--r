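test_that("Severinghaus/Ellis round-trip is exact to 1e-6", {
  s <- seq(0.5, 0.999, by = 0.0005)
  p <- ellis_pao2(s)
  expect_lt(max(abs(severinghaus(p) - s)), 1e-6)
  # monotone
  expect_true(all(diff(p) > 0))
  # P50 of the standard curve is near 26-27 mmHg
  expect_equal(severinghaus(ellis_pao2(0.5)), 0.5, tolerance = 1e-9)
  expect_true(ellis_pao2(0.5) > 25 && ellis_pao2(0.5) < 28)
  expect_warning(ellis_pao2(1.0), "clamped")
  expect_error(ellis_pao2(0), "positive")
})

test_that("SpO2 percentile smoother matches hand-computed windows", {
  expect_equal(smooth_spo2(rep(97, 20)), rep(97, 20))
  x <- c(90, 96, 97, 98)
  # every bin's window covers all four values (half-width 3)
  expect_equal(smooth_spo2(x), rep(bf_quantile7(x, 0.75), 4))
  expect_equal(bf_quantile7(x, 0.75), 97.25)
  single <- c(NA, NA, 94, NA, NA)
  expect_equal(smooth_spo2(single), rep(94, 5))
  expect_true(all(is.na(smooth_spo2(rep(NA_real_, 5)))))
})

test_that("PaO2 sample weights follow the printed sigmoid", {
  expect_equal(pao2_sample_weight(110), 60)
  expect_equal(pao2_sample_weight(1e6), 10)
  expect_equal(pao2_sample_weight(70), 10 + 100 / (1 + exp(0.025 * (70 - 110))))
  expect_equal(round(pao2_sample_weight(70), 1), 83.1)
})

test_that("polynomial expansion has 120 deterministic monomials", {
  X <- matrix(rnorm(14), 2, 7)
  P <- pao2_feature_vector(X)
  expect_equal(ncol(P), choose(7 + 3, 3))
  # all-zero base vector -> only the bias monomial is nonzero
  P0 <- pao2_feature_vector(matrix(0, 1, 7))
  expect_equal(sum(P0 != 0), 1L)
  expect_equal(unname(P0[1, "1"]), 1)
  # determinism
  expect_identical(pao2_feature_vector(X), P)
})

make_ellis_world_stays <- function(n_stays, seed, ph_shift = 0) {
  # PaO2 generated exactly on the dissociation curve (optionally pH-shifted);
  # ABGA panels arrive at irregular, clinically realistic intervals
  set.seed(seed)
  lapply(seq_len(n_stays), function(i) {
    n <- 150
    s <- pmin(0.995, pmax(0.7, 0.93 + cumsum(stats::rnorm(n, 0, 0.004))))
    ph <- 7.4 + cumsum(stats::rnorm(n, 0, 0.002))
    pao2 <- ellis_pao2(s) * exp(-ph_shift * (ph - 7.4))
    tt <- 5 * (seq_len(n) - 1)
    abga <- sort(sample(2:(n - 1), 10))
    stay_record(paste0("el", i), 0, 5 * n, list(
      hr = data.frame(time = tt, value = 80),
      spo2 = data.frame(time = tt, value = s),
      pao2 = data.frame(time = tt[abga], value = pao2[abga]),
      sao2 = data.frame(time = tt[abga], value = s[abga]),
      ph = data.frame(time = tt[abga], value = ph[abga])))
  })
}

test_that("nested PaO2 estimator recovers an Ellis-generated world", {
  stays <- make_ellis_world_stays(24, seed = 31)
  sc <- default_schema()
  grids <- lapply(stays, build_grid, schema = sc)
  est <- fit_pao2_estimator(grids[1:16], grids[17:24])
  # validation-sample RMSE of the meta model vs the Ellis inversion of the
  # current SpO2 at the same eligible time points
  pred <- pao2_estimator_validation(grids[17:24], est)
  rmse <- function(e) sqrt(mean(e^2))
  expect_lt(rmse(pred$meta - pred$y), rmse(pred$ellis - pred$y) + 1.0)
  # meta model uses the prior-error context at least as well as the base
  expect_lte(rmse(pred$meta - pred$y), rmse(pred$base - pred$y) + 0.5)
})

test_that("estimator refuses tiny training sets and track sources are right", {
  stays <- make_ellis_world_stays(3, seed = 32)
  sc <- default_schema()
  grids <- lapply(stays, build_grid, schema = sc)
  short <- lapply(grids[1], function(g) g)
  expect_error(fit_pao2_estimator(short, grids[2]), "< 50 eligible")

  g <- grids[[1]]
  tr <- estimate_pao2_track(g, NULL, sc)
  first_meas <- min(which(g$measured$pao2 == 1L))
  expect_true(all(tr$source[seq_len(first_meas - 1)] == "forward_fill"))
  expect_equal(tr$source[first_meas], "measured")
  expect_equal(tr$pao2_est[first_meas], g$values$pao2[first_meas])
  expect_true(all(tr$source[(first_meas + 1):g$n_steps] %in%
                    c("model", "measured")))
  # stay without any PaO2 -> all forward_fill
  st0 <- toy_stay(60)
  g0 <- build_grid(st0, sc)
  expect_true(all(estimate_pao2_track(g0, NULL, sc)$source == "forward_fill"))
})

test_that("FIO2 rule cascade follows its precedence order", {
  sc <- default_schema()
  n_vent <- rep(FALSE, 25)
  # no oxygen variables -> ambient air
  g <- build_grid(toy_stay(120), sc)
  expect_true(all(estimate_fio2_track(g, rep(FALSE, g$n_steps)) == 0.21))
  # ventilated with fresh ventilator FIO2 -> rule 1
  st <- toy_stay(120, extra = list(
    fio2 = data.frame(time = c(0, 50), value = 0.6)))
  g <- build_grid(st, sc)
  vent <- rep(TRUE, g$n_steps)
  f <- estimate_fio2_track(g, vent)
  expect_equal(f[11], 0.6)  # bin 11 starts at 50 min, measurement 10 min old
  # stale (> 30 min) ventilator FIO2 falls through to ambient
  expect_equal(f[9], 0.21)  # bin 9 starts 40 min after the t=0 measurement
  # supplemental beats high-flow within 12 h
  st2 <- toy_stay(400, extra = list(
    suppl_fio2 = data.frame(time = 0, value = 0.35),
    highflow_fio2 = data.frame(time = 300, value = 0.5)))
  g2 <- build_grid(st2, sc)
  f2 <- estimate_fio2_track(g2, rep(FALSE, g2$n_steps))
  expect_equal(f2[73], 0.35)  # 6 h in: supplemental takes precedence
  # NIV mode admits the ventilator FIO2 even when not "ventilated"
  st3 <- toy_stay(60, extra = list(
    vent_mode = data.frame(time = 0, value = 4),
    fio2 = data.frame(time = 0, value = 0.45)))
  g3 <- build_grid(st3, sc)
  expect_equal(estimate_fio2_track(g3, rep(FALSE, g3$n_steps))[3], 0.45)
})

test_that("P/F smoothing preserves constants and matches a kernel-sum oracle", {
  expect_equal(pf_track(rep(84, 50), rep(0.21, 50)), rep(400, 50))
  set.seed(9)
  x <- stats::runif(50, 100, 400)
  bw <- 5
  sm <- nadaraya_watson(x, bw)
  oracle <- vapply(seq_len(50), function(t) {
    w <- exp(-0.5 * ((seq_len(50) - t) / bw)^2)
    w[abs(seq_len(50) - t) > ceiling(4 * bw)] <- 0  # same finite reach
    sum(w * x) / sum(w)
  }, 0)
  expect_equal(sm, oracle, tolerance = 1e-10)
  # zero bandwidth reproduces the raw ratios
  expect_equal(nadaraya_watson(x, 0), x)
  # uniform time shift invariance
  expect_equal(nadaraya_watson(c(NA, x), 5)[-1], nadaraya_watson(x, 5),
               tolerance = 1e-6)
})

test_that("oxygenation estimates never leak from the future", {
  co <- cached_cohort(6, seed = 5)
  sc <- default_schema()
  stay <- co$stays[[2]]
  g <- build_grid(stay, sc)
  cut <- floor(g$n_steps / 2)
  cut_min <- g$grid_start + 5 * cut
  trunc_obs <- lapply(stay$observations, function(o)
    o[o$time < cut_min, , drop = FALSE])
  stay2 <- stay_record(stay$patient_id, stay$admission_time,
                       stay$discharge_time, trunc_obs)
  g2 <- build_grid(stay2, sc)
  tr1 <- estimate_pao2_track(g, NULL, sc)
  tr2 <- estimate_pao2_track(g2, NULL, sc)
  keep <- seq_len(min(g2$n_steps, cut) - 4)  # clear of the smoother edge
  expect_equal(tr1$pao2_est[keep], tr2$pao2_est[keep], tolerance = 1e-9)
})
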