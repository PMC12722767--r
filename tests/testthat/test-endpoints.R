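test_that("annotate_rf applies the 2/3 forward-window rule", {
  n <- 60
  no_vent <- rep(FALSE, n)
  expect_true(all(annotate_rf(rep(150, n), no_vent) == "moderate"))
  expect_true(all(annotate_rf(rep(400, n), no_vent) == "stable"))
  expect_true(all(annotate_rf(rep(90, n), no_vent) == "severe"))
  expect_true(all(annotate_rf(rep(250, n), no_vent) == "mild"))
  # 7 of 12 bins below 200 fails the two-thirds requirement
  pf <- rep(c(rep(150, 7), rep(350, 5)), 5)
  expect_equal(annotate_rf(pf, rep(FALSE, length(pf)))[1], "stable")
  # 8 of 12 passes
  pf8 <- rep(c(rep(150, 8), rep(350, 4)), 5)
  expect_equal(annotate_rf(pf8, rep(FALSE, length(pf8)))[1], "moderate")
  # unknown when two thirds of the window lack an estimate
  pfna <- c(rep(NA_real_, 20), rep(400, 40))
  expect_equal(annotate_rf(pfna, no_vent)[1], "unknown")
})

test_that("ventilation consistency gates severity qualification", {
  n <- 24
  pf <- rep(150, n)
  vent <- rep(TRUE, n)
  # ventilated with dense PEEP < 4: bins do not qualify -> stable
  low_peep <- annotate_rf(pf, vent, peep = rep(3, n),
                          peep_avail = rep(TRUE, n))
  expect_true(all(low_peep == "stable"))
  ok_peep <- annotate_rf(pf, vent, peep = rep(8, n),
                         peep_avail = rep(TRUE, n))
  expect_true(all(ok_peep == "moderate"))
  # PEEP not densely available: condition passes
  no_peep <- annotate_rf(pf, vent, peep = rep(3, n),
                         peep_avail = rep(FALSE, n))
  expect_true(all(no_peep == "moderate"))
})

test_that("right-edge correction extends events along satisfying bins only", {
  fx <- make_fixtures("right-edge")
  out <- correct_right_edges(fx$inputs$rf_status, fx$inputs$pf)
  expect_identical(out, fx$expected$rf_status)
  # no extension when the edge bin fails the criterion
  status <- c(rep("moderate", 10), rep("stable", 5))
  pf <- c(rep(150, 10), rep(250, 5))
  expect_identical(correct_right_edges(status, pf), status)
  # extension never crosses a missing-P/F bin
  pf_gap <- c(rep(150, 10), NA, rep(150, 4))
  expect_identical(correct_right_edges(status, pf_gap), status)
})

test_that("sandwich post-processing merges gaps and deletes short events", {
  fx <- make_fixtures("sandwich-merge")
  expect_identical(postprocess_rf(fx$inputs$rf_status),
                   fx$expected$rf_status)
  fx2 <- make_fixtures("short-event-delete")
  expect_identical(postprocess_rf(fx2$inputs$rf_status),
                   fx2$expected$rf_status)
  fx3 <- make_fixtures("gap-too-long")
  expect_identical(postprocess_rf(fx3$inputs$rf_status),
                   fx3$expected$rf_status)
})

test_that("postprocess_rf is idempotent on random tracks", {
  set.seed(12)
  lv <- c("stable", "mild", "moderate", "severe", "unknown")
  for (i in 1:200) {
    x <- sample(lv, 150, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.05, 0.05))
    once <- postprocess_rf(x)
    expect_identical(postprocess_rf(once), once)
  }
})

test_that("ventilation vote reproduces the point table", {
  v <- vote_ventilation(FALSE, TRUE, 2, 450, FALSE, FALSE)
  expect_equal(v$score, 4L)  # EtCO2 +2, mode 2 +1, TV +1
  expect_true(v$vent)
  v2 <- vote_ventilation(FALSE, FALSE, 4, NA, FALSE, TRUE)
  expect_equal(v2$score, -3L)  # NIV -2, mask -1
  expect_false(v2$vent)
  expect_equal(vote_ventilation(FALSE, FALSE, NA, NA, FALSE, FALSE)$score, 0L)
  # era bonus alone cannot trip the cutoff
  expect_false(vote_ventilation(TRUE, FALSE, 3, NA, FALSE, FALSE)$vent)
  # invasive airway +2 with EtCO2 +2 reaches the cutoff
  expect_true(vote_ventilation(FALSE, TRUE, NA, NA, TRUE, FALSE)$vent)
})

test_that("vote matches a brute-force oracle on random bin states", {
  set.seed(77)
  for (i in 1:300) {
    era <- sample(c(TRUE, FALSE), 1)
    et <- sample(c(TRUE, FALSE), 1)
    mode <- sample(c(NA, 1:6), 1)
    tv <- sample(c(NA, 0, 450), 1)
    inv <- sample(c(TRUE, FALSE), 1)
    noninv <- sample(c(TRUE, FALSE), 1)
    got <- vote_ventilation(era, et, mode, tv, inv, noninv)
    expect_equal(got$score, bf_vote(era, et, mode, tv, inv, noninv))
    expect_equal(got$vent, got$score >= 4)
  }
})

test_that("ventilation post-processing closes and deletes per the rules", {
  for (sc in c("micro-gap", "offunit-gap", "trach-gap", "short-vent-delete",
               "short-vent-start")) {
    fx <- make_fixtures(sc)
    out <- postprocess_ventilation(fx$inputs$vent, fx$inputs$hr_near,
                                   fx$inputs$trach, fx$inputs$hr_before)
    expect_identical(out, fx$expected$vent, label = sc)
  }
})

test_that("postprocess_ventilation is idempotent on random tracks", {
  set.seed(13)
  for (i in 1:200) {
    n <- 200
    vent <- stats::runif(n) < stats::filter(stats::runif(n), rep(1, 9) / 9,
                                            circular = TRUE)
    vent <- as.logical(ifelse(is.na(vent), FALSE, vent))
    hr_near <- stats::runif(n) > 0.2
    trach <- rep(sample(c(TRUE, FALSE), 1), n)
    hr_before <- c(FALSE, rep(TRUE, n - 1))
    once <- postprocess_ventilation(vent, hr_near, trach, hr_before)
    expect_identical(postprocess_ventilation(once, hr_near, trach, hr_before),
                     once)
  }
})

test_that("REXT violation scores match the printed criteria", {
  base <- list(mode = 3, peep = 5, pressure_support = 8, fio2 = 0.3, rr = 16,
               tv = 450, minute_volume = 7, pf = 300, paco2 = 40, gcs = 15,
               map = 80, norepinephrine = 0, inotrope = 0, lactate = 1)
  expect_equal(rext_violation_score(base), 0L)
  st <- base; st$peep <- 8; st$fio2 <- 0.5
  expect_equal(rext_violation_score(st), 6L)
  st2 <- base; st2$mode <- 2
  expect_gte(rext_violation_score(st2), 9L)
  fx <- make_fixtures("pre2010-era")
  expect_equal(rext_violation_score(fx$inputs$state, era_pre2010 = TRUE),
               fx$expected$score_pre2010)
  expect_equal(rext_violation_score(fx$inputs$state, era_pre2010 = FALSE),
               fx$expected$score_post2010)
})

test_that("REXT scores match a brute-force oracle on random states", {
  set.seed(21)
  for (i in 1:300) {
    st <- list(mode = sample(c(NA, 1:6), 1),
               peep = sample(c(NA, 4, 8, 12), 1),
               pressure_support = sample(c(NA, 6, 12), 1),
               fio2 = sample(c(NA, 0.21, 0.5), 1),
               rr = sample(c(NA, 14, 36), 1), tv = sample(c(300, 500), 1),
               minute_volume = sample(c(NA, 6, 12), 1),
               pf = sample(c(NA, 120, 300), 1),
               paco2 = sample(c(NA, 38, 55), 1),
               gcs = sample(c(NA, 6, 15), 1), map = sample(c(55, 80), 1),
               norepinephrine = sample(c(NA, 0, 0.2), 1),
               inotrope = sample(c(NA, 0, 1), 1),
               lactate = sample(c(NA, 1, 3), 1))
    era <- sample(c(TRUE, FALSE), 1)
    expect_equal(rext_violation_score(st, era), bf_rext_score(st, era))
  }
})

test_that("readiness needs 2/3 of the trailing hour below the cutoff", {
  vent <- rep(TRUE, 30)
  ready12 <- annotate_rext(rep(6L, 30), vent)
  expect_false(any(ready12[1:11]))  # a full trailing hour must exist
  expect_true(all(ready12[12:30]))
  alt <- annotate_rext(rep(c(6L, 12L), 15), vent)
  expect_false(any(alt))  # 6 of 12 passing bins < 2/3
  expect_false(any(annotate_rext(rep(6L, 30), rep(FALSE, 30))))
})

test_that("respiratory failure status has no future dependence beyond its window", {
  co <- cached_cohort(6, seed = 5)
  sc <- default_schema()
  st <- grid_stats(co$stays, sc)
  p <- process_stay(co$stays[[2]], sc, st)
  n <- p$grid$n_steps
  cut <- floor(n * 0.7)
  pf_cut <- p$endpoints$pf
  pf_cut[(cut + 1):n] <- NA
  vent <- p$endpoints$vent
  r_full <- annotate_rf(p$endpoints$pf, vent)
  r_cut <- annotate_rf(pf_cut, vent)
  keep <- seq_len(cut - 12)
  expect_identical(r_full[keep], r_cut[keep])
})

test_that("status track and extracted events round-trip", {
  set.seed(5)
  lv <- c("stable", "mild", "moderate", "severe", "unknown")
  x <- sample(lv, 300, replace = TRUE)
  ev <- rf_events(x)
  inside <- rep(FALSE, 300)
  for (i in seq_len(nrow(ev))) inside[ev$start[i]:ev$end[i]] <- TRUE
  expect_identical(inside, x %in% c("moderate", "severe"))
  if (nrow(ev) > 1) {
    expect_true(all(ev$start[-1] > ev$end[-nrow(ev)] + 1))  # maximal runs
  }
})
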