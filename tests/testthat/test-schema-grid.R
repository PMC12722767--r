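test_that("variable_spec enforces its invariants", {
  expect_error(variable_spec("x", "ordinal",
                             imputation_mode = "limited_ffill_fixed"),
               "positive ffill_minutes")
  expect_error(variable_spec("x", "ordinal",
                             severity_levels = list(list(op = "~", value = 1))),
               "malformed")
  sp <- variable_spec("peep", "ordinal", "cmH2O", "limited_ffill_fixed", 5,
                      ffill_minutes = 480)
  expect_s3_class(sp, "variable_spec")
})

test_that("schema JSON round-trips", {
  sc <- default_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(sc, path)
  sc2 <- read_schema(path)
  expect_equal(names(sc2), names(sc))
  expect_equal(sc2$spo2$severity_levels, sc$spo2$severity_levels)
  expect_equal(sc2$peep$ffill_minutes, sc$peep$ffill_minutes)
})

test_that("build_grid follows the bin convention", {
  sc <- default_schema()
  st <- toy_stay(60, extra = list(
    spo2 = data.frame(time = c(0, 7), value = c(0.95, 0.97))))
  g <- build_grid(st, sc)
  expect_equal(g$measured$spo2[1:3], c(1L, 1L, 0L))
  # bin 3 starts at t = 10 min; last observation at 7 min
  expect_equal(g$tsm$spo2[3], 3)
  expect_equal(g$tsm$spo2[1], 0)  # in-bin observation
  # never observed variable
  expect_true(all(g$tsm$pao2 == -1))
  expect_true(all(is.na(g$values$pao2)))
})

test_that("build_grid caps at 28 days and rejects bad input", {
  sc <- default_schema()
  long <- stay_record("long", 0, 31 * 1440, list(
    hr = data.frame(time = seq(0, 30 * 1440, by = 720), value = 80)))
  g <- build_grid(long, sc)
  expect_equal(g$n_steps, 8064L)
  expect_error(build_grid(stay_record("x", 0, 10, list(
    spo2 = data.frame(time = 0, value = 0.97))), sc), "heart-rate")
  expect_error(build_grid(stay_record("x", 0, 10, list(
    hr = data.frame(time = c(0, 5), value = 80),
    bogus = data.frame(time = 0, value = 1))), sc), "not in schema")
})

test_that("same-timestamp duplicates average and latest-in-bin wins", {
  sc <- default_schema()
  st <- toy_stay(30, extra = list(
    map = data.frame(time = c(2, 2, 4), value = c(80, 90, 70))))
  g <- build_grid(st, sc)
  # bin 1 holds mean(80, 90) = 85 at t=2, then 70 at t=4: latest wins
  expect_equal(g$values$map[1], 70)
  st2 <- toy_stay(30, extra = list(
    map = data.frame(time = c(2, 2), value = c(80, 90))))
  expect_equal(build_grid(st2, sc)$values$map[1], 85)
})

test_that("adaptive_horizon matches printed examples and a brute-force oracle", {
  expect_equal(adaptive_horizon(c(60, 60, 60)), 120)
  expect_equal(adaptive_horizon(c(10, 30, 50)), 80)
  expect_equal(adaptive_horizon(5), 10)
  expect_error(adaptive_horizon(numeric()), "interval")
  set.seed(42)
  for (i in 1:200) {
    iv <- stats::runif(sample(1:30, 1), 1, 500)
    expect_equal(adaptive_horizon(iv), bf_adaptive_horizon(iv))
  }
})

test_that("imputation modes behave per contract", {
  sc <- default_schema()
  st <- toy_stay(120, extra = list(
    etco2 = data.frame(time = 33, value = 35),
    peep = data.frame(time = 2, value = 8)))
  g <- build_grid(st, sc)
  gf <- suppressWarnings(impute_grid(g, sc, "feature"))  # no stats: adaptive fallback
  # exact_grid_point: exactly one non-missing bin
  expect_equal(sum(!is.na(gf$values$etco2)), 1L)
  # fixed k = 480 min exceeds this short stay: all bins after obs filled
  expect_true(all(!is.na(gf$values$peep)))
  gd <- suppressWarnings(impute_grid(g, sc, "dense"))
  expect_true(all(!vapply(gd$values, anyNA, TRUE)))
  # never measured -> normal value everywhere in dense mode
  expect_true(all(gd$values$pao2 == sc$pao2$normal_value))
})

test_that("fixed-horizon forward fill stops at k minutes", {
  sc <- list(hr = default_schema()$hr,
             x = variable_spec("x", "ordinal", "u", "limited_ffill_fixed",
                               0, ffill_minutes = 60))
  class(sc) <- "icu_schema"
  st <- stay_record("s", 0, 200, list(
    hr = data.frame(time = seq(0, 180, by = 5), value = 80),
    x = data.frame(time = 0, value = 7)))
  g <- build_grid(st, sc)
  gf <- impute_grid(g, sc, "feature")
  # bins 1..13 (start times 0..60 min) filled; bin 14 (65 min) missing
  expect_true(all(gf$values$x[1:13] == 7))
  expect_true(is.na(gf$values$x[14]))
  gd <- impute_grid(g, sc, "dense")
  expect_equal(gd$values$x[14], 0)
})

test_that("grid invariants hold on simulated stays", {
  co <- cached_cohort(6, seed = 5)
  sc <- default_schema()
  st <- grid_stats(co$stays, sc)
  for (stay in co$stays[1:4]) {
    g <- build_grid(stay, sc)
    gd <- impute_grid(g, sc, "dense", st)
    gf <- impute_grid(g, sc, "feature", st)
    # dense output has zero missing entries
    expect_false(any(vapply(gd$values, anyNA, TRUE)))
    for (v in names(sc)) {
      # feature-missing set equals the dense-normal-value fallback set
      miss <- is.na(gf$values[[v]])
      expect_true(all(gd$values[[v]][miss] == sc[[v]]$normal_value))
      # measured indicator equals a brute-force per-bin count
      obs <- stay$observations[[v]]
      if (!is.null(obs)) {
        bf <- vapply(seq_len(g$n_steps), function(t) {
          lo <- g$grid_start + 5 * (t - 1)
          as.integer(any(obs$time >= lo & obs$time < lo + 5))
        }, 0L)
        expect_equal(g$measured[[v]], bf)
      }
    }
  }
})

test_that("grid_stats serializes and never uses validation data", {
  co <- cached_cohort(6, seed = 5)
  sc <- default_schema()
  st1 <- grid_stats(co$stays[1:3], sc)
  st2 <- grid_stats(co$stays[4:6], sc)
  expect_false(isTRUE(all.equal(st1$median_interval, st2$median_interval)))
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_stats(st1, path)
  rt <- read_grid_stats(path)
  expect_equal(rt$adaptive_horizon, st1$adaptive_horizon, tolerance = 1e-12)
})

test_that("long-format CSV round-trips a cohort", {
  co <- cached_cohort(6, seed = 5)
  op <- withr::local_tempfile(fileext = ".csv")
  sp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co$stays[1:2], op, sp)
  back <- read_cohort_csv(op, sp)
  expect_equal(length(back), 2L)
  i <- match(co$stays[[1]]$patient_id, vapply(back, `[[`, "", "patient_id"))
  expect_equal(back[[i]]$observations$hr$value,
               co$stays[[1]]$observations$hr$value)
  expect_equal(back[[i]]$statics$elective, co$stays[[1]]$statics$elective)
})
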