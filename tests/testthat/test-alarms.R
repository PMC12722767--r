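test_that("alarm silencing and reset follow the hand-walked scenarios", {
  # score above threshold for 6 h straight -> alarms at t and t + 4 h
  n <- 73
  al <- generate_alarms(rep(1, n), rep(FALSE, n), 0.5)
  expect_equal(al, c(1L, 49L))
  # threshold above the maximum score -> silence
  expect_length(generate_alarms(rep(0.4, n), rep(FALSE, n), 0.5), 0)
  # alarm at 1 h, event 2-3 h, high score afterwards -> next alarm 30 min
  # after recovery
  n <- 60
  scores <- rep(1, n)
  in_event <- rep(FALSE, n)
  in_event[25:36] <- TRUE  # event from 2 h to 3 h
  al2 <- generate_alarms(scores, in_event, 0.5)
  expect_equal(al2[1:2], c(1L, 43L))  # recovery at 37, reactivation 37 + 6
  # no alarms while in the event
  expect_false(any(al2 %in% 25:36))
})

test_that("event metrics match examples and the brute-force oracle", {
  # single alarm 20 h before the only onset
  m <- event_metrics(list(c(10L)), list(data.frame(start = 250L)))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # alarm 30 h before onset: outside the horizon
  m2 <- event_metrics(list(c(10L)), list(data.frame(start = 370L)))
  expect_equal(m2$recall, 0)
  expect_equal(m2$precision, 0)
  # no alarms -> precision missing
  m3 <- event_metrics(list(integer()), list(data.frame(start = 5L)))
  expect_true(is.na(m3$precision))
  set.seed(41)
  for (i in 1:300) {
    n_stay <- sample(1:4, 1)
    al <- lapply(seq_len(n_stay), function(j)
      sort(sample(1:500, sample(0:6, 1))))
    ev <- lapply(seq_len(n_stay), function(j)
      data.frame(start = sort(sample(1:500, sample(0:3, 1)))))
    got <- event_metrics(al, ev)
    bf <- bf_event_metrics(al, ev)
    expect_equal(got$recall, bf$recall)
    expect_equal(got$precision, bf$precision)
    expect_equal(got$tp, bf$tp)
    expect_equal(got$fp, bf$fp)
  }
})

make_perfect_stays <- function(n_stays = 6, seed = 43) {
  set.seed(seed)
  lapply(seq_len(n_stays), function(i) {
    n <- 600
    in_event <- rep(FALSE, n)
    onset <- sample(200:400, 1)
    in_event[onset:(onset + 50)] <- TRUE
    scores <- rep(0, n)
    scores[max(1, onset - 100):(onset - 1)] <- 1  # high only before events
    list(scores = scores, in_event = in_event,
         events = data.frame(start = onset))
  })
}

test_that("event PR curve is exact for a perfect scorer and grid-stable", {
  stays <- make_perfect_stays()
  pr <- event_pr_curve(stays, thresholds = seq(0.05, 0.95, by = 0.05))
  expect_equal(pr$auprc, 1)
  # constant score: every stay alarms every 4 h from bin 1 -> full recall
  const <- lapply(stays, function(s) { s$scores <- rep(0.7, 600); s })
  prc <- event_pr_curve(const, thresholds = 0.5)
  expect_equal(prc$curve$recall, 1)
  expect_lt(prc$curve$precision, 1)
})

test_that("earliness fractions bucket lead times and are non-increasing", {
  ev <- list(data.frame(start = 300L, stable_before = Inf))
  # alarm 12 h before onset counts for every cutoff up to 10 h
  fr <- earliness(list(c(300L - 144L)), ev, cutoffs_hours = c(0, 2, 5, 10))
  expect_equal(unname(fr), c(1, 1, 1, 1))
  fr2 <- earliness(list(c(299L)), ev, cutoffs_hours = c(0, 2, 5, 10))
  expect_equal(unname(fr2), c(1, 0, 0, 0))
  set.seed(47)
  al <- list(sort(sample(1:280, 5)))
  fr3 <- earliness(al, ev, cutoffs_hours = c(0, 2, 5, 10, 20))
  expect_true(all(diff(fr3) <= 0))
  # stability filter drops unstable events
  ev_unstable <- list(data.frame(start = 300L, stable_before = 60))
  expect_true(all(is.na(earliness(list(200L), ev_unstable))))
})

test_that("detectable prevalence is a seeded Monte-Carlo chance floor", {
  none <- list(list(scores = rep(0, 100), in_event = rep(FALSE, 100),
                    events = data.frame(start = integer())))
  expect_equal(detectable_prevalence(none), 0)
  stays <- make_perfect_stays()
  d1 <- detectable_prevalence(stays, n_sim = 10, seed = 5)
  d2 <- detectable_prevalence(stays, n_sim = 10, seed = 5)
  expect_identical(d1, d2)
  expect_gt(d1, 0)
  expect_lt(d1, 1)
})

test_that("prevalence correction: identity, formula, involution", {
  curve <- data.frame(threshold = c(0.2, 0.5), recall = c(1, 0.5),
                      precision = c(0.4, 0.6), tp = c(20, 6), fp = c(30, 4))
  same <- prevalence_correct(curve, 0.3, 0.3)
  expect_equal(same$precision, curve$precision)
  # s = (1/0.2 - 1)/(1/0.5 - 1) = 4
  corr <- prevalence_correct(curve, 0.5, 0.2)
  expect_equal(corr$precision[1], 20 / (20 + 4 * 30))
  expect_equal(corr$recall, curve$recall)
  # involution with swapped prevalences
  back <- prevalence_correct(corr, 0.2, 0.5)
  expect_equal(back$precision, curve$precision, tolerance = 1e-12)
  expect_equal(back$fp, curve$fp, tolerance = 1e-12)
  expect_error(prevalence_correct(curve, 0, 0.5), "between 0 and 1")
})

test_that("subgroup bootstrap flags a planted worse-off group only", {
  set.seed(49)
  good <- make_perfect_stays(10, seed = 51)
  bad <- lapply(make_perfect_stays(10, seed = 53), function(s) {
    s$scores <- stats::runif(length(s$scores))  # pure noise: uninformative
    s
  })
  stays <- c(good, bad)
  groups <- rep(c("g_good", "g_bad"), each = 10)
  out <- subgroup_bootstrap(stays, groups, target_recall = 0.8, n_boot = 30,
                            seed = 9)
  expect_true(out$worse_off[out$group == "g_bad"])
  expect_false(out$worse_off[out$group == "g_good"])
  # identical groups -> no flags
  out2 <- subgroup_bootstrap(c(good, good),
                             rep(c("a", "b"), each = 10), n_boot = 20,
                             seed = 11)
  expect_false(any(out2$worse_off))
})
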