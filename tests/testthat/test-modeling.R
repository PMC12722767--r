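# deterministic separable toy problem: one informative feature + noise
toy_problem <- function(n = 1200, p_noise = 5, seed = 101) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- as.numeric(stats::runif(n) < stats::plogis(3 * x))
  X <- cbind(signal = x, matrix(stats::rnorm(n * p_noise), n,
                                dimnames = list(NULL, paste0("noise", 1:p_noise))))
  list(X = X, y = y)
}

test_that("make_splits partitions patients correctly and reproducibly", {
  ids <- sprintf("p%03d", 1:125)
  sp <- make_splits(ids, test_fraction = 0.2, n_replicates = 5, seed = 4)
  expect_equal(length(sp$test), 25L)
  for (r in sp$replicates) {
    expect_equal(length(r$train), 80L)
    expect_equal(length(r$validation), 20L)
    expect_length(intersect(r$train, r$validation), 0)
    expect_length(intersect(r$train, sp$test), 0)
    expect_length(intersect(r$validation, sp$test), 0)
  }
  expect_identical(make_splits(ids, seed = 4), sp)
  expect_error(make_splits(ids[1:5]), ">= 10")
})

test_that("gbt learns separable data, not shuffled labels, deterministically", {
  tp <- toy_problem()
  tr <- 1:800; va <- 801:1200
  fit <- gbt_fit(tp$X[tr, ], tp$y[tr], tp$X[va, ], tp$y[va], nrounds = 120L,
                 min_leaf = 20L)
  expect_gt(max(fit$metric_trace), 0.9)
  set.seed(55)
  ysh <- sample(tp$y[tr])
  fit_sh <- gbt_fit(tp$X[tr, ], ysh, tp$X[va, ], tp$y[va], nrounds = 60L,
                    min_leaf = 20L)
  expect_lt(max(fit_sh$metric_trace), mean(tp$y[va]) + 0.12)
  # determinism: identical refit reproduces the early-stopping round
  fit2 <- gbt_fit(tp$X[tr, ], tp$y[tr], tp$X[va, ], tp$y[va], nrounds = 120L,
                  min_leaf = 20L)
  expect_equal(fit2$best_iter, fit$best_iter)
  expect_equal(predict(fit2, tp$X[va, ]), predict(fit, tp$X[va, ]))
  expect_error(gbt_fit(tp$X[tr, ], rep(1, 800)), "single-class")
})

test_that("gbt routes missing values natively", {
  tp <- toy_problem(seed = 7)
  X <- tp$X
  X[sample(length(X), length(X) / 4)] <- NA
  fit <- gbt_fit(X[1:800, ], tp$y[1:800], X[801:1200, ], tp$y[801:1200],
                 nrounds = 80L, min_leaf = 20L)
  expect_gt(max(fit$metric_trace), 0.75)
  pr <- predict(fit, X[801:1200, ])
  expect_false(anyNA(pr))
})

test_that("TreeSHAP is additive and ranks the planted signal first", {
  tp <- toy_problem(seed = 13)
  fit <- gbt_fit(tp$X[1:800, ], tp$y[1:800], nrounds = 40L, min_leaf = 20L)
  sh <- gbt_shap(fit, tp$X[801:900, ])
  marg <- predict(fit, tp$X[801:900, ], type = "margin")
  expect_equal(rowSums(sh$phi) + sh$base, marg, tolerance = 1e-9)
  imp <- colMeans(abs(sh$phi))
  expect_equal(names(which.max(imp)), "signal")
  expect_gt(imp["signal"], 3 * max(imp[-1]))
})

test_that("variable-level importance is a max over derived features", {
  tp <- toy_problem(seed = 17)
  dt <- data.table::as.data.table(tp$X)
  dt <- cbind(data.table::data.table(
    stay = rep(sprintf("s%02d", 1:30), each = 40), bin = 1L), dt)
  labels <- ifelse(tp$y == 1, "positive", "negative")
  split <- list(train = sprintf("s%02d", 1:20),
                validation = sprintf("s%02d", 21:30))
  m <- train_task_model(dt, labels, split, min_leaf = 20L, nrounds = 60L)
  # duplicated-column manifest: signal + noise1 belong to variable "v1"
  man <- data.frame(name = c("signal", paste0("noise", 1:5)),
                    category = "current",
                    variable = c("v1", "v1", "v2", "v2", "v3", "v3"))
  vi <- shap_variable_importance(m, dt[dt$stay %in% split$validation, ], man)
  expect_equal(names(vi$variable_importance)[1], "v1")
  expect_equal(vi$variable_importance[["v1"]],
               max(vi$feature_importance[c("signal", "noise1")]))
})

test_that("greedy forward selection finds the generative variable first", {
  tp <- toy_problem(n = 1500, seed = 23)
  dt <- data.table::as.data.table(tp$X)
  dt <- cbind(data.table::data.table(
    stay = rep(sprintf("s%02d", 1:50), each = 30), bin = 1L), dt)
  labels <- ifelse(tp$y == 1, "positive", "negative")
  splits <- make_splits(sprintf("s%02d", 1:50), test_fraction = 0.1,
                        n_replicates = 3, seed = 2)
  vf <- as.list(stats::setNames(colnames(tp$X), colnames(tp$X)))
  gs <- greedy_forward_select(c("signal", "noise1", "noise2"), vf, dt, labels,
                              splits, max_steps = 3, nrounds = 30L,
                              min_leaf = 20L)
  expect_true(all(vapply(gs$traces, function(tr) tr[1] == "signal", TRUE)))
  expect_equal(gs$mrr[["signal"]], 1)
  expect_equal(gs$ranking[1], "signal")
  expect_equal(length(gs$traces[[1]]), 3L)
  # MRR arithmetic: rank 2 in every split -> 0.5
  fake <- list(c("a", "b"), c("a", "b"))
  ranks <- vapply(c("a", "b"), function(v)
    mean(vapply(fake, function(tr) 1 / match(v, tr), 0)), 0)
  expect_equal(unname(ranks["b"]), 0.5)
  expect_error(greedy_forward_select(character(), vf, dt, labels, splits),
               "empty")
})

test_that("greedy first step equals exhaustive search on a tiny problem", {
  tp <- toy_problem(n = 900, seed = 29)
  dt <- data.table::as.data.table(tp$X[, 1:4])
  dt <- cbind(data.table::data.table(
    stay = rep(sprintf("s%02d", 1:30), each = 30), bin = 1L), dt)
  labels <- ifelse(tp$y == 1, "positive", "negative")
  splits <- make_splits(sprintf("s%02d", 1:30), test_fraction = 0.1,
                        n_replicates = 1, seed = 3)
  cand <- colnames(tp$X)[1:4]
  vf <- as.list(stats::setNames(cand, cand))
  gs <- greedy_forward_select(cand, vf, dt, labels, splits, max_steps = 1,
                              nrounds = 25L, min_leaf = 20L)
  # exhaustive single-variable scan with the same fitter
  sp <- splits$replicates[[1]]
  y <- ifelse(labels == "positive", 1, 0)
  tr <- dt$stay %in% sp$train; va <- dt$stay %in% sp$validation
  sc <- vapply(cand, function(v) {
    f <- gbt_fit(as.matrix(dt[, v, with = FALSE])[tr, , drop = FALSE], y[tr],
                 as.matrix(dt[, v, with = FALSE])[va, , drop = FALSE], y[va],
                 nrounds = 25L, min_leaf = 20L)
    max(f$metric_trace)
  }, 0)
  expect_equal(gs$traces[[1]][1], names(which.max(sc)))
})

test_that("calibration report matches closed forms and brute-force binning", {
  y <- c(rep(1, 40), rep(0, 60))
  expect_equal(calibration_report(y, y)$brier, 0)
  p <- 0.4
  cr <- calibration_report(rep(p, 100), y)
  expect_equal(cr$brier, p * (1 - p))
  set.seed(31)
  s <- stats::runif(500); l <- as.numeric(stats::runif(500) < 0.3)
  cr2 <- calibration_report(s, l, bin_size = 0.05)
  breaks <- seq(min(s), max(s) + 0.05, by = 0.05)
  for (k in seq_len(nrow(cr2$curve))) {
    sel <- findInterval(s, breaks, rightmost.closed = TRUE) ==
      findInterval(cr2$curve$mean_score[k], breaks, rightmost.closed = TRUE)
    expect_equal(cr2$curve$observed[k], mean(l[sel]))
    expect_equal(cr2$curve$n[k], sum(sel))
  }
  expect_equal(cr2$brier, mean((s - l)^2))
})

test_that("time-point AUPRC and AUROC match brute-force references", {
  set.seed(37)
  for (i in 1:20) {
    s <- round(stats::runif(80), 2)  # ties on purpose
    l <- as.numeric(stats::runif(80) < 0.4)
    if (sum(l) == 0 || sum(l) == 80) next
    expect_equal(auprc(s, l), bf_auprc(s, l), tolerance = 1e-12)
    expect_equal(auroc(s, l),
                 as.numeric(stats::wilcox.test(s[l == 1], s[l == 0],
                                               exact = FALSE)$statistic) /
                   (sum(l) * sum(1 - l)), tolerance = 1e-12)
  }
  expect_equal(auprc(c(1, 0.5, 0), c(1, 0, 0)), 1)
})

test_that("clinical baselines expose the documented scores", {
  co <- cached_cohort(8, seed = 19)
  sc <- default_schema()
  st <- grid_stats(co$stays, sc)
  ps <- lapply(co$stays, process_stay, schema = sc, stats = st)
  feat <- data.table::rbindlist(lapply(ps, `[[`, "features"))
  lab <- unlist(lapply(ps, function(p) p$labels$RF[p$feature_bins]))
  ids <- vapply(co$stays, `[[`, "", "patient_id")
  split <- list(train = ids[1:6], validation = ids[7:8])
  bl <- clinical_baselines(feat, lab, split)
  # S/F ordering: lower saturation on more oxygen ranks riskier
  sf <- function(spo2, fio2) -(spo2 * 100) / fio2
  expect_gt(sf(0.92, 0.4), sf(0.98, 0.21))
  expect_equal(bl$sf_ratio, -(feat$spo2_cur * 100) / feat$fio2_est)
  expect_length(bl$tree, nrow(feat))
  # EF baseline is the shared REXT violation-score code path
  expect_identical(ps[[1]]$endpoints$rext_score,
                   rext_violation_score(list(
                     mode = ps[[1]]$endpoints$vent_mode_now,
                     peep = ps[[1]]$grid_dense$values$peep,
                     pressure_support = ps[[1]]$grid_dense$values$pressure_support,
                     fio2 = ps[[1]]$endpoints$fio2_est,
                     rr = ps[[1]]$grid_dense$values$rr,
                     tv = ps[[1]]$grid_dense$values$tv,
                     minute_volume = ps[[1]]$grid_dense$values$minute_volume,
                     pf = ps[[1]]$endpoints$pf,
                     paco2 = ps[[1]]$grid_dense$values$paco2,
                     gcs = ps[[1]]$grid_dense$values$gcs,
                     map = ps[[1]]$grid_dense$values$map,
                     norepinephrine = ps[[1]]$grid_dense$values$norepinephrine,
                     inotrope = ps[[1]]$grid_dense$values$inotrope,
                     lactate = ps[[1]]$grid_dense$values$lactate),
                     era_pre2010 = isTRUE(co$stays[[1]]$statics$era_pre2010)))
})
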