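# End-to-end glue: simulate/ingest -> grid -> annotate -> label ->
# featurize -> train -> score -> evaluate.

#' Process one stay through gridding, annotation, labels and features
#'
#' @param stay A [stay_record].
#' @param schema,stats Schema and training statistics.
#' @param pao2_estimator Optional nested PaO2 estimator (Ellis fallback
#'   otherwise).
#' @param feature_stride Evaluate features every this-many bins (1 = every
#'   5 min).
#' @param rf_thresholds Severity cutoffs (sensitivity configurations swap
#'   these).
#' @return List with `grid`, `grid_dense`, `endpoints`, `labels`,
#'   `features`.
#' @export
process_stay <- function(stay, schema = default_schema(), stats = NULL,
                         pao2_estimator = NULL, feature_stride = 6L,
                         rf_thresholds = RF_THRESHOLDS) {
  grid <- build_grid(stay, schema)
  grid_dense <- impute_grid(grid, schema, "dense", stats)
  grid_feat <- impute_grid(grid, schema, "feature", stats)
  ep <- annotate_endpoints(grid, grid_dense, pao2_estimator, schema, stats,
                           rf_thresholds)
  lab <- label_tasks(ep, grid)
  bins <- seq(1L, grid$n_steps, by = feature_stride)
  feat <- assemble_features(grid_feat, grid_dense, ep, schema, stats, bins)
  list(grid = grid, grid_dense = grid_dense, endpoints = ep, labels = lab,
       features = feat, feature_bins = bins)
}

#' Run the full monitoring pipeline on a cohort
#'
#' Splits the cohort by patient, computes training statistics from the
#' first replicate's training stays only, processes every stay, trains one
#' gradient-boosted model per requested task on the first replicate, and
#' scores all test stays (scores at strided bins are carried forward onto
#' the 5-min grid for the alarm policy).
#'
#' @param stays List of [stay_record]s.
#' @param tasks Subset of `c("RF", "MVStart", "MVEnd", "EF")`.
#' @param seed Seed for the split plan.
#' @param feature_stride Feature evaluation stride in bins.
#' @param schema Schema.
#' @param fit_pao2 Fit the nested PaO2 estimator (slower); otherwise the
#'   Severinghaus-Ellis fallback is used for P/F annotation.
#' @param ... Passed to [gbt_fit()].
#' @return A `rms_run` list: `splits`, `stats`, `processed` (named by
#'   stay), `models`, `scores` (per test stay, per task, full-grid),
#'   `eval_sets` (per task, in [event_pr_curve()] layout).
#' @export
run_rms_pipeline <- function(stays, tasks = c("RF", "MVStart", "MVEnd", "EF"),
                             seed = 1, feature_stride = 6L,
                             schema = default_schema(), fit_pao2 = FALSE,
                             ...) {
  ids <- vapply(stays, `[[`, "", "patient_id")
  names(stays) <- ids
  splits <- make_splits(ids, seed = seed)
  split1 <- splits$replicates[[1]]
  stats <- grid_stats(stays[split1$train], schema)
  estimator <- NULL
  if (fit_pao2) {
    tg <- lapply(stays[split1$train], build_grid, schema = schema)
    vg <- lapply(stays[split1$validation], build_grid, schema = schema)
    estimator <- fit_pao2_estimator(tg, vg)
  }
  processed <- lapply(stays, process_stay, schema = schema, stats = stats,
                      pao2_estimator = estimator,
                      feature_stride = feature_stride)
  feat_all <- data.table::rbindlist(lapply(processed, `[[`, "features"))
  lab_all <- lapply(tasks, function(task) {
    unlist(lapply(processed, function(p) p$labels[[task]][p$feature_bins]),
           use.names = FALSE)
  })
  names(lab_all) <- tasks
  models <- list()
  scores <- list()
  for (task in tasks) {
    models[[task]] <- train_task_model(feat_all, lab_all[[task]], split1,
                                       task = task, ...)
    sc <- predict(models[[task]], feat_all)
    scores[[task]] <- sc
  }
  # full-grid score tracks for the test stays (carry forward over stride)
  test_scores <- lapply(splits$test, function(id) {
    p <- processed[[id]]
    idx <- which(feat_all$stay == id)
    out <- lapply(tasks, function(task) {
      s <- rep(NA_real_, p$grid$n_steps)
      s[p$feature_bins] <- scores[[task]][idx]
      # carry forward between strided bins
      li <- cummax(ifelse(is.na(s), 0L, seq_along(s)))
      ifelse(li > 0L, s[pmax(li, 1L)], NA_real_)
    })
    names(out) <- tasks
    out
  })
  names(test_scores) <- splits$test
  eval_sets <- lapply(tasks, function(task)
    make_eval_set(processed[splits$test], test_scores, task))
  names(eval_sets) <- tasks
  structure(list(splits = splits, stats = stats, estimator = estimator,
                 processed = processed, features = feat_all,
                 labels = lab_all, models = models,
                 test_scores = test_scores, eval_sets = eval_sets),
            class = "rms_run")
}

#' Build an event-evaluation set for one task
#'
#' Converts processed test stays plus full-grid score tracks into the
#' per-stay `scores` / `in_event` / `events` layout the alarm evaluators
#' consume. For RF the events are maximal moderate/severe runs; for
#' MVStart, ventilation episodes; for MVEnd, readiness episodes.
#'
#' @param processed Named list of [process_stay()] outputs (test stays).
#' @param score_tracks Named list of per-stay per-task full-grid scores.
#' @param task Task id.
#' @return List of stays for [event_pr_curve()].
#' @export
make_eval_set <- function(processed, score_tracks, task = "RF") {
  lapply(names(processed), function(id) {
    p <- processed[[id]]
    ep <- p$endpoints
    if (task == "RF") {
      in_event <- ep$rf_status %in% c("moderate", "severe") |
        ep$rf_status == "unknown"
      ev <- ep$rf_events
    } else if (task == "MVStart") {
      in_event <- ep$vent
      ev <- ep$vent_events
    } else {
      in_event <- ep$rext | !ep$vent
      rr <- status_runs(ep$rext)
      ev <- rr[rr$value, c("start", "end"), drop = FALSE]
    }
    # prior stability in minutes before each onset (for earliness)
    if (nrow(ev)) {
      ev$stable_before <- vapply(seq_len(nrow(ev)), function(j) {
        o <- ev$start[j]
        prior <- which(in_event[seq_len(max(o - 1, 1))])
        if (!length(prior)) (o - 1) * GRID_STEP_MIN
        else (o - 1 - max(prior)) * GRID_STEP_MIN
      }, 0)
    } else ev$stable_before <- numeric(0)
    list(scores = score_tracks[[id]][[task]], in_event = in_event,
         events = ev)
  })
}
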