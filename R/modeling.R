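# Task-model training, variable selection, calibration, clinical baselines.

#' Patient-level data splits
#'
#' One fixed held-out test set plus `n_replicates` independent random 80:20
#' train/validation partitions of the remaining development stays, split by
#' whole patients. Deterministic given the seed.
#'
#' @param stay_ids Character vector of stay ids.
#' @param test_fraction Fraction held out for the fixed test set.
#' @param n_replicates Number of train/validation partitions.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `test` and `replicates` (each a list
#'   with `train`, `validation`).
#' @export
make_splits <- function(stay_ids, test_fraction = 0.2, n_replicates = 5,
                        seed = 1) {
  if (length(stay_ids) < 10) stop("need >= 10 stays to split")
  set.seed(seed)
  ids <- sample(stay_ids)
  n_test <- max(1L, round(test_fraction * length(ids)))
  test <- sort(ids[seq_len(n_test)])
  dev <- ids[-seq_len(n_test)]
  replicates <- lapply(seq_len(n_replicates), function(r) {
    dv <- sample(dev)
    n_val <- max(1L, round(0.2 * length(dv)))
    list(validation = sort(dv[seq_len(n_val)]), train = sort(dv[-seq_len(n_val)]))
  })
  structure(list(test = test, replicates = replicates, seed = seed),
            class = "split_plan")
}

label_to_numeric <- function(lab) {
  ifelse(lab == "positive", 1, ifelse(lab == "negative", 0, NA))
}

#' Train one task model
#'
#' Gradient-boosted trees on rows with defined labels; missing feature
#' values pass through natively (no imputation or scaling). Trees are added
#' until the validation time-point AUPRC has not improved for 50 rounds.
#'
#' @param features `data.table` from [assemble_features()] rows (must carry
#'   `stay` and `bin` columns).
#' @param labels Character label vector aligned with `features` rows.
#' @param split One replicate of a [make_splits()] plan.
#' @param task Task id (metadata).
#' @param feature_cols Optional subset of feature columns.
#' @param ... Passed to [gbt_fit()].
#' @return A `task_model`.
#' @export
train_task_model <- function(features, labels, split, task = "RF",
                             feature_cols = NULL,
                             learning_rate = 0.05, max_depth = 3L,
                             min_leaf = 200L, ...) {
  y <- label_to_numeric(labels)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), c("stay", "bin"))
  }
  tr <- features$stay %in% split$train & !is.na(y)
  va <- features$stay %in% split$validation & !is.na(y)
  if (length(unique(y[tr])) < 2 || length(unique(y[va])) < 2) {
    stop("need positives and negatives in both train and validation")
  }
  X <- as.matrix(features[, feature_cols, with = FALSE])
  # clustered time-series rows overfit fast: shallow, slow, big leaves
  fit <- gbt_fit(X[tr, , drop = FALSE], y[tr], X[va, , drop = FALSE], y[va],
                 objective = "binary", learning_rate = learning_rate,
                 max_depth = max_depth, min_leaf = min_leaf, ...)
  structure(list(task = task, model = fit, feature_cols = feature_cols,
                 val_auprc = max(fit$metric_trace),
                 best_iter = fit$best_iter), class = "task_model")
}

#' @rdname train_task_model
#' @param object A `task_model`.
#' @param newdata Feature `data.table` or matrix.
#' @param ... Unused.
#' @export
predict.task_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, object$feature_cols, with = FALSE])
  predict(object$model, X)
}

#' SHAP-based variable importance
#'
#' Mean absolute TreeSHAP value per feature on validation rows, optionally
#' averaged over replicate models; the importance of a clinical variable is
#' the maximum over the features derived from it.
#'
#' @param models List of `task_model`s (one per replicate).
#' @param features Validation feature `data.table`.
#' @param manifest Column manifest (from [assemble_features()]); maps
#'   feature names to source variables. Features without a source variable
#'   map to themselves.
#' @return List with `feature_importance` and `variable_importance`, both
#'   sorted decreasing.
#' @export
shap_variable_importance <- function(models, features, manifest = NULL) {
  if (inherits(models, "task_model")) models <- list(models)
  fi <- NULL
  for (m in models) {
    X <- as.matrix(features[, m$feature_cols, with = FALSE])
    sh <- gbt_shap(m$model, X)
    imp <- colMeans(abs(sh$phi))
    fi <- if (is.null(fi)) imp else fi + imp
  }
  fi <- fi / length(models)
  varmap <- if (!is.null(manifest)) {
    stats::setNames(ifelse(is.na(manifest$variable), manifest$name,
                           manifest$variable), manifest$name)
  } else NULL
  vi <- if (!is.null(varmap)) {
    tapply(fi, varmap[names(fi)], max)
  } else fi
  list(feature_importance = sort(fi, decreasing = TRUE),
       variable_importance = sort(unlist(as.list(vi)), decreasing = TRUE))
}

#' Greedy forward variable selection
#'
#' Per replicate, iteratively adds the candidate variable whose inclusion
#' maximizes the validation time-point AUPRC; the final importance of a
#' variable is its mean reciprocal rank over the replicate forward traces.
#'
#' @param candidates Character vector of variable names.
#' @param var_features Named list mapping each variable to its feature
#'   columns.
#' @param features,labels Data and labels as in [train_task_model()].
#' @param splits A [make_splits()] plan (all replicates are used).
#' @param max_steps Optional cap on the forward trace length.
#' @param ... Passed to [gbt_fit()] (use small ensembles here).
#' @return List with `traces` (per replicate character vectors), `mrr`
#'   (named, sorted decreasing) and `ranking`.
#' @export
greedy_forward_select <- function(candidates, var_features, features, labels,
                                  splits, max_steps = length(candidates),
                                  ...) {
  if (!length(candidates)) stop("empty candidate set")
  y <- label_to_numeric(labels)
  traces <- lapply(splits$replicates, function(split) {
    tr <- features$stay %in% split$train & !is.na(y)
    va <- features$stay %in% split$validation & !is.na(y)
    chosen <- character(0)
    remaining <- candidates
    for (step in seq_len(min(max_steps, length(candidates)))) {
      sc <- vapply(remaining, function(v) {
        cols <- unlist(var_features[c(chosen, v)], use.names = FALSE)
        X <- as.matrix(features[, cols, with = FALSE])
        fit <- gbt_fit(X[tr, , drop = FALSE], y[tr], X[va, , drop = FALSE],
                       y[va], objective = "binary", ...)
        max(fit$metric_trace)
      }, 0)
      pick <- remaining[which.max(sc)]
      chosen <- c(chosen, pick)
      remaining <- setdiff(remaining, pick)
    }
    chosen
  })
  ranks <- vapply(candidates, function(v) {
    mean(vapply(traces, function(tr) {
      r <- match(v, tr)
      if (is.na(r)) 1 / (length(tr) + 1) else 1 / r
    }, 0))
  }, 0)
  mrr <- sort(ranks, decreasing = TRUE)
  list(traces = traces, mrr = mrr, ranking = names(mrr))
}

#' Calibration curve and Brier score
#'
#' Scores are binned between the observed minimum and maximum with a fixed
#' bin width (default 0.05); per bin the observed event fraction is
#' reported. The Brier score is the mean squared difference between score
#' and outcome.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 outcomes (rows with defined labels only).
#' @param bin_size Bin width.
#' @return List with `curve` (data.frame: bin_mid, mean_score, observed,
#'   n) and `brier`.
#' @export
calibration_report <- function(scores, labels, bin_size = 0.05) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  lo <- min(scores); hi <- max(scores)
  breaks <- seq(lo, hi + bin_size, by = bin_size)
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE)
  curve <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin_mid = breaks[b] + bin_size / 2,
               mean_score = mean(scores[sel]),
               observed = mean(labels[sel]), n = sum(sel))
  }))
  list(curve = curve, brier = mean((scores - labels)^2))
}

#' Clinical comparator baselines
#'
#' Three reference scores: (1) a shallow decision tree on the printed
#' current-value variable list (SpO2, FIO2, PaO2, PEEP, RR, ventilator
#' presence, HR, GCS); (2) the negated SpO2/FIO2 ratio (a threshold sweep
#' over it is the classical saturation-based alarm system); (3) for
#' extubation failure, the readiness-to-extubate violation score at
#' prediction time.
#'
#' @param features Feature `data.table` containing `spo2_cur`, `fio2_est`,
#'   `pao2_cur`, `peep_cur`, `rr_cur`, `vent_status`, `hr_cur`, `gcs_cur`.
#' @param labels Labels for fitting the decision tree.
#' @param split Replicate split for the tree fit.
#' @param tree_depth Depth of the decision-tree baseline.
#' @return List with score vectors `tree`, `sf_ratio` and the fitted tree
#'   model.
#' @export
clinical_baselines <- function(features, labels, split, tree_depth = 3L) {
  cols <- intersect(c("spo2_cur", "fio2_est", "pao2_cur", "peep_cur",
                      "rr_cur", "vent_status", "hr_cur", "gcs_cur"),
                    names(features))
  y <- label_to_numeric(labels)
  tr <- features$stay %in% split$train & !is.na(y)
  X <- as.matrix(features[, cols, with = FALSE])
  tree <- gbt_fit(X[tr, , drop = FALSE], y[tr], objective = "binary",
                  nrounds = 1L, learning_rate = 1.0, max_depth = tree_depth,
                  min_leaf = 50L)
  sf <- -(features$spo2_cur * 100) / features$fio2_est
  list(tree = predict(tree, X), sf_ratio = sf, tree_model = tree)
}
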