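# R interface to the compiled gradient-boosted tree learner.

#' Fit a gradient-boosted tree ensemble
#'
#' Exact greedy trees on all samples, Newton leaf weights with an L2 penalty,
#' and native missing-value handling: each split learns a default direction
#' for `NA`s, so feature matrices are passed un-imputed and un-scaled. Trees
#' are added until the validation metric has not improved for
#' `early_stopping_rounds` rounds (time-point AUPRC for the binary
#' objective, negative RMSE for regression); the ensemble is truncated at
#' the best round. Fits are deterministic given the data and settings.
#'
#' @param X,y Training features (numeric matrix, `NA` allowed) and targets
#'   (0/1 for `objective = "binary"`).
#' @param Xval,yval Validation set driving early stopping; when `NULL`, the
#'   full `nrounds` are kept.
#' @param objective `"binary"` (logistic) or `"regression"` (squared loss).
#' @param nrounds Maximum boosting rounds.
#' @param learning_rate,max_depth,min_leaf,lambda Usual boosting
#'   hyperparameters.
#' @param early_stopping_rounds Patience in rounds.
#' @return A `gbt_model`.
#' @export
gbt_fit <- function(X, y, Xval = NULL, yval = NULL,
                    objective = c("binary", "regression"), nrounds = 300L,
                    learning_rate = 0.1, max_depth = 4L, min_leaf = 20L,
                    lambda = 1.0, early_stopping_rounds = 50L) {
  objective <- match.arg(objective)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (objective == "binary") {
    if (length(unique(y)) < 2) stop("single-class training labels")
    prev <- mean(y)
    base_score <- log(prev / (1 - prev))
  } else {
    base_score <- mean(y)
  }
  has_val <- !is.null(Xval) && nrow(Xval) > 0
  Xv <- if (has_val) {
    Xv <- as.matrix(Xval); storage.mode(Xv) <- "double"; Xv
  } else matrix(0, 0, ncol(X))
  fit <- .gbt_train_cpp(X, y, objective, as.integer(nrounds), learning_rate,
                        as.integer(max_depth), as.integer(min_leaf), lambda,
                        base_score, Xv)
  best_iter <- as.integer(nrounds)
  metric_trace <- NULL
  if (has_val) {
    metric_trace <- vapply(seq_len(nrounds), function(r) {
      m <- fit$val_margins[, r]
      if (objective == "binary") {
        auprc(1 / (1 + exp(-m)), yval)
      } else {
        -sqrt(mean((m - yval)^2))
      }
    }, 0)
    best_iter <- which.max(metric_trace)
    # patience: stop counting rounds once no improvement for the window
    run <- which(seq_along(metric_trace) - best_iter >
                   early_stopping_rounds)
    if (length(run)) metric_trace <- metric_trace[seq_len(min(run) - 1)]
  }
  structure(list(
    trees = fit$trees[seq_len(best_iter)], base_score = base_score,
    objective = objective, best_iter = best_iter,
    metric_trace = metric_trace, feature_names = colnames(X),
    params = list(learning_rate = learning_rate, max_depth = max_depth,
                  min_leaf = min_leaf, lambda = lambda, nrounds = nrounds,
                  early_stopping_rounds = early_stopping_rounds)
  ), class = "gbt_model")
}

#' @rdname gbt_fit
#' @param object A `gbt_model`.
#' @param newdata Feature matrix (columns as in training; `NA` allowed).
#' @param type `"response"` (probability for binary) or `"margin"`.
#' @param ... Unused.
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "margin"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  m <- .gbt_predict_cpp(object$trees, X, object$base_score,
                        length(object$trees))
  if (object$objective == "binary" && type == "response") {
    1 / (1 + exp(-m))
  } else m
}

#' TreeSHAP attributions for a fitted ensemble
#'
#' Exact per-feature Shapley attributions on the margin scale, computed with
#' the polynomial-time tree traversal; `rowSums(phi) + base` equals the raw
#' margin prediction.
#'
#' @param model A `gbt_model`.
#' @param X Feature matrix to explain.
#' @return List with `phi` (n x p matrix, columns named as the features) and
#'   scalar `base`.
#' @export
gbt_shap <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  out <- .gbt_shap_cpp(model$trees, X, model$base_score)
  colnames(out$phi) <- model$feature_names
  out
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model: %s, %d trees (depth<=%d, lr=%.3g)>\n",
              x$objective, length(x$trees), x$params$max_depth,
              x$params$learning_rate))
  invisible(x)
}
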