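# Continuous PaO2 / FIO2 / P-F ratio estimation on the 5-min grid.

#' Severinghaus oxygen-hemoglobin dissociation curve
#'
#' Forward model `S(p) = 1 / (23400 / (p^3 + 150 p) + 1)` mapping arterial
#' oxygen partial pressure (mmHg) to fractional hemoglobin saturation.
#'
#' @param pao2 Partial pressure in mmHg (> 0).
#' @return Saturation as a fraction in (0, 1).
#' @export
severinghaus <- function(pao2) {
  1 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Ellis inversion of the dissociation curve
#'
#' Closed-form inverse of [severinghaus()]: solves the depressed cubic
#' `p^3 + 150 p - c = 0` with `c = 23400 * s / (1 - s)` by Cardano's
#' formula. Saturations at or above 1 are clamped to 0.9995 (with a
#' warning); non-positive saturations are an error.
#'
#' @param spo2 Saturation fraction in (0, 1); vectorized.
#' @return PaO2 estimate in mmHg.
#' @export
ellis_pao2 <- function(spo2) {
  if (any(spo2 <= 0, na.rm = TRUE)) stop("spo2 must be positive")
  if (any(spo2 >= 1, na.rm = TRUE)) {
    warning("spo2 >= 1 clamped to 0.9995")
    spo2 <- pmin(spo2, 0.9995)
  }
  cc <- 23400 * spo2 / (1 - spo2)
  disc <- sqrt((cc / 2)^2 + 50^3)
  (cc / 2 + disc)^(1 / 3) - (disc - cc / 2)^(1 / 3)
}

#' Percentile smoothing of the SpO2 series
#'
#' Robust pre-processing of pulse-oximetry: the value at each grid point is
#' the 75th percentile (linear interpolation) of the non-missing SpO2 values
#' in a centered 30-min kernel window (grid offsets -3..+3). Bins whose
#' window holds no value stay missing.
#'
#' @param spo2 Gridded SpO2 values (fraction or percent), `NA` allowed.
#' @param window_bins Half-width in bins (default 3 = 15 min each side).
#' @return Smoothed series, same length.
#' @export
smooth_spo2 <- function(spo2, window_bins = 3L) {
  n <- length(spo2)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    w <- spo2[max(1, t - window_bins):min(n, t + window_bins)]
    w <- w[!is.na(w)]
    if (length(w)) out[t] <- stats::quantile(w, 0.75, names = FALSE, type = 7)
  }
  out
}

#' Sample weight for PaO2 regression
#'
#' `10 + 100 / (1 + exp(0.025 * (pao2 - 110)))`: true PaO2 values near the
#' respiratory-failure decision boundaries get higher weight.
#'
#' @param true_pao2 Measured PaO2 in mmHg.
#' @return Weight(s).
#' @export
pao2_sample_weight <- function(true_pao2) {
  10 + 100 / (1 + exp(0.025 * (true_pao2 - 110)))
}

# Exponent matrix for all monomials of total degree <= 3 over d variables
# (including the bias monomial), in deterministic lexicographic order.
poly3_exponents <- function(d) {
  ex <- as.matrix(expand.grid(rep(list(0:3), d)))[, d:1, drop = FALSE]
  ex <- ex[rowSums(ex) <= 3, , drop = FALSE]
  ex[order(rowSums(ex), apply(ex, 1, paste, collapse = "")), , drop = FALSE]
}

#' Polynomial feature expansion of the PaO2 base features
#'
#' Expands the 7 hand-crafted features (last SpO2 / PaO2 / SaO2 / pH
#' measurements, time since last SpO2 / PaO2, and the SpO2 value closest to
#' the last PaO2 measurement) to all monomials of total degree <= 3
#' including the bias term: `choose(7 + 3, 3) = 120` columns, in a stable
#' deterministic order.
#'
#' @param X Numeric matrix, one row per sample, 7 columns.
#' @return Numeric matrix with 120 columns.
#' @export
pao2_feature_vector <- function(X) {
  X <- as.matrix(X)
  ex <- poly3_exponents(ncol(X))
  out <- matrix(1, nrow(X), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    for (k in which(ex[j, ] > 0)) out[, j] <- out[, j] * X[, k]^ex[j, k]
  }
  colnames(out) <- apply(ex, 1, function(e) {
    if (all(e == 0)) "1" else
      paste(sprintf("x%d^%d", which(e > 0), e[e > 0]), collapse = "*")
  })
  out
}

# Weighted Huber-loss linear regression with L2 penalty, solved by
# iteratively reweighted ridge. Features standardized internally.
huber_ridge <- function(X, y, weights = NULL, alpha = 0.01, delta = 10,
                        max_iter = 30, tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  # degenerate (constant-in-training) columns carry no information and must
  # not leak out-of-distribution shifts into predictions: zero them out
  scl[!is.finite(scl) | scl < 1e-10] <- Inf
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ym <- stats::weighted.mean(y, weights)
  beta <- rep(0, p)
  w <- weights
  for (it in seq_len(max_iter)) {
    A <- crossprod(Xs, Xs * w) + diag(alpha * n, p)
    b <- crossprod(Xs, w * (y - ym))
    beta_new <- tryCatch(as.numeric(solve(A, b)),
                         error = function(e) as.numeric(qr.solve(A, b)))
    r <- y - ym - Xs %*% beta_new
    hub <- pmin(1, delta / pmax(abs(r), 1e-12))  # Huber psi(r)/r
    w <- weights * as.numeric(hub)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(beta = beta, intercept = ym, center = ctr, scale = scl,
                 alpha = alpha, delta = delta), class = "huber_ridge")
}

predict_huber_ridge <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$center), 2, fit$scale, "/")
  as.numeric(fit$intercept + Xs %*% fit$beta)
}

# Per-bin oxygenation state: the 7 hand-crafted features plus eligibility.
# Feature order: last_spo2, last_pao2, last_sao2, last_ph, dt_last_spo2,
# dt_last_pao2, spo2_at_last_pao2. The continuously monitored SpO2 updates
# before the features are recorded; the blood-gas panel (PaO2/SaO2/pH)
# updates afterwards, so at a bin with an in-bin panel the features reflect
# only *prior* panels -- the panel measured at the training bin is the
# regression target and must not appear among its own features.
oxygenation_state_walk <- function(g) {
  n <- g$n_steps
  f <- matrix(NA_real_, n, 7)
  colnames(f) <- c("last_spo2", "last_pao2", "last_sao2", "last_ph",
                   "dt_last_spo2", "dt_last_pao2", "spo2_at_last_pao2")
  last <- c(spo2 = NA, pao2 = NA, sao2 = NA, ph = NA)
  spo2_at_pao2 <- NA_real_
  pao2_time <- NA_real_
  for (t in seq_len(n)) {
    if (g$measured$spo2[t] == 1L) last["spo2"] <- g$values$spo2[t]
    f[t, 1:4] <- last
    f[t, 5] <- max(g$tsm$spo2[t], 0)
    f[t, 6] <- if (is.na(pao2_time)) -1 else
      max(0, g$grid_start + GRID_STEP_MIN * (t - 1) - pao2_time)
    f[t, 7] <- spo2_at_pao2
    for (v in c("pao2", "sao2", "ph")) {
      if (g$measured[[v]][t] == 1L) last[v] <- g$values[[v]][t]
    }
    if (g$measured$pao2[t] == 1L) {
      spo2_at_pao2 <- last[["spo2"]]
      pao2_time <- g$grid_start + GRID_STEP_MIN * (t - 1)
    }
  }
  list(features = f, has_all_prior = !is.na(f[, 1]) & !is.na(f[, 2]) &
         !is.na(f[, 3]) & !is.na(f[, 4]))
}

#' Fit the nested PaO2 estimator
#'
#' Two nested L2-regularized robust (Huber-loss) regressions. The base model
#' maps degree-3 polynomial expansions of the 7 hand-crafted features to
#' measured PaO2. The meta model additionally receives the base prediction
#' and the signed offsets between base prediction and ground truth for the
#' (up to) 10 prior PaO2 measurements of the same stay, zero-padded. Both
#' are trained with samples weighted by [pao2_sample_weight()]; the
#' regularization weight is chosen on the validation stays over
#' `alpha_grid` by weighted Huber validation error.
#'
#' @param train_grids,val_grids Lists of raw `gridded_stay` objects.
#' @param alpha_grid Regularization weights to search.
#' @return A `pao2_estimator`.
#' @export
fit_pao2_estimator <- function(train_grids, val_grids,
                               alpha_grid = c(1, 0.1, 0.01, 0.001, 1e-4)) {
  tr <- pao2_nested_design(train_grids)
  va <- pao2_nested_design(val_grids)
  if (nrow(tr$P) < 50) stop("refusing to fit: < 50 eligible training samples")
  wt <- pao2_sample_weight(tr$y)
  wv <- pao2_sample_weight(va$y)
  pick <- function(Xtr, ytr, Xva, yva) {
    best <- NULL; best_err <- Inf
    for (a in alpha_grid) {
      fit <- huber_ridge(Xtr, ytr, wt, alpha = a)
      pred <- predict_huber_ridge(fit, Xva)
      r <- abs(yva - pred); d <- fit$delta
      hub <- ifelse(r <= d, 0.5 * r^2, d * (r - 0.5 * d))
      err <- if (length(r)) stats::weighted.mean(hub, wv) else Inf
      if (err < best_err) { best_err <- err; best <- fit }
    }
    best
  }
  base <- pick(tr$P, tr$y, va$P, va$y)
  # recompute designs with prior errors from this base model
  tr2 <- pao2_nested_design(train_grids, base)
  va2 <- pao2_nested_design(val_grids, base)
  meta <- pick(tr2$M, tr2$y, va2$M, va2$y)
  structure(list(base = base, meta = meta), class = "pao2_estimator")
}

# Builds base design P (120 cols) and, given a base fit, meta design M
# (120 + 1 + 10 cols) with per-stay running prior-error buffers.
pao2_nested_design <- function(grids, base_fit = NULL) {
  Ps <- list(); Ms <- list(); ys <- list()
  for (g in grids) {
    st <- oxygenation_state_walk(g)
    eligible <- which(g$measured$pao2 == 1L & st$has_all_prior)
    if (!length(eligible)) next
    P <- pao2_feature_vector(st$features[eligible, , drop = FALSE])
    y <- g$values$pao2[eligible]
    Ps[[length(Ps) + 1L]] <- P; ys[[length(ys) + 1L]] <- y
    if (!is.null(base_fit)) {
      bp <- predict_huber_ridge(base_fit, P)
      M <- matrix(0, length(eligible), ncol(P) + 1 + 10)
      errbuf <- numeric(0)
      for (i in seq_along(eligible)) {
        pe <- utils::tail(errbuf, 10)
        M[i, ] <- c(P[i, ], bp[i], c(rep(0, 10 - length(pe)), pe))
        errbuf <- c(errbuf, bp[i] - y[i])  # signed offset, oldest -> newest
      }
      Ms[[length(Ms) + 1L]] <- M
    }
  }
  out <- list(P = do.call(rbind, c(Ps, list(matrix(0, 0, 120)))),
              y = unlist(c(ys, list(numeric()))))
  if (!is.null(base_fit)) {
    out$M <- do.call(rbind, c(Ms, list(matrix(0, 0, 131))))
  }
  out
}

#' Continuous PaO2 track with provenance
#'
#' Per bin: a measured in-bin PaO2 is used verbatim (`source = "measured"`);
#' after at least one prior PaO2 measurement the nested estimator predicts
#' (`source = "model"`); before the first PaO2 measurement the normal
#' forward-fill/normal-value imputation applies (`source = "forward_fill"`).
#' Prior-error buffers update only at measured bins. Bins eligible for
#' prediction but missing one of the SaO2/pH/SpO2 priors fall back to the
#' Ellis inversion of the smoothed SpO2 (still `source = "model"`).
#'
#' @param grid Raw `gridded_stay`.
#' @param estimator A `pao2_estimator`, or `NULL` for the pure
#'   Severinghaus-Ellis baseline.
#' @param schema Schema (for the PaO2 normal value).
#' @param stats Optional [grid_stats()] for the forward-fill horizon.
#' @return List with `pao2_est` and `source` (character) tracks.
#' @export
estimate_pao2_track <- function(grid, estimator = NULL, schema = default_schema(),
                                stats = NULL) {
  n <- grid$n_steps
  st <- oxygenation_state_walk(grid)
  smoothed <- smooth_spo2(ifelse(grid$measured$spo2 == 1L, grid$values$spo2, NA))
  # forward-fill / normal-value baseline for pao2
  spec <- schema[["pao2"]]
  horizon <- ffill_horizon_minutes(spec, stats)
  ffill <- rep(spec$normal_value, n)
  li <- cummax(ifelse(grid$measured$pao2 == 1L, seq_len(n), 0L))
  ok <- li > 0L & grid$tsm$pao2 >= 0 & grid$tsm$pao2 <= horizon
  ffill[ok] <- grid$values$pao2[li[ok]]

  out <- ffill
  src <- rep("forward_fill", n)
  seen_pao2 <- cummax(grid$measured$pao2) == 1L
  measured_bins <- grid$measured$pao2 == 1L
  out[measured_bins] <- grid$values$pao2[measured_bins]
  src[measured_bins] <- "measured"

  model_bins <- which(seen_pao2 & !measured_bins)
  if (length(model_bins)) {
    full <- st$has_all_prior[model_bins]
    if (!is.null(estimator) && any(full)) {
      mb <- model_bins[full]
      P <- pao2_feature_vector(st$features[mb, , drop = FALSE])
      bp <- predict_huber_ridge(estimator$base, P)
      # prior errors from measured bins only
      meas_idx <- which(measured_bins & st$has_all_prior)
      errs <- if (length(meas_idx)) {
        Pm <- pao2_feature_vector(st$features[meas_idx, , drop = FALSE])
        predict_huber_ridge(estimator$base, Pm) - grid$values$pao2[meas_idx]
      } else numeric()
      M <- matrix(0, length(mb), 131)
      for (i in seq_along(mb)) {
        pe <- utils::tail(errs[meas_idx < mb[i]], 10)
        M[i, ] <- c(P[i, ], bp[i], c(rep(0, 10 - length(pe)), pe))
      }
      out[mb] <- predict_huber_ridge(estimator$meta, M)
      src[mb] <- "model"
    }
    # fallback (or estimator NULL): Ellis on smoothed SpO2 where available
    rest <- model_bins[if (!is.null(estimator)) !full else rep(TRUE, length(model_bins))]
    s <- smoothed[rest]
    usable <- !is.na(s) & s > 0
    if (any(usable)) {
      out[rest[usable]] <- ellis_pao2(pmin(s[usable], 0.9995))
      src[rest[usable]] <- "model"
    }
  }
  list(pao2_est = out, source = src, spo2_smoothed = smoothed)
}

#' Continuous FIO2 track
#'
#' Rule cascade per grid point: (1) the ventilator FIO2 is forward-filled if
#' its last measurement is at most 30 min old and the patient is estimated
#' to be ventilated or the current ventilation mode is NIV (code 4); (2)
#' otherwise the supplemental-oxygen FIO2 variables apply when measured in
#' the last 12 h, plain supplemental FIO2 taking precedence over high-flow;
#' (3) otherwise ambient air, 0.21.
#'
#' @param grid Raw `gridded_stay`.
#' @param vent Logical ventilation track (from [annotate_ventilation()]);
#'   the ventilation annotation itself uses no FIO2, which breaks the
#'   circular dependency.
#' @return Numeric FIO2 fractions in `[0.21, 1]`.
#' @export
estimate_fio2_track <- function(grid, vent) {
  n <- grid$n_steps
  lastval <- function(v) {
    li <- cummax(ifelse(grid$measured[[v]] == 1L, seq_len(n), 0L))
    ifelse(li > 0L, grid$values[[v]][li], NA_real_)
  }
  vent_fio2 <- lastval("fio2"); vent_fio2_age <- grid$tsm$fio2
  suppl <- lastval("suppl_fio2"); suppl_age <- grid$tsm$suppl_fio2
  hf <- lastval("highflow_fio2"); hf_age <- grid$tsm$highflow_fio2
  mode_now <- lastval("vent_mode")
  out <- rep(0.21, n)
  rule2_hf <- !is.na(hf) & hf_age >= 0 & hf_age <= 720
  out[rule2_hf] <- hf[rule2_hf]
  rule2_su <- !is.na(suppl) & suppl_age >= 0 & suppl_age <= 720
  out[rule2_su] <- suppl[rule2_su]
  rule1 <- !is.na(vent_fio2) & vent_fio2_age >= 0 & vent_fio2_age <= 30 &
    (vent | (!is.na(mode_now) & mode_now == 4))
  out[rule1] <- vent_fio2[rule1]
  pmin(pmax(out, 0.21), 1.0)
}

#' P/F ratio track
#'
#' Tentative per-bin ratio `pao2_est / fio2_est`, post-processed with a
#' Nadaraya-Watson kernel smoother (Gaussian kernel; bandwidth in grid
#' steps, default 20). Missing tentative ratios are skipped by the smoother;
#' a bin with no finite ratio within reach stays missing.
#'
#' @param pao2_est,fio2_est Aligned tracks.
#' @param bandwidth Kernel bandwidth in 5-min grid steps.
#' @return Smoothed P/F series (mmHg).
#' @export
pf_track <- function(pao2_est, fio2_est, bandwidth = 20) {
  ratio <- pao2_est / fio2_est
  nadaraya_watson(ratio, bandwidth)
}

#' @rdname pf_track
#' @param x Series with possible `NA`s.
#' @export
nadaraya_watson <- function(x, bandwidth = 20) {
  n <- length(x)
  if (bandwidth <= 1e-8) return(x)
  reach <- min(n - 1, ceiling(4 * bandwidth))
  k <- exp(-0.5 * ((-reach:reach) / bandwidth)^2)
  xf <- ifelse(is.na(x), 0, x)
  mf <- as.numeric(!is.na(x))
  num <- stats::filter(c(rep(0, reach), xf, rep(0, reach)), k, sides = 2)
  den <- stats::filter(c(rep(0, reach), mf, rep(0, reach)), k, sides = 2)
  num <- num[(reach + 1):(reach + n)]; den <- den[(reach + 1):(reach + n)]
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  as.numeric(out)
}

#' Validation predictions of the nested estimator and the Ellis baseline
#'
#' Collects, over the eligible time points of the given stays (measured
#' PaO2 with at least one prior panel), the measured target together with
#' the base-model, meta-model and Severinghaus-Ellis (current SpO2)
#' predictions. Used to compare estimator and physiological baseline on
#' equal footing.
#'
#' @param grids List of raw `gridded_stay` objects.
#' @param estimator A fitted `pao2_estimator`.
#' @return data.frame with columns `y`, `base`, `meta`, `ellis`.
#' @export
pao2_estimator_validation <- function(grids, estimator) {
  des <- pao2_nested_design(grids, estimator$base)
  base <- predict_huber_ridge(estimator$base, des$M[, 1:120, drop = FALSE])
  meta <- predict_huber_ridge(estimator$meta, des$M)
  ellis <- ellis_pao2(pmin(des$M[, 1], 0.9995))  # column 1 = last SpO2
  data.frame(y = des$y, base = base, meta = meta, ellis = ellis)
}
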