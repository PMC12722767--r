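# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (loops, no shared code with the package internals).

bf_adaptive_horizon <- function(iv) {
  2 * bf_quantile7(iv, 0.5) + (bf_quantile7(iv, 0.75) - bf_quantile7(iv, 0.25))
}

bf_vote <- function(era, etco2_win, mode, tv, inv, noninv) {
  s <- 0
  if (era) s <- s + 1
  if (etco2_win) s <- s + 2
  if (!is.na(mode)) {
    if (mode == 2 || mode == 3) s <- s + 1
    if (mode == 1) s <- s - 1
    if (mode %in% c(4, 5, 6)) s <- s - 2
  }
  if (!is.na(tv) && tv > 0) s <- s + 1
  if (inv) s <- s + 2
  if (noninv) s <- s - 1
  s
}

bf_rext_score <- function(st, era_pre2010) {
  s <- 0
  add <- function(cond, pts) if (!is.na(cond) && cond) pts else 0
  if (!era_pre2010) s <- s + add(st$mode != 3, 9)
  s <- s + add(st$peep > 7, 3)
  s <- s + add(st$pressure_support > 10, 3)
  s <- s + add(st$fio2 > 0.4, 3)
  rsbi <- 1000 * st$rr / st$tv
  s <- s + add(rsbi >= 105, 3)
  s <- s + add(st$rr >= 35, 3)
  s <- s + add(st$minute_volume >= 10, 3)
  s <- s + add(st$pf <= 150, 3)
  s <- s + add(st$paco2 >= 50, 3)
  s <- s + add(st$gcs <= 8, 1)
  s <- s + add(st$map <= 60, 1)
  med <- isTRUE(!is.na(st$norepinephrine) && st$norepinephrine > 0.05) ||
    isTRUE(!is.na(st$inotrope) && st$inotrope > 0)
  if (med) s <- s + 1
  s <- s + add(st$lactate >= 2.5, 1)
  s
}

bf_event_metrics <- function(alarm_list, event_list, horizon = 288) {
  tp <- 0; fp <- 0; caught <- 0; n_ev <- 0
  for (i in seq_along(alarm_list)) {
    for (a in alarm_list[[i]]) {
      hit <- FALSE
      for (o in event_list[[i]]$start) {
        if (o > a && o <= a + horizon) hit <- TRUE
      }
      if (hit) tp <- tp + 1 else fp <- fp + 1
    }
    for (o in event_list[[i]]$start) {
      n_ev <- n_ev + 1
      got <- FALSE
      for (a in alarm_list[[i]]) if (a >= o - horizon && a < o) got <- TRUE
      if (got) caught <- caught + 1
    }
  }
  list(recall = if (n_ev) caught / n_ev else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp)
}

bf_multires <- function(values, kind, w, bins) {
  lapply(bins, function(t) {
    v <- values[max(1, t - w + 1):t]
    keep <- !is.na(v)
    idx <- (max(1, t - w + 1):t)[keep]
    v <- v[keep]
    if (!length(v)) return(list(NA_real_, NA_real_, NA_real_))
    if (kind == "ordinal") {
      med <- bf_quantile7(v, 0.5)
      iqr <- bf_quantile7(v, 0.75) - bf_quantile7(v, 0.25)
      tr <- if (length(v) < 2) 0 else {
        cf <- stats::lm.fit(cbind(1, idx - 1), v)$coefficients
        unname(cf[2])
      }
      list(med, iqr, tr)
    } else if (kind == "binary") {
      list(mean(v), NA_real_, NA_real_)
    } else {
      tb <- table(v)
      list(as.numeric(names(tb)[which.max(tb)]), NA_real_, NA_real_)
    }
  })
}

bf_auprc <- function(scores, labels) {
  # threshold sweep over unique scores, rectangle integration over recall
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (th in ths) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
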