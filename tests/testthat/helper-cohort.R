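# Shared fixtures: memoized small simulated cohorts and hand-built stays.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n = 20, seed = 7, ...) {
  key <- paste(n, seed, ...)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(sim_config(n_stays = n, ...),
                                            seed = seed)
  }
  .cohort_cache[[key]]
}

# minimal stay: regular HR plus whatever extra observations are supplied
toy_stay <- function(duration_min = 120, extra = list(), hr_by = 5,
                     id = "toy", ...) {
  obs <- c(list(hr = data.frame(time = seq(0, duration_min, by = hr_by),
                                value = 80)), extra)
  stay_record(id, 0, duration_min + 5, obs, ...)
}

# brute-force type-7 percentile, independent of stats::quantile
bf_quantile7 <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x[1])
  h <- (n - 1) * q
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
}
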