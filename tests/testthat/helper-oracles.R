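# Independent oracles used to validate the detectors and the stats layer.
# These deliberately recompute everything from scratch with naive loops and
# closed forms, sharing no code path with the package implementation.

# Brute-force flow-limitation oracle: recompute each 100-breath window's
# mean/SD with mean()/sd() and apply the dual criterion literally.
oracle_ifl <- function(breaths, params) {
  w <- params$window_w
  z <- params$z_thresh
  n <- nrow(breaths)
  flags <- logical(n)
  for (i in seq_len(n)) {
    if (i <= w) next
    rw <- breaths$ratio_s_per_ml[(i - w):(i - 1)]
    pw <- breaths$pif_ml_s[(i - w):(i - 1)]
    sr <- stats::sd(rw)
    sp <- stats::sd(pw)
    cr <- if (sr > 0) breaths$ratio_s_per_ml[i] >= mean(rw) + z * sr
          else breaths$ratio_s_per_ml[i] > mean(rw)
    cp <- if (sp > 0) breaths$pif_ml_s[i] <= mean(pw) - z * sp
          else breaths$pif_ml_s[i] < mean(pw)
    flags[i] <- cr && cp
  }
  flags
}

# From-scratch rolling window stats (for the mean/SD equivalence check).
oracle_window_stats <- function(x, w) {
  n <- length(x)
  m <- rep(NA_real_, n)
  s <- rep(NA_real_, n)
  for (i in (w + 1):n) {
    win <- x[(i - w):(i - 1)]
    m[i] <- mean(win)
    s[i] <- stats::sd(win)
  }
  list(mean = m, sd = s)
}

# Interval-scan apnea oracle: per-breath thresholds recomputed with median()
# in a loop, run boundaries found by diff() on the padded indicator.
oracle_apneas <- function(trace, breaths, params) {
  f <- trace$flow
  fs <- trace$sample_rate_hz
  w <- params$window_w
  pif <- breaths$pif_ml_s
  nb <- length(pif)
  thr <- numeric(nb + 1)
  thr[1] <- stats::median(pif)
  for (j in seq_len(nb))
    thr[j + 1] <- if (j >= w) stats::median(pif[(j - w + 1):j])
                  else stats::median(pif)
  tt <- trace$start_time_s + (seq_along(f) - 1) / fs
  j <- findInterval(tt, breaths$onset_s)
  below <- abs(f) < params$apnea_flow_frac * thr[j + 1]
  d <- diff(c(FALSE, below, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  len_s <- (ends - starts + 1) / fs
  keep <- len_s >= params$apnea_min_s
  data.frame(start_s = trace$start_time_s + (starts[keep] - 1) / fs,
             end_s = trace$start_time_s + ends[keep] / fs)
}

# Maximal-run oracle by run-length encoding done manually.
oracle_runs <- function(flags, min_len) {
  out <- data.frame(first_breath_index = integer(0), length = integer(0))
  i <- 1
  n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len)
        out <- rbind(out, data.frame(first_breath_index = i - 1L,
                                     length = j - i + 1L))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Two-sided pooled-variance t-test p-value: explicit statistic plus the t
# density integrated numerically (no pt()).
oracle_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  dens <- function(t)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tstat), Inf)$value
}

# OLS by explicit 2x2 normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  A <- matrix(c(n, sum(x), sum(x), sum(x^2)), 2)
  beta <- solve(A, c(sum(y), sum(x * y)))
  list(intercept = beta[1], slope = beta[2])
}

# Small event-free / event-bearing simulations shared across tests.
quiet_config <- function(duration_s = 400, seed = 1, fs = 1000, ...)
  sim_config(duration_s = duration_s, sample_rate_hz = fs,
             apnea_rate_per_h = 0, ifl_event_rate_per_h = 0,
             noise_sd_ml_s = 0, seed = seed, ...)
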