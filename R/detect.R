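#' Detector parameters
#'
#' Parameters of the flow-limitation and apnea detectors. The defaults are
#' the study settings: a 100-breath running baseline, a 2.576-SD threshold
#' (the two-sided standard-normal 99% critical value), aggregates of 3 or
#' more consecutive flow-limited breaths, apneas of at least 1 s, a relative
#' flow-cessation threshold of 5% of the running median PIF, and an
#' abnormality cut-off of control mean + 2 SD.
#'
#' @param window_w Running-baseline width in breaths (>= 2). Default 100.
#' @param z_thresh Threshold in SD multiples (> 0). Default 2.576.
#' @param aggregate_min Minimum run length of consecutive flow-limited
#'   breaths for an aggregate (>= 2). Default 3.
#' @param apnea_min_s Minimum apnea duration (s, > 0). Default 1.
#' @param apnea_flow_frac Flow-cessation threshold as a fraction of the
#'   running median PIF (0 < f < 1). Default 0.05.
#' @param cutoff_k SD multiples above the control mean for the abnormality
#'   cut-off. Default 2.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(window_w = 100L, z_thresh = 2.576,
                            aggregate_min = 3L, apnea_min_s = 1,
                            apnea_flow_frac = 0.05, cutoff_k = 2) {
  stopifnot(window_w >= 2, z_thresh > 0, aggregate_min >= 2,
            apnea_min_s > 0, apnea_flow_frac > 0, apnea_flow_frac < 1,
            cutoff_k >= 0)
  structure(list(window_w = as.integer(window_w), z_thresh = z_thresh,
                 aggregate_min = as.integer(aggregate_min),
                 apnea_min_s = apnea_min_s,
                 apnea_flow_frac = apnea_flow_frac, cutoff_k = cutoff_k),
            class = "detector_params")
}

#' Detect inspiratory flow limitation breath by breath
#'
#' Flags breath `i` as flow limited when, relative to the mean and sample SD
#' (n-1 denominator) of the preceding `window_w` breaths (the current breath
#' excluded, all prior breaths included regardless of their own flags):
#' the Ti/TV ratio is at least `z_thresh` SDs ABOVE the running mean, AND the
#' peak inspiratory flow is at least `z_thresh` SDs BELOW the running mean of
#' PIF. The conjunction guards against false positives from ratio outliers
#' with normal inspiratory drive. The first `window_w` breaths have no full
#' baseline and are never flagged. Degenerate windows with zero SD make the
#' corresponding criterion a strict inequality against the mean (any
#' deviation from a constant baseline is infinitely many SDs).
#'
#' The z-scores are scale-free, so rescaling the flow signal by any positive
#' constant leaves every flag unchanged.
#'
#' @param breaths Breath table from [segment_breaths()] (needs columns
#'   `ratio_s_per_ml` and `pif_ml_s`, in onset order).
#' @param params A [detector_params()].
#' @return Logical vector, one flag per breath.
#' @export
detect_ifl <- function(breaths, params = detector_params()) {
  w <- params$window_w
  z <- params$z_thresh
  n <- nrow(breaths)
  flags <- logical(n)
  if (n < w + 1L) {
    warning("fewer than window_w + 1 breaths; no breath has a full baseline")
    return(flags)
  }
  rs <- rolling_prev_stats(breaths$ratio_s_per_ml, w)
  ps <- rolling_prev_stats(breaths$pif_ml_s, w)
  i <- (w + 1L):n
  r <- breaths$ratio_s_per_ml[i]
  p <- breaths$pif_ml_s[i]
  cond_r <- ifelse(rs$sd[i] > 0, r >= rs$mean[i] + z * rs$sd[i], r > rs$mean[i])
  cond_p <- ifelse(ps$sd[i] > 0, p <= ps$mean[i] - z * ps$sd[i], p < ps$mean[i])
  flags[i] <- cond_r & cond_p
  flags
}

## rolling mean and sample SD of the w values PRECEDING each position
## (positions 1..w get NA). Centered cumulative sums keep the sum-of-squares
## update numerically clean.
rolling_prev_stats <- function(x, w) {
  n <- length(x)
  mu0 <- mean(x)
  xc <- x - mu0
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc^2))
  m <- rep(NA_real_, n)
  s <- rep(NA_real_, n)
  i <- (w + 1L):n
  s1 <- cs[i] - cs[i - w]
  s2 <- cs2[i] - cs2[i - w]
  v <- (s2 - s1^2 / w) / (w - 1)
  v[v < 0] <- 0
  ## scrub float dust so constant windows report an exact zero SD
  scale2 <- s2 / (w - 1)
  v[v < 1e-20 * pmax(scale2, 1e-300)] <- 0
  m[i] <- mu0 + s1 / w
  s[i] <- sqrt(v)
  list(mean = m, sd = s)
}

#' Detect aggregates of consecutive flow-limited breaths
#'
#' Maximal runs of consecutive flagged breaths with length at least
#' `aggregate_min` (default 3, the aggregate definition). A run of five
#' flagged breaths is one aggregate of length five, not three overlapping
#' runs of three.
#'
#' @param flags Logical vector from [detect_ifl()].
#' @param params A [detector_params()].
#' @return Data frame `first_breath_index` (0-based), `length`.
#' @export
detect_aggregates <- function(flags, params = detector_params()) {
  if (length(flags) == 0L)
    return(data.frame(first_breath_index = integer(0), length = integer(0)))
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$aggregate_min
  data.frame(first_breath_index = starts[keep] - 1L,
             length = r$lengths[keep])
}

#' Detect apneas on the raw flow signal
#'
#' An apnea is a maximal interval during which `|flow|` stays continuously
#' below a cessation threshold for at least `apnea_min_s` (default 1 s). The
#' threshold is relative -- `apnea_flow_frac` (default 5%) of the running
#' median PIF over the preceding `window_w` breaths -- so apnea calls, like
#' the flow-limitation flags, are invariant under rescaling the signal.
#' Where fewer than `window_w` breaths precede a sample, the global median
#' PIF is used as fallback. Detection runs on the raw trace, independent of
#' segmentation, so apneic gaps that belong to no breath are scanned
#' directly.
#'
#' @param trace A [flow_trace()].
#' @param breaths Breath table from [segment_breaths()] for the same trace
#'   (supplies the PIF baseline).
#' @param params A [detector_params()].
#' @return Data frame `start_s`, `end_s` of disjoint, ordered apnea
#'   intervals (half-open, `end_s - start_s >= apnea_min_s`).
#' @export
detect_apneas <- function(trace, breaths, params = detector_params()) {
  f <- trace$flow
  fs <- trace$sample_rate_hz
  n <- length(f)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n == 0L) return(empty)
  if (nrow(breaths) == 0L) {
    warning("no breaths segmented; cannot calibrate the cessation threshold")
    return(empty)
  }
  w <- params$window_w
  pif <- breaths$pif_ml_s
  nb <- length(pif)
  global_med <- stats::median(pif)
  thr_b <- rep(global_med, nb + 1L)  # thr_b[j+1] applies after j breaths began
  if (nb >= w) {
    rmed <- data.table::frollapply(pif, w, stats::median)
    ## after j >= w breaths, use the median of breaths (j-w+1)..j
    thr_b[(w + 1L):(nb + 1L)] <- rmed[w:nb]
  }
  t <- trace$start_time_s + (seq_len(n) - 1) / fs
  j <- findInterval(t, breaths$onset_s)
  theta <- params$apnea_flow_frac * thr_b[j + 1L]
  below <- abs(f) < theta
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs) >= params$apnea_min_s
  data.frame(start_s = trace$start_time_s + (starts[keep] - 1L) / fs,
             end_s = trace$start_time_s + ends[keep] / fs)
}

#' Summarize events over an observation period
#'
#' Absolute frequencies normalize to the total observation period
#' (apnea/h, IFL/h, aggregates/h); the proportional IFL frequency (%)
#' normalizes to the total number of breaths.
#'
#' @param events List with `ifl_flags` (logical per breath), `aggregates`
#'   (data frame), and `apneas` (data frame), e.g. from [detect_events()].
#' @param observation_h Observation period in hours (> 0).
#' @param n_breaths Total breath count (>= 0).
#' @return A one-row data frame: `observation_h`, `n_breaths`, `apnea_per_h`,
#'   `ifl_per_h`, `ifl_pct`, `aggregate_per_h`.
#' @export
summarize_events <- function(events, observation_h, n_breaths) {
  stopifnot(observation_h > 0, n_breaths >= 0)
  n_ifl <- sum(events$ifl_flags)
  data.frame(observation_h = observation_h,
             n_breaths = n_breaths,
             apnea_per_h = nrow(events$apneas) / observation_h,
             ifl_per_h = n_ifl / observation_h,
             ifl_pct = if (n_breaths > 0) 100 * n_ifl / n_breaths else 0,
             aggregate_per_h = nrow(events$aggregates) / observation_h)
}

#' Run all detectors on one recording
#'
#' Convenience wrapper: IFL flags, aggregates, and apneas for one segmented
#' recording, optionally restricted to sleep or wake epochs (an event counts
#' toward an epoch when its start -- breath onset or apnea start -- lies in
#' that epoch; the observation period is then the summed epoch duration).
#'
#' @param trace A [flow_trace()].
#' @param breaths Breath table from [segment_breaths()].
#' @param params A [detector_params()].
#' @param epoch `"all"` (default), `"sleep"`, or `"wake"`.
#' @return List of class `event_set`: `ifl_flags`, `aggregates`, `apneas`,
#'   `summary` (from [summarize_events()]), `params`, `epoch`.
#' @export
detect_events <- function(trace, breaths, params = detector_params(),
                          epoch = c("all", "sleep", "wake")) {
  epoch <- match.arg(epoch)
  flags <- detect_ifl(breaths, params)
  aggs <- detect_aggregates(flags, params)
  apneas <- detect_apneas(trace, breaths, params)
  if (epoch == "all") {
    obs_h <- trace_duration_s(trace) / 3600
    fl <- flags; ag <- aggs; ap <- apneas; nb <- nrow(breaths)
  } else {
    sched <- trace$epoch_schedule
    obs_h <- sum(sched$end_s[sched$state == epoch] -
                 sched$start_s[sched$state == epoch]) / 3600
    if (obs_h <= 0) stop("no '", epoch, "' epochs in the schedule")
    b_in <- epoch_state(breaths$onset_s, sched) == epoch
    b_in[is.na(b_in)] <- FALSE
    fl <- flags & b_in
    agg_onset <- breaths$onset_s[aggs$first_breath_index + 1L]
    ag <- aggs[!is.na(agg_onset) &
               epoch_state(agg_onset, sched) == epoch, , drop = FALSE]
    ap_in <- epoch_state(apneas$start_s, sched) == epoch
    ap_in[is.na(ap_in)] <- FALSE
    ap <- apneas[ap_in, , drop = FALSE]
    nb <- sum(b_in)
  }
  ev <- list(ifl_flags = fl, aggregates = ag, apneas = ap)
  ev$summary <- summarize_events(ev, obs_h, nb)
  ev$params <- params
  ev$epoch <- epoch
  class(ev) <- "event_set"
  ev
}

#' Abnormality cut-off from control animals
#'
#' The apnea frequency above which an animal is called abnormal: control
#' mean plus `k` sample SDs (n-1 denominator). With the printed control
#' statistics (mean 6.27/h, SEM 0.80, N = 28, so SD = 0.80 * sqrt(28)) and
#' k = 2 this reconstructs the 14.75 apneas/h cut-off to within rounding of
#' the printed SEM.
#'
#' @param control_values Per-animal apnea frequencies (/h) of the control
#'   group; at least 2 values.
#' @param k SD multiples above the mean. Default 2.
#' @return The cut-off (/h).
#' @export
abnormal_cutoff <- function(control_values, k = 2) {
  if (length(control_values) < 2)
    stop("need at least 2 control values to estimate a standard deviation")
  mean(control_values) + k * stats::sd(control_values)
}

#' Classify an apnea frequency against the cut-off
#'
#' Abnormal means strictly greater than the cut-off.
#'
#' @param apnea_per_h Apnea frequency (/h), scalar or vector.
#' @param cutoff Cut-off (/h), >= 0.
#' @return Logical.
#' @export
classify_abnormal <- function(apnea_per_h, cutoff) {
  stopifnot(cutoff >= 0)
  apnea_per_h > cutoff
}
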