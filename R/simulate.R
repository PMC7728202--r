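#' Simulate a box-flow recording with ground-truth events
#'
#' Generates a uniformly sampled whole-body plethysmography box-flow signal
#' (inspiration positive by convention) built from per-breath half-sine
#' templates, together with a ground-truth log of every injected event.
#'
#' Each breath cycle of period `P` has a half-sine inspiratory lobe of
#' duration `Ti = insp_fraction * P` and amplitude `PIF`, and a half-sine
#' expiratory lobe scaled so the cycle integrates to zero; the inspiratory
#' tidal volume is then `TV = 2 * PIF * Ti / pi` in closed form. Obstructive
#' bursts replace affected breaths with a plateau-clipped inspiratory lobe:
#' PIF is lowered by `ifl_pif_drop_sd` baseline SDs and Ti lengthened by
#' `ifl_ti_gain_sd` baseline SDs, the conjunction the dual IFL criterion
#' requires. Apneas replace whole consecutive breath cycles with zero flow
#' (plus sensor noise), never splitting a lobe, so segmentation stays
#' well-posed; each injected apnea lasts at least the drawn duration (>= 1 s).
#'
#' A single global random stream seeded from `config$seed` is consumed in a
#' fixed, documented order -- (1) apnea count, (2) burst count, (3) apnea
#' durations, (4) burst lengths, (5) breath periods, (6) breath amplitudes,
#' (7) burst placements, (8) apnea placements, (9) additive noise -- so that
#' event counts can be replayed independently (e.g. the number of apneas is
#' the first `rpois` draw under the same seed). Identical configs give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (a [flow_trace()]) and `truth`, a
#'   `ground_truth_log` list with:
#'   \describe{
#'     \item{apneas}{data frame `start_s`, `end_s` (each >= 1 s, disjoint,
#'       inside sleep epochs).}
#'     \item{ifl_breaths}{0-based ordinals of flow-limited breaths within the
#'       emitted breath sequence.}
#'     \item{bursts}{data frame `first_breath_index` (0-based), `length`.}
#'     \item{ifl_onsets_s}{onset times of the flow-limited breaths.}
#'     \item{n_breaths}{number of emitted (non-replaced) breaths.}
#'     \item{breaths}{data frame of nominal per-breath features
#'       (`onset_s`, `ti_s`, `te_s`, `tv_ml`, `pif_ml_s`).}
#'   }
#' @examples
#' rec <- simulate_recording(sim_config(duration_s = 60, seed = 42))
#' length(rec$trace$flow)
#' nrow(rec$truth$apneas)
#' @export
simulate_recording <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  dur <- config$duration_s
  sched <- config$epoch_schedule

  sleep <- sched[sched$state == "sleep", , drop = FALSE]
  sleep_h <- sum(pmax(0, sleep$end_s - sleep$start_s)) / 3600

  ## (1)-(2) event counts (rates first, so replay needs only these draws)
  n_apneas <- stats::rpois(1, config$apnea_rate_per_h * sleep_h)
  n_bursts <- stats::rpois(1, config$ifl_event_rate_per_h * sleep_h)

  ## (3)-(4) event morphologies
  ap_dur <- if (n_apneas > 0)
    stats::runif(n_apneas, config$apnea_duration_s_range[1],
                 config$apnea_duration_s_range[2]) else numeric(0)
  burst_len <- if (n_bursts == 0L) integer(0)
  else if (identical(config$ifl_burst_len_dist, "fixed"))
    rep(max(1L, as.integer(round(config$ifl_burst_mean_len))), n_bursts)
  else 1L + stats::rgeom(n_bursts, 1 / config$ifl_burst_mean_len)

  ## (5)-(6) breath morphologies: periods and amplitudes, log-normal
  mean_period <- 1 / config$breath_rate_hz
  n_est <- ceiling(dur / mean_period * 1.5) + 20L
  period <- rlnorm_mean_cv(n_est, mean_period, config$breath_rate_cv)
  amp <- rlnorm_mean_cv(n_est, config$amplitude_ml_s, config$amplitude_cv)

  onset <- cumsum(c(0, period))[seq_len(n_est)]
  keep <- onset + period <= dur
  nb <- sum(keep)
  if (nb < 1L) stop("duration too short for a single breath cycle")
  period <- period[seq_len(nb)]
  onset <- onset[seq_len(nb)]
  amp <- amp[seq_len(nb)]
  ti <- config$insp_fraction * period
  te <- period - ti

  breath_sleep <- epoch_state(onset, sched) == "sleep" &
    epoch_state(pmin(onset + period, dur - 1e-12), sched) == "sleep"
  breath_sleep[is.na(breath_sleep)] <- FALSE

  ## analytic baseline SDs (the units the effect sizes are stated in)
  sd_pif <- config$amplitude_ml_s * config$amplitude_cv
  sd_ti <- config$insp_fraction * mean_period * config$breath_rate_cv

  type <- rep("normal", nb)  # normal | event | apnea
  pif_target <- amp

  ## (7) burst placements: rejection-resample starts among sleep breaths
  occupied <- logical(nb)
  sleep_idx <- which(breath_sleep)
  place <- function(len, buffer = 0L, max_try = 500L) {
    for (a in seq_len(max_try)) {
      if (length(sleep_idx) == 0L) break
      s <- sleep_idx[sample.int(length(sleep_idx), 1L)]
      span <- s:(s + len - 1L)
      guard <- max(1L, s - buffer):min(nb, s + len - 1L + buffer)
      if (s + len - 1L <= nb && all(breath_sleep[span]) && !any(occupied[guard]))
        return(s)
    }
    stop("event density too high: could not place an injected event after ",
         max_try, " attempts")
  }
  burst_start <- integer(n_bursts)
  for (b in seq_len(n_bursts)) {
    s <- place(burst_len[b])
    burst_start[b] <- s
    span <- s:(s + burst_len[b] - 1L)
    occupied[span] <- TRUE
    type[span] <- "event"
  }

  ## (8) apnea placements: replace whole cycles covering the drawn duration;
  ## one-breath buffer keeps injected apneas non-adjacent as well as disjoint
  apnea_first <- integer(n_apneas)
  apnea_k <- integer(n_apneas)
  for (a in seq_len(n_apneas)) {
    dur_a <- ap_dur[a]
    k_at <- function(s) {
      cs <- cumsum(period[s:nb])
      k <- which(cs >= dur_a)[1]
      if (is.na(k)) Inf else k
    }
    found <- FALSE
    for (try in seq_len(500L)) {
      s <- sleep_idx[sample.int(length(sleep_idx), 1L)]
      k <- k_at(s)
      if (!is.finite(k)) next
      span <- s:(s + k - 1L)
      guard <- max(1L, s - 1L):min(nb, s + k)
      if (s + k - 1L <= nb && all(breath_sleep[span]) && !any(occupied[guard])) {
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("event density too high: could not place an injected apnea after 500 attempts")
    apnea_first[a] <- s
    apnea_k[a] <- k
    span <- s:(s + k - 1L)
    occupied[span] <- TRUE
    type[span] <- "apnea"
  }

  ## obstructive morphology: lower PIF, lengthen Ti (plateau-clipped lobe).
  ## Targets are referenced to the population baseline (mean - k SD), not the
  ## breath's own draw, so the realized effect size IS the configured one.
  ev <- type == "event"
  clip_frac <- 0.85  # plateau begins where the underlying sine exceeds this
  if (any(ev)) {
    pif_target[ev] <- max(config$amplitude_ml_s -
                            config$ifl_pif_drop_sd * sd_pif,
                          0.05 * config$amplitude_ml_s)
    ti[ev] <- pmin(config$insp_fraction * mean_period +
                     config$ifl_ti_gain_sd * sd_ti, 0.9 * period[ev])
    te[ev] <- period[ev] - ti[ev]
  }

  ## per-breath inspiratory tidal volume (closed forms)
  tv <- 2 * amp * ti / pi
  if (any(ev)) {
    au <- pif_target[ev] / clip_frac
    tau0 <- ti[ev] * asin(clip_frac) / pi
    tv[ev] <- 2 * au * ti[ev] / pi * (1 - sqrt(1 - clip_frac^2)) +
      pif_target[ev] * (ti[ev] - 2 * tau0)
  }
  a_exp <- tv * pi / (2 * te)  # expiratory amplitude balancing the cycle area

  ## assemble signal
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  bi <- findInterval(t, onset)
  bi[bi < 1L] <- 1L
  tau <- t - onset[bi]
  a_und <- ifelse(ev, pif_target / clip_frac, amp)  # underlying insp amplitude
  clip <- ifelse(ev, pif_target, Inf)
  live <- type[bi] != "apnea"
  flow <- numeric(n)
  ii <- live & tau < ti[bi]
  flow[ii] <- pmin(a_und[bi[ii]] * sin(pi * tau[ii] / ti[bi[ii]]), clip[bi[ii]])
  ee <- live & tau >= ti[bi] & tau < ti[bi] + te[bi]
  flow[ee] <- -a_exp[bi[ee]] * sin(pi * (tau[ee] - ti[bi[ee]]) / te[bi[ee]])

  ## (9) sensor noise, drawn last
  if (config$noise_sd_ml_s > 0)
    flow <- flow + stats::rnorm(n, 0, config$noise_sd_ml_s)

  ## ground truth in final (emitted-breath) ordinals, 0-based
  kept <- type != "apnea"
  final_idx <- cumsum(kept) - 1L  # valid where kept
  ifl0 <- final_idx[ev]
  bursts <- if (n_bursts > 0)
    data.frame(first_breath_index = final_idx[burst_start],
               length = burst_len) else
    data.frame(first_breath_index = integer(0), length = integer(0))
  apneas <- if (n_apneas > 0) {
    st <- onset[apnea_first]
    en <- st + vapply(seq_len(n_apneas), function(a)
      sum(period[apnea_first[a]:(apnea_first[a] + apnea_k[a] - 1L)]), 0)
    o <- order(st)
    data.frame(start_s = st[o], end_s = en[o])
  } else data.frame(start_s = numeric(0), end_s = numeric(0))

  truth <- list(
    apneas = apneas,
    ifl_breaths = sort(as.integer(ifl0)),
    bursts = bursts[order(bursts$first_breath_index), , drop = FALSE],
    ifl_onsets_s = sort(onset[ev]),
    n_breaths = sum(kept),
    breaths = data.frame(onset_s = onset[kept], ti_s = ti[kept],
                         te_s = te[kept], tv_ml = tv[kept],
                         pif_ml_s = ifelse(ev, pif_target, amp)[kept])
  )
  class(truth) <- "ground_truth_log"

  trace <- flow_trace(flow, sample_rate_hz = fs, start_time_s = 0,
                      epoch_schedule = sched)
  list(trace = trace, truth = truth)
}

## log-normal draws parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}
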