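#' Simulation configuration for synthetic box-flow recordings
#'
#' Builds the parameter set consumed by [simulate_recording()]. The defaults
#' describe a quietly sleeping adult mouse: breathing around 3 Hz with ~10%
#' cycle-to-cycle variability, peak inspiratory flow (PIF) around 1 ml/s, and
#' obstructive events (clustered flow-limited breaths and >= 1 s apneas)
#' injected only within sleep epochs.
#'
#' Per-breath rate and amplitude are drawn log-normally; obstructive breaths
#' lower PIF and lengthen inspiration by effect sizes expressed in multiples
#' of the baseline between-breath standard deviation, so detectability is
#' controlled directly in the units the detector thresholds use.
#'
#' @param duration_s Recording length in seconds.
#' @param sample_rate_hz Sampling rate of the box-flow signal (Hz).
#' @param breath_rate_hz Mean breathing rate (breaths per second).
#' @param breath_rate_cv Coefficient of variation of the breath period.
#' @param amplitude_ml_s Mean peak inspiratory flow (ml/s).
#' @param amplitude_cv Coefficient of variation of PIF across breaths.
#' @param insp_fraction Fraction of each breath cycle spent in inspiration
#'   (0 < f < 1).
#' @param epoch_schedule Data frame with columns `start_s`, `end_s`, `state`
#'   (`"sleep"` or `"wake"`) covering `[0, duration_s]` without gaps or
#'   overlap.
#' @param apnea_rate_per_h Expected apneas per hour of sleep.
#' @param apnea_duration_s_range Length-2 numeric, minimum and maximum
#'   injected apnea duration in seconds; the minimum must be >= 1 so every
#'   injected event satisfies the >= 1 s apnea definition.
#' @param ifl_event_rate_per_h Expected obstructive bursts (clusters of
#'   flow-limited breaths) per hour of sleep.
#' @param ifl_burst_mean_len Mean burst length in breaths; under the default
#'   geometric mode lengths are drawn as 1 + geometric so the support is
#'   >= 1 and >= 3-breath aggregates arise.
#' @param ifl_burst_len_dist `"geometric"` (default, the study condition) or
#'   `"fixed"`, in which every burst has exactly
#'   `round(ifl_burst_mean_len)` breaths. The fixed mode yields the
#'   controlled bursts used for detector validation, where burst length must
#'   be held at a known value (a long geometric burst contaminates its own
#'   running baseline and degrades late-breath detectability; see the
#'   methods vignette).
#' @param ifl_pif_drop_sd PIF reduction on affected breaths, in baseline-SD
#'   units.
#' @param ifl_ti_gain_sd Inspiration-time lengthening on affected breaths, in
#'   baseline-SD units.
#' @param noise_sd_ml_s Standard deviation of additive Gaussian sensor noise
#'   (ml/s).
#' @param seed Integer seed; identical configs (including seed) reproduce the
#'   recording bit for bit.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_recording()], [wake_sleep_preset()]
#' @export
sim_config <- function(duration_s = 600,
                       sample_rate_hz = 1000,
                       breath_rate_hz = 3,
                       breath_rate_cv = 0.10,
                       amplitude_ml_s = 1,
                       amplitude_cv = 0.10,
                       insp_fraction = 0.40,
                       epoch_schedule = data.frame(start_s = 0,
                                                   end_s = duration_s,
                                                   state = "sleep"),
                       apnea_rate_per_h = 6,
                       apnea_duration_s_range = c(1, 3),
                       ifl_event_rate_per_h = 15,
                       ifl_burst_mean_len = 4,
                       ifl_burst_len_dist = c("geometric", "fixed"),
                       ifl_pif_drop_sd = 5,
                       ifl_ti_gain_sd = 5,
                       noise_sd_ml_s = 0.005,
                       seed = 1L) {
  cfg <- list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
              breath_rate_hz = breath_rate_hz, breath_rate_cv = breath_rate_cv,
              amplitude_ml_s = amplitude_ml_s, amplitude_cv = amplitude_cv,
              insp_fraction = insp_fraction, epoch_schedule = epoch_schedule,
              apnea_rate_per_h = apnea_rate_per_h,
              apnea_duration_s_range = apnea_duration_s_range,
              ifl_event_rate_per_h = ifl_event_rate_per_h,
              ifl_burst_mean_len = ifl_burst_mean_len,
              ifl_burst_len_dist = match.arg(ifl_burst_len_dist),
              ifl_pif_drop_sd = ifl_pif_drop_sd,
              ifl_ti_gain_sd = ifl_ti_gain_sd,
              noise_sd_ml_s = noise_sd_ml_s,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: positive duration and
#' sampling rate, inspiratory fraction in (0, 1), injected apnea durations
#' >= 1 s, and an epoch schedule that tiles `[0, duration_s]` exactly.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly; errors if any invariant is violated.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(is.numeric(cfg$duration_s) && cfg$duration_s > 0))
    stop("duration_s must be > 0")
  if (!(is.numeric(cfg$sample_rate_hz) && cfg$sample_rate_hz > 0))
    stop("sample_rate_hz must be > 0")
  if (!(cfg$insp_fraction > 0 && cfg$insp_fraction < 1))
    stop("insp_fraction must lie strictly between 0 and 1")
  rng <- cfg$apnea_duration_s_range
  if (length(rng) != 2 || rng[1] < 1 || rng[2] < rng[1])
    stop("apnea_duration_s_range must be (min >= 1, max >= min): injected apneas must last at least 1 s")
  if (cfg$breath_rate_hz <= 0 || cfg$breath_rate_cv < 0 ||
      cfg$amplitude_ml_s <= 0 || cfg$amplitude_cv < 0 ||
      cfg$apnea_rate_per_h < 0 || cfg$ifl_event_rate_per_h < 0 ||
      cfg$ifl_burst_mean_len < 1 || cfg$noise_sd_ml_s < 0)
    stop("rate, amplitude, burst-length and noise parameters must be non-negative (mean burst length >= 1)")
  validate_epoch_schedule(cfg$epoch_schedule, cfg$duration_s)
  invisible(cfg)
}

validate_epoch_schedule <- function(sched, duration_s) {
  stopifnot(is.data.frame(sched),
            all(c("start_s", "end_s", "state") %in% names(sched)))
  if (!all(sched$state %in% c("sleep", "wake")))
    stop("epoch states must be 'sleep' or 'wake'")
  sched <- sched[order(sched$start_s), , drop = FALSE]
  tol <- 1e-9 * max(1, duration_s)
  if (abs(sched$start_s[1]) > tol ||
      abs(sched$end_s[nrow(sched)] - duration_s) > tol ||
      any(sched$end_s <= sched$start_s) ||
      (nrow(sched) > 1 &&
       any(abs(sched$start_s[-1] - sched$end_s[-nrow(sched)]) > tol)))
    stop("epoch_schedule must cover [0, duration_s] without gaps or overlap")
  invisible(sched)
}

#' Ready-made recording schedules
#'
#' Returns a [sim_config()] for the two standard observation designs:
#' `day_sleep_8h`, an 8 h day-time recording treated as one sleep-dominant
#' block (28800 s), and `full_22h`, a 22 h observation starting at 10 p.m.
#' with a 9 h night-time wake block (mice are nocturnal) followed by a 13 h
#' day-time sleep block (79200 s total). Obstructive events are injected in
#' sleep epochs only, so the wake block of `full_22h` is event-free by
#' construction.
#'
#' @param kind `"day_sleep_8h"` or `"full_22h"`.
#' @param ... Overrides passed on to [sim_config()] (e.g. `seed`,
#'   `apnea_rate_per_h`).
#' @return A `sim_config`.
#' @export
wake_sleep_preset <- function(kind = c("day_sleep_8h", "full_22h"), ...) {
  kind <- match.arg(kind)
  if (kind == "day_sleep_8h") {
    dur <- 8 * 3600
    sched <- data.frame(start_s = 0, end_s = dur, state = "sleep")
  } else {
    dur <- 22 * 3600
    night <- 9 * 3600  # 10 p.m. to 7 a.m.
    sched <- data.frame(start_s = c(0, night), end_s = c(night, dur),
                        state = c("wake", "sleep"))
  }
  sim_config(duration_s = dur, epoch_schedule = sched, ...)
}

#' State of the epoch schedule at given times
#'
#' @param t_s Numeric vector of times (s).
#' @param sched Epoch schedule data frame (`start_s`, `end_s`, `state`).
#' @return Character vector of states (`NA` outside the schedule). Epochs are
#'   half-open `[start_s, end_s)`.
#' @export
epoch_state <- function(t_s, sched) {
  sched <- sched[order(sched$start_s), , drop = FALSE]
  idx <- findInterval(t_s, sched$start_s)
  out <- rep(NA_character_, length(t_s))
  ok <- idx >= 1 & t_s < sched$end_s[pmax(idx, 1)]
  out[ok] <- sched$state[idx[ok]]
  out
}
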