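#' Flow trace container
#'
#' A uniformly sampled box-flow signal. Flow is in ml/s with inspiration
#' positive (the package-wide sign convention; use `invert` on read for
#' recordings acquired with the opposite polarity). Gaps are not allowed:
#' a trace must be one contiguous uniformly sampled block.
#'
#' @param flow Numeric vector of flow samples (ml/s).
#' @param sample_rate_hz Sampling rate (Hz), > 0.
#' @param start_time_s Time of the first sample (s).
#' @param epoch_schedule Optional sleep/wake schedule data frame
#'   (`start_s`, `end_s`, `state`); defaults to one sleep epoch spanning the
#'   trace.
#' @return An object of class `flow_trace`.
#' @export
flow_trace <- function(flow, sample_rate_hz, start_time_s = 0,
                       epoch_schedule = NULL) {
  stopifnot(is.numeric(flow), length(flow) > 0,
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  if (anyNA(flow)) stop("flow contains missing samples")
  dur <- length(flow) / sample_rate_hz
  if (is.null(epoch_schedule))
    epoch_schedule <- data.frame(start_s = start_time_s,
                                 end_s = start_time_s + dur,
                                 state = "sleep")
  structure(list(flow = as.numeric(flow),
                 sample_rate_hz = sample_rate_hz,
                 start_time_s = start_time_s,
                 epoch_schedule = epoch_schedule),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples @ %g Hz (%.1f s), start %.3f s\n",
              length(x$flow), x$sample_rate_hz,
              length(x$flow) / x$sample_rate_hz, x$start_time_s))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A [flow_trace()].
#' @return Duration (s).
#' @export
trace_duration_s <- function(trace) length(trace$flow) / trace$sample_rate_hz

#' Write a flow trace as CSV with a JSON sidecar
#'
#' Writes a two-column CSV (`time_s,flow_ml_s`) and a `<path>.json` sidecar
#' holding the sampling rate, start time, and epoch schedule so that
#' [read_flow_csv()] can round-trip the trace.
#'
#' @param trace A [flow_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(trace, path) {
  n <- length(trace$flow)
  time_s <- trace$start_time_s + (seq_len(n) - 1) / trace$sample_rate_hz
  data.table::fwrite(data.table::data.table(time_s = time_s,
                                            flow_ml_s = trace$flow),
                     path)
  side <- list(sample_rate_hz = trace$sample_rate_hz,
               start_time_s = trace$start_time_s,
               units = "ml_s",
               epoch_schedule = trace$epoch_schedule)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a flow trace from CSV
#'
#' Reads a two-column CSV (`time_s,flow_ml_s`), merging the `<path>.json`
#' sidecar (sampling rate, start time, epoch schedule) when present.
#' Timestamps must be uniform: the maximum deviation of any timestamp from
#' the ideal uniform grid may not exceed 1 ppm of the recording span, so a
#' dropped-sample gap is rejected with a discontinuity diagnostic rather than
#' silently zero-padded.
#'
#' @param path CSV path.
#' @param invert If `TRUE`, flip the sign of the flow channel (for recordings
#'   where inspiration was acquired as negative).
#' @param units Expected flow units; only `"ml_s"` is supported. Files whose
#'   sidecar declares other units are rejected unless `units` overrides them.
#' @return A [flow_trace()].
#' @export
read_flow_csv <- function(path, invert = FALSE, units = NULL) {
  dt <- data.table::fread(path)
  if (!all(c("time_s", "flow_ml_s") %in% names(dt)))
    stop("expected columns 'time_s' and 'flow_ml_s' in ", path)
  n <- nrow(dt)
  if (n < 2) stop("trace must contain at least 2 samples")
  tt <- dt$time_s
  span <- tt[n] - tt[1]
  fs <- (n - 1) / span
  ideal <- tt[1] + (seq_len(n) - 1) / fs
  if (max(abs(tt - ideal)) > 1e-6 * max(span, 1))
    stop("time discontinuity: timestamps deviate from a uniform grid by more ",
         "than 1 ppm of the recording span (missing samples are rejected, ",
         "not zero-padded)")
  side_path <- paste0(path, ".json")
  sched <- NULL
  start_time <- tt[1]
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$sample_rate_hz)) fs <- side$sample_rate_hz
    if (!is.null(side$start_time_s)) start_time <- side$start_time_s
    if (!is.null(side$epoch_schedule))
      sched <- as.data.frame(side$epoch_schedule)
    if (!is.null(side$units) && side$units != "ml_s" && is.null(units))
      stop("unknown flow units '", side$units,
           "' in sidecar; pass units = 'ml_s' to override")
  }
  flow <- dt$flow_ml_s
  if (invert) flow <- -flow
  flow_trace(flow, sample_rate_hz = fs, start_time_s = start_time,
             epoch_schedule = sched)
}
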