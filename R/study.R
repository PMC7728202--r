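#' Study configuration
#'
#' Declares a two-group plethysmography study: one entry per animal, either
#' a [sim_config()] to simulate or a CSV trace path to read, plus detector
#' settings, the epoch restriction, optional per-animal metadata (e.g.
#' tongue diameters) and the regression pairs to fit.
#'
#' @param recordings List of entries, each a list with `animal_id`
#'   (unique), `group` (`"control"` or `"treated"`), and either `config`
#'   (a `sim_config`) or `trace_path` (CSV readable by [read_flow_csv()]).
#' @param detector A [detector_params()].
#' @param epoch_filter `"all"`, `"sleep"`, or `"wake"`.
#' @param metadata Optional data frame keyed by `animal_id`, merged into the
#'   per-animal table before regressions.
#' @param regressions List of 2-element character vectors `c(x, y)` naming
#'   columns of the per-animal table to regress.
#' @param seed Integer base seed; recording `i` simulated from a `sim_config`
#'   has its seed replaced by `seed + 7919 * i` (unless the entry sets
#'   `keep_seed = TRUE`).
#' @return List of class `study_config`.
#' @export
study_config <- function(recordings, detector = detector_params(),
                         epoch_filter = c("all", "sleep", "wake"),
                         metadata = NULL, regressions = list(),
                         seed = 1L) {
  epoch_filter <- match.arg(epoch_filter)
  if (length(recordings) == 0) stop("empty recording list")
  ids <- vapply(recordings, function(r) as.character(r$animal_id), "")
  if (anyDuplicated(ids)) stop("animal_ids must be unique")
  groups <- vapply(recordings, function(r) as.character(r$group), "")
  if (!all(groups %in% c("control", "treated")))
    stop("group labels must be 'control' or 'treated'")
  structure(list(recordings = recordings, detector = detector,
                 epoch_filter = epoch_filter, metadata = metadata,
                 regressions = regressions, seed = as.integer(seed)),
            class = "study_config")
}

#' Run a two-group plethysmography study end to end
#'
#' For every recording: obtain the trace (simulate or read), segment it,
#' run the flow-limitation, aggregate and apnea detectors, and summarize
#' event frequencies under the configured epoch restriction. Then derive
#' the abnormality cut-off from the control group (mean + `cutoff_k` SD of
#' per-animal apnea frequency), build the group-by-abnormal 2x2 table and
#' test it with the uncorrected chi-square, run the normality-gated
#' comparison on each endpoint (`apnea_per_h`, `ifl_per_h`, `ifl_pct`,
#' `aggregate_per_h`), and fit any configured regressions.
#'
#' The full parameter set and seed are echoed in the returned report, so
#' every reported number is reproducible from the report alone.
#'
#' @param config A [study_config()].
#' @return List of class `study_report`: `per_animal` (data frame),
#'   `cutoff`, `abnormal_table` (2x2), `chisq` (or `NULL` if a margin is
#'   degenerate), `comparisons` (named list of `comparison_result` or
#'   `NULL`), `regressions` (named list), `config_echo`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  params <- config$detector
  rows <- vector("list", length(config$recordings))
  for (i in seq_along(config$recordings)) {
    rec <- config$recordings[[i]]
    if (!is.null(rec$config)) {
      cfg <- rec$config
      if (!isTRUE(rec$keep_seed))
        cfg$seed <- as.integer((config$seed + 7919 * i) %% .Machine$integer.max)
      trace <- simulate_recording(cfg)$trace
    } else if (!is.null(rec$trace_path)) {
      trace <- read_flow_csv(rec$trace_path)
    } else {
      stop("recording entry needs either a sim config or a trace path")
    }
    breaths <- segment_breaths(trace)
    ev <- detect_events(trace, breaths, params, epoch = config$epoch_filter)
    rows[[i]] <- cbind(data.frame(animal_id = as.character(rec$animal_id),
                                  group = as.character(rec$group),
                                  stringsAsFactors = FALSE),
                       ev$summary)
  }
  per_animal <- do.call(rbind, rows)

  ctrl <- per_animal$apnea_per_h[per_animal$group == "control"]
  if (length(ctrl) == 0) stop("control group empty: cannot compute cut-off")
  if (length(ctrl) < 2) stop("need >= 2 control animals for the cut-off SD")
  cutoff <- abnormal_cutoff(ctrl, k = params$cutoff_k)
  per_animal$abnormal <- classify_abnormal(per_animal$apnea_per_h, cutoff)

  abn_tab <- table(factor(per_animal$group, c("control", "treated")),
                   factor(per_animal$abnormal, c(TRUE, FALSE),
                          labels = c("abnormal", "normal")))
  abn_tab <- unclass(abn_tab)
  chisq <- NULL
  if (all(rowSums(abn_tab) > 0) && all(colSums(abn_tab) > 0))
    chisq <- chi_square_2x2(abn_tab)
  else
    warning("degenerate abnormality margins; chi-square skipped")

  endpoints <- c("apnea_per_h", "ifl_per_h", "ifl_pct", "aggregate_per_h")
  ga <- function(col) {
    a <- per_animal[[col]][per_animal$group == "treated"]
    b <- per_animal[[col]][per_animal$group == "control"]
    if (length(a) < 3 || length(b) < 3) {
      warning("group too small for '", col, "' comparison; skipped")
      return(NULL)
    }
    gated_compare(a, b)
  }
  comparisons <- stats::setNames(lapply(endpoints, ga), endpoints)

  tab <- per_animal
  if (!is.null(config$metadata))
    tab <- merge(tab, config$metadata, by = "animal_id", sort = FALSE)
  regs <- list()
  for (pair in config$regressions) {
    nm <- paste(pair[2], "on", pair[1])
    regs[[nm]] <- lin_regress(tab[[pair[1]]], tab[[pair[2]]])
  }

  structure(list(per_animal = per_animal, cutoff = cutoff,
                 abnormal_table = abn_tab, chisq = chisq,
                 comparisons = comparisons, regressions = regs,
                 config_echo = config),
            class = "study_report")
}

#' Render a study report as markdown
#'
#' One mean±SEM row per endpoint (two decimals, the conventional table
#' format) with the test used and its p-value, the abnormality cut-off and
#' 2x2 table with the chi-square result, any regressions, and the full
#' detector-parameter provenance. Rendering is deterministic: the same
#' report yields byte-identical text.
#'
#' @param report A `study_report` from [run_study()].
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "study_report"))
  p <- report$config_echo$detector
  fmt <- function(m, s) sprintf("%.2f±%.2f", m, s)
  out <- c("# Plethysmography study report", "",
           sprintf("Animals: %d control, %d treated; epoch filter: %s.",
                   sum(report$per_animal$group == "control"),
                   sum(report$per_animal$group == "treated"),
                   report$config_echo$epoch_filter), "",
           "## Endpoints (treated vs control)", "",
           "| Endpoint | Treated | Control | Test | p |",
           "|---|---|---|---|---|")
  for (nm in names(report$comparisons)) {
    cr <- report$comparisons[[nm]]
    out <- c(out, if (is.null(cr))
      sprintf("| %s | – | – | skipped | – |", nm)
    else
      sprintf("| %s | %s | %s | %s | %.3g |", nm,
              fmt(cr$mean_a, cr$sem_a), fmt(cr$mean_b, cr$sem_b),
              ifelse(cr$test_used == "t_test", "Student's t", "Mann-Whitney"),
              cr$p_two_sided))
  }
  out <- c(out, "",
           sprintf("Abnormality cut-off (control mean + %g SD): %.2f apneas/h.",
                   p$cutoff_k, report$cutoff), "",
           sprintf("Abnormal (apnea/h > cut-off): control %d/%d, treated %d/%d.",
                   report$abnormal_table["control", "abnormal"],
                   sum(report$abnormal_table["control", ]),
                   report$abnormal_table["treated", "abnormal"],
                   sum(report$abnormal_table["treated", ])))
  if (!is.null(report$chisq))
    out <- c(out, sprintf("Chi-square (uncorrected): X2 = %.3f, df = 1, p = %.3g.",
                          report$chisq$statistic, report$chisq$p_two_sided))
  if (length(report$regressions) > 0) {
    out <- c(out, "", "## Regressions", "")
    for (nm in names(report$regressions)) {
      r <- report$regressions[[nm]]
      out <- c(out, sprintf("- %s: slope %.4g, R^2 = %.2f, p = %.3g (n = %d)",
                            nm, r$slope, r$r_squared, r$p_two_sided, r$n))
    }
  }
  out <- c(out, "", "## Detector provenance", "",
           sprintf("window_w = %d breaths, z_thresh = %g SD, aggregate_min = %d,",
                   p$window_w, p$z_thresh, p$aggregate_min),
           sprintf("apnea_min_s = %g s, apnea_flow_frac = %g, cutoff_k = %g, seed = %d.",
                   p$apnea_min_s, p$apnea_flow_frac, p$cutoff_k,
                   report$config_echo$seed))
  out
}
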