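# synthetic breath tables with controlled deviations
make_breaths <- function(n = 150, seed = 1, ratio_cv = 0.05, pif_cv = 0.05) {
  set.seed(seed)
  ratio <- 0.8 * (1 + ratio_cv * rnorm(n))
  pif <- 1.0 * (1 + pif_cv * rnorm(n))
  data.frame(index = seq_len(n) - 1L, onset_s = (seq_len(n) - 1) / 3,
             ti_s = 0.13, te_s = 0.2, tv_ml = 0.13 / ratio,
             pif_ml_s = pif, ratio_s_per_ml = ratio)
}

test_that("identical breaths are never flagged (zero-SD windows)", {
  br <- make_breaths(150, ratio_cv = 0, pif_cv = 0)
  expect_false(any(detect_ifl(br)))
})

test_that("a joint ratio/PIF outlier is flagged and matches the brute-force oracle", {
  br <- make_breaths(150, seed = 2)
  p <- detector_params()
  i <- 121  # 0-based breath 120
  mr <- mean(br$ratio_s_per_ml[21:120]); sr <- sd(br$ratio_s_per_ml[21:120])
  mp <- mean(br$pif_ml_s[21:120]); sp <- sd(br$pif_ml_s[21:120])
  br$ratio_s_per_ml[i] <- mr + 10 * sr
  br$pif_ml_s[i] <- mp - 10 * sp
  flags <- detect_ifl(br, p)
  expect_true(flags[i])
  expect_identical(flags, oracle_ifl(br, p))

  # conjunction: the same ratio deviation with a normal PIF is not flagged
  br2 <- make_breaths(150, seed = 2)
  br2$ratio_s_per_ml[i] <- mr + 10 * sr
  br2$pif_ml_s[i] <- mp  # inspiratory drive exactly at the running mean
  flags2 <- detect_ifl(br2, p)
  expect_false(flags2[i])
  expect_identical(flags2, oracle_ifl(br2, p))
})

test_that("running window statistics equal a from-scratch recomputation", {
  set.seed(9)
  x <- rlnorm(400, 0, 0.2)
  w <- 100L
  got <- wbpleth:::rolling_prev_stats(x, w)
  want <- oracle_window_stats(x, w)
  i <- (w + 1):400
  expect_true(all(abs(got$mean[i] - want$mean[i]) <=
                    1e-9 * abs(want$mean[i])))
  expect_true(all(abs(got$sd[i] - want$sd[i]) <= 1e-9 * abs(want$sd[i])))
})

test_that("the first window_w breaths carry no flags and short series warn", {
  br <- make_breaths(130, seed = 3)
  flags <- detect_ifl(br)
  expect_false(any(flags[1:100]))
  expect_warning(f2 <- detect_ifl(make_breaths(50, seed = 3)), "window_w")
  expect_false(any(f2))
})

test_that("raising the z threshold never adds flags", {
  rec <- simulate_recording(sim_config(duration_s = 400, seed = 17))
  br <- segment_breaths(rec$trace)
  f1 <- detect_ifl(br, detector_params(z_thresh = 2.576))
  f2 <- detect_ifl(br, detector_params(z_thresh = 3.5))
  expect_true(all(f1[f2]))  # flags at 3.5 are a subset of flags at 2.576
  expect_lte(sum(f2), sum(f1))
})

test_that("aggregates are maximal runs of at least aggregate_min flags", {
  p <- detector_params()
  a <- detect_aggregates(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), p)
  expect_equal(a$first_breath_index, 3L)
  expect_equal(a$length, 3L)
  expect_equal(nrow(detect_aggregates(rep(FALSE, 10), p)), 0)
  five <- detect_aggregates(rep(TRUE, 5), p)
  expect_equal(nrow(five), 1)  # one run of 5, not three overlapping runs of 3
  expect_equal(five$length, 5L)
  set.seed(4)
  flags <- runif(500) < 0.2
  expect_equal(detect_aggregates(flags, p), oracle_runs(flags, 3),
               ignore_attr = TRUE)
})

test_that("apnea calls respect the 1 s minimum and match the interval oracle", {
  # hand-built trace: breaths with gaps of 0.8 s, 1.2 s, and two 1.1 s gaps
  fs <- 1000
  breath <- function() c(sin(pi * seq(0, 1, length.out = 134)[-1]),
                         -0.67 * sin(pi * seq(0, 1, length.out = 200)[-1]))
  gap <- function(s) rep(0, round(s * fs))
  f <- c(rep(breath(), 10), gap(0.8), rep(breath(), 3), gap(1.2),
         rep(breath(), 3), gap(1.1), rep(breath(), 2), gap(1.1),
         rep(breath(), 5))
  tr <- flow_trace(f, fs)
  br <- segment_breaths(tr)
  p <- detector_params()
  ap <- detect_apneas(tr, br, p)
  expect_equal(nrow(ap), 3)  # the 0.8 s gap is below the 1 s minimum
  expect_true(all(ap$end_s - ap$start_s >= p$apnea_min_s))
  expect_equal(ap, oracle_apneas(tr, br, p), ignore_attr = TRUE)
})

test_that("simulated apneas are recalled exactly on the raw signal", {
  cfg <- sim_config(duration_s = 900, apnea_rate_per_h = 40,
                    ifl_event_rate_per_h = 0, seed = 23)
  rec <- simulate_recording(cfg)
  br <- segment_breaths(rec$trace)
  p <- detector_params()
  ap <- detect_apneas(rec$trace, br, p)
  expect_equal(ap, oracle_apneas(rec$trace, br, p), ignore_attr = TRUE)
  # every injected gap is covered by a detected interval
  tru <- rec$truth$apneas
  expect_true(nrow(tru) > 0)
  tol <- 2 / rec$trace$sample_rate_hz
  for (k in seq_len(nrow(tru))) {
    hit <- any(ap$start_s <= tru$start_s[k] + tol &
               ap$end_s >= tru$end_s[k] - tol)
    expect_true(hit)
  }
  expect_true(all(ap$end_s - ap$start_s >= p$apnea_min_s))
})

test_that("event summaries normalize to period and breath count", {
  ev <- list(ifl_flags = c(rep(TRUE, 90), rep(FALSE, 10)),
             aggregates = data.frame(first_breath_index = c(0, 50),
                                     length = c(4, 3)),
             apneas = data.frame(start_s = seq_len(48), end_s = seq_len(48) + 1.5))
  s <- summarize_events(ev, observation_h = 8, n_breaths = 18000)
  expect_equal(s$apnea_per_h, 6)
  expect_equal(s$ifl_pct, 0.5)
  expect_equal(s$ifl_per_h, 90 / 8)
  expect_equal(s$aggregate_per_h, 0.25)
  empty <- list(ifl_flags = logical(0),
                aggregates = data.frame(first_breath_index = integer(0),
                                        length = integer(0)),
                apneas = data.frame(start_s = numeric(0), end_s = numeric(0)))
  s0 <- summarize_events(empty, 8, 0)
  expect_equal(unlist(s0[c("apnea_per_h", "ifl_per_h", "ifl_pct",
                           "aggregate_per_h")]),
               c(apnea_per_h = 0, ifl_per_h = 0, ifl_pct = 0,
                 aggregate_per_h = 0))
})

test_that("the abnormality cut-off is mean + k sample SDs, strictly compared", {
  expect_equal(abnormal_cutoff(c(4, 6, 8), k = 2), 10)  # SD of {4,6,8} is 2
  expect_equal(abnormal_cutoff(rep(5, 6), k = 3), 5)
  expect_error(abnormal_cutoff(4), "at least 2")
  expect_true(classify_abnormal(20, 14.75))
  expect_false(classify_abnormal(14.75, 14.75))  # boundary is not abnormal
  expect_false(classify_abnormal(0, 14.75))
})

test_that("rescaling the flow changes no event call", {
  cfg <- sim_config(duration_s = 500, apnea_rate_per_h = 25,
                    ifl_event_rate_per_h = 30, seed = 37)
  rec <- simulate_recording(cfg)
  br1 <- segment_breaths(rec$trace)
  ev1 <- detect_events(rec$trace, br1)
  scaled <- rec$trace
  scaled$flow <- 3.7 * scaled$flow
  br2 <- segment_breaths(scaled)
  ev2 <- detect_events(scaled, br2)
  expect_equal(nrow(br2), nrow(br1))
  expect_equal(br2$tv_ml, 3.7 * br1$tv_ml, tolerance = 1e-12)
  expect_equal(br2$ratio_s_per_ml, br1$ratio_s_per_ml / 3.7, tolerance = 1e-12)
  expect_identical(ev2$ifl_flags, ev1$ifl_flags)
  expect_equal(ev2$aggregates, ev1$aggregates)
  expect_equal(ev2$apneas, ev1$apneas)
})

test_that("epoch-restricted summaries count only events starting in the epoch", {
  sched <- data.frame(start_s = c(0, 500), end_s = c(500, 1000),
                      state = c("wake", "sleep"))
  cfg <- sim_config(duration_s = 1000, epoch_schedule = sched,
                    apnea_rate_per_h = 40, ifl_event_rate_per_h = 40,
                    seed = 41)
  rec <- simulate_recording(cfg)
  br <- segment_breaths(rec$trace)
  ev_sleep <- detect_events(rec$trace, br, epoch = "sleep")
  ev_wake <- detect_events(rec$trace, br, epoch = "wake")
  ev_all <- detect_events(rec$trace, br, epoch = "all")
  expect_equal(ev_sleep$summary$observation_h, 500 / 3600)
  # injected events are sleep-only; detected apneas should be too
  expect_equal(nrow(ev_wake$apneas), 0)
  expect_equal(nrow(ev_sleep$apneas), nrow(ev_all$apneas))
  expect_equal(ev_sleep$summary$n_breaths + ev_wake$summary$n_breaths,
               nrow(br))
})
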