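test_that("presets define the standard observation windows", {
  day <- wake_sleep_preset("day_sleep_8h")
  expect_equal(day$duration_s, 28800)
  expect_equal(unique(day$epoch_schedule$state), "sleep")

  full <- wake_sleep_preset("full_22h")
  expect_equal(full$duration_s, 79200)
  expect_setequal(full$epoch_schedule$state, c("wake", "sleep"))
  for (cfg in list(day, full)) {
    sched <- cfg$epoch_schedule[order(cfg$epoch_schedule$start_s), ]
    expect_equal(sched$start_s[1], 0)
    expect_equal(sched$end_s[nrow(sched)], cfg$duration_s)
    if (nrow(sched) > 1)
      expect_equal(sched$start_s[-1], sched$end_s[-nrow(sched)])
  }
  expect_error(wake_sleep_preset("weekend"))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(duration_s = -5), "duration")
  expect_error(sim_config(insp_fraction = 1.2), "insp_fraction")
  expect_error(sim_config(apnea_duration_s_range = c(0.5, 2)), "at least 1 s")
  expect_error(sim_config(duration_s = 100,
                          epoch_schedule = data.frame(start_s = 0, end_s = 50,
                                                      state = "sleep")),
               "cover")
})

test_that("zero event rates give an empty ground-truth log", {
  rec <- simulate_recording(quiet_config(seed = 3))
  expect_equal(nrow(rec$truth$apneas), 0)
  expect_equal(nrow(rec$truth$bursts), 0)
  expect_length(rec$truth$ifl_breaths, 0)
})

test_that("identical seeds reproduce the recording bit for bit", {
  cfg <- sim_config(duration_s = 120, seed = 11)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$trace$flow, r2$trace$flow)
  expect_identical(r1$truth, r2$truth)
  r3 <- simulate_recording(sim_config(duration_s = 120, seed = 12))
  expect_false(identical(r1$trace$flow, r3$trace$flow))
})

test_that("apnea count replays the Poisson event stream under the same seed", {
  cfg <- sim_config(duration_s = 3600, apnea_rate_per_h = 20,
                    ifl_event_rate_per_h = 0, seed = 99)
  rec <- simulate_recording(cfg)
  set.seed(99)
  expect_equal(nrow(rec$truth$apneas), rpois(1, 20 * 1))  # 1 h all-sleep
})

test_that("injected apneas are >= 1 s, disjoint, and inside sleep epochs", {
  sched <- data.frame(start_s = c(0, 600), end_s = c(600, 1200),
                      state = c("wake", "sleep"))
  cfg <- sim_config(duration_s = 1200, epoch_schedule = sched,
                    apnea_rate_per_h = 40, ifl_event_rate_per_h = 30,
                    seed = 5)
  tru <- simulate_recording(cfg)$truth
  ap <- tru$apneas
  expect_true(nrow(ap) > 0)
  expect_true(all(ap$end_s - ap$start_s >= 1))
  expect_true(all(ap$start_s >= 600 & ap$end_s <= 1200))
  if (nrow(ap) > 1)
    expect_true(all(ap$start_s[-1] >= ap$end_s[-nrow(ap)]))
  # bursts: lengths >= 1, members are exactly the union of the bursts
  expect_true(all(tru$bursts$length >= 1))
  members <- unlist(mapply(function(s, l) s:(s + l - 1),
                           tru$bursts$first_breath_index, tru$bursts$length,
                           SIMPLIFY = FALSE))
  expect_setequal(tru$ifl_breaths, members)
})

test_that("event-free noiseless cycles are area-balanced", {
  rec <- simulate_recording(quiet_config(duration_s = 60, seed = 2))
  f <- rec$trace$flow
  fs <- rec$trace$sample_rate_hz
  br <- rec$truth$breaths
  onset_idx <- round(br$onset_s * fs) + 1
  cyc_end <- c(onset_idx[-1], length(f)) - 1
  for (k in seq_len(nrow(br) - 1)) {
    area <- sum(f[onset_idx[k]:cyc_end[k]]) / fs
    expect_lt(abs(area), 5e-3)
  }
})

test_that("mean simulated breath rate matches the configured rate", {
  rec <- simulate_recording(quiet_config(duration_s = 500, seed = 8))
  n <- rec$truth$n_breaths
  expect_gt(n, 1000)
  rate <- n / 500
  se <- 3 * 0.10 / sqrt(n)  # renewal-process SE of the mean rate, CV = 0.10
  expect_lt(abs(rate - 3), 3 * se)
})

test_that("infeasible event density is rejected with a clear error", {
  cfg <- sim_config(duration_s = 30, apnea_rate_per_h = 4000,
                    apnea_duration_s_range = c(2, 3), seed = 1)
  expect_error(simulate_recording(cfg), "density")
})
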