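test_that("movement events merge across sub-threshold still gaps", {
  expect_equal(nrow(detect_movement_events(rep(0, 50), fps = 15)), 0)
  # at 15 Hz one still frame is 66.7 ms < 67 ms: merged into one event
  ev <- detect_movement_events(c(1, 0, 1), fps = 15)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset, ev$offset), c(1, 3))
  # two still frames = 133 ms >= 67 ms: two events
  ev2 <- detect_movement_events(c(1, 0, 0, 1), fps = 15)
  expect_equal(nrow(ev2), 2)
  expect_error(detect_movement_events(numeric(0), fps = 15), "empty")
})

test_that("movement-event detection matches a brute-force scan", {
  set.seed(101)
  for (fps in c(15, 30)) {
    disp <- rbinom(2000, 1, 0.3) * runif(2000, 0.5, 3)
    got <- detect_movement_events(disp, fps = fps)
    want <- oracle_events(disp, fps = fps)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
  }
})

test_that("sleep scoring is elementwise zero-activity comparison", {
  expect_equal(score_sleep(c(0, 0, 5, 0)), c(TRUE, TRUE, FALSE, TRUE))
  expect_false(any(score_sleep(runif(50, 0.1, 60))))
  set.seed(7)
  v <- ifelse(rbinom(1e4, 1, 0.4) == 1, 0, runif(1e4, 1e-6, 60))
  expect_identical(score_sleep(v), v <= 1e-9)
})

test_that("bout extraction matches run-length oracle and conserves sleep", {
  b <- extract_bouts(c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(b), 2)
  expect_equal(b$length, c(2, 1))
  expect_equal(nrow(extract_bouts(rep(FALSE, 10))), 0)
  set.seed(11)
  mask <- rbinom(1e5, 1, 0.35) == 1
  got <- extract_bouts(mask)
  want <- oracle_runs(mask)
  expect_equal(got$start_min, want$start_min)
  expect_equal(got$end_min, want$end_min)
  expect_equal(sum(got$length), sum(mask))  # sum of bouts = sleep minutes
})

test_that("sleep latency handles onset, ongoing bouts and censoring", {
  mask <- c(rep(FALSE, 12), TRUE, TRUE, FALSE)
  b <- extract_bouts(mask)
  expect_equal(sleep_latency(b, reference = 1, epoch_end = 16)$latency, 12)
  # bout ongoing at the reference: latency 0
  expect_equal(sleep_latency(b, reference = 14, epoch_end = 16)$latency, 0)
  # no bout before epoch end: censored at epoch length
  lat <- sleep_latency(extract_bouts(rep(FALSE, 20)), reference = 5,
                       epoch_end = 15)
  expect_true(lat$censored)
  expect_equal(lat$latency, 10)
})

test_that("activity metrics match their definitions", {
  m <- activity_metrics(c(0, 0, 6, 6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$average_activity, 180)
  expect_equal(m$wake_activity, 360)
  # no sleep minutes: average = wake
  v <- runif(100, 1, 10)
  m2 <- activity_metrics(v, rep(FALSE, 100))
  expect_equal(m2$average_activity, m2$wake_activity)
  set.seed(13)
  v <- ifelse(rbinom(5000, 1, 0.3) == 1, 0, runif(5000, 0, 60))
  mk <- score_sleep(v)
  m3 <- activity_metrics(v, mk)
  expect_equal(m3$average_activity, 60 * sum(v) / length(v))
  expect_equal(m3$wake_activity, 60 * sum(v) / sum(!mk))
  expect_gte(m3$wake_activity, m3$average_activity)
  expect_error(activity_metrics(1:3, c(TRUE, FALSE)), "length")
})

test_that("epoch metrics split boundary-spanning bouts and conserve sleep", {
  sch <- light_schedule(lights_on = 9, lights_off = 23, n_days = 1)
  day_len <- 14 * 60
  # bout straddling lights-off: 3 min before + 4 min after
  v <- rep(1, 24 * 60)
  v[(day_len - 2):(day_len + 4)] <- 0
  em <- epoch_metrics(v, sch)
  expect_equal(em$total_sleep_min[em$epoch == "day"], 3)
  expect_equal(em$total_sleep_min[em$epoch == "night"], 4)
  expect_equal(em$bout_count, c(1, 1))  # counted once in each epoch touched
  expect_equal(sum(em$total_sleep_min), sum(v == 0))
  # latency measured from the epoch transition
  expect_equal(em$latency_min[em$epoch == "day"], day_len - 3)
  expect_equal(em$latency_min[em$epoch == "night"], 0)  # ongoing at lights-off
})

test_that("whole-trace metrics equal per-epoch totals for a one-epoch trace", {
  sch <- light_schedule(9, 23, n_days = 1)
  set.seed(17)
  v <- ifelse(rbinom(200, 1, 0.4) == 1, 0, runif(200, 1, 30))
  em <- epoch_metrics(v, sch)  # trace lies inside the first day epoch
  expect_equal(nrow(em), 1)
  expect_equal(em$total_sleep_min, sum(score_sleep(v)))
  expect_equal(em$average_activity, activity_metrics(v)$average_activity)
})

test_that("scoring a trace twice or permuting larvae changes nothing", {
  cfg <- sim_config(n_larvae = 4, seed = 19)
  sch <- light_schedule(9, 23, n_days = 1)
  act <- gen_activity_traces(cfg, sch)
  m1 <- cohort_metrics(act, sch)
  m2 <- cohort_metrics(act[sample(nrow(act)), ], sch)
  k1 <- order(m1$larva_id, m1$epoch, m1$start_min)
  k2 <- order(m2$larva_id, m2$epoch, m2$start_min)
  expect_equal(m1$total_sleep_min[k1], m2$total_sleep_min[k2])
  expect_equal(m1$latency_min[k1], m2$latency_min[k2])
})

test_that("1-h smoothing matches the windowed-mean oracle", {
  expect_equal(smooth_series(rep(3, 20)), rep(3, 20))
  x <- rep(0, 30); x[15] <- 6
  sm <- smooth_series(x)
  expect_equal(sum(sm > 0), 6)     # impulse spread over the 6-bin window
  expect_true(all(abs(sm[sm > 0] - 1) < 1e-12))
  set.seed(23)
  y <- rnorm(100)
  expect_equal(smooth_series(y), oracle_moving_mean(y, -3, 2))
})

test_that("percent-of-control normalization is 100 * value / control mean", {
  expect_equal(normalize_to_control(3, c(2, 4)), 100)
  expect_equal(normalize_to_control(c(2, 4), c(2, 4)), c(200, 400) / 3)
  expect_error(normalize_to_control(1, c(0, 0)), "control mean")
  set.seed(29)
  v <- runif(20); ctrl <- runif(10, 1, 2)
  expect_equal(normalize_to_control(v, ctrl), 100 * v / mean(ctrl))
})

test_that("light-pulse response excludes onset/offset windows and normalizes", {
  bins_per_min <- 6
  n_bins <- 70 * bins_per_min
  onset <- 31 * bins_per_min + 1
  base <- matrix(2, nrow = 4, ncol = n_bins)
  expect_equal(light_pulse_response(base, onset), rep(1, 4))
  # excluded minutes (1 min either side of onset) can hold anything
  spiky <- base
  spiky[, (onset - bins_per_min):(onset + bins_per_min - 1)] <- 1e6
  expect_equal(light_pulse_response(spiky, onset), rep(1, 4))
  # 27% suppression during the pulse shows up as a ratio near 0.73
  supp <- base
  supp[, onset:(onset + 30 * bins_per_min - 1)] <- 2 * 0.73
  expect_equal(light_pulse_response(supp, onset), rep(0.73, 4))
  expect_error(light_pulse_response(base, 10), "baseline")
})

test_that("synthetic transgenic pulse suppression is recovered on average", {
  set.seed(31)
  bins_per_min <- 6
  n_bins <- 70 * bins_per_min
  onset <- 31 * bins_per_min + 1
  n <- 24
  mk <- function(mult) {
    t(sapply(seq_len(n), function(i) {
      x <- rgamma(n_bins, shape = 2, scale = 1)
      x[onset:n_bins] <- x[onset:n_bins] * mult
      x
    }))
  }
  ratio_wt <- mean(light_pulse_response(mk(1), onset))
  ratio_tg <- mean(light_pulse_response(mk(0.73), onset))
  expect_equal(ratio_wt, 1, tolerance = 0.1)
  expect_equal(ratio_tg, 0.73, tolerance = 0.1)
})
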