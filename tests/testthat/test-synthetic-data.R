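test_that("light schedules cover every minute with one epoch label", {
  for (args in list(c(9, 23), c(9, 22), c(23, 9))) {
    sch <- light_schedule(args[1], args[2], n_days = 2)
    expect_equal(length(sch$epoch), 2 * 24 * 60)
    expect_true(all(sch$epoch %in% c("day", "night")))
    # day + night lengths sum to 24 h per day
    expect_equal(sum(sch$epoch == "day") + sum(sch$epoch == "night"),
                 2 * 24 * 60)
  }
  sch <- light_schedule(9, 23, n_days = 1)
  expect_equal(sum(sch$epoch == "day") / 60, 14)
  expect_equal(sum(sch$epoch == "night") / 60, 10)
  sch2 <- light_schedule(9, 22, n_days = 1)  # imaging entrainment 13:11
  expect_equal(sum(sch2$epoch == "day") / 60, 13)
})

test_that("sim_config validates probabilities, multipliers and tap scale", {
  expect_error(sim_config(groups = list(g = list(
    activity_multiplier = 1, p_wake_to_sleep = c(day = -0.1, night = 0.1),
    p_sleep_to_wake = c(day = 0.1, night = 0.1), latency_shift = 0))),
    "probabilities")
  expect_error(sim_config(tap = list(powers = c(0, 1, 2), trials_per_power = 30,
                                     bottom = 0, top = 1, etp50 = 5, hill = 1,
                                     background_move_prob = 0)),
               "powers")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
})

absorbing_cfg <- function(p_ws, p_sw, n_larvae = 1, seed = 11) {
  sim_config(n_larvae = n_larvae, seed = seed, groups = list(
    g = list(activity_multiplier = 1,
             p_wake_to_sleep = c(day = p_ws, night = p_ws),
             p_sleep_to_wake = c(day = p_sw, night = p_sw),
             latency_shift = 0)))
}

test_that("absorbing wake state yields zero sleep minutes", {
  sch <- light_schedule(9, 23, n_days = 1)
  act <- gen_activity_traces(absorbing_cfg(0, 0.3, n_larvae = 3), sch)
  expect_true(all(act$activity > 0))
  expect_equal(sum(score_sleep(act$activity)), 0)
})

test_that("absorbing sleep state yields one all-zero bout spanning the trace", {
  sch <- light_schedule(9, 23, n_days = 1)
  act <- gen_activity_traces(absorbing_cfg(1, 0), sch)
  v <- trace_values(act, act$larva_id[1])
  expect_true(all(v == 0))
  b <- extract_bouts(score_sleep(v))
  expect_equal(nrow(b), 1)
  expect_equal(b$length, length(v))
})

test_that("empirical sleep fraction matches the chain's stationary distribution", {
  p_ws <- 0.08; p_sw <- 0.25
  sch <- light_schedule(9, 23, n_days = 70)  # ~1e5 minutes
  act <- gen_activity_traces(absorbing_cfg(p_ws, p_sw, seed = 21), sch)
  frac <- mean(score_sleep(act$activity))
  expected <- p_ws / (p_ws + p_sw)
  se <- markov_se(p_ws, p_sw, nrow(act))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("sleep-bout lengths are geometric with mean 1/p_sleep_to_wake", {
  p_sw <- 0.3
  sch <- light_schedule(9, 23, n_days = 60)
  act <- gen_activity_traces(absorbing_cfg(0.3, p_sw, seed = 31), sch)
  lens <- extract_bouts(score_sleep(act$activity))$length
  expect_gt(length(lens), 1e4)
  expect_equal(mean(lens), 1 / p_sw, tolerance = 0.05)
  # chi-square GOF against geometric(p_sw), tail pooled
  kmax <- 15
  obs <- tabulate(pmin(lens, kmax), nbins = kmax)
  pr <- stats::dgeom(0:(kmax - 2), prob = p_sw)
  pr <- c(pr, 1 - sum(pr))
  gof <- stats::chisq.test(obs, p = pr)
  expect_gt(gof$p.value, 0.01)
})

test_that("heat shock transiently increases sleep pressure and decays", {
  hs <- list(start_min = 300, duration_min = 60, p_ws_mult = 12,
             p_sw_mult = 0.5, half_life_h = 2)
  cfg <- sim_config(n_larvae = 24, seed = 41, heat_shock = hs)
  sch <- light_schedule(9, 23, n_days = 1)
  act <- gen_activity_traces(cfg, sch)
  sleep_by_min <- tapply(score_sleep(act$activity), act$time_min, mean)
  post <- mean(sleep_by_min[301:420])   # 2 h after onset
  pre <- mean(sleep_by_min[100:299])
  late <- mean(sleep_by_min[700:840])   # >6 h later, effect mostly decayed
  expect_gt(post, pre + 0.1)
  expect_lt(late, post)
})

test_that("fixed seed reproduces datasets; extra larvae do not perturb others", {
  sch <- light_schedule(9, 23, n_days = 1)
  a1 <- gen_activity_traces(sim_config(n_larvae = 3, seed = 5), sch)
  a2 <- gen_activity_traces(sim_config(n_larvae = 3, seed = 5), sch)
  expect_identical(a1, a2)
  a5 <- gen_activity_traces(sim_config(n_larvae = 5, seed = 5), sch)
  expect_identical(a1$activity,
                   a5$activity[a5$larva_id %in% unique(a1$larva_id)])
  t1 <- gen_tap_dataset(sim_config(n_larvae = 2, seed = 5))
  t2 <- gen_tap_dataset(sim_config(n_larvae = 2, seed = 5))
  expect_identical(t1, t2)
})

test_that("tap generator honors the psychometric ground truth", {
  cfg <- sim_config(n_larvae = 2, seed = 7)
  taps <- gen_tap_dataset(cfg)
  expect_equal(nrow(taps), 2 * 14 * 30)
  expect_equal(as.vector(table(taps$larva_id)), rep(420L, 2))

  # top = bottom = 0, background 0: nothing responds
  tap0 <- utils::modifyList(cfg$tap, list(top = 0, bottom = 0,
                                          background_move_prob = 0))
  t0 <- gen_tap_dataset(cfg, tap = tap0)
  expect_false(any(t0$responded))
  expect_false(any(t0$pre_moved))

  # at power = etp50 with bg 0 the response fraction is (bottom + top)/2
  tap_mid <- utils::modifyList(cfg$tap, list(
    powers = rep(cfg$tap$etp50, 14), background_move_prob = 0,
    trials_per_power = 60))
  cfg_many <- sim_config(n_larvae = 20, seed = 9)
  tm <- gen_tap_dataset(cfg_many, tap = tap_mid)
  p_hat <- mean(tm$responded)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(tm)))
})

test_that("responses at the largest power approach top + bg(1 - top)", {
  cfg <- sim_config(n_larvae = 24, seed = 13)
  taps <- gen_tap_dataset(cfg)
  pmax_ <- max(taps$power)
  resp <- taps$responded[taps$power == pmax_]
  psi <- psychometric_curve(pmax_, cfg$tap$bottom, cfg$tap$top,
                            log10(cfg$tap$etp50), cfg$tap$hill)
  expected <- psi + cfg$tap$background_move_prob * (1 - psi)
  se <- sqrt(expected * (1 - expected) / length(resp))
  expect_lt(abs(mean(resp) - expected), 3 * se)
})

test_that("calcium trial kernel reproduces configured window contrasts", {
  cc <- list(day_mean = 1, night_mean = 0.75, on_amp = 0.5, off_amp = 0.4,
             tau_s = 3, suppression_target = 0.32,
             suppression_tau_trials = 1.5, suppression_transient = 0.6,
             noise_sd = 0)
  cfg <- sim_config(seed = 3, calcium = cc)
  day <- trial_matrix(gen_trial_recordings(cfg, 2, "subjective_day"))
  night <- trial_matrix(gen_trial_recordings(cfg, 2, "subjective_night"))
  wm_d <- trial_window_means(day[1, ])
  wm_n <- trial_window_means(night[1, ])
  # noiseless: intrinsic window sits exactly at the phase baseline
  expect_equal(unname(wm_d["intrinsic"]), 1)
  expect_equal(unname(wm_n["intrinsic"]), 0.75)
  # evoked window mean minus intrinsic equals the configured amplitude
  expect_equal(unname(wm_d["on_evoked"] - wm_d["intrinsic"]), cc$on_amp)
  expect_equal(unname(wm_d["off_evoked"] - wm_d["intrinsic"]), cc$off_amp)
  # zero amplitudes: flat trace at baseline
  cc0 <- utils::modifyList(cc, list(on_amp = 0, off_amp = 0))
  flat <- trial_matrix(gen_trial_recordings(sim_config(seed = 3, calcium = cc0),
                                            1, "subjective_day"))
  expect_true(all(flat == 1))
})

test_that("movie generator plants recoverable ground truth", {
  cfg <- sim_config(seed = 17)
  mov0 <- gen_movie(cfg, n_cells = 0, frame_shape = c(32, 32), n_frames = 30)
  expect_equal(dim(mov0$masks)[3], 0)

  # one bright static cell, zero noise: a single connected bright region at
  # the planted centroid in every frame
  mov1 <- gen_movie(cfg, n_cells = 1, frame_shape = c(32, 32), n_frames = 10,
                    noise_sd = 0)
  fr <- mov1$stack[, , 1] - min(mov1$stack[, , 1])
  lab <- EBImage::bwlabel(EBImage::Image((fr > 0.5 * max(fr)) * 1))
  expect_equal(max(lab), 1)
  px <- which(lab@.Data == 1)
  rr <- (px - 1) %% 32 + 1; cc <- (px - 1) %/% 32 + 1
  expect_lt(sqrt((mean(rr) - mov1$centers[1, 1])^2 +
                 (mean(cc) - mov1$centers[1, 2])^2), 1)

  # 20 planted high-SNR cells: temporal-variance map peaks at the centroids
  mov <- gen_movie(cfg, n_cells = 20, frame_shape = c(64, 64), n_frames = 100)
  vmap <- apply(mov$stack, c(1, 2), var)
  for (i in seq_len(20)) {
    r0 <- round(mov$centers[i, 1]); c0 <- round(mov$centers[i, 2])
    win <- vmap[max(1, r0 - 3):min(64, r0 + 3), max(1, c0 - 3):min(64, c0 + 3)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    pr <- max(1, r0 - 3) + peak[1] - 1; pc <- max(1, c0 - 3) + peak[2] - 1
    expect_lt(sqrt((pr - mov$centers[i, 1])^2 + (pc - mov$centers[i, 2])^2),
              1 + 1e-9)
  }
  expect_error(gen_movie(cfg, n_cells = 500, frame_shape = c(32, 32),
                         n_frames = 10), "too many cells")
})
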