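#' Simulate per-minute activity traces from a two-state behavior model
#'
#' Each larva alternates between wake and sleep according to a first-order
#' Markov chain on 1-min bins with epoch-specific transition probabilities.
#' Sleep minutes record exactly 0 s of movement; wake minutes draw
#' seconds-moved from a gamma distribution (clamped to `[0, 60]`) scaled by
#' the group's `activity_multiplier`. An optional heat shock multiplies the
#' transition probabilities by factors that decay exponentially from
#' heat-shock onset (configurable half-life), emulating transient
#' overexpression of a heat-inducible transgene.
#'
#' @param config A [sim_config()].
#' @param schedule A [light_schedule()] covering the requested duration.
#' @return A data.frame of class `activity_data` in long format with columns
#'   `time_min` (1-based bin index), `larva_id`, `group`, `activity`
#'   (seconds moved in the bin).
#' @examples
#' cfg <- sim_config(n_larvae = 2, seed = 7)
#' sch <- light_schedule(9, 23, n_days = 1)
#' act <- gen_activity_traces(cfg, sch)
#' head(act)
#' @export
gen_activity_traces <- function(config, schedule) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "light_schedule"))
  n_min <- schedule$n_min
  if (n_min <= 0) stop("schedule duration must be positive")
  epoch <- as.character(schedule$epoch)
  hs_mult <- heat_shock_multipliers(config$heat_shock, n_min)
  out <- vector("list", length(config$groups) * config$n_larvae)
  k <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    seeds <- unit_seeds(config$seed, paste0("behavior:", gname), config$n_larvae)
    p_ws <- unname(g$p_wake_to_sleep[epoch])
    p_sw <- unname(g$p_sleep_to_wake[epoch])
    # heat shock scales transition probabilities, clamped to [0, 1]
    p_ws <- pmin(1, p_ws * hs_mult$ws)
    p_sw <- pmin(1, p_sw * hs_mult$sw)
    # suppress sleep entry for latency_shift minutes after each lights switch
    if (g$latency_shift > 0) {
      switches <- which(c(TRUE, epoch[-1] != epoch[-n_min]))
      for (s in switches) {
        idx <- s:min(n_min, s + g$latency_shift - 1L)
        p_ws[idx] <- 0
      }
    }
    for (i in seq_len(config$n_larvae)) {
      set.seed(seeds[i])
      asleep <- logical(n_min)
      state <- FALSE  # start awake
      u <- stats::runif(n_min)
      for (t in seq_len(n_min)) {
        state <- if (state) u[t] >= p_sw[t] else u[t] < p_ws[t]
        asleep[t] <- state
      }
      act <- numeric(n_min)
      nw <- sum(!asleep)
      if (nw > 0) {
        a <- stats::rgamma(nw, shape = config$wake_activity$shape,
                           scale = config$wake_activity$scale)
        act[!asleep] <- pmin(60, a * g$activity_multiplier)
      }
      k <- k + 1L
      out[[k]] <- data.frame(time_min = seq_len(n_min),
                             larva_id = sprintf("%s_%02d", gname, i),
                             group = gname, activity = act)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("activity_data", "data.frame")
  res
}

heat_shock_multipliers <- function(hs, n_min) {
  if (is.null(hs)) return(list(ws = rep(1, n_min), sw = rep(1, n_min)))
  t <- seq_len(n_min)
  # effect strength 1 at onset, halving every half_life_h; multiplier decays
  # geometrically back to 1 (no effect) as the strength fades
  decay <- ifelse(t >= hs$start_min,
                  2 ^ (-(t - hs$start_min) / (hs$half_life_h * 60)), 0)
  list(ws = hs$p_ws_mult ^ decay, sw = hs$p_sw_mult ^ decay)
}

#' Extract one larva's activity vector
#'
#' @param activity An `activity_data` data.frame from [gen_activity_traces()]
#'   or read from CSV.
#' @param larva_id The larva to extract.
#' @return Numeric vector of seconds-moved per minute, ordered by `time_min`.
#' @export
trace_values <- function(activity, larva_id) {
  rows <- activity$larva_id == larva_id
  if (!any(rows)) stop("unknown larva_id: ", larva_id)
  v <- activity$activity[rows]
  v[order(activity$time_min[rows])]
}

#' Simulate a mechano-acoustic tap assay
#'
#' For every larva x power x trial, the response is Bernoulli with
#' probability `psi(power) + bg * (1 - psi(power))` - the psychometric curve
#' OR background movement - where `psi` is the variable-slope log-dose curve
#' with the configured bottom/top/ETP50/Hill parameters. Pre-stimulus
#' movement (`pre_moved`, the 5 s before each tap) is Bernoulli with the
#' background probability. Tap presentation order is randomized per larva.
#' The standard design (14 powers x 30 trials) yields 420 trials per larva.
#'
#' @param config A [sim_config()]; `config$tap` holds the ground truth.
#' @param group Group label stored on the rows.
#' @param tap Optional override of `config$tap` (same fields), e.g. to give a
#'   treated group a shifted ETP50.
#' @return A data.frame with columns `larva_id`, `group`, `power`, `trial`
#'   (presentation index within larva), `responded`, `pre_moved` (logical).
#' @examples
#' cfg <- sim_config(n_larvae = 2, seed = 1)
#' taps <- gen_tap_dataset(cfg)
#' nrow(taps) / 2  # 420 trials per larva
#' @export
gen_tap_dataset <- function(config, group = "wt", tap = config$tap) {
  stopifnot(inherits(config, "sim_config"))
  if (any(tap$powers <= 0)) stop("tap powers must be > 0")
  if (tap$trials_per_power < 1) stop("trials_per_power must be >= 1")
  seeds <- unit_seeds(config$seed, paste0("taps:", group), config$n_larvae)
  psi <- psychometric_curve(tap$powers, tap$bottom, tap$top,
                            log10(tap$etp50), tap$hill)
  p_resp <- pmin(1, psi + tap$background_move_prob * (1 - psi))
  out <- vector("list", config$n_larvae)
  for (i in seq_len(config$n_larvae)) {
    set.seed(seeds[i])
    sched <- rep(seq_along(tap$powers), each = tap$trials_per_power)
    sched <- sample(sched)  # randomized presentation order
    n <- length(sched)
    out[[i]] <- data.frame(
      larva_id = sprintf("%s_%02d", group, i), group = group,
      power = tap$powers[sched], trial = seq_len(n),
      responded = stats::runif(n) < p_resp[sched],
      pre_moved = stats::runif(n) < tap$background_move_prob)
  }
  do.call(rbind, out)
}

# Evoked-transient kernel on integer seconds: exponential decay from onset,
# truncated at `end`, scaled so its mean over the first `win` samples is
# exactly 1. A configured amplitude A then raises the evoked-window mean by
# exactly A in the noiseless limit.
transient_kernel <- function(t, onset, end, tau, win = 6L) {
  k <- ifelse(t >= onset & t < end, exp(-(t - onset) / tau), 0)
  k / mean(exp(-(0:(win - 1)) / tau))
}

#' Simulate trial-structured calcium recordings
#'
#' Each trial is 2 min of fluorescence at 1 Hz (120 samples, t = 0..119 s).
#' The first 31 s are intrinsic activity at a phase-dependent baseline; a
#' perturbing red light turns on at t = 32 s and off at t = 93 s, producing
#' evoked transients that habituate (decay) after each switch. In
#' `reachr = TRUE` mode, optogenetic stimulation starts after trial 5: the
#' trial-level activity shows an initial transient then decays toward a
#' suppressed steady state (`suppression_target` x baseline).
#'
#' @param config A [sim_config()]; `config$calcium` holds the kernel truth.
#' @param n_trials Number of trials.
#' @param phase `"subjective_day"` or `"subjective_night"` (sets the
#'   intrinsic baseline).
#' @param reachr Logical; simulate optogenetic suppression after trial 5.
#' @param animal_id Label stored on the rows.
#' @return Data.frame with columns `animal`, `trial_idx`, `t_s` (0..119),
#'   `F`.
#' @examples
#' cfg <- sim_config(seed = 2)
#' rec <- gen_trial_recordings(cfg, n_trials = 3, phase = "subjective_day")
#' with(rec[rec$trial_idx == 1, ], plot(t_s, F, type = "l"))
#' @export
gen_trial_recordings <- function(config, n_trials,
                                 phase = c("subjective_day", "subjective_night"),
                                 reachr = FALSE, animal_id = "a1") {
  stopifnot(inherits(config, "sim_config"), n_trials >= 1)
  phase <- match.arg(phase)
  cc <- config$calcium
  base <- if (phase == "subjective_day") cc$day_mean else cc$night_mean
  t <- 0:119
  on_k <- transient_kernel(t, 32, 93, cc$tau_s)
  off_k <- transient_kernel(t, 93, 120, cc$tau_s)
  seeds <- unit_seeds(config$seed, paste0("calcium:", animal_id, ":", phase),
                      n_trials)
  out <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    scale_k <- 1
    if (reachr && k > 5) {
      tgt <- cc$suppression_target
      scale_k <- tgt + (1 - tgt) * exp(-(k - 6) / cc$suppression_tau_trials) +
        (k == 6) * cc$suppression_transient
    }
    f <- scale_k * (base + cc$on_amp * on_k + cc$off_amp * off_k) +
      stats::rnorm(120, sd = cc$noise_sd)
    out[[k]] <- data.frame(animal = animal_id, trial_idx = k, t_s = t, F = f)
  }
  do.call(rbind, out)
}

#' Convert long trial recordings to a trials x time matrix
#'
#' @param recordings Data.frame from [gen_trial_recordings()] (or CSV with
#'   the same columns), one animal.
#' @return Numeric matrix, one row per trial, 120 columns (t = 0..119 s).
#' @export
trial_matrix <- function(recordings) {
  trials <- sort(unique(recordings$trial_idx))
  m <- t(vapply(trials, function(k) {
    r <- recordings[recordings$trial_idx == k, ]
    r$F[order(r$t_s)]
  }, numeric(sum(recordings$trial_idx == trials[1]))))
  rownames(m) <- trials
  m
}

#' Simulate a calcium-imaging movie with planted cells
#'
#' Builds an image stack containing `n_cells` Gaussian-blob nuclei (nominal
#' diameter `diameter_px`, the pixel stand-in for ~5 um nuclei) at random
#' non-overlapping positions, each driven by an independent spiking trace
#' (Poisson-like spikes convolved with an exponential calcium kernel), over a
#' uniform background with additive Gaussian noise. Ground truth (centers,
#' half-maximum masks, traces) is returned alongside for validating
#' segmentation.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param n_cells Number of planted cells (0 allowed).
#' @param frame_shape `c(height, width)` in pixels.
#' @param n_frames Number of frames.
#' @param diameter_px Nominal blob diameter (FWHM), px.
#' @param amp Peak fluorescence amplitude of a fully active cell.
#' @param background Constant background level.
#' @param noise_sd Per-pixel Gaussian noise sd.
#' @param spike_prob Per-frame spike probability of each cell.
#' @param tau_frames Calcium decay constant, frames.
#' @return List with `stack` (height x width x frames array), `centers`
#'   (n_cells x 2 matrix, row/col), `masks` (logical height x width x
#'   n_cells array), `traces` (n_cells x n_frames matrix).
#' @examples
#' cfg <- sim_config(seed = 3)
#' mov <- gen_movie(cfg, n_cells = 4, frame_shape = c(32, 32), n_frames = 40)
#' dim(mov$stack)
#' @export
gen_movie <- function(config, n_cells, frame_shape = c(64, 64), n_frames = 200,
                      diameter_px = 5, amp = 10, background = 20,
                      noise_sd = 0.5, spike_prob = 0.03, tau_frames = 8) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 0, n_frames >= 1)
  h <- frame_shape[1]; w <- frame_shape[2]
  if (n_cells * (1.5 * diameter_px) ^ 2 > 0.7 * h * w)
    stop("too many cells for frame area")
  set.seed(unit_seeds(config$seed, "movie", 1))
  sigma <- diameter_px / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  margin <- ceiling(diameter_px)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_cells) {
    cand <- c(stats::runif(1, margin + 1, h - margin),
              stats::runif(1, margin + 1, w - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= 1.5 * diameter_px) {
      centers <- rbind(centers, cand)
    }
    tries <- tries + 1
    if (tries > 10000 * max(1, n_cells)) stop("could not place cells without overlap")
  }
  # spiking traces: spikes convolved with exponential decay, plus a tonic floor
  traces <- matrix(0, max(1, n_cells), n_frames)
  if (n_cells > 0) {
    kern <- exp(-(0:(n_frames - 1)) / tau_frames)
    for (i in seq_len(n_cells)) {
      spikes <- stats::rbinom(n_frames, 1, spike_prob) * stats::runif(n_frames, 0.5, 1)
      # an "active neuron" must actually fire: ensure >= 3 events so every
      # planted cell carries temporal variance for PCA/ICA to find
      while (sum(spikes > 0) < 3) {
        at <- sample.int(n_frames, 1)
        spikes[at] <- stats::runif(1, 0.5, 1)
      }
      conv <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(n_frames)]
      traces[i, ] <- 0.15 + pmin(conv, 1.2)
    }
  }
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  blobs <- array(0, c(h, w, max(1, n_cells)))
  masks <- array(FALSE, c(h, w, max(1, n_cells)))
  for (i in seq_len(n_cells)) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    blobs[, , i] <- exp(-d2 / (2 * sigma^2))
    masks[, , i] <- blobs[, , i] >= 0.5
  }
  stack <- array(stats::rnorm(h * w * n_frames, background, noise_sd),
                 c(h, w, n_frames))
  for (i in seq_len(n_cells)) {
    stack <- stack + outer(blobs[, , i], amp * traces[i, ])
  }
  list(stack = stack,
       centers = if (n_cells > 0) centers else matrix(numeric(0), 0, 2),
       masks = if (n_cells > 0) masks[, , seq_len(n_cells), drop = FALSE]
               else array(FALSE, c(h, w, 0)),
       traces = if (n_cells > 0) traces[seq_len(n_cells), , drop = FALSE]
                else matrix(0, 0, n_frames))
}

#' Write synthetic datasets to disk
#'
#' Activity, tap and trial tables are written as plain CSV; movies as
#' multi-page TIFF (requires the `tiff` package); ground truth as a JSON-like
#' sidecar is left to the caller.
#'
#' @param x Data.frame (activity/tap/trial tables) or a `gen_movie()` list.
#' @param path Output file path (`.csv` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else if (is.list(x) && !is.null(x$stack)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write movies")
    s <- x$stack
    s <- (s - min(s)) / max(1e-12, diff(range(s)))
    pages <- lapply(seq_len(dim(s)[3]), function(k) s[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else stop("unsupported dataset type")
  invisible(path)
}
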