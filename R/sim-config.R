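#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects every parameter the generators need: cohort structure, two-state
#' (wake/sleep) Markov transition probabilities per light epoch, heat-shock
#' effect kinetics, tap-assay psychometric truth, and calcium-trial kernels.
#' Defaults describe a typical larval cohort: 48 larvae per group, little
#' daytime sleep (stationary sleep fraction ~5%), consolidated night sleep
#' (~50% of night minutes, mean bout ~8 min), a 14-power tap ladder on the
#' 0.01-40.95 solenoid scale with 30 trials per power, and day > night
#' intrinsic calcium activity.
#'
#' @param n_larvae Larvae per group.
#' @param groups Named list of group definitions. Each group is a list with
#'   `activity_multiplier` (unitless scale on wake-minute activity),
#'   `p_wake_to_sleep` and `p_sleep_to_wake` (named numeric `c(day=, night=)`,
#'   per-minute transition probabilities), and `latency_shift` (minutes after
#'   each lights transition during which sleep entry is suppressed).
#' @param wake_activity Gamma parameters (`shape`, `scale`) of seconds-moved
#'   in a wake minute, clamped to `[0, 60]`.
#' @param heat_shock `NULL`, or a list with `start_min`, `duration_min`,
#'   `p_ws_mult`, `p_sw_mult` (peak multipliers on the transition
#'   probabilities) and `half_life_h` (exponential decay of the effect from
#'   heat-shock onset).
#' @param tap Psychometric ground truth: `powers` (tap intensities on the
#'   0.01-40.95 scale), `trials_per_power`, `bottom`, `top`, `etp50`, `hill`,
#'   `background_move_prob`.
#' @param calcium Trial-kernel truth: `day_mean`, `night_mean` (intrinsic
#'   baselines, fluorescence units), `on_amp`, `off_amp` (evoked window
#'   amplitudes), `tau_s` (transient decay, s), `suppression_target`
#'   (steady-state fraction of baseline under optogenetic suppression),
#'   `suppression_tau_trials`, `suppression_transient`, `noise_sd`.
#' @param seed Integer master seed; fixed seed gives identical datasets.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_larvae = 8)
#' cfg$tap$etp50
#' @export
sim_config <- function(
    n_larvae = 48,
    groups = list(
      wt = list(activity_multiplier = 1,
                p_wake_to_sleep = c(day = 0.02, night = 0.12),
                p_sleep_to_wake = c(day = 0.35, night = 0.12),
                latency_shift = 0)
    ),
    wake_activity = list(shape = 1.5, scale = 4),
    heat_shock = NULL,
    tap = list(powers = round(10 ^ seq(log10(1), log10(36.31), length.out = 14), 2),
               trials_per_power = 30,
               bottom = 0, top = 1, etp50 = 6.2, hill = 1.8,
               background_move_prob = 0.07),
    calcium = list(day_mean = 1, night_mean = 0.75,
                   on_amp = 0.5, off_amp = 0.4, tau_s = 3,
                   suppression_target = 0.32, suppression_tau_trials = 1.5,
                   suppression_transient = 0.6, noise_sd = 0.05),
    seed = 1L) {
  cfg <- list(n_larvae = as.integer(n_larvae), groups = groups,
              wake_activity = wake_activity, heat_shock = heat_shock,
              tap = tap, calcium = calcium, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_larvae >= 1, length(cfg$groups) >= 1,
            !is.null(names(cfg$groups)), all(nzchar(names(cfg$groups))))
  for (g in cfg$groups) {
    p <- c(g$p_wake_to_sleep, g$p_sleep_to_wake)
    if (any(p < 0 | p > 1)) stop("transition probabilities must be in [0, 1]")
    if (g$activity_multiplier <= 0) stop("activity_multiplier must be > 0")
    if (g$latency_shift < 0) stop("latency_shift must be >= 0 minutes")
  }
  with(cfg$tap, {
    if (any(powers <= 0)) stop("tap powers must be > 0 (log-dose undefined at 0)")
    if (trials_per_power < 1) stop("trials_per_power must be >= 1")
    if (top < bottom) stop("tap top must be >= bottom")
    if (etp50 <= 0) stop("etp50 must be > 0")
    if (background_move_prob < 0 || background_move_prob > 1)
      stop("background_move_prob must be a probability")
  })
  if (!is.null(cfg$heat_shock)) {
    hs <- cfg$heat_shock
    stopifnot(hs$start_min >= 0, hs$duration_min > 0, hs$half_life_h > 0,
              hs$p_ws_mult > 0, hs$p_sw_mult > 0)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d larvae/group, groups: %s; seed %d\n",
              x$n_larvae, paste(names(x$groups), collapse = ", "), x$seed))
  cat(sprintf("  tap: %d powers x %d trials, ETP50 %.2f, hill %.2f, bg %.3f\n",
              length(x$tap$powers), x$tap$trials_per_power, x$tap$etp50,
              x$tap$hill, x$tap$background_move_prob))
  invisible(x)
}

# Deterministic per-unit seed streams. Seeds for units 1..n are the first n
# draws from a generator seeded with (master, stream label), so enlarging a
# cohort never changes existing units and streams are independent across
# labels (behavior / taps / calcium / movie).
unit_seeds <- function(master, label, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed((as.integer(master) + sum(utf8ToInt(label)) * 10007L) %% 2147483646L)
  sample.int(2147483646L, n)
}
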