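#' Detect movement events in a per-frame displacement series
#'
#' A movement event is a maximal run of nonzero pixel displacement preceded
#' and followed by at least `min_gap_ms` of stillness. Runs of movement
#' separated by a still gap shorter than `min_gap_ms` merge into one event.
#' At the usual 15 Hz capture rate one still frame spans 66.7 ms and so does
#' NOT separate events; two still frames (133 ms) do.
#'
#' @param displacements Nonnegative per-frame pixel displacements.
#' @param fps Frames per second of the recording.
#' @param min_gap_ms Minimum stillness, in ms, required between events.
#' @return Data.frame with columns `onset`, `offset`: 1-based frame indices
#'   of the first and last moving frame of each event.
#' @examples
#' detect_movement_events(c(1, 0, 0, 1, 0), fps = 15)   # two events
#' detect_movement_events(c(1, 0, 1), fps = 15)          # one merged event
#' @export
detect_movement_events <- function(displacements, fps, min_gap_ms = 67) {
  if (length(displacements) == 0) stop("empty displacement series")
  if (fps <= 0) stop("fps must be > 0")
  if (any(displacements < 0)) stop("displacements must be >= 0")
  moving <- displacements > 0
  if (!any(moving)) {
    return(data.frame(onset = integer(0), offset = integer(0)))
  }
  # a gap of k still frames spans k * (1000/fps) ms
  min_gap_frames <- ceiling(min_gap_ms * fps / 1000 - 1e-9)
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  if (length(on) > 1) {
    gaps <- on[-1] - off[-length(off)] - 1L
    keep <- gaps >= min_gap_frames
    # merge runs whose separating gap is too short
    grp <- cumsum(c(TRUE, keep))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  data.frame(onset = as.integer(on), offset = as.integer(off))
}

#' Score sleep from a per-minute activity trace
#'
#' Any one-minute bin with no movement is one minute of sleep. "No movement"
#' means activity at or below `zero_tol` (exact zero up to float noise).
#'
#' @param values Seconds of movement per 1-min bin (0-60).
#' @param zero_tol Tolerance below which a bin counts as motionless.
#' @return Logical vector, `TRUE` for sleep minutes; same length as input.
#' @examples
#' score_sleep(c(0, 0, 5, 0))
#' @export
score_sleep <- function(values, zero_tol = 1e-9) {
  stopifnot(is.numeric(values))
  values <= zero_tol
}

#' Extract sleep bouts from a sleep mask
#'
#' A sleep bout is a maximal run of consecutive sleep minutes.
#'
#' @param mask Logical sleep mask from [score_sleep()].
#' @return Data.frame with columns `start_min`, `end_min` (half-open, 1-based:
#'   a bout covering minutes 3-5 has `start_min = 3`, `end_min = 6`) and
#'   `length` in minutes. Zero rows if no sleep.
#' @examples
#' extract_bouts(c(TRUE, TRUE, FALSE, TRUE))
#' @export
extract_bouts <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    return(data.frame(start_min = integer(0), end_min = integer(0),
                      length = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_min = starts[keep], end_min = ends[keep] + 1L,
             length = r$lengths[keep])
}

#' Sleep latency relative to a reference event
#'
#' Time from a reference minute (lights on/off, or heat shock) to the start
#' of the first sleep bout at or after it. A bout already ongoing at the
#' reference gives latency 0. If no bout starts before `epoch_end`, the
#' latency is censored at the epoch length (reported, flagged, not dropped).
#'
#' @param bouts Bout table from [extract_bouts()].
#' @param reference Reference minute (1-based bin index).
#' @param epoch_end First minute after the epoch of interest (half-open);
#'   used both to restrict the search and as the censoring bound.
#' @return List with `latency` (minutes) and `censored` (logical).
#' @examples
#' b <- extract_bouts(c(rep(FALSE, 12), TRUE, TRUE))
#' sleep_latency(b, reference = 1, epoch_end = 15)$latency  # 12
#' @export
sleep_latency <- function(bouts, reference, epoch_end = Inf) {
  ongoing <- bouts$start_min <= reference & bouts$end_min > reference
  if (any(ongoing)) return(list(latency = 0, censored = FALSE))
  nxt <- bouts$start_min[bouts$start_min >= reference & bouts$start_min < epoch_end]
  if (length(nxt) == 0) {
    return(list(latency = if (is.finite(epoch_end)) epoch_end - reference else NA_real_,
                censored = TRUE))
  }
  list(latency = min(nxt) - reference, censored = FALSE)
}

#' Average and wake activity of a trace
#'
#' Average activity includes sleep bouts; wake activity excludes them. Both
#' are expressed in seconds of movement per hour.
#'
#' @param values Seconds-moved per minute.
#' @param mask Sleep mask aligned to `values` (default: scored from them).
#' @return List with `average_activity` and `wake_activity` (s/h);
#'   `wake_activity` is `NaN` when there are no wake minutes.
#' @examples
#' activity_metrics(c(0, 0, 6, 6))  # average 180 s/h, wake 360 s/h
#' @export
activity_metrics <- function(values, mask = score_sleep(values)) {
  if (length(values) != length(mask)) stop("mask and trace lengths differ")
  list(average_activity = 60 * mean(values),
       wake_activity = if (any(!mask)) 60 * mean(values[!mask]) else NaN)
}

#' Per-epoch sleep metrics for one larva
#'
#' Computes, within every day and night epoch of the schedule, the paper-style
#' sleep summary: total sleep, bout count, mean bout length, latency from the
#' epoch's lights transition, and average/wake activity. Bouts spanning an
#' epoch boundary are split at the boundary for the totals and counted once
#' in each epoch they touch (splitting conserves total sleep).
#'
#' @param values Seconds-moved per minute, anchored at the schedule start.
#' @param schedule A [light_schedule()] covering the trace.
#' @return Data.frame, one row per epoch: `epoch`, `day_index`, `start_min`,
#'   `epoch_min`, `total_sleep_min`, `sleep_per_h`, `bout_count`,
#'   `mean_bout_length`, `latency_min`, `latency_censored`,
#'   `average_activity`, `wake_activity`.
#' @export
epoch_metrics <- function(values, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (length(values) > schedule$n_min) stop("trace extends beyond schedule")
  mask <- score_sleep(values)
  bouts <- extract_bouts(mask)
  et <- epoch_table(schedule)
  et <- et[et$start_min <= length(values), , drop = FALSE]
  et$end_min <- pmin(et$end_min, length(values) + 1L)
  res <- lapply(seq_len(nrow(et)), function(i) {
    s <- et$start_min[i]; e <- et$end_min[i]
    idx <- s:(e - 1L)
    n_ep <- length(idx)
    # clip bouts to the epoch
    cs <- pmax(bouts$start_min, s)
    ce <- pmin(bouts$end_min, e)
    keep <- cs < ce
    lens <- (ce - cs)[keep]
    act <- activity_metrics(values[idx], mask[idx])
    lat <- sleep_latency(bouts, reference = s, epoch_end = e)
    data.frame(epoch = et$epoch[i], day_index = et$day_index[i],
               start_min = s, epoch_min = n_ep,
               total_sleep_min = sum(lens),
               sleep_per_h = 60 * sum(lens) / n_ep,
               bout_count = sum(keep),
               mean_bout_length = if (any(keep)) mean(lens) else 0,
               latency_min = lat$latency, latency_censored = lat$censored,
               average_activity = act$average_activity,
               wake_activity = act$wake_activity)
  })
  do.call(rbind, res)
}

#' Per-epoch metrics for a whole cohort
#'
#' @param activity Long `activity_data` data.frame (see
#'   [gen_activity_traces()]).
#' @param schedule A [light_schedule()].
#' @return Data.frame of [epoch_metrics()] rows with `larva_id` and `group`
#'   prepended.
#' @export
cohort_metrics <- function(activity, schedule) {
  ids <- unique(activity$larva_id)
  do.call(rbind, lapply(ids, function(id) {
    rows <- activity$larva_id == id
    m <- epoch_metrics(trace_values(activity, id), schedule)
    cbind(larva_id = id, group = activity$group[rows][1], m)
  }))
}

#' Smooth a 10-minute-binned series over 1-hour windows
#'
#' Centered moving mean over a 6-point (1 h) window on a 10-min grid; the
#' even window spans offsets -3..+2 bins and shrinks to the available points
#' at the series edges (no padding).
#'
#' @param x Numeric series on a 10-min grid.
#' @param window Window width in points (default 6, i.e. 1 h).
#' @return Smoothed series, same length.
#' @export
smooth_series <- function(x, window = 6L) {
  stopifnot(length(x) >= window)
  n <- length(x)
  # offsets -floor(w/2) .. +(w - floor(w/2) - 1): for w = 6, -3..+2
  lo <- pmax(1L, seq_len(n) - (window %/% 2))
  hi <- pmin(n, seq_len(n) + window - (window %/% 2) - 1L)
  vapply(seq_len(n), function(i) mean(x[lo[i]:hi[i]]), numeric(1))
}

#' Express per-animal values as percent of a control group
#'
#' @param values Per-animal values.
#' @param control Values of the control (e.g. wild-type) group.
#' @return `100 * values / mean(control)`.
#' @examples
#' normalize_to_control(3, c(2, 4))  # 100
#' @export
normalize_to_control <- function(values, control) {
  m <- mean(control)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  100 * values / m
}

#' Normalized locomotor response to a light pulse
#'
#' Quantifies activity during a 30-min light pulse relative to pre-pulse
#' baseline on 10-s-binned data. The minute after light onset (onset burst)
#' and the minute before onset are excluded; everything from pulse offset on
#' (the lights-off burst) is outside both windows by construction. Each
#' larva's pulse total is divided by the group-mean baseline total.
#'
#' @param traces Numeric matrix of 10-s-bin activity, one row per larva of
#'   the same group, columns = time bins.
#' @param onset_bin 1-based bin index of light onset.
#' @param pulse_min Pulse duration in minutes (default 30).
#' @param baseline_min Baseline duration before onset in minutes (default 30).
#' @return Numeric vector: per-larva pulse activity as a fraction of the
#'   group baseline (1 = unchanged).
#' @export
light_pulse_response <- function(traces, onset_bin, pulse_min = 30,
                                 baseline_min = 30) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  bins_per_min <- 6L
  need <- baseline_min * bins_per_min
  if (onset_bin - 1 < need) stop("insufficient pre-pulse baseline")
  # baseline: 30 min before onset minus the final minute
  base_idx <- (onset_bin - need):(onset_bin - bins_per_min - 1L)
  # pulse: 30 min from onset minus the first minute
  pulse_idx <- (onset_bin + bins_per_min):(onset_bin + pulse_min * bins_per_min - 1L)
  if (max(pulse_idx) > ncol(traces)) stop("trace too short for pulse window")
  base_tot <- rowSums(traces[, base_idx, drop = FALSE])
  pulse_tot <- rowSums(traces[, pulse_idx, drop = FALSE])
  # windows have equal length (29 min) so identical activity gives ratio 1
  pulse_tot / mean(base_tot)
}
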