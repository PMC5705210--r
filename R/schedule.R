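#' Define a light:dark schedule
#'
#' Builds a minute-resolution day/night schedule for a multi-day experiment.
#' The standard rearing schedule is 14:10 LD with lights on at 9:00 and off
#' at 23:00; imaging entrainment uses 13:11 LD. Both (and any other split)
#' are expressible.
#'
#' @param lights_on Time of day lights switch on, in hours (e.g. `9`).
#' @param lights_off Time of day lights switch off, in hours (e.g. `23`).
#' @param n_days Number of 24-h days covered.
#' @param start Time of day (h) at which the recording starts. Defaults to
#'   `lights_on` so minute 1 is the first day minute.
#'
#' @return An object of class `light_schedule`: a list with the arguments and
#'   `epoch`, a factor of `"day"`/`"night"` with one entry per experiment
#'   minute, plus `day_index`, the calendar day (1-based) of each minute.
#' @examples
#' sch <- light_schedule(9, 23, n_days = 2)
#' table(sch$epoch) / 60  # 28 h day, 20 h night
#' @export
light_schedule <- function(lights_on = 9, lights_off = 23, n_days = 1,
                           start = lights_on) {
  stopifnot(n_days >= 1, lights_on >= 0, lights_on < 24,
            lights_off >= 0, lights_off < 24, lights_on != lights_off)
  n_min <- as.integer(round(n_days * 24 * 60))
  # time of day in minutes for each 1-min bin (bin i covers [t, t+1))
  tod <- (round(start * 60) + seq_len(n_min) - 1L) %% (24L * 60L)
  on_m <- round(lights_on * 60)
  off_m <- round(lights_off * 60)
  is_day <- if (on_m < off_m) tod >= on_m & tod < off_m else tod >= on_m | tod < off_m
  structure(list(
    lights_on = lights_on, lights_off = lights_off, n_days = n_days,
    start = start, n_min = n_min,
    epoch = factor(ifelse(is_day, "day", "night"), levels = c("day", "night")),
    day_index = ((seq_len(n_min) - 1L) %/% (24L * 60L)) + 1L
  ), class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  day_h <- sum(x$epoch == "day") / 60 / x$n_days
  cat(sprintf("light_schedule: %g:%g h LD, lights on %02.0f:%02.0f, off %02.0f:%02.0f, %d day(s), %d min\n",
              day_h, 24 - day_h,
              floor(x$lights_on), (x$lights_on %% 1) * 60,
              floor(x$lights_off), (x$lights_off %% 1) * 60,
              x$n_days, x$n_min))
  invisible(x)
}

#' Epoch boundaries of a schedule
#'
#' Start minutes (1-based) of each maximal day or night epoch, used to anchor
#' per-epoch metrics and sleep-latency references.
#'
#' @param schedule A [light_schedule()].
#' @return A data.frame with columns `epoch`, `day_index`, `start_min`,
#'   `end_min` (half-open, 1-based minute indices).
#' @export
epoch_table <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  e <- as.character(schedule$epoch)
  r <- rle(e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(epoch = r$values,
             day_index = schedule$day_index[starts],
             start_min = starts, end_min = ends + 1L)
}
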