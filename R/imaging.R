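#' Baseline-subtracted fluorescence (dF)
#'
#' `dF = F - F0` with the baseline chosen by `mode`:
#' \describe{
#'   \item{`global_min`}{F0 = lowest signal over the whole recording, so
#'     `min(dF) = 0` (used for long day/night tectal recordings).}
#'   \item{`first5_mean`}{F0 = mean signal over the first five trials
#'     (optogenetic-stimulation sessions); requires `trial_idx`.}
#'   \item{`smoothed_min_5s`}{F0 = minimum of the trace after a 5-s sliding
#'     (boxcar) smooth, computed per trial when `trial_idx` is given — the
#'     per-neuron convention for segmented ROIs.}
#' }
#'
#' @param f Fluorescence trace (1 Hz samples).
#' @param mode Baseline mode (see above).
#' @param trial_idx Optional integer trial index per sample, required for
#'   `first5_mean` and used to bound the smoothing for `smoothed_min_5s`.
#' @return Numeric dF trace, same length as `f`.
#' @examples
#' delta_f(c(1, 2, 3), "global_min")  # 0 1 2
#' @export
delta_f <- function(f, mode = c("global_min", "first5_mean", "smoothed_min_5s"),
                    trial_idx = NULL) {
  mode <- match.arg(mode)
  if (length(f) == 0) stop("empty trace")
  f0 <- switch(mode,
    global_min = min(f),
    first5_mean = {
      if (is.null(trial_idx)) stop("first5_mean needs trial_idx")
      if (length(unique(trial_idx)) < 5) stop("fewer than 5 trials")
      mean(f[trial_idx %in% sort(unique(trial_idx))[1:5]])
    },
    smoothed_min_5s = {
      if (length(f) < 5) stop("trace shorter than the 5-s smoothing window")
      if (is.null(trial_idx)) min(boxcar5(f))
      else min(unlist(tapply(f, trial_idx, boxcar5)))
    })
  f - f0
}

# centered 5-sample moving mean, shrink-at-edges
boxcar5 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - 2):min(n, i + 2)]),
         numeric(1))
}

#' Phase-window means of a 2-min trial
#'
#' Arithmetic means of the fluorescence samples in the intrinsic (5-25 s),
#' light-on evoked (32-37 s) and light-off evoked (93-98 s) windows.
#' Windows are inclusive on integer seconds (sample t = 5 through t = 25 is
#' 21 samples) with t = 0 the first sample of the trial.
#'
#' @param trial Numeric vector of 120 samples at 1 Hz (t = 0..119 s).
#' @return Named numeric vector `intrinsic`, `on_evoked`, `off_evoked`.
#' @export
trial_window_means <- function(trial) {
  if (length(trial) < 99) stop("trial too short for the 93-98 s window")
  c(intrinsic = mean(trial[5:25 + 1]),
    on_evoked = mean(trial[32:37 + 1]),
    off_evoked = mean(trial[93:98 + 1]))
}

#' Window means for every trial of a session
#'
#' @param trials Matrix (one row per trial, 120 columns; see
#'   [trial_matrix()]).
#' @return Data.frame with `trial_idx`, `intrinsic`, `on_evoked`,
#'   `off_evoked`.
#' @export
session_window_means <- function(trials) {
  wm <- t(apply(trials, 1, trial_window_means))
  data.frame(trial_idx = seq_len(nrow(trials)), wm)
}

#' Sliding smooth across trials
#'
#' Centered moving mean over a 5-trial window (shrink-at-edges), applied to a
#' per-trial summary series before plotting/averaging.
#'
#' @param x Per-trial values.
#' @param window Window width in trials (odd; default 5).
#' @return Smoothed series, same length.
#' @export
sliding_trial_smooth <- function(x, window = 5L) {
  stopifnot(length(x) >= 1, window %% 2 == 1)
  n <- length(x)
  h <- window %/% 2
  vapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

#' Normalize a fluorescence series by a reference level F_N
#'
#' @param x Series (dF values, window means, or per-trial summaries).
#' @param f_n The normalization constant: the subjective-day intrinsic mean,
#'   the per-animal post-light peak, or the per-animal day mean, depending on
#'   the analysis.
#' @return `x / f_n`.
#' @export
normalize_trace <- function(x, f_n) {
  if (!is.finite(f_n) || f_n <= 0) stop("F_N must be > 0")
  x / f_n
}

#' Post-light peak normalization constant
#'
#' `F_N` for optogenetic-stimulation sessions: the peak of the signal after
#' the (red) stimulation light first turns on.
#'
#' @param x Per-trial (or per-sample) series.
#' @param light_on_idx Index of the first value after light onset.
#' @return The maximum over `x[light_on_idx:length(x)]`.
#' @export
post_light_peak <- function(x, light_on_idx) {
  stopifnot(light_on_idx >= 1, light_on_idx <= length(x))
  max(x[light_on_idx:length(x)])
}

#' Correlation of evoked and intrinsic activity
#'
#' Pearson correlation across trials between the intrinsic window mean and an
#' evoked window mean.
#'
#' @param summaries Data.frame from [session_window_means()].
#' @param evoked Which evoked window to correlate (`"on_evoked"` or
#'   `"off_evoked"`).
#' @return Pearson r.
#' @export
evoked_intrinsic_correlation <- function(summaries,
                                         evoked = c("on_evoked", "off_evoked")) {
  evoked <- match.arg(evoked)
  if (nrow(summaries) < 3) stop("need >= 3 trials")
  if (stats::sd(summaries$intrinsic) == 0 || stats::sd(summaries[[evoked]]) == 0)
    stop("zero variance in window means")
  stats::cor(summaries$intrinsic, summaries[[evoked]])
}

#' Steady-state level after stimulation
#'
#' Mean of the normalized per-trial values over trials 10-15 (the last six
#' trials of the 15-trial stimulation protocol).
#'
#' @param x Normalized per-trial values, indexed by trial (1-based).
#' @return Scalar steady-state level.
#' @export
steady_state <- function(x) {
  if (length(x) < 15) stop("need >= 15 trials")
  mean(x[10:15])
}

#' Segment active neurons from a movie by PCA/ICA
#'
#' Classic PCA/ICA segmentation for calcium movies: the pixel x time matrix
#' is mean-centered per pixel, reduced to `n_pcs` principal components
#' (or to the smallest count reaching `var_target` explained variance when
#' given), and FastICA then unmixes the retained components into spatially
#' independent filters. Each filter is sign-aligned to positive skewness,
#' z-scored, and thresholded; connected components whose equivalent diameter
#' lies within `[0.5, 2] * spatial_filter_px` become ROI masks. ROI traces
#' are mean fluorescence over mask pixels per frame; per-ROI baseline F0 is
#' the minimum of the 5-sample boxcar-smoothed trace.
#'
#' @param movie Numeric array height x width x frames.
#' @param n_pcs Number of principal components to retain (default 15).
#' @param spatial_filter_px Characteristic ROI diameter in pixels (default 5,
#'   the nominal nuclear size).
#' @param var_target Optional explained-variance fraction (e.g. 0.75) that
#'   overrides `n_pcs`.
#' @param z_thresh z-score threshold on ICA spatial filters.
#' @return Object of class `neuron_set`: `masks` (logical h x w x n array),
#'   `centroids` (n x 2, row/col), `traces` (n x frames), `f0` (length n),
#'   `n_neurons`, `explained_variance` (fraction covered by the retained
#'   PCs).
#' @export
segment_neurons <- function(movie, n_pcs = 15, spatial_filter_px = 5,
                            var_target = NULL, z_thresh = 3) {
  d <- dim(movie)
  stopifnot(length(d) == 3)
  h <- d[1]; w <- d[2]; nt <- d[3]
  x <- matrix(movie, h * w, nt)
  x <- x - rowMeans(x)  # per-pixel centering: offset-invariant
  tot_var <- sum(x ^ 2)
  if (tot_var < .Machine$double.eps) stop("degenerate (constant) movie")
  if (nt < n_pcs) stop("movie has fewer frames than requested components")
  sv <- svd(x, nu = min(50, nt - 1), nv = 0)
  ev <- sv$d ^ 2 / sum(sv$d ^ 2)
  if (!is.null(var_target)) {
    n_pcs <- min(which(cumsum(ev) >= var_target), length(sv$d))
  }
  n_pcs <- min(n_pcs, ncol(sv$u))
  explained <- sum(ev[seq_len(n_pcs)])
  # spatial ICA on the PC maps (pixels x components)
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE]
  ic_maps <- tryCatch({
    res <- ica::icafast(pcs, nc = n_pcs, center = TRUE, maxit = 200,
                        tol = 1e-6)
    res$S
  }, error = function(e) pcs)
  empty <- function() structure(
    list(masks = array(FALSE, c(h, w, 0)),
         centroids = matrix(numeric(0), 0, 2),
         traces = matrix(numeric(0), 0, nt), f0 = numeric(0),
         n_neurons = 0L, explained_variance = explained),
    class = "neuron_set")
  masks <- list(); cents <- list()
  lo_d <- 0.5 * spatial_filter_px; hi_d <- 2 * spatial_filter_px
  for (j in seq_len(ncol(ic_maps))) {
    m <- ic_maps[, j]
    if (mean((m - mean(m))^3) / stats::sd(m)^3 < 0) m <- -m  # positive skew
    z <- (m - stats::median(m)) / max(stats::mad(m), 1e-12)
    bin <- matrix(z > z_thresh, h, w)
    if (!any(bin)) next
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      # refine to the blob's half-maximum support: the filter of a Gaussian
      # nucleus then has diameter = its FWHM (the nominal cell size)
      px <- px[z[px] >= 0.5 * max(z[px])]
      area <- length(px)
      dia <- 2 * sqrt(area / pi)
      if (dia < lo_d || dia > hi_d) next
      mk <- matrix(FALSE, h, w); mk[px] <- TRUE
      rr <- (px - 1) %% h + 1; cc <- (px - 1) %/% h + 1
      masks[[length(masks) + 1]] <- mk
      cents[[length(cents) + 1]] <- c(mean(rr), mean(cc))
    }
  }
  if (length(masks) == 0) return(empty())
  # deduplicate masks found by several components (Jaccard > 0.5)
  keep <- rep(TRUE, length(masks))
  for (i in seq_along(masks)) {
    if (!keep[i]) next
    for (j in seq_along(masks)) {
      if (j <= i || !keep[j]) next
      inter <- sum(masks[[i]] & masks[[j]])
      if (inter / sum(masks[[i]] | masks[[j]]) > 0.5) keep[j] <- FALSE
    }
  }
  masks <- masks[keep]; cents <- cents[keep]
  n <- length(masks)
  traces <- t(vapply(masks, function(mk) colMeans(matrix(movie, h * w, nt)[as.vector(mk), , drop = FALSE]),
                     numeric(nt)))
  f0 <- apply(traces, 1, function(tr) min(boxcar5(tr)))
  structure(list(
    masks = array(unlist(masks), c(h, w, n)),
    centroids = do.call(rbind, cents),
    traces = traces, f0 = f0, n_neurons = n,
    explained_variance = explained), class = "neuron_set")
}

#' @export
print.neuron_set <- function(x, ...) {
  cat(sprintf("neuron_set: %d ROI(s); retained PCs cover %.1f%% of variance\n",
              x$n_neurons, 100 * x$explained_variance))
  invisible(x)
}

#' Day/night activity contrast of segmented neurons
#'
#' Averages dF over all segmented neurons within each imaging session, labels
#' sessions day or night, and summarizes: the day value is the mean of the
#' two flanking day periods (before and after the night); night activity is
#' optionally normalized by the same animal's day mean (making the day value
#' exactly 1), the convention for between-genotype comparisons.
#'
#' @param session_means Data.frame with columns `animal`, `period`
#'   (`"day1"`, `"night"`, `"day2"` — or `"day"`/`"night"`), `activity`
#'   (mean dF over neurons for the session).
#' @param normalize Normalize each animal's values by its day mean.
#' @return Data.frame per animal: `day`, `night`, `contrast`
#'   (`(day - night)/day`), and the inputs used.
#' @export
day_night_activity <- function(session_means, normalize = FALSE) {
  need <- c("animal", "period", "activity")
  stopifnot(all(need %in% names(session_means)))
  out <- lapply(split(session_means, session_means$animal), function(sm) {
    is_day <- grepl("^day", sm$period)
    if (!any(is_day) || all(is_day)) stop("each animal needs day and night sessions")
    day_periods <- tapply(sm$activity[is_day], sm$period[is_day], mean)
    day <- mean(day_periods)  # average of both flanking day periods
    night <- mean(sm$activity[!is_day])
    if (normalize) { night <- night / day; day <- 1 }
    data.frame(animal = sm$animal[1], day = day, night = night,
               contrast = (day - night) / day)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
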