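# Brute-force oracles kept deliberately independent of the package internals.

# run-length extraction by explicit loop
oracle_runs <- function(mask) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(mask)) {
    if (mask[i] && !in_run) { starts <- c(starts, i); in_run <- TRUE }
    if (!mask[i] && in_run) { ends <- c(ends, i); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, length(mask) + 1L)
  data.frame(start_min = starts, end_min = ends)
}

# movement-event merger by explicit scan over frame gaps
oracle_events <- function(disp, fps, min_gap_ms = 67) {
  moving <- which(disp > 0)
  if (length(moving) == 0) return(data.frame(onset = integer(0), offset = integer(0)))
  on <- moving[1]; off <- moving[1]
  res <- NULL
  for (i in moving[-1]) {
    gap_ms <- (i - off - 1) * 1000 / fps
    if (gap_ms >= min_gap_ms - 1e-9 && i - off - 1 > 0) {
      res <- rbind(res, c(on, off)); on <- i
    }
    off <- i
  }
  res <- rbind(res, c(on, off))
  data.frame(onset = res[, 1], offset = res[, 2])
}

# centered moving mean with arbitrary offsets, shrink at edges
oracle_moving_mean <- function(x, lo_off, hi_off) {
  n <- length(x)
  sapply(seq_len(n), function(i)
    mean(x[max(1, i + lo_off):min(n, i + hi_off)]))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# recovery score of a segmentation against planted ground truth
match_planted <- function(mov, ns, max_dist = 1, min_jacc = 0.5) {
  hits <- 0L
  if (ns$n_neurons == 0) return(0L)
  for (i in seq_len(nrow(mov$centers))) {
    d <- sqrt(colSums((t(ns$centroids) - mov$centers[i, ]) ^ 2))
    j <- which.min(d)
    if (d[j] <= max_dist &&
        jaccard(mov$masks[, , i], ns$masks[, , j]) >= min_jacc) hits <- hits + 1L
  }
  hits
}

# standard error of a mean of a stationary two-state chain observed n minutes
# (binomial variance inflated by the chain's lag-1 autocorrelation)
markov_se <- function(p_ws, p_sw, n) {
  pi1 <- p_ws / (p_ws + p_sw)
  rho <- 1 - p_ws - p_sw
  sqrt(pi1 * (1 - pi1) / n * (1 + rho) / (1 - rho))
}
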