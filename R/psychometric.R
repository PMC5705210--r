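#' Variable-slope log-dose response curve
#'
#' The four-parameter logistic in log10(dose):
#' `y = bottom + (top - bottom) / (1 + 10^((log_etp50 - log10(power)) * hill))`.
#' At `power = etp50` the curve is exactly halfway between bottom and top;
#' `hill` sets the slope (and direction) of the transition.
#'
#' @param power Stimulus intensities (> 0, tap-power units).
#' @param bottom,top Lower and upper response-fraction asymptotes.
#' @param log_etp50 log10 of the half-maximal intensity.
#' @param hill Hill slope.
#' @return Response fractions at `power`.
#' @export
psychometric_curve <- function(power, bottom, top, log_etp50, hill) {
  stopifnot(all(power > 0))
  bottom + (top - bottom) / (1 + 10 ^ ((log_etp50 - log10(power)) * hill))
}

#' Per-power response fractions
#'
#' @param trials Tap-trial data.frame with columns `power`, `responded`, and
#'   optionally `group` (fractions computed per group).
#' @return Data.frame `group` (if present), `power` (ascending), `fraction`,
#'   `n_trials`.
#' @export
response_table <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  grp <- if ("group" %in% names(trials)) trials$group else "all"
  agg <- stats::aggregate(trials$responded,
                          by = list(group = grp, power = trials$power),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(group = agg$group, power = agg$power,
                    fraction = agg$x[, 1], n_trials = agg$x[, 2])
  out[order(out$group, out$power), , drop = FALSE]
}

#' Background probability of movement
#'
#' The fraction of trials in which the larva was already moving in the 5 s
#' before the stimulus, pooled over all trials of a group (420 per larva in
#' the standard 14 x 30 design).
#'
#' @param trials Tap-trial data.frame with `pre_moved` and optionally
#'   `group`.
#' @return Named numeric vector of per-group probabilities.
#' @export
background_probability <- function(trials) {
  if (any(is.na(trials$pre_moved))) stop("pre_moved missing for some trials")
  grp <- if ("group" %in% names(trials)) trials$group else "all"
  p <- tapply(trials$pre_moved, grp, mean)
  stats::setNames(as.numeric(p), names(p))
}

#' Subtract background movement from response fractions
#'
#' The group's background probability is subtracted from each per-power
#' response fraction; results are clamped to a floor of 0 (fractions are
#' probabilities).
#'
#' @param fractions Response fractions in `[0, 1]`.
#' @param background Background movement probability in `[0, 1]`.
#' @return Adjusted fractions in `[0, 1]`.
#' @examples
#' adjust_fractions(c(0.25, 0.03), 0.05)  # 0.20, 0.00
#' @export
adjust_fractions <- function(fractions, background) {
  if (background < 0 || background > 1) stop("background must be in [0, 1]")
  stopifnot(all(fractions >= 0 & fractions <= 1))
  pmax(0, fractions - background)
}

# Fixed jitter directions for multi-start fits (deterministic, no RNG use so
# fitting never perturbs the caller's random stream). Rows beyond the table
# recycle with growing scale.
jittered_starts <- function(start0, lower, upper, n_restarts, scale) {
  dirs <- matrix(c( 1, -1,  1, -1,
                   -1,  1, -1,  1,
                    1,  1, -1, -1,
                   -1, -1,  1,  1,
                    0,  0,  1, -1,
                    0,  0, -1,  1,
                    1, -1,  0,  2,
                   -1,  1,  0, -2), ncol = 4, byrow = TRUE)
  starts <- list(start0)
  for (j in seq_len(n_restarts)) {
    d <- dirs[(j - 1) %% nrow(dirs) + 1, ]
    k <- 1 + (j - 1) %/% nrow(dirs)
    s <- start0 + k * d * scale[seq_along(start0)]
    starts[[j + 1]] <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
  }
  starts
}

#' Fit the variable-slope log-dose psychometric model
#'
#' Least-squares fit of [psychometric_curve()] to per-power response
#' fractions, the analysis behind arousal-threshold (ETP50) estimation.
#' Bounded Levenberg-Marquardt (`0 <= bottom`, `top <= 1`) with a data-driven
#' start (`bottom = min(y)`, `top = max(y)`, `log_etp50` at the mid-range
#' power, `hill = 1`) plus 8 jittered restarts; the lowest residual sum of
#' squares wins. Unweighted by default; supply `weights` (e.g. trial counts)
#' for weighted least squares.
#'
#' @param power Tap powers (> 0), at least 4 distinct values.
#' @param fraction Response fraction at each power.
#' @param weights Optional nonnegative weights, same length.
#' @param n_restarts Number of jittered restarts beyond the base start.
#' @return An object of class `psychfit`: coefficients `bottom`, `top`,
#'   `log_etp50`, `hill`; `ss_resid`; `n_points`; `df` (`n_points - 4`);
#'   `degenerate` flag (constant fractions: no threshold exists and
#'   `log_etp50`/`hill` are `NA`); and the data. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' p <- c(1, 2, 4, 8, 16, 32)
#' y <- psychometric_curve(p, 0, 1, log10(6), 2)
#' fit <- fit_psychometric(p, y)
#' etp50(fit)  # ~6
#' @export
fit_psychometric <- function(power, fraction, weights = NULL, n_restarts = 8) {
  stopifnot(all(power > 0), length(power) == length(fraction))
  if (length(unique(power)) < 4) stop("need >= 4 distinct powers")
  if (is.null(weights)) weights <- rep(1, length(power))
  o <- order(power)
  power <- power[o]; fraction <- fraction[o]; weights <- weights[o]
  data <- data.frame(power = power, fraction = fraction, weights = weights)

  if (diff(range(fraction)) < 1e-12) {
    fit <- structure(list(
      coefficients = c(bottom = fraction[1], top = fraction[1],
                       log_etp50 = NA_real_, hill = NA_real_),
      ss_resid = 0, n_points = length(power), df = length(power) - 4L,
      degenerate = TRUE, data = data), class = "psychfit")
    return(fit)
  }

  lp <- log10(power)
  start0 <- c(bottom = max(0, min(fraction)), top = min(1, max(fraction)),
              log_etp50 = lp[which.min(abs(fraction - stats::median(fraction)))],
              hill = 1)
  lower <- c(0, 0, min(lp) - 2, -50)
  upper <- c(1, 1, max(lp) + 2, 50)
  starts <- jittered_starts(start0, lower, upper, n_restarts,
                            scale = c(0.1, 0.1, 0.6, 1.2))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = s,
        fn = function(par) sqrt(weights) *
          (fraction - psychometric_curve(power, par[1], par[2], par[3], par[4])),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(f)) next
    ss <- sum(f$fvec ^ 2)
    if (is.null(best) || ss < best$ss - 1e-15) best <- list(par = f$par, ss = ss)
  }
  if (is.null(best)) stop("psychometric fit failed to converge from all starts")
  par <- best$par
  names(par) <- c("bottom", "top", "log_etp50", "hill")
  structure(list(coefficients = par, ss_resid = best$ss,
                 n_points = length(power), df = length(power) - 4L,
                 degenerate = FALSE, data = data),
            class = "psychfit")
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
fitted.psychfit <- function(object, ...) {
  if (object$degenerate) return(rep(object$coefficients["bottom"],
                                    object$n_points))
  with(object$data, psychometric_curve(power, object$coefficients[1],
                                       object$coefficients[2],
                                       object$coefficients[3],
                                       object$coefficients[4]))
}

#' @export
residuals.psychfit <- function(object, ...) object$data$fraction - fitted(object)

#' Predict response fractions from a fitted psychometric curve
#'
#' @param object A `psychfit`.
#' @param newdata Optional data.frame with a `power` column (or a numeric
#'   vector of powers).
#' @param ... Unused.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  if (object$degenerate) stop("degenerate fit: threshold undefined")
  p <- if (is.null(newdata)) object$data$power
       else if (is.data.frame(newdata)) newdata$power else newdata
  psychometric_curve(p, object$coefficients[1], object$coefficients[2],
                     object$coefficients[3], object$coefficients[4])
}

#' @export
print.psychfit <- function(x, ...) {
  if (x$degenerate) {
    cat("psychfit (degenerate): constant response fraction",
        format(x$coefficients[["bottom"]]), "- ETP50 undefined\n")
    return(invisible(x))
  }
  cat("Variable-slope log(dose) psychometric fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("ETP50 = %.3f; residual SS = %.4g on %d df (%d points)\n",
              etp50(x), x$ss_resid, x$df, x$n_points))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              etp50 = if (object$degenerate) NA_real_ else etp50(object),
              ss_resid = object$ss_resid, df = object$df,
              n_points = object$n_points, degenerate = object$degenerate,
              rmse = sqrt(object$ss_resid / max(1, object$df)))
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat("Psychometric fit summary\n")
  print(round(x$coefficients, 4))
  cat(sprintf("ETP50 %.3f | SS %.4g | RMSE %.4g | n %d | df %d%s\n",
              x$etp50, x$ss_resid, x$rmse, x$n_points, x$df,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Plot a fitted psychometric curve over its data
#'
#' @param x A `psychfit`.
#' @param n_grid Number of curve-evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psychfit <- function(x, n_grid = 200, ...) {
  with(x$data, graphics::plot(power, fraction, log = "x",
                              xlab = "tap power", ylab = "response fraction",
                              ...))
  if (!x$degenerate) {
    g <- 10 ^ seq(log10(min(x$data$power)), log10(max(x$data$power)),
                  length.out = n_grid)
    graphics::lines(g, predict(x, g))
    graphics::abline(v = etp50(x), lty = 2)
  }
  invisible(x)
}

#' Effective tap power 50
#'
#' The stimulus intensity at which the fitted curve reaches the midpoint of
#' its bottom and top asymptotes; higher ETP50 means a higher arousal
#' threshold.
#'
#' @param fit A `psychfit` from [fit_psychometric()].
#' @return ETP50 in tap-power units (`10^log_etp50`).
#' @export
etp50 <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  if (fit$degenerate) stop("degenerate fit: ETP50 undefined")
  unname(10 ^ fit$coefficients["log_etp50"])
}

#' Extra sum-of-squares F test for an ETP50 difference
#'
#' Nested nonlinear model comparison between two groups' dose-response data:
#' the null model shares all four parameters (one curve for both groups); the
#' alternative shares bottom, top and hill but lets each group have its own
#' `log_etp50` (df1 = 1). `F = ((SS0 - SS1)/(df0 - df1)) / (SS1/df1_resid)`,
#' with p from the F distribution.
#'
#' @param data_a,data_b Data.frames with columns `power`, `fraction`, and
#'   optionally `n_trials` (trial count behind each fraction, used by
#'   binomial weighting), one per group.
#' @param n_restarts Restarts passed to the underlying joint fits.
#' @param weighting `"none"` for ordinary least squares, or `"binomial"` to
#'   weight each point by the reciprocal of its (shrunken) binomial variance
#'   `p(1-p)/n` - needed for a calibrated F test when response fractions come
#'   from many Bernoulli trials, whose variance collapses at the asymptotes.
#' @return Object of class `psych_ftest`: `F`, `df1`, `df2`, `p_value`,
#'   `ss_null`, `ss_alt`, `etp50_a`, `etp50_b`, `perfect_fit` flag.
#' @export
compare_fits_extra_ss <- function(data_a, data_b, n_restarts = 4,
                                  weighting = c("none", "binomial")) {
  weighting <- match.arg(weighting)
  pooled <- rbind(cbind(data_a[c("power", "fraction")], g = 0),
                  cbind(data_b[c("power", "fraction")], g = 1))
  n <- nrow(pooled)
  pooled$w <- if (weighting == "binomial") {
    nt <- c(if ("n_trials" %in% names(data_a)) data_a$n_trials else rep(30, nrow(data_a)),
            if ("n_trials" %in% names(data_b)) data_b$n_trials else rep(30, nrow(data_b)))
    # Jeffreys-shrunken fraction keeps weights finite at 0/1
    p_sh <- (pooled$fraction * nt + 0.5) / (nt + 1)
    nt / (p_sh * (1 - p_sh))
  } else rep(1, n)
  null_fit <- fit_psychometric(pooled$power, pooled$fraction,
                               weights = pooled$w, n_restarts = n_restarts)
  ss0 <- null_fit$ss_resid
  alt <- fit_shared_shift(pooled, start = coef(null_fit),
                          n_restarts = n_restarts)
  ss1 <- alt$ss
  # re-polish the null from the alternative's solution so the nested model
  # can never appear worse than its own special case (a convergence artifact)
  repolish <- tryCatch(
    minpack.lm::nls.lm(
      par = c(alt$par[1:3], log_etp50 = unname(mean(alt$par[4:5]))),
      fn = function(par) sqrt(pooled$w) *
        (pooled$fraction -
           psychometric_curve(pooled$power, par[1], par[2], par[4], par[3])),
      lower = c(0, 0, -50, min(log10(pooled$power)) - 2),
      upper = c(1, 1, 50, max(log10(pooled$power)) + 2),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(repolish)) ss0 <- min(ss0, sum(repolish$fvec ^ 2))
  ss1 <- min(ss1, ss0)
  df1_resid <- n - 5L
  perfect <- ss1 <= .Machine$double.eps * n
  Fstat <- if (perfect) Inf else max(0, (ss0 - ss1) / 1 / (ss1 / df1_resid))
  p <- if (perfect) .Machine$double.xmin
       else stats::pf(Fstat, 1, df1_resid, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = 1L, df2 = df1_resid, p_value = p,
                 ss_null = ss0, ss_alt = ss1,
                 etp50_a = 10 ^ alt$par[["le50_a"]],
                 etp50_b = 10 ^ alt$par[["le50_b"]],
                 perfect_fit = perfect),
            class = "psych_ftest")
}

jittered_starts5 <- function(s0, lower, upper, n_restarts) {
  dirs <- matrix(c( 1, -1,  1, -1,  1,
                   -1,  1, -1,  1, -1,
                    0,  0,  2,  1, -1,
                    0,  0, -2, -1,  1), ncol = 5, byrow = TRUE)
  scale <- c(0.05, 0.05, 0.8, 0.4, 0.4)
  starts <- list(s0)
  for (j in seq_len(n_restarts)) {
    d <- dirs[(j - 1) %% nrow(dirs) + 1, ]
    k <- 1 + (j - 1) %/% nrow(dirs)
    starts[[j + 1]] <- pmin(pmax(s0 + k * d * scale, lower + 1e-6),
                            upper - 1e-6)
  }
  starts
}

# Joint fit with shared bottom/top/hill and per-group log_etp50.
fit_shared_shift <- function(pooled, start, n_restarts = 4) {
  sw <- sqrt(if (is.null(pooled$w)) rep(1, nrow(pooled)) else pooled$w)
  resid_fn <- function(par) {
    le <- ifelse(pooled$g == 0, par[4], par[5])
    sw * (pooled$fraction -
      (par[1] + (par[2] - par[1]) /
         (1 + 10 ^ ((le - log10(pooled$power)) * par[3]))))
  }
  s0 <- c(bottom = unname(start["bottom"]), top = unname(start["top"]),
          hill = unname(start["hill"]), le50_a = unname(start["log_etp50"]),
          le50_b = unname(start["log_etp50"]))
  lp <- log10(pooled$power)
  lower <- c(0, 0, -50, min(lp) - 2, min(lp) - 2)
  upper <- c(1, 1, 50, max(lp) + 2, max(lp) + 2)
  starts <- jittered_starts5(s0, lower, upper, n_restarts)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(f)) next
    ss <- sum(f$fvec ^ 2)
    if (is.null(best) || ss < best$ss - 1e-15) best <- list(par = f$par, ss = ss)
  }
  if (is.null(best)) stop("joint psychometric fit failed")
  best
}

#' @export
print.psych_ftest <- function(x, ...) {
  cat(sprintf("Extra sum-of-squares F test: F(%d,%d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_value))
  cat(sprintf("  ETP50: %.3f vs %.3f (shared bottom/top/hill)\n",
              x$etp50_a, x$etp50_b))
  if (x$perfect_fit) cat("  note: alternative model fits perfectly; p at machine floor\n")
  invisible(x)
}

#' Percent change between two ETP50 values
#'
#' `100 * (treated - reference) / reference` with the fractional part
#' truncated toward zero — the convention that reproduces the reported
#' figure-caption arithmetic (e.g. 20.3 vs 6.2 gives +227).
#'
#' @param treated,reference ETP50 (or any positive quantity) values.
#' @return Signed integer percent change.
#' @examples
#' percent_change(20.3, 6.2)  # 227
#' percent_change(2.8, 8.2)   # -65
#' @export
percent_change <- function(treated, reference) {
  if (reference <= 0) stop("reference must be > 0")
  as.integer(trunc(100 * (treated - reference) / reference))
}

#' Full arousal-threshold analysis of a tap dataset
#'
#' Convenience pipeline: per-group response fractions, background movement
#' probability, background subtraction, psychometric fit per group, and (for
#' exactly two groups) the extra sum-of-squares comparison of ETP50.
#'
#' @param trials Tap-trial data.frame (`larva_id`, `group`, `power`,
#'   `responded`, `pre_moved`).
#' @return List with `background`, `fractions` (adjusted response table),
#'   `fits` (named list of `psychfit`), `etp50` (named vector), and for two
#'   groups `comparison` (`psych_ftest`) and `percent_change`.
#' @export
arousal_analysis <- function(trials) {
  bg <- background_probability(trials)
  rt <- response_table(trials)
  rt$adjusted <- NA_real_
  fits <- list()
  for (g in names(bg)) {
    rows <- rt$group == g
    rt$adjusted[rows] <- adjust_fractions(rt$fraction[rows], bg[[g]])
    fits[[g]] <- fit_psychometric(rt$power[rows], rt$adjusted[rows])
  }
  out <- list(background = bg, fractions = rt, fits = fits,
              etp50 = vapply(fits, etp50, numeric(1)))
  if (length(fits) == 2) {
    ga <- names(fits)[1]; gb <- names(fits)[2]
    da <- data.frame(power = rt$power[rt$group == ga],
                     fraction = rt$adjusted[rt$group == ga])
    db <- data.frame(power = rt$power[rt$group == gb],
                     fraction = rt$adjusted[rt$group == gb])
    out$comparison <- compare_fits_extra_ss(da, db)
    out$percent_change <- percent_change(out$etp50[[gb]], out$etp50[[ga]])
  }
  out
}
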