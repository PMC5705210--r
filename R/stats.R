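#' Group summary (mean +/- SEM)
#'
#' @param values Per-animal values.
#' @param group Group label per value.
#' @return Data.frame `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, group) {
  res <- lapply(split(values, group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v))))
  out <- do.call(rbind, res)
  cbind(group = rownames(out), out, row.names = NULL)
}

#' Student's t test
#'
#' Two-sample (pooled-variance, unpaired, two-tailed) or one-sample t test.
#' The pooled-variance form is used deliberately (the classical Student
#' test); Welch's correction is available via `var_equal = FALSE`. Samples
#' with zero variance and equal means return `t = 0`, `p = 1` by convention.
#'
#' @param a First sample.
#' @param b Second sample, or `NULL` for a one-sample test.
#' @param null_value Hypothesized mean for the one-sample test (default 0;
#'   use 1 for normalized ratios).
#' @param var_equal Pool variances (Student's form) in the two-sample test.
#' @return List of class `zf_test`: `statistic`, `df`, `p_value`, `method`.
#' @export
t_test <- function(a, b = NULL, null_value = 0, var_equal = TRUE) {
  if (is.null(b)) {
    stopifnot(length(a) >= 2)
    if (stats::sd(a) == 0) {
      eq <- isTRUE(all.equal(mean(a), null_value))
      return(zf_test(if (eq) 0 else Inf, length(a) - 1L,
                     if (eq) 1 else 0, "one-sample t-test"))
    }
    ht <- stats::t.test(a, mu = null_value)
    return(zf_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                   "one-sample t-test"))
  }
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(zf_test(if (eq) 0 else Inf, length(a) + length(b) - 2L,
                   if (eq) 1 else 0, "Student's two-sample t-test"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  zf_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
          if (var_equal) "Student's two-sample t-test" else "Welch's t-test")
}

zf_test <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p_value = p, method = method),
            class = "zf_test")
}

#' @export
print.zf_test <- function(x, ...) {
  df <- if (length(x$df) == 1) sprintf("df = %.4g", x$df)
        else sprintf("df = (%s)", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: statistic = %.4g, %s, p = %.4g\n",
              x$method, x$statistic, df, x$p_value))
  invisible(x)
}

#' One- or two-way analysis of variance
#'
#' One-way: F test across groups (with two groups the F statistic equals the
#' squared pooled t statistic). Two-way: main effects and interaction via
#' `aov` on a (near-)balanced design; unbalanced input triggers a warning
#' and Type-II sums of squares (through `car::Anova` when available).
#'
#' @param values Response values.
#' @param f1 First factor.
#' @param f2 Optional second factor.
#' @return Data.frame, one row per effect: `effect`, `df`, `F`, `p_value`.
#' @export
anova_test <- function(values, f1, f2 = NULL) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2) stop("factor needs >= 2 levels")
  if (is.null(f2)) {
    if (stats::var(values) == 0) {  # all-equal data: no effect by convention
      return(data.frame(effect = "f1", df = nlevels(f1) - 1L,
                        F = 0, p_value = 1))
    }
    fit <- stats::aov(values ~ f1)
    tab <- summary(fit)[[1]]
    return(data.frame(effect = "f1", df = tab$Df[1],
                      F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1]))
  }
  f2 <- factor(f2)
  if (nlevels(f2) < 2) stop("factor needs >= 2 levels")
  balanced <- length(unique(table(f1, f2))) == 1
  if (!balanced) warning("unbalanced two-way design; using Type-II sums of squares")
  fit <- stats::aov(values ~ f1 * f2)
  if (!balanced && requireNamespace("car", quietly = TRUE)) {
    tab <- car::Anova(stats::lm(values ~ f1 * f2), type = 2)
    eff <- rownames(tab)[1:3]
    return(data.frame(effect = eff, df = tab$Df[1:3],
                      F = tab$`F value`[1:3], p_value = tab$`Pr(>F)`[1:3]))
  }
  tab <- summary(fit)[[1]]
  data.frame(effect = trimws(rownames(tab)[1:3]), df = tab$Df[1:3],
             F = tab$`F value`[1:3], p_value = tab$`Pr(>F)`[1:3])
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: sort raw p ascending and set
#' `p_adj(i) = max_{j <= i} 1 - (1 - p(j))^(m - j + 1)`, clipped to 1, with
#' the original order restored. Controls the familywise error rate and is
#' uniformly at least as powerful as Holm's Bonferroni form.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, 1 - (1 - ps) ^ (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Dunnett's many-to-one comparisons
#'
#' Compares each treatment group with a single shared control, adjusting for
#' the familywise error rate under the Dunnett correlation structure. Each
#' comparison's statistic is the usual pooled-variance t; the adjusted
#' p-value is `P(max_i |T_i| >= |t|)` computed from the exact equicorrelated
#' multivariate-t distribution.
#'
#' @param values Response values.
#' @param group Group labels.
#' @param control Label of the control group.
#' @return Data.frame, one row per treatment: `comparison`, `statistic`,
#'   `df`, `p_raw`, `p_adj`.
#' @export
dunnett <- function(values, group, control) {
  group <- as.character(group)
  if (!control %in% group) stop("control group not present")
  labs <- setdiff(unique(group), control)
  if (length(labs) < 1) stop("need at least one treatment group")
  ns <- table(group)
  if (ns[[control]] < 2) stop("control group needs n >= 2")
  k <- length(labs)
  n_tot <- length(values)
  df <- n_tot - (k + 1)
  # pooled residual variance across all groups
  s2 <- sum(unlist(lapply(split(values, group),
                          function(v) (length(v) - 1) * stats::var(v)))) / df
  tstat <- vapply(labs, function(g) {
    vi <- values[group == g]; vc <- values[group == control]
    (mean(vi) - mean(vc)) / sqrt(s2 * (1 / length(vi) + 1 / length(vc)))
  }, numeric(1))
  # Dunnett correlation: rho_ij = sqrt(ni nc^-1 ...) — for contrasts vs a
  # shared control, corr(T_i, T_j) = sqrt(l_i l_j), l_i = n_i/(n_i + n_c)
  lam <- vapply(labs, function(g) {
    ni <- sum(group == g); ni / (ni + ns[[control]])
  }, numeric(1))
  corr <- sqrt(outer(lam, lam))
  diag(corr) <- 1
  p_adj <- vapply(tstat, function(t0) {
    1 - mvtnorm::pmvt(lower = rep(-abs(t0), k), upper = rep(abs(t0), k),
                      df = df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
  }, numeric(1))
  data.frame(comparison = paste(labs, "-", control),
             statistic = tstat, df = df,
             p_raw = 2 * stats::pt(-abs(tstat), df),
             p_adj = pmin(1, pmax(p_adj, 2 * stats::pt(-abs(tstat), df))))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; the calibrator is the sample
#' with the highest target Ct (lowest expression), whose relative expression
#' is therefore exactly 1; `ddCt = dCt - dCt_calibrator` and relative
#' expression is `2^(-ddCt)`.
#'
#' @param ct_target Target-gene Ct per sample.
#' @param ct_reference Reference-gene Ct per sample (e.g. *rpl13a*).
#' @return Numeric vector of relative expression values (calibrator = 1).
#' @export
ddct <- function(ct_target, ct_reference) {
  if (length(ct_target) != length(ct_reference)) stop("length mismatch")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  dct <- ct_target - ct_reference
  cal <- which.max(ct_target)
  2 ^ (-(dct - dct[cal]))
}

#' Tidy multiple-comparison report
#'
#' Runs pairwise pooled t tests of every group against a reference (or all
#' pairs), applies Holm-Sidak, and returns a tidy table - the standard
#' figure-statistics workflow downstream of the sleep and imaging metrics.
#'
#' @param values Per-animal metric values.
#' @param group Group labels.
#' @param reference Optional reference group; when given only
#'   reference-vs-other comparisons are made.
#' @return Data.frame `comparison`, `statistic`, `df`, `p_raw`, `p_adj`,
#'   `method`.
#' @export
stats_report <- function(values, group, reference = NULL) {
  group <- as.character(group)
  labs <- unique(group)
  pairs <- if (is.null(reference)) utils::combn(labs, 2, simplify = FALSE)
           else lapply(setdiff(labs, reference), function(g) c(reference, g))
  rows <- lapply(pairs, function(pr) {
    ht <- t_test(values[group == pr[1]], values[group == pr[2]])
    data.frame(comparison = paste(pr[2], "-", pr[1]),
               statistic = ht$statistic, df = ht$df, p_raw = ht$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak(out$p_raw)
  out$method <- "Student's t + Holm-Sidak"
  out
}
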