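#' Size-weighted pooled mean
#'
#' `sum(n_i * mean_i) / sum(n_i)` — the pooled mean implied by subgroup
#' sizes and subgroup means, as used to check a descriptive table's pooled
#' column against its ethnicity cells.
#'
#' @param n subgroup sizes (>= 0, sum > 0).
#' @param means subgroup means.
#' @return Pooled mean.
#' @examples
#' pooled_mean(c(494, 213, 273), c(4.56, 5.89, 5.05))  # ~4.99 kN
#' @export
pooled_mean <- function(n, means) {
  if (length(n) != length(means)) stop("n and means must have equal length")
  if (any(n < 0)) stop("group sizes must be >= 0")
  if (sum(n) == 0) stop("total group size is zero")
  sum(n * means) / sum(n)
}

#' Size-weighted pooled standard deviation
#'
#' Combines subgroup means and SDs into the SD of the pooled sample
#' (within-group variance plus between-group dispersion about the pooled
#' mean), treating the reported SDs as population-style moments.
#'
#' @inheritParams pooled_mean
#' @param sds subgroup standard deviations.
#' @return Pooled standard deviation.
#' @export
pooled_sd <- function(n, means, sds) {
  m <- pooled_mean(n, means)
  sqrt(sum(n * (sds^2 + (means - m)^2)) / sum(n))
}

#' One-way analysis of variance
#'
#' Classical between/within F statistic with (k - 1, N - k) degrees of
#' freedom, as used to compare baseline characteristics across ethnic
#' groups. Zero within-group variance with unequal group means returns
#' `F = Inf`, `p = 0` by convention.
#'
#' @param values numeric outcome vector.
#' @param groups group labels, same length.
#' @return List with `F`, `p`, `df` (length 2), and per-group `n`.
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))  # F = 1.5
#' @export
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups)) stop("length mismatch")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ns <- tabulate(g)
  if (any(ns < 2)) stop("every group needs n >= 2")
  k <- nlevels(g)
  N <- length(values)
  gm <- mean(values)
  mug <- tapply(values, g, mean)
  ssb <- sum(ns * (mug - gm)^2)
  ssw <- sum((values - mug[g])^2)
  df <- c(k - 1, N - k)
  if (ssw <= 1e-300 * max(ssb, 1)) {
    if (ssb > 0) return(list(F = Inf, p = 0, df = df, n = as.vector(ns)))
    return(list(F = 0, p = 1, df = df, n = as.vector(ns)))
  }
  Fv <- (ssb / df[1]) / (ssw / df[2])
  list(F = Fv, p = pf(Fv, df[1], df[2], lower.tail = FALSE), df = df,
       n = as.vector(ns))
}

#' Age-adjusted group means (ANCOVA)
#'
#' Fits the classical single-slope analysis-of-covariance model
#' `value ~ age + group` by least squares, reports each group's adjusted
#' mean evaluated at the grand mean age, and the F test for the group
#' effect conditional on age. With a constant age vector the slope is
#' unidentifiable and the function falls back to [anova_oneway()] with a
#' warning.
#'
#' @param values numeric outcome.
#' @param ages covariate (years), same length.
#' @param groups group labels, same length.
#' @return List with `adjusted_means` (named), `slope`, `F`, `p`, `df`.
#' @export
age_adjust <- function(values, ages, groups) {
  if (length(unique(c(length(values), length(ages), length(groups)))) != 1)
    stop("length mismatch")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (sd(ages) == 0) {
    warning("constant age vector: slope unidentifiable, reporting ",
            "unadjusted one-way ANOVA")
    a <- anova_oneway(values, g)
    return(list(adjusted_means = tapply(values, g, mean), slope = NA_real_,
                F = a$F, p = a$p, df = a$df))
  }
  fit0 <- lm(values ~ ages)
  fit1 <- lm(values ~ ages + g)
  cf <- coef(fit1)
  grand_age <- mean(ages)
  adj <- vapply(levels(g), function(lv) {
    off <- if (lv == levels(g)[1]) 0 else cf[[paste0("g", lv)]]
    cf[[1]] + cf[["ages"]] * grand_age + off
  }, 0)
  rss0 <- sum(residuals(fit0)^2)
  rss1 <- sum(residuals(fit1)^2)
  df1 <- nlevels(g) - 1
  df2 <- length(values) - nlevels(g) - 1
  if (rss1 <= 1e-300 * max(rss0, 1)) {
    Fv <- if (rss0 > rss1) Inf else 0
    pv <- if (is.infinite(Fv)) 0 else 1
  } else {
    Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pv <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  list(adjusted_means = adj, slope = cf[["ages"]], F = Fv, p = pv,
       df = c(df1, df2))
}

#' LOWESS age trajectory with bootstrap confidence band
#'
#' Locally weighted scatterplot smoothing of an outcome against age,
#' evaluated on an evenly spaced age grid, with a percentile bootstrap
#' confidence band (rows resampled with replacement, seeded). The default
#' span is 2/3 with one robustness iteration.
#'
#' @param ages covariate, years (n >= 10).
#' @param values outcome, same length.
#' @param frac smoother span in (0, 1].
#' @param n_grid number of grid points.
#' @param n_boot bootstrap resamples for the band (0 disables it).
#' @param level band coverage (default 0.95).
#' @param iter robustness iterations passed to the smoother.
#' @param seed integer seed for the bootstrap.
#' @param variable,sex,ethnicity optional labels stored with the fit.
#' @return Object of class `trajectory_fit`: `age` (grid), `fit`, `lower`,
#'   `upper`, plus the smoothing settings.
#' @export
lowess_trajectory <- function(ages, values, frac = 2 / 3, n_grid = 50,
                              n_boot = 199, level = 0.95, iter = 1,
                              seed = 1, variable = NULL, sex = NULL,
                              ethnicity = NULL) {
  if (length(ages) != length(values)) stop("length mismatch")
  if (length(ages) < 10) stop("need at least 10 observations")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (sd(ages) == 0) stop("all ages identical: trajectory undefined")
  grid <- seq(min(ages), max(ages), length.out = n_grid)
  smooth_on_grid <- function(a, v) {
    lw <- lowess(a, v, f = frac, iter = iter)
    approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
  }
  fit <- smooth_on_grid(ages, values)
  lower <- upper <- NULL
  if (n_boot > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    boots <- matrix(NA_real_, n_boot, n_grid)
    for (b in seq_len(n_boot)) {
      i <- sample.int(length(ages), replace = TRUE)
      if (sd(ages[i]) == 0) i <- seq_along(ages)  # degenerate resample
      boots[b, ] <- smooth_on_grid(ages[i], values[i])
    }
    alpha <- (1 - level) / 2
    lower <- apply(boots, 2, quantile, probs = alpha, na.rm = TRUE)
    upper <- apply(boots, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  }
  structure(list(age = grid, fit = fit, lower = lower, upper = upper,
                 frac = frac, iter = iter, n = length(ages),
                 n_boot = n_boot, level = level, variable = variable,
                 sex = sex, ethnicity = ethnicity),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  lab <- paste(c(x$variable, x$sex, x$ethnicity), collapse = " / ")
  cat("LOWESS trajectory", if (nzchar(lab)) paste0("(", lab, ")"),
      "\n  n =", x$n, ", span =", signif(x$frac, 3),
      ", grid", length(x$age), "ages in [",
      signif(min(x$age), 4), ",", signif(max(x$age), 4), "]\n")
  cat("  fitted range: [", signif(min(x$fit), 4), ",",
      signif(max(x$fit), 4), "]\n")
  invisible(x)
}

#' @export
predict.trajectory_fit <- function(object, newage = object$age, ...) {
  approx(object$age, object$fit, xout = newage, rule = 2)$y
}

#' @export
plot.trajectory_fit <- function(x, add = FALSE, col = "black",
                                band_col = grDevices::adjustcolor(col, 0.2),
                                ylab = x$variable, ...) {
  if (!add) {
    plot(x$age, x$fit, type = "n", xlab = "age (years)",
         ylab = if (is.null(ylab)) "value" else ylab,
         ylim = range(c(x$fit, x$lower, x$upper)), ...)
  }
  if (!is.null(x$lower)) {
    graphics::polygon(c(x$age, rev(x$age)), c(x$lower, rev(x$upper)),
                      border = NA, col = band_col)
  }
  graphics::lines(x$age, x$fit, col = col, lwd = 2)
  invisible(x)
}

#' Per-stratum LOWESS trajectories for a cohort
#'
#' Convenience wrapper fitting [lowess_trajectory()] for one or more cohort
#' variables within every sex-by-ethnicity stratum.
#'
#' @param cohort cohort `data.frame` as from [generate_cohort()].
#' @param vars variable names to smooth (columns of `cohort`).
#' @param seed bootstrap seed.
#' @param ... passed on to [lowess_trajectory()].
#' @return Nested list `fits[[var]][[sex]][[ethnicity]]` of
#'   `trajectory_fit` objects.
#' @export
cohort_trajectories <- function(cohort, vars = c("abmd", "frax_hfp",
                                                 "tstt_sup", "strength"),
                                seed = 1, ...) {
  out <- list()
  for (v in vars) {
    if (!v %in% names(cohort)) stop("no column '", v, "' in cohort")
    out[[v]] <- list()
    for (sx in unique(cohort$sex)) {
      out[[v]][[sx]] <- list()
      for (eth in unique(cohort$ethnicity)) {
        rows <- cohort$sex == sx & cohort$ethnicity == eth
        if (sum(rows) < 10) next
        out[[v]][[sx]][[eth]] <- lowess_trajectory(
          cohort$age[rows], cohort[[v]][rows], seed = seed,
          variable = v, sex = sx, ethnicity = eth, ...)
      }
    }
  }
  out
}

#' Descriptive summary per stratum
#'
#' Mean, SD and n of a variable within each group, plus the size-weighted
#' pooled mean and pooled SD.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return List of class `group_summary` with `table` (n, mean, sd per
#'   group) and `pooled` (mean, sd).
#' @export
group_summary <- function(values, groups) {
  g <- factor(groups)
  ns <- as.vector(tabulate(g))
  if (any(ns < 1)) stop("every reported group needs n >= 1")
  mu <- as.vector(tapply(values, g, mean))
  sds <- as.vector(tapply(values, g, function(v)
    if (length(v) > 1) sd(v) else 0))
  structure(list(
    table = data.frame(group = levels(g), n = ns, mean = mu, sd = sds,
                       stringsAsFactors = FALSE),
    pooled = c(mean = pooled_mean(ns, mu), sd = pooled_sd(ns, mu, sds))),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("pooled: mean %.4g, sd %.4g\n", x$pooled[["mean"]],
              x$pooled[["sd"]]))
  invisible(x)
}
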