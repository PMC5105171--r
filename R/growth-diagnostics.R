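#' Fit the linear one-box sink model of the CO2 growth rate
#'
#' Models the annual growth rate of atmospheric carbon as anthropogenic
#' emissions minus a sink proportional to the excess atmospheric mass:
#' \deqn{G = F_{anthro} + F_0 - B\,M}
#' where `B` (yr^-1) is an inverse residence time for excess carbon and the
#' composite intercept \eqn{F_0 = B M_0} absorbs the unidentifiable
#' equilibrium mass. By default emissions enter as a fixed offset
#' (coefficient 1), i.e. `G - F_anthro` is regressed on `M` by ordinary
#' least squares; `free_emissions = TRUE` instead estimates a free
#' coefficient on `F_anthro`.
#'
#' Residuals (observed minus predicted growth) are computed for the entire
#' series, not only the fit window, so post-window structural change can be
#' examined with [residual_break_test()].
#'
#' @param series A budget tibble (`year, F_anthro, ca, M, G`), e.g. from
#'   [make_budget_series()] or [read_budget_csv()]; `G` and `F_anthro` in
#'   PgC yr^-1, `M` in PgC.
#' @param window Optional length-2 vector of years delimiting the fit
#'   window (inclusive); default: the whole series. Must span at least 10
#'   years.
#' @param free_emissions Estimate a coefficient on `F_anthro` instead of
#'   fixing it at 1.
#' @return An object of class `"sink_fit"`: a list with elements `B`, `F0`,
#'   `se_B`, `se_F0`, `window`, `residuals` (tibble `year, residual`),
#'   `model` (the underlying `lm`), and `data`.
#' @export
fit_sink_model <- function(series, window = NULL, free_emissions = FALSE) {
  series <- as_tibble(series)
  ok <- stats::complete.cases(series[c("year", "F_anthro", "M", "G")])
  series <- series[ok, ]
  if (is.null(window)) window <- range(series$year)
  in_win <- series$year >= window[1] & series$year <= window[2]
  if (sum(in_win) < 10) abort("The fit window must contain at least 10 years.")
  if (sd(series$M[in_win]) == 0) {
    abort("Singular design: `M` is constant within the fit window.")
  }
  df <- tibble(y = series$G - series$F_anthro, M = series$M,
               G = series$G, F_anthro = series$F_anthro)
  fit <- if (free_emissions) {
    lm(G ~ M + F_anthro, data = df, subset = in_win)
  } else {
    lm(y ~ M, data = df, subset = in_win)
  }
  cf <- summary(fit)$coefficients
  B <- -cf["M", "Estimate"]
  F0 <- cf["(Intercept)", "Estimate"]
  pred <- if (free_emissions) {
    F0 + cf["F_anthro", "Estimate"] * series$F_anthro - B * series$M
  } else {
    F0 + series$F_anthro - B * series$M
  }
  structure(list(
    B = B, F0 = F0,
    se_B = cf["M", "Std. Error"], se_F0 = cf["(Intercept)", "Std. Error"],
    window = window, free_emissions = free_emissions,
    residuals = tibble(year = series$year, residual = series$G - pred),
    model = fit, data = series
  ), class = "sink_fit")
}

#' @export
print.sink_fit <- function(x, ...) {
  cat("Linear sink model of the CO2 growth rate\n")
  cat(sprintf("  fit window : %d-%d\n", x$window[1], x$window[2]))
  cat(sprintf("  B  = %.4f yr^-1  (se %.4f)\n", x$B, x$se_B))
  cat(sprintf("  F0 = %.2f PgC yr^-1 (se %.2f, composite intercept B*M0)\n",
              x$F0, x$se_F0))
  invisible(x)
}

#' @export
tidy.sink_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble(
    term = c("B", "F0"),
    estimate = c(x$B, x$F0),
    std.error = c(x$se_B, x$se_F0),
    statistic = c(-cf["M", "t value"], cf["(Intercept)", "t value"]),
    p.value = c(cf["M", "Pr(>|t|)"], cf["(Intercept)", "Pr(>|t|)"])
  )
}

#' @export
glance.sink_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    B = x$B, F0 = x$F0, r.squared = s$r.squared, sigma = s$sigma,
    nobs = length(s$residuals),
    window_start = x$window[1], window_end = x$window[2]
  )
}

#' @export
autoplot.sink_fit <- function(object, break_year = NULL, ...) {
  df <- object$residuals
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$residual)) +
    ggplot2::annotate("rect",
      xmin = object$window[1], xmax = object$window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.08
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = NULL, y = expression("Growth-rate residual (PgC" ~ yr^-1 * ")"),
      title = "Observed minus predicted CO2 growth rate",
      subtitle = "Shaded band: fit window"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(break_year)) {
    p <- p + ggplot2::geom_vline(xintercept = break_year, colour = "red",
                                 linetype = 3)
  }
  p
}

#' Structural-change test on sink-model residuals
#'
#' Two-sided one-sample t-test of the growth-rate residuals from
#' `candidate_year` onward against zero. A significant negative mean
#' indicates growth rates persistently below the linear sink model's
#' prediction, i.e. a strengthening of the global sink relative to the fit
#' window.
#'
#' If the post-candidate residuals are all (numerically) zero the test is
#' degenerate and `p = 1` is returned.
#'
#' @param x A `"sink_fit"` object, or a data frame with columns `year` and
#'   `residual`.
#' @param candidate_year First year of the candidate post-break period.
#' @return A one-row tibble: `candidate_year, n_post, mean_residual,
#'   statistic, df, p_value`.
#' @export
residual_break_test <- function(x, candidate_year) {
  res <- if (inherits(x, "sink_fit")) x$residuals else as_tibble(x)
  stopifnot(all(c("year", "residual") %in% names(res)))
  post <- res$residual[res$year >= candidate_year]
  if (length(post) < 5) {
    abort("At least 5 residuals on or after `candidate_year` are required.")
  }
  m <- mean(post)
  s <- sd(post)
  n <- length(post)
  if (s < .Machine$double.eps^0.5 * max(1, abs(m))) {
    tt <- if (abs(m) < .Machine$double.eps^0.5) 0 else sign(m) * Inf
    p <- if (tt == 0) 1 else 0
  } else {
    tt <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(tt), df = n - 1)
  }
  tibble(candidate_year = candidate_year, n_post = n, mean_residual = m,
         statistic = tt, df = n - 1, p_value = p)
}

#' Annual airborne fraction
#'
#' Fraction of each year's anthropogenic emissions remaining in the
#' atmosphere: `AF(t) = G(t) / F_anthro(t)`, both in PgC yr^-1.
#'
#' @param series Budget tibble with `year`, `G`, `F_anthro`.
#' @return A tibble `year, af`.
#' @export
airborne_fraction <- function(series) {
  if (any(series$F_anthro <= 0, na.rm = TRUE)) {
    abort("`F_anthro` must be positive in every year.")
  }
  tibble(year = series$year, af = series$G / series$F_anthro)
}

#' Mann-Kendall trend test with Sen's slope
#'
#' Non-parametric trend test: the Kendall statistic
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}, its tie-corrected variance,
#' a normal approximation with continuity correction for the two-sided
#' p-value, the Tau-b correlation, and Sen's slope (the median of all
#' pairwise slopes, in units of `x` per unit of `time`).
#'
#' An all-equal series returns `tau = 0`, slope 0 and `p = 1` (not an
#' error).
#'
#' @param x Numeric series (length >= 4 after removing missing values).
#' @param time Time coordinate (default `seq_along(x)`); assumed untied.
#' @return A one-row tibble: `n, S, var_S, tau, sen_slope, statistic,
#'   p_value`.
#' @export
mann_kendall_sen <- function(x, time = seq_along(x)) {
  keep <- is.finite(x) & is.finite(time)
  x <- x[keep]
  time <- time[keep]
  n <- length(x)
  if (n < 4) abort("At least 4 finite observations are required.")
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]
  j <- pairs[2, ]
  dx <- x[j] - x[i]
  dt <- time[j] - time[i]
  S <- sum(sign(dx))
  ## tie correction over groups of equal x
  tie_sizes <- table(x)
  tie_sizes <- tie_sizes[tie_sizes > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  n_pairs <- n * (n - 1) / 2
  tx <- sum(tie_sizes * (tie_sizes - 1) / 2)
  tau <- if (n_pairs - tx > 0) S / sqrt((n_pairs - tx) * n_pairs) else 0
  if (S == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (S - sign(S)) / sqrt(var_S)
    p <- 2 * pnorm(-abs(z))
  }
  slope <- if (all(dx == 0)) 0 else median(dx / dt)
  tibble(n = n, S = S, var_S = var_S, tau = tau, sen_slope = slope,
         statistic = z, p_value = p)
}

#' Remove the mean seasonal cycle from a monthly series
#'
#' Subtracts the calendar-month climatology (mean over all years of each
#' calendar month, computed from the months available). By construction the
#' anomalies of each calendar month average to zero; any long-term trend in
#' the series is retained in the anomalies.
#'
#' @param x Monthly values.
#' @param month Calendar month (1-12) of each value.
#' @return Anomalies, same length as `x`.
#' @export
deseasonalize <- function(x, month) {
  stopifnot(length(x) == length(month))
  if (length(unique(month[!is.na(x)])) < 12 || length(x) < 24) {
    warn("Fewer than 2 full years: climatology built from the months available.")
  }
  x - stats::ave(x, month, FUN = function(v) mean(v, na.rm = TRUE))
}
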