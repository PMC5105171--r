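#' Remove the long-term trend from one forcing driver
#'
#' For the chosen driver, fits an ordinary-least-squares linear trend in
#' year separately for every grid cell and calendar month, removes it, and
#' re-anchors the detrended values to the baseline-period mean:
#' \deqn{x' = x - b\,(year - \bar{y}_{baseline})}
#' so the post-detrend trend is zero and the baseline-period mean of the
#' driver is preserved exactly. Other drivers are untouched. Physical
#' bounds are re-imposed afterwards (`fapar`, `alpha` in \[0,1\], `vpd`
#' non-negative) with a warning reporting how many values were clipped.
#'
#' @param forcing A forcing tibble.
#' @param driver One of `"tair"`, `"vpd"`, `"i0"`, `"fapar"`, `"alpha"`,
#'   `"ca"`, or `"climate"` (= `tair` and `vpd` together).
#' @param baseline Length-2 year range whose mean anchors the detrended
#'   series; default: the first 15 years.
#' @return The forcing tibble with the driver detrended.
#' @export
detrend_driver <- function(forcing, driver, baseline = NULL) {
  cols <- switch(driver,
    climate = c("tair", "vpd"),
    tair = , vpd = , i0 = , fapar = , alpha = , ca = driver,
    abort(sprintf("Unknown driver '%s'.", driver))
  )
  if (is.null(baseline)) {
    baseline <- c(min(forcing$year), min(forcing$year) + 14)
  }
  if (!any(forcing$year >= baseline[1] & forcing$year <= baseline[2])) {
    abort("`baseline` lies outside the forcing period.")
  }
  ybar_base <- mean(unique(forcing$year[forcing$year >= baseline[1] &
                                          forcing$year <= baseline[2]]))
  out <- forcing |>
    group_by(.data$lat, .data$lon, .data$month) |>
    mutate(across(dplyr::all_of(cols), function(x) {
      yc <- .data$year - mean(.data$year)
      b <- sum(yc * (x - mean(x))) / sum(yc^2)
      x - b * (.data$year - .env$ybar_base)
    })) |>
    ungroup()
  n_clip <- 0L
  for (cl in intersect(cols, c("fapar", "alpha"))) {
    bad <- out[[cl]] < 0 | out[[cl]] > 1
    n_clip <- n_clip + sum(bad)
    out[[cl]] <- pmin(pmax(out[[cl]], 0), 1)
  }
  if ("vpd" %in% cols) {
    bad <- out$vpd < 0
    n_clip <- n_clip + sum(bad)
    out$vpd <- pmax(out$vpd, 0)
  }
  if (n_clip > 0) {
    warn(sprintf("Detrending clipped %d value(s) back to physical bounds.", n_clip))
  }
  attr(out, "truth") <- attr(forcing, "truth")
  out
}

#' Replace early-period fAPAR with a calendar-month climatology
#'
#' Satellite fAPAR records begin only in the early 1980s; for years before
#' `cutoff_year` the per-cell calendar-month mean over `climatology_window`
#' is used instead. Values from `cutoff_year` onward are untouched.
#'
#' @param forcing A forcing tibble.
#' @param climatology_window Length-2 year range (inclusive) over which the
#'   climatology is computed; must overlap the data.
#' @param cutoff_year First year with direct observations (default 1981).
#' @return The forcing tibble with pre-cutoff fAPAR replaced.
#' @export
apply_fapar_climatology <- function(forcing, climatology_window,
                                    cutoff_year = 1981) {
  win <- forcing$year >= climatology_window[1] &
    forcing$year <= climatology_window[2]
  if (!any(win)) abort("`climatology_window` contains no data years.")
  clim <- forcing[win, ] |>
    group_by(.data$lat, .data$lon, .data$month) |>
    summarise(fapar_clim = mean(.data$fapar), .groups = "drop")
  out <- forcing |>
    left_join(clim, by = c("lat", "lon", "month")) |>
    mutate(fapar = ifelse(.data$year < cutoff_year,
                          .data$fapar_clim, .data$fapar)) |>
    select(-"fapar_clim")
  attr(out, "truth") <- attr(forcing, "truth")
  out
}

#' Run a single-driver attribution experiment
#'
#' Removes the long-term trend from every driver except the one named in
#' `keep` (the paper-style factorial design: the remaining trend isolates
#' that driver's first-order effect), solves the preindustrial respiration
#' equilibrium on the experiment's own forcing, and evaluates monthly GPP,
#' ecosystem respiration and NEP over the full period.
#'
#' @param forcing A forcing tibble.
#' @param keep Driver whose trend is retained: `"ca"`, `"climate"`,
#'   `"fapar"`, `"alpha"`; `"none"` detrends everything (control) and
#'   `"all"` detrends nothing (full run).
#' @param baseline Anchoring window for [detrend_driver()]; default first
#'   15 years.
#' @param preind Year range used as the preindustrial climatology for
#'   [solve_r0()]; default first 15 years.
#' @param phot,resp Parameter objects.
#' @param fapar_climatology Optional `list(window =, cutoff_year =)` passed
#'   to [apply_fapar_climatology()] before detrending.
#' @return A flux tibble `lat, lon, year, month, gpp, reco, nep` with an
#'   `experiment` column naming `keep`.
#' @export
run_experiment <- function(forcing, keep = "all", baseline = NULL,
                           preind = NULL, phot = phot_params(),
                           resp = resp_params(), fapar_climatology = NULL) {
  drivers <- c("ca", "climate", "fapar", "alpha")
  if (!keep %in% c(drivers, "none", "all")) {
    abort(sprintf("`keep` must be one of %s, 'none' or 'all'.",
                  paste(drivers, collapse = ", ")))
  }
  y0 <- min(forcing$year)
  if (is.null(baseline)) baseline <- c(y0, y0 + 14)
  if (is.null(preind)) preind <- c(y0, y0 + 14)
  f <- forcing
  if (!is.null(fapar_climatology)) {
    f <- apply_fapar_climatology(f, fapar_climatology$window,
                                 fapar_climatology$cutoff_year %||% 1981)
  }
  to_detrend <- switch(keep, all = character(), none = drivers,
                       setdiff(drivers, keep))
  for (d in to_detrend) f <- detrend_driver(f, d, baseline)
  pre <- filter(f, .data$year >= preind[1], .data$year <= preind[2])
  r0 <- solve_r0(pre, resp, phot)
  g <- gpp_field(f, phot)
  r <- reco_field(f, g, r0, resp)
  nep_field(g, r) |> mutate(experiment = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flux change between two periods
#'
#' Mean annual global totals of GPP, ecosystem respiration and NEP over two
#' periods and their difference (P2 minus P1), together with zonal
#' (latitude-band) profiles of the change in both PgC yr^-1 and
#' gC m^-2 yr^-1.
#'
#' @param flux A flux tibble from [run_experiment()] or [nep_field()].
#' @param areas Tibble `lat, lon, cell_area`.
#' @param p1,p2 Length-2 year ranges (inclusive); `p1` precedes `p2`.
#' @return An object of class `"attribution_delta"`: list with `global`
#'   (tibble `term, p1_mean, p2_mean, delta`), `zonal` (tibble `lat, term,
#'   delta_pgc, delta_gcm2`), and the periods.
#' @export
period_delta <- function(flux, areas, p1, p2) {
  rng <- range(flux$year)
  if (p1[1] < rng[1] || p2[2] > rng[2]) {
    abort("`p1`/`p2` must lie within the flux period.")
  }
  vars <- intersect(c("gpp", "reco", "nep"), names(flux))
  fa <- left_join(flux, areas, by = c("lat", "lon"))
  period_mean <- function(lo, hi) {
    fa |>
      filter(.data$year >= lo, .data$year <= hi) |>
      group_by(.data$year) |>
      summarise(across(dplyr::all_of(vars),
                       ~ sum(.x * .data$cell_area) * 1e-15), .groups = "drop") |>
      summarise(across(dplyr::all_of(vars), mean))
  }
  m1 <- period_mean(p1[1], p1[2])
  m2 <- period_mean(p2[1], p2[2])
  global <- tibble(
    term = vars,
    p1_mean = as.numeric(m1[1, vars]),
    p2_mean = as.numeric(m2[1, vars]),
    delta = as.numeric(m2[1, vars]) - as.numeric(m1[1, vars])
  )
  zonal_mean <- function(lo, hi) {
    fa |>
      filter(.data$year >= lo, .data$year <= hi) |>
      group_by(.data$lat, .data$year) |>
      summarise(
        across(dplyr::all_of(vars), ~ sum(.x * .data$cell_area)),
        band_area = sum(.data$cell_area[.data$month == 1]), .groups = "drop"
      ) |>
      group_by(.data$lat) |>
      summarise(across(dplyr::all_of(c(vars, "band_area")), mean),
                .groups = "drop")
  }
  z1 <- zonal_mean(p1[1], p1[2])
  z2 <- zonal_mean(p2[1], p2[2])
  zonal <- purrr::map_dfr(vars, function(v) {
    tibble(
      lat = z1$lat, term = v,
      delta_pgc = (z2[[v]] - z1[[v]]) * 1e-15,
      delta_gcm2 = (z2[[v]] - z1[[v]]) / z1$band_area
    )
  })
  exp_label <- if ("experiment" %in% names(flux)) flux$experiment[1] else NA_character_
  structure(list(global = global, zonal = zonal, p1 = p1, p2 = p2,
                 experiment = exp_label),
            class = "attribution_delta")
}

#' @export
print.attribution_delta <- function(x, ...) {
  cat(sprintf("Flux change, %d-%d minus %d-%d (PgC yr^-1)\n",
              x$p2[1], x$p2[2], x$p1[1], x$p1[2]))
  print(x$global)
  invisible(x)
}

#' @export
tidy.attribution_delta <- function(x, ...) x$global

#' @export
autoplot.attribution_delta <- function(object, ...) {
  ggplot2::ggplot(object$global,
                  ggplot2::aes(.data$term, .data$delta, fill = .data$term)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = NULL, y = expression(Delta * " flux (PgC" ~ yr^-1 * ")"),
      title = sprintf("Change between %d-%d and %d-%d",
                      object$p1[1], object$p1[2], object$p2[1], object$p2[2])
    ) +
    ggplot2::theme_minimal()
}

#' How well do single-driver effects add up?
#'
#' Compares the sum of single-driver period deltas with the full-run delta;
#' the remainder measures driver interactions (zero for a model linear in
#' its drivers, small when trends are small).
#'
#' @param singles Named list of `"attribution_delta"` objects, one per
#'   driver experiment.
#' @param full The `"attribution_delta"` of the all-trends run.
#' @return A tibble `term, sum_single, full, remainder, remainder_frac`.
#' @export
additivity_check <- function(singles, full) {
  sums <- purrr::map_dfr(singles, ~ .x$global) |>
    group_by(.data$term) |>
    summarise(sum_single = sum(.data$delta), .groups = "drop")
  full_g <- select(full$global, "term", full = "delta")
  left_join(sums, full_g, by = "term") |>
    mutate(
      remainder = .data$full - .data$sum_single,
      remainder_frac = ifelse(.data$full == 0, NA_real_,
                              .data$remainder / .data$full)
    )
}
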