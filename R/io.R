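FORCING_COLS <- c("lat", "lon", "year", "month", "tair", "vpd", "i0",
                  "fapar", "alpha", "ca", "pft", "cell_area")

FORCING_UNITS <- c(
  "lat: degrees_north (cell centres, ascending)",
  "lon: degrees_east (-180..180, cell centres)",
  "time: year, month columns (monthly, gapless)",
  "tair: degC", "vpd: Pa", "i0: mol photon m-2 month-1 (before fAPAR scaling)",
  "fapar: 1 (0..1)", "alpha: 1 (0..1, actual/equilibrium evapotranspiration)",
  "ca: ppm (spatially uniform per month)", "pft: plant functional type",
  "cell_area: m2"
)

#' Write / read gridded monthly forcing
#'
#' Plain-text CSV serialisation of a forcing table, with a commented header
#' documenting coordinates and units. Doubles are written in shortest
#' round-trippable form, so a write -> read cycle reproduces values
#' bit-identically.
#'
#' @param forcing A forcing tibble.
#' @param path File path.
#' @return `write_forcing` returns `path` invisibly; `read_forcing` a
#'   forcing tibble.
#' @export
write_forcing <- function(forcing, path) {
  miss <- setdiff(FORCING_COLS, names(forcing))
  if (length(miss)) {
    abort(paste0("`forcing` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  readr::write_lines(paste0("# ", FORCING_UNITS), path)
  readr::write_csv(forcing[FORCING_COLS], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  ## base read.csv: correctly-rounded strtod parsing, so values written in
  ## shortest round-trippable form come back bit-identical
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  miss <- setdiff(FORCING_COLS, names(out))
  if (length(miss)) {
    abort(paste0("Forcing file lacks variable(s): ", paste(miss, collapse = ", ")))
  }
  if (any(out$fapar < 0 | out$fapar > 1) || any(out$vpd < 0)) {
    abort("Forcing file violates bounds (fapar in [0,1], vpd >= 0).")
  }
  out
}

#' Read / write an annual carbon-budget series
#'
#' The CSV schema mirrors annual global carbon-budget tables: columns
#' `year`, `F_anthro` (PgC yr^-1, fossil + land-use + cement), `ca` (ppm),
#' and optionally `M` (PgC) and `G` (PgC yr^-1). Missing `M` is derived as
#' `ca * mass_per_ppm`; missing `G` by differencing `M` under the chosen
#' convention (`"forward"`: `G(t) = M(t+1) - M(t)`, last year `NA`;
#' `"centered"`: `(M(t+1) - M(t-1))/2`, one-sided at the ends). Years must
#' be contiguous.
#'
#' @param path File path.
#' @param mass_per_ppm PgC per ppm (2.124).
#' @param growth_convention `"forward"` or `"centered"`.
#' @return A budget tibble `year, F_anthro, ca, M, G`.
#' @export
read_budget_csv <- function(path, mass_per_ppm = PGC_PER_PPM,
                            growth_convention = c("forward", "centered")) {
  growth_convention <- match.arg(growth_convention)
  df <- as_tibble(utils::read.csv(path, comment.char = "#"))
  need <- c("year", "F_anthro", "ca")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Budget file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  df <- arrange(df, .data$year)
  if (any(diff(df$year) != 1)) abort("Budget years must be contiguous (no gaps).")
  if (!"M" %in% names(df)) df$M <- df$ca * mass_per_ppm
  if (!"G" %in% names(df)) {
    n <- nrow(df)
    df$G <- switch(growth_convention,
      forward = c(diff(df$M), NA_real_),
      centered = c(df$M[2] - df$M[1],
                   (df$M[3:n] - df$M[1:(n - 2)]) / 2,
                   df$M[n] - df$M[n - 1])
    )
  }
  as_tibble(df[c("year", "F_anthro", "ca", "M", "G")])
}

#' @rdname read_budget_csv
#' @param series A budget tibble.
#' @export
write_budget_csv <- function(series, path) {
  readr::write_csv(series[c("year", "F_anthro", "ca", "M", "G")], path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of [run_pipeline()]: grid
#' and period of the synthetic forcing, attribution periods, sink-model
#' settings, and the root seed from which each stage's seed is derived.
#'
#' @param years Forcing years.
#' @param nlat,nlon Grid size.
#' @param budget_years Years of the budget series.
#' @param p1,p2 Attribution comparison periods.
#' @param fit_window Sink-model fit window (years).
#' @param break_year Candidate structural-change year.
#' @param min_period SSA band definition (years).
#' @param n_surrogates IAAFT ensemble size.
#' @param seed Root seed; stage seeds are `seed + 1, 2, 3`.
#' @param trends,noise Forcing generator specifications.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(years = 1900:2013, nlat = 18, nlon = 36,
                            budget_years = 1959:2014,
                            p1 = c(1901, 1915), p2 = c(1995, 2010),
                            fit_window = c(1959, 1988), break_year = 2002,
                            min_period = 5, n_surrogates = 100, seed = 1,
                            trends = trend_spec(), noise = noise_spec()) {
  cfg <- list(
    years = years, nlat = nlat, nlon = nlon, budget_years = budget_years,
    p1 = p1, p2 = p2, fit_window = fit_window, break_year = break_year,
    min_period = min_period, n_surrogates = n_surrogates, seed = seed,
    trends = trends, noise = noise
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full diagnostic pipeline
#'
#' Chains the stages end to end on synthetic inputs: (1) gridded forcing
#' and the factorial attribution experiments with the
#' photosynthesis-respiration model; (2) the annual budget series with the
#' sink-model fit, structural-change test, airborne fraction and
#' Mann-Kendall trend; (3) SSA extraction of the low-frequency growth-rate
#' dynamic with surrogate uncertainty. Results are returned as a list and,
#' if `out_dir` is given, written as CSV/JSON together with a copy of the
#' configuration; a failing stage aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param write_forcing_file Also serialise the (large) forcing table.
#' @return Invisibly, a named list with elements `forcing`, `experiments`,
#'   `deltas`, `additivity`, `budget`, `sink_fit`, `break_test`,
#'   `airborne`, `af_trend`, `ssa`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_forcing_file = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  log_msg <- function(...) message(sprintf(...))

  log_msg("[forcing] %d-%d on a %dx%d grid",
          min(config$years), max(config$years), config$nlat, config$nlon)
  forcing <- stage("forcing", make_forcing(
    config$years, config$nlat, config$nlon, trends = config$trends,
    noise = config$noise, seed = config$seed + 1
  ))
  areas <- distinct(forcing, .data$lat, .data$lon, .data$cell_area)

  log_msg("[attribution] factorial single-driver experiments")
  keeps <- c("none", "ca", "climate", "fapar", "alpha", "all")
  experiments <- stage("attribution", purrr::map(
    setNames(keeps, keeps), ~ run_experiment(forcing, keep = .x)
  ))
  deltas <- purrr::map(experiments,
                       ~ period_delta(.x, areas, config$p1, config$p2))
  additivity <- additivity_check(
    deltas[c("ca", "climate", "fapar", "alpha")], deltas$all
  )

  log_msg("[budget] sink model, break test, airborne fraction")
  budget <- stage("budget", make_budget_series(
    config$budget_years, seed = config$seed + 2
  ))
  fit <- fit_sink_model(budget, window = config$fit_window)
  brk <- residual_break_test(fit, config$break_year)
  af <- airborne_fraction(budget)
  af_trend <- mann_kendall_sen(af$af, af$year)

  log_msg("[ssa] low-frequency growth-rate dynamic, %d surrogates",
          config$n_surrogates)
  ssa_out <- stage("ssa", subsignal_uncertainty(
    budget$G, min_period = config$min_period,
    n_surrogates = config$n_surrogates, seed = config$seed + 3
  ))
  ssa_out$year <- budget$year

  res <- list(
    forcing = forcing, experiments = experiments, deltas = deltas,
    additivity = additivity, budget = budget, sink_fit = fit,
    break_test = brk, airborne = af, af_trend = af_trend, ssa = ssa_out
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    if (write_forcing_file) write_forcing(forcing, fp("forcing.csv"))
    write_budget_csv(budget, fp("budget.csv"))
    readr::write_csv(fit$residuals, fp("sink_residuals.csv"))
    readr::write_csv(af, fp("airborne_fraction.csv"))
    readr::write_csv(ssa_out, fp("ssa_subsignal.csv"))
    readr::write_csv(purrr::map_dfr(deltas, ~ .x$global, .id = "experiment"),
                     fp("attribution_global.csv"))
    readr::write_csv(purrr::map_dfr(deltas, ~ .x$zonal, .id = "experiment"),
                     fp("attribution_zonal.csv"))
    jsonlite::write_json(
      list(
        sink_fit = list(B = fit$B, F0 = fit$F0, se_B = fit$se_B,
                        window = fit$window),
        break_test = as.list(brk),
        af_trend = as.list(af_trend)
      ),
      fp("diagnostics.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(unclass(config), fp("config.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("[done] outputs in %s", out_dir)
  }
  invisible(res)
}
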