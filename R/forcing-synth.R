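#' Per-driver linear trend specification
#'
#' Linear slopes (units per year) added to each driver's climatology. The
#' defaults represent twentieth-century study conditions: CO2 rising 110 ppm
#' over 113 years (about 290 ppm in 1900 to 400 ppm by 2013), warming of
#' 0.008 degC yr^-1 over vegetated land, a modest greening of fAPAR, and no
#' long-term change in moisture availability or radiation.
#'
#' @param tair degC yr^-1.
#' @param vpd Pa yr^-1.
#' @param i0 mol photon m^-2 month^-1 yr^-1.
#' @param fapar yr^-1.
#' @param alpha yr^-1.
#' @param ca ppm yr^-1.
#' @return A named list.
#' @export
trend_spec <- function(tair = 0.008, vpd = 0, i0 = 0, fapar = 3e-4,
                       alpha = 0, ca = 110 / 113) {
  list(tair = tair, vpd = vpd, i0 = i0, fapar = fapar, alpha = alpha, ca = ca)
}

#' Per-driver noise specification
#'
#' Standard deviations of AR(1) cell-level monthly noise (lag-1 correlation
#' `ar1`, marginal sd as given). Zero disables noise for a driver.
#'
#' @param tair degC; @param vpd Pa; @param i0 mol photon m^-2 month^-1;
#' @param fapar,alpha dimensionless; @param ca ppm (applied globally,
#'   uniform over space); @param ar1 lag-1 autocorrelation shared by all
#'   drivers.
#' @return A named list.
#' @export
noise_spec <- function(tair = 0.5, vpd = 30, i0 = 10, fapar = 0.02,
                       alpha = 0.03, ca = 0, ar1 = 0.3) {
  list(tair = tair, vpd = vpd, i0 = i0, fapar = fapar, alpha = alpha,
       ca = ca, ar1 = ar1)
}

## AR(1) noise matrix (ncell x nt), marginal sd `sd`, lag-1 correlation rho.
ar1_noise <- function(ncell, nt, sd, rho) {
  if (sd == 0) return(matrix(0, ncell, nt))
  e <- matrix(0, ncell, nt)
  e[, 1] <- rnorm(ncell, 0, sd)
  if (nt > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:nt) e[, t] <- rho * e[, t - 1] + rnorm(ncell, 0, innov_sd)
  }
  e
}

#' Latitudinal-band plant functional type map
#'
#' Splits the latitude rows of a regular grid into `n_pfts` contiguous
#' bands. Band boundaries are drawn at random (deterministically per seed);
#' every PFT occupies at least one row.
#'
#' @param nlat,nlon Grid dimensions.
#' @param n_pfts Number of PFTs (`1 <= n_pfts <= nlat`).
#' @param seed Integer seed.
#' @param labels Optional character vector of PFT names (length `n_pfts`).
#' @return A tibble `lat, lon, pft` with 10 degree-style cell centres.
#' @export
make_pft_map <- function(nlat = 18, nlon = 36, n_pfts = 6, seed = 1,
                         labels = paste0("pft", seq_len(n_pfts))) {
  if (n_pfts < 1) abort("`n_pfts` must be at least 1.")
  if (n_pfts > nlat) abort("`n_pfts` must not exceed the number of latitude rows.")
  stopifnot(length(labels) == n_pfts)
  withr::local_seed(seed)
  cuts <- if (n_pfts > 1) sort(sample(seq_len(nlat - 1), n_pfts - 1)) else integer()
  band <- findInterval(seq_len(nlat), c(0, cuts) + 1L)
  lat <- grid_centers(nlat, 180) # -90..90
  lon <- grid_centers(nlon, 360) # -180..180
  tidyr::expand_grid(lat = lat, lon = lon) |>
    mutate(pft = labels[band[match(.data$lat, .env$lat)]])
}

## cell centres for a span (180 for lat, 360 for lon), ascending
grid_centers <- function(n, span) {
  d <- span / n
  seq(-span / 2 + d / 2, span / 2 - d / 2, by = d)
}

## climatically banded default map using the shipped PFT names
climatic_pft_map <- function(nlat, nlon) {
  lat <- grid_centers(nlat, 180)
  lon <- grid_centers(nlon, 360)
  tidyr::expand_grid(lat = lat, lon = lon) |>
    mutate(pft = case_when(
      abs(.data$lat) < 15 ~ "tropical_forest",
      abs(.data$lat) < 25 ~ "savanna",
      abs(.data$lat) < 35 ~ "grassland",
      abs(.data$lat) < 50 ~ "temperate_forest",
      abs(.data$lat) < 65 ~ "boreal_forest",
      TRUE ~ "tundra"
    ))
}

#' Synthetic gridded monthly forcing
#'
#' Builds each driver as latitude-dependent climatology + seasonal cycle +
#' linear trend + AR(1) noise, on a regular lat-lon grid with monthly time
#' steps. Atmospheric CO2 is spatially uniform. Physical bounds are enforced
#' after assembly (`fapar`, `alpha` clipped to \[0, 1\], `vpd` floored at
#' 5 Pa so downstream optima remain defined); if the deterministic part of
#' the fAPAR trend would push more than 5% of cell-months outside \[0, 1\],
#' the trend specification is rejected.
#'
#' The returned tibble carries a `"truth"` attribute recording the
#' generating slopes and seed, so any grid can be regenerated bit-identically.
#'
#' @param years Integer vector of consecutive years (length >= 2).
#' @param nlat,nlon Grid dimensions (default 18 x 36, i.e. 10 degree cells).
#' @param trends A [trend_spec()].
#' @param seasonal Scalar in \[0, 1\] scaling all seasonal cycles (0 turns
#'   seasonality off).
#' @param noise A [noise_spec()].
#' @param ca_start CO2 (ppm) in the first year.
#' @param pft_map Optional tibble `lat, lon, pft`; defaults to a climatic
#'   banding matching [default_pft_params()].
#' @param seed Integer seed; same seed and specification regenerate the
#'   identical grid.
#' @return A tibble with columns `lat, lon, year, month, tair, vpd, i0,
#'   fapar, alpha, ca, pft, cell_area`. Units: degC, Pa,
#'   mol photon m^-2 month^-1, -, -, ppm, -, m^2.
#' @export
make_forcing <- function(years, nlat = 18, nlon = 36,
                         trends = trend_spec(), seasonal = 1,
                         noise = noise_spec(), ca_start = 290,
                         pft_map = NULL, seed = 1) {
  years <- as.integer(years)
  if (length(years) < 2 || any(diff(years) != 1L)) {
    abort("`years` must be at least two consecutive years.")
  }
  withr::local_seed(seed)
  lat <- grid_centers(nlat, 180)
  lon <- grid_centers(nlon, 360)
  if (is.null(pft_map)) pft_map <- climatic_pft_map(nlat, nlon)

  grid <- tidyr::expand_grid(
    year = years, month = 1:12, lat = lat, lon = lon
  )
  phi <- grid$lat * pi / 180
  alat <- abs(grid$lat) / 90
  yr_off <- grid$year - years[1]
  ## hemisphere-aware seasonal shape: +1 in local mid-summer
  s_m <- ifelse(grid$lat >= 0, 1, -1) * cos(2 * pi * (grid$month - 7) / 12)
  ## solar declination (rad), peaking at +0.409 near the June solstice
  delta <- seasonal * 0.409 * cos(2 * pi * (grid$month - 6.5) / 12)
  ncell <- nlat * nlon
  nt <- length(years) * 12
  ## grid rows are ordered year, month, lat, lon -> contiguous blocks of
  ## ncell cells per month, matching column-major ncell x nt noise matrices
  nz <- function(sdv) as.vector(ar1_noise(ncell, nt, sdv, noise$ar1))

  tair_clim <- 28 - 38 * alat^1.6 +
    seasonal * (2 + 18 * alat^1.5) * s_m
  tair <- tair_clim + trends$tair * yr_off + nz(noise$tair)

  ## ~1100 mol photon m^-2 month^-1 clear-sky at the sub-solar point, times
  ## a bulk 0.45 cloud/atmosphere transmission factor
  i0_clim <- 495 * pmax(cos(phi - delta), 0.02)^1.2
  i0 <- pmax(i0_clim + trends$i0 * yr_off + nz(noise$i0), 1)

  f_clim <- (0.02 + 0.85 * exp(-((abs(grid$lat) - 8) / 40)^2)) *
    (1 + seasonal * 0.8 * alat^1.5 * (s_m - 1) / 2)
  f_det <- f_clim + trends$fapar * yr_off
  if (mean(f_det < 0 | f_det > 1) > 0.05) {
    abort("`trends$fapar` drives fAPAR outside [0, 1] for more than 5% of cell-months.")
  }
  fapar <- pmin(pmax(f_det + nz(noise$fapar), 0), 1)

  a_clim <- 0.85 - 0.4 * exp(-((abs(grid$lat) - 22) / 12)^2)
  alpha <- pmin(pmax(a_clim + trends$alpha * yr_off + nz(noise$alpha), 0), 1)

  vpd_clim <- 0.35 * sat_vapour_pressure(pmin(pmax(tair_clim, -60), 60))
  vpd <- pmax(vpd_clim + trends$vpd * yr_off + nz(noise$vpd), 5)

  ## spatially uniform CO2: one AR(1) draw per month
  ca_t <- ca_start + trends$ca * (rep(years, each = 12) - years[1]) +
    as.vector(ar1_noise(1, nt, noise$ca, noise$ar1))
  ca <- rep(ca_t, each = ncell)

  ## vegetated-land area per cell: geometric cell area times a bulk global
  ## land fraction of 0.3 (the grid carries no explicit ocean mask)
  dlat_rad <- pi / nlat
  dlon_rad <- 2 * pi / nlon
  r_earth <- 6371000
  area_row <- 0.3 * r_earth^2 * dlon_rad *
    (sin(lat * pi / 180 + dlat_rad / 2) - sin(lat * pi / 180 - dlat_rad / 2))
  out <- grid |>
    mutate(
      tair = tair, vpd = vpd, i0 = i0, fapar = fapar, alpha = alpha, ca = ca,
      cell_area = area_row[match(.data$lat, .env$lat)]
    ) |>
    left_join(pft_map, by = c("lat", "lon")) |>
    select("lat", "lon", "year", "month", "tair", "vpd", "i0", "fapar",
           "alpha", "ca", "pft", "cell_area") |>
    arrange(.data$year, .data$month, .data$lat, .data$lon)
  attr(out, "truth") <- list(trends = trends, seasonal = seasonal,
                             noise = noise, ca_start = ca_start, seed = seed)
  out
}

#' Synthetic annual global carbon-budget series
#'
#' Integrates the one-box linear sink model forward in time. The growth rate
#' of atmospheric carbon during year `t` is
#' \deqn{G(t) = F_{anthro}(t) - B\,(M(t) - M_0) + \varepsilon(t)}
#' and the atmospheric mass updates as \eqn{M(t+1) = M(t) + G(t)}. Under the
#' default (`"forward"`) convention the reported `G` of year `t` is exactly
#' `M(t+1) - M(t)`, so refitting the model on a noise-free series recovers
#' `B` and the composite intercept to machine precision. The `"centered"`
#' convention reports `(M(t+1) - M(t-1))/2` (one-sided at the ends).
#'
#' Defaults describe a realistic 1959-2014 budget: inverse sink residence
#' rate `B = 0.03 yr^-1`, equilibrium mass 616 PgC (290 ppm), initial mass
#' 671 PgC (316 ppm), anthropogenic emissions rising linearly from 4 to 11
#' PgC yr^-1, and interannual noise of sd 0.2 PgC yr^-1 on the growth rate.
#'
#' @param years Consecutive years.
#' @param B_true Sink rate (yr^-1), positive. Plays the role of an inverse
#'   residence time for excess atmospheric carbon.
#' @param M0 Equilibrium (background) atmospheric mass (PgC).
#' @param F0 Optional: intercept `B * M0` (PgC yr^-1); if supplied, overrides
#'   `M0` as `M0 = F0 / B_true`.
#' @param M_init Atmospheric mass in the first year (PgC).
#' @param emissions Numeric vector (length of `years`) of anthropogenic
#'   emissions (PgC yr^-1), or a function of year; default linear 4 -> 11.
#' @param noise_sd Gaussian noise sd on the growth rate (PgC yr^-1).
#' @param break_spec Optional `list(year =, B =)`: from `year` onward the
#'   sink rate switches to `B`.
#' @param growth_convention `"forward"` (default) or `"centered"`.
#' @param mass_per_ppm PgC per ppm conversion (2.124).
#' @param seed Integer seed.
#' @return A tibble `year, F_anthro, ca, M, G` (`G` in PgC yr^-1; `ca` in
#'   ppm, `M = ca * mass_per_ppm`), with a `"truth"` attribute recording
#'   `B_true`, `F0`, `M0`, the break and the seed.
#' @export
make_budget_series <- function(years = 1959:2014, B_true = 0.03, M0 = 616,
                               F0 = NULL, M_init = 671, emissions = NULL,
                               noise_sd = 0.2, break_spec = NULL,
                               growth_convention = c("forward", "centered"),
                               mass_per_ppm = PGC_PER_PPM, seed = 1) {
  growth_convention <- match.arg(growth_convention)
  years <- as.integer(years)
  n <- length(years)
  if (n < 2 || any(diff(years) != 1L)) abort("`years` must be consecutive.")
  if (B_true <= 0) abort("`B_true` must be positive.")
  if (!is.null(F0)) M0 <- F0 / B_true
  if (is.null(emissions)) emissions <- seq(4, 11, length.out = n)
  if (is.function(emissions)) emissions <- emissions(years)
  if (length(emissions) != n || any(!is.finite(emissions))) {
    abort("`emissions` must be finite and defined for every year.")
  }
  withr::local_seed(seed)
  B <- rep(B_true, n)
  if (!is.null(break_spec)) B[years >= break_spec$year] <- break_spec$B
  M <- numeric(n + 1)
  M[1] <- M_init
  G <- numeric(n)
  eps <- rnorm(n, 0, noise_sd)
  for (t in seq_len(n)) {
    G[t] <- emissions[t] - B[t] * (M[t] - M0) + eps[t]
    M[t + 1] <- M[t] + G[t]
  }
  G_rep <- switch(growth_convention,
    forward = G,
    centered = c(G[1], (M[3:(n + 1)] - M[1:(n - 1)]) / 2)
  )
  out <- tibble(
    year = years, F_anthro = emissions, ca = M[seq_len(n)] / mass_per_ppm,
    M = M[seq_len(n)], G = G_rep
  )
  attr(out, "truth") <- list(
    B_true = B_true, F0_true = B_true * M0, M0 = M0, M_init = M_init,
    noise_sd = noise_sd, break_spec = break_spec,
    growth_convention = growth_convention, seed = seed
  )
  out
}
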