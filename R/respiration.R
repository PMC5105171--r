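#' Lloyd-Taylor temperature scalar of ecosystem respiration
#'
#' \deqn{f(T) = \exp\left[E_0\left(\frac{1}{T_{ref} - T_0} -
#'                                 \frac{1}{T - T_0}\right)\right]}
#' with all temperatures in degC. Equals 1 at `T = tref` and increases
#' strictly with temperature for `E0 > 0`.
#'
#' @param t_c Air temperature (degC), must exceed `t0`.
#' @param e0 Activation energy parameter (K).
#' @param tref Reference temperature (degC).
#' @param t0 Lloyd-Taylor zero (degC).
#' @return Dimensionless scalar.
#' @export
temperature_scalar <- function(t_c, e0, tref = 15, t0 = -46.02) {
  if (any(t_c <= t0)) {
    abort(sprintf("`t_c` must exceed the Lloyd-Taylor zero T0 = %.2f degC.", t0))
  }
  exp(e0 * (1 / (tref - t0) - 1 / (t_c - t0)))
}

#' Photosynthesis-dependent ecosystem respiration
#'
#' Monthly ecosystem respiration as the sum of a GPP-independent term (slow
#' heterotrophic pools, scaled by the reference rate `r0`) and a
#' GPP-dependent term (autotrophic plus labile heterotrophic respiration,
#' proportional to GPP through `k`), both modulated by the Lloyd-Taylor
#' temperature scalar and by water availability `alpha` (ratio of actual to
#' equilibrium evapotranspiration, reference value 1):
#' \deqn{R_{eco} = (R_0 + k\,GPP)\; f(T)\; \alpha.}
#' At `GPP = 0`, `T = tref`, `alpha = 1` this returns `r0` exactly.
#'
#' @param t_c Air temperature (degC).
#' @param alpha Water availability index in \[0, 1\].
#' @param gpp_val GPP (gC m^-2 month^-1), non-negative.
#' @param r0 Reference respiration rate at `tref` (gC m^-2 month^-1).
#' @param e0 Activation energy parameter (K).
#' @param k Proportional contribution of GPP at the reference temperature.
#' @param tref,t0 Reference and zero temperatures (degC).
#' @return Respiration in gC m^-2 month^-1.
#' @export
reco <- function(t_c, alpha, gpp_val, r0, e0, k, tref = 15, t0 = -46.02) {
  if (any(gpp_val < 0)) abort("`gpp_val` must be non-negative.")
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1].")
  (r0 + k * gpp_val) * temperature_scalar(t_c, e0, tref, t0) * alpha
}

#' Solve for the reference respiration rate at preindustrial equilibrium
#'
#' For each grid cell, finds the `R0` that makes mean annual net ecosystem
#' production exactly zero over a preindustrial climatology, i.e. solves the
#' linear (in `R0`) balance
#' \deqn{\sum_m GPP_m = \sum_m (R_0 + k\,GPP_m)\, f(T_m)\,\alpha_m}
#' giving
#' \deqn{R_0 = \frac{\sum_m GPP_m - k \sum_m GPP_m\, s_m}{\sum_m s_m},
#'   \qquad s_m = f(T_m)\,\alpha_m.}
#' The solution is verified by recomputing respiration: any cell with
#' |annual NEP| above 1e-8 gC m^-2 raises an error. Negative solutions
#' (possible only for extreme `E0`/`k` combinations) are clamped to zero
#' with a warning, in which case exact equilibrium is infeasible for that
#' cell.
#'
#' @param preind_forcing Forcing tibble covering at least one full year of
#'   preindustrial (trend-free or early-window) conditions.
#' @param resp A [resp_params()] object.
#' @param phot A [phot_params()] object.
#' @return A tibble `lat, lon, pft, E0, k, r0`.
#' @export
solve_r0 <- function(preind_forcing, resp = resp_params(), phot = phot_params()) {
  if (length(unique(paste(preind_forcing$year, preind_forcing$month))) < 12) {
    abort("`preind_forcing` must cover at least one full year.")
  }
  par_cells <- assign_pft_params(
    distinct(preind_forcing, .data$lat, .data$lon, .data$pft), resp$pft_table
  )
  g <- gpp_field(preind_forcing, phot)
  df <- preind_forcing |>
    select("lat", "lon", "year", "month", "tair", "alpha") |>
    left_join(g, by = c("lat", "lon", "year", "month")) |>
    left_join(par_cells, by = c("lat", "lon")) |>
    mutate(s = temperature_scalar(.data$tair, .data$E0, resp$tref, resp$t0) *
             .data$alpha)
  sol <- df |>
    group_by(.data$lat, .data$lon, .data$pft, .data$E0, .data$k) |>
    summarise(
      sum_gpp = sum(.data$gpp), sum_s = sum(.data$s),
      sum_gpp_s = sum(.data$gpp * .data$s), .groups = "drop"
    )
  if (any(sol$sum_s <= 0)) {
    abort("Degenerate preindustrial climatology: temperature-water scalar sums to 0.")
  }
  sol <- mutate(sol,
    r0 = (.data$sum_gpp - .data$k * .data$sum_gpp_s) / .data$sum_s
  )
  if (any(sol$r0 < 0)) {
    warn(sprintf("R0 negative in %d cell(s); clamped to 0 (equilibrium infeasible).",
                 sum(sol$r0 < 0)))
    sol$r0 <- pmax(sol$r0, 0)
  } else {
    ## verification: annual NEP must vanish to numerical precision
    nyr <- length(unique(df$year))
    chk <- df |>
      left_join(select(sol, "lat", "lon", "r0"), by = c("lat", "lon")) |>
      group_by(.data$lat, .data$lon) |>
      summarise(nep = sum(.data$gpp - (.data$r0 + .data$k * .data$gpp) * .data$s) /
                  .env$nyr, .groups = "drop")
    if (max(abs(chk$nep)) > 1e-8) {
      abort("Internal error: preindustrial equilibrium residual exceeds 1e-8 gC m^-2.")
    }
  }
  select(sol, "lat", "lon", "pft", "E0", "k", "r0")
}

#' Attach per-PFT respiration parameters to a PFT map
#'
#' @param pft_map Tibble with columns `lat`, `lon`, `pft`.
#' @param pft_table Data frame with columns `pft`, `E0`, `k`.
#' @return `pft_map` with `E0` and `k` columns added.
#' @export
assign_pft_params <- function(pft_map, pft_table = default_pft_params()) {
  missing_pfts <- setdiff(unique(pft_map$pft), pft_table$pft)
  if (length(missing_pfts)) {
    abort(paste0("PFT(s) absent from the parameter table: ",
                 paste(missing_pfts, collapse = ", ")))
  }
  left_join(pft_map, as_tibble(pft_table)[c("pft", "E0", "k")], by = "pft")
}

#' Gridded ecosystem respiration
#'
#' Evaluates the respiration model over every cell-month, given a GPP field
#' and the per-cell reference rates from [solve_r0()].
#'
#' @param forcing Forcing tibble (supplies `tair`, `alpha`).
#' @param gpp_tbl Output of [gpp_field()] on the same forcing.
#' @param r0_tbl Output of [solve_r0()] (columns `lat, lon, E0, k, r0`).
#' @param resp A [resp_params()] object (for `tref`, `t0`).
#' @return A tibble `lat, lon, year, month, reco`.
#' @export
reco_field <- function(forcing, gpp_tbl, r0_tbl, resp = resp_params()) {
  df <- forcing |>
    select("lat", "lon", "year", "month", "tair", "alpha") |>
    left_join(select(gpp_tbl, "lat", "lon", "year", "month", "gpp"),
              by = c("lat", "lon", "year", "month")) |>
    left_join(select(r0_tbl, "lat", "lon", "E0", "k", "r0"), by = c("lat", "lon"))
  if (any(is.na(df$gpp)) || any(is.na(df$r0))) {
    abort("Grid mismatch between `forcing`, `gpp_tbl` and `r0_tbl`.")
  }
  df |>
    mutate(reco = reco(.data$tair, .data$alpha, .data$gpp, .data$r0,
                       .data$E0, .data$k, resp$tref, resp$t0)) |>
    select("lat", "lon", "year", "month", "reco")
}

#' Net ecosystem production field
#'
#' NEP = GPP - R_eco, cell-wise and exactly.
#'
#' @param gpp_tbl Output of [gpp_field()].
#' @param reco_tbl Output of [reco_field()] on the same grid and period.
#' @return A tibble `lat, lon, year, month, gpp, reco, nep`.
#' @export
nep_field <- function(gpp_tbl, reco_tbl) {
  if (nrow(gpp_tbl) != nrow(reco_tbl)) {
    abort("Grid mismatch between `gpp_tbl` and `reco_tbl`.")
  }
  out <- left_join(
    select(gpp_tbl, "lat", "lon", "year", "month", "gpp"),
    select(reco_tbl, "lat", "lon", "year", "month", "reco"),
    by = c("lat", "lon", "year", "month")
  )
  if (nrow(out) != nrow(gpp_tbl) || any(is.na(out$reco))) {
    abort("Grid mismatch between `gpp_tbl` and `reco_tbl`.")
  }
  mutate(out, nep = .data$gpp - .data$reco)
}

#' Global annual flux totals
#'
#' Area-weighted integration of per-area monthly fluxes to global annual
#' totals in PgC yr^-1.
#'
#' @param flux A flux tibble (`lat, lon, year, month`, plus any of `gpp`,
#'   `reco`, `nep` in gC m^-2 month^-1).
#' @param areas Tibble `lat, lon, cell_area` (m^2), e.g.
#'   `dplyr::distinct(forcing, lat, lon, cell_area)`.
#' @return A tibble with `year` and one column per flux, in PgC yr^-1.
#' @export
global_flux_total <- function(flux, areas) {
  vars <- intersect(c("gpp", "reco", "nep"), names(flux))
  flux |>
    left_join(areas, by = c("lat", "lon")) |>
    group_by(.data$year) |>
    summarise(across(dplyr::all_of(vars),
                     ~ sum(.x * .data$cell_area) * 1e-15),
              .groups = "drop")
}
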