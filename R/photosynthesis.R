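#' Arrhenius temperature scaling of a kinetic constant
#'
#' Scales a biochemical rate parameter from its value at 25 degC (298.15 K)
#' to temperature `t_k` using
#' \deqn{x(T) = x_{25} \exp\left(\frac{\Delta H (T - 298.15)}{298.15\, R\, T}\right)}
#' so that `x(298.15) = x25` exactly and `x` is strictly increasing in `T`
#' for positive activation energies.
#'
#' @param t_k Temperature in Kelvin. Values outside (200, 350) K raise an
#'   error; this guards against silently passing degrees Celsius.
#' @param x25 Value of the constant at 298.15 K (Pa).
#' @param dH Activation energy (J mol^-1).
#' @param r_gas Molar gas constant (J mol^-1 K^-1).
#' @return Scaled value, same units as `x25`.
#' @export
arrhenius_rate <- function(t_k, x25, dH, r_gas = 8.314) {
  if (any(!is.finite(t_k)) || any(t_k <= 200) || any(t_k >= 350)) {
    abort("`t_k` must be in Kelvin, strictly inside (200, 350) K.")
  }
  x25 * exp(dH * (t_k - 298.15) / (298.15 * r_gas * t_k))
}

#' Photorespiratory compensation point
#'
#' \eqn{\Gamma^*}, the CO2 compensation point in the absence of dark
#' respiration, at temperature `t_k`, via [arrhenius_rate()] with
#' `gamma_star_x25` = 4.22 Pa and activation energy 37,830 J mol^-1.
#'
#' @param t_k Temperature (K).
#' @param params A [phot_params()] object.
#' @return \eqn{\Gamma^*} in Pa.
#' @export
gamma_star <- function(t_k, params = phot_params()) {
  arrhenius_rate(t_k, params$gamma_star_x25, params$gamma_star_dH, params$r_gas)
}

#' Convert a partial pressure to a mole fraction in ppm
#'
#' @param x_pa Partial pressure (Pa).
#' @param params A [phot_params()] object supplying the surface pressure.
#' @return Mole fraction in ppm.
#' @export
pa_to_ppm <- function(x_pa, params = phot_params()) {
  x_pa / params$atm_pressure * 1e6
}

#' Effective Michaelis-Menten coefficient of Rubisco
#'
#' \deqn{K = K_c(T)\,\left(1 + P_o / K_o(T)\right)}
#' combining the carboxylation and oxygenation coefficients, each scaled with
#' temperature by [arrhenius_rate()]. `po` defaults to the O2 partial
#' pressure implied by `params` (`o2_frac * atm_pressure`).
#'
#' @param t_k Temperature (K).
#' @param params A [phot_params()] object.
#' @param po O2 partial pressure (Pa); `po = 0` reduces `K` to `Kc(T)`.
#' @return K in Pa.
#' @export
michaelis_k <- function(t_k, params = phot_params(), po = params$po) {
  kc <- arrhenius_rate(t_k, params$kc_x25, params$kc_dH, params$r_gas)
  ko <- arrhenius_rate(t_k, params$ko_x25, params$ko_dH, params$r_gas)
  kc * (1 + po / ko)
}

#' Saturation vapour pressure of water
#'
#' Magnus-type approximation to the Clausius-Clapeyron relation
#' (Alduchov-Eskridge coefficients):
#' \deqn{e_s(T) = 610.94 \exp\left(\frac{17.625\,T}{T + 243.04}\right)}
#' with `T` in degrees Celsius and the result in Pa. Accurate to a few tenths
#' of a percent over the accepted range.
#'
#' @param t_c Air temperature (degC), in \[-60, 60\].
#' @return Saturation vapour pressure (Pa).
#' @export
sat_vapour_pressure <- function(t_c) {
  if (any(!is.finite(t_c)) || any(t_c < -60) || any(t_c > 60)) {
    abort("`t_c` must be in degrees Celsius, within [-60, 60].")
  }
  610.94 * exp(17.625 * t_c / (t_c + 243.04))
}

#' Vapour pressure deficit from daily temperature extremes
#'
#' The deficit is computed against the mean of the saturation vapour
#' pressures at the daily minimum and maximum temperature, floored at zero:
#' \deqn{D = \max\left(0, \frac{e_s(T_{min}) + e_s(T_{max})}{2} - e_a\right)}
#'
#' @param tmin,tmax Daily minimum/maximum temperature (degC).
#' @param e_actual Actual vapour pressure (Pa), non-negative.
#' @return VPD in Pa.
#' @export
vpd_from_tminmax <- function(tmin, tmax, e_actual) {
  if (any(tmin > tmax)) abort("`tmin` must not exceed `tmax`.")
  if (any(e_actual < 0)) abort("`e_actual` must be non-negative.")
  pmax(0, (sat_vapour_pressure(tmin) + sat_vapour_pressure(tmax)) / 2 - e_actual)
}

#' Viscosity of water relative to 25 degC
#'
#' Ratio \eqn{\eta^*(T) = \eta(T)/\eta(25^\circ C)} from a Vogel-type
#' correlation \eqn{\eta \propto 10^{247.8/(T_K - 140)}} (accurate to about
#' 2.5% between 0 and 100 degC). By construction \eqn{\eta^*(25) = 1}
#' exactly, and \eqn{\eta^*} decreases with temperature.
#'
#' @param t_c Water temperature (degC), in \[0, 50\].
#' @return Dimensionless relative viscosity.
#' @export
water_viscosity_rel <- function(t_c) {
  if (any(!is.finite(t_c)) || any(t_c < 0) || any(t_c > 50)) {
    abort("`t_c` must be within [0, 50] degC.")
  }
  10^(247.8 / (t_c + 273.15 - 140) - 247.8 / (25 + 273.15 - 140))
}

#' Least-cost optimal ratio of leaf-internal to ambient CO2
#'
#' The long-term effective \eqn{\chi = c_i/c_a} predicted by the least-cost
#' hypothesis: plants minimise the combined carbon costs of water transport
#' and carboxylation capacity, giving
#' \deqn{\chi = \frac{\xi}{\xi + \sqrt{D}}, \qquad
#'       \xi = \sqrt{\frac{\beta\,K(T)}{1.6\,\eta^*(T)}}}
#' with `D` the vapour pressure deficit in Pa, `K` the effective
#' Michaelis-Menten coefficient in Pa and \eqn{\eta^*} the relative viscosity
#' of water. With the default calibration `beta_cost = 356.51`,
#' \eqn{\chi(298.15\,K, 1\,kPa) = 0.80} to within 0.01.
#'
#' For temperatures outside the validity range of the viscosity correlation
#' (0-50 degC) the viscosity argument is clamped to that range; the kinetic
#' constants still use the actual temperature.
#'
#' @param t_k Air temperature (K).
#' @param d_pa Vapour pressure deficit (Pa), strictly positive.
#' @param ca Ambient CO2 (ppm). Only used to validate that `ca` exceeds the
#'   compensation point; the optimum itself is independent of `ca`.
#' @param params A [phot_params()] object.
#' @return \eqn{\chi} in (0, 1).
#' @export
#' @examples
#' optimal_chi(298.15, 1000) # ~0.80
optimal_chi <- function(t_k, d_pa, ca = 400, params = phot_params()) {
  if (any(d_pa <= 0)) {
    abort("`d_pa` must be strictly positive (the optimum is degenerate at D = 0).")
  }
  gs_ppm <- pa_to_ppm(gamma_star(t_k, params), params)
  if (any(ca <= gs_ppm)) {
    abort("`ca` must exceed the compensation point Gamma* (in ppm).")
  }
  xi <- least_cost_xi(t_k, params)
  xi / (xi + sqrt(d_pa))
}

## sqrt(beta * K / (1.6 eta*)); viscosity temperature clamped to [0, 50] degC.
least_cost_xi <- function(t_k, params) {
  eta <- water_viscosity_rel(pmin(pmax(t_k - 273.15, 0), 50))
  sqrt(params$beta_cost * michaelis_k(t_k, params) / (1.6 * eta))
}

#' Invert the least-cost model for its cost parameter
#'
#' Given an observed (or assumed) \eqn{\chi} at temperature `t_k` and deficit
#' `d_pa`, returns the `beta_cost` value consistent with the least-cost
#' optimum:
#' \deqn{\beta = \frac{1.6\,\eta^*\,\xi^2}{K}, \qquad
#'       \xi = \frac{\chi}{1-\chi}\sqrt{D}.}
#' Used to check the calibration at the reference point
#' \eqn{\chi_{25} = 0.8}, T = 298.15 K, D = 1 kPa.
#'
#' @param chi Observed ratio of internal to ambient CO2, in (0, 1).
#' @param t_k Temperature (K).
#' @param d_pa Vapour pressure deficit (Pa).
#' @param params A [phot_params()] object (supplies kinetics and the O2
#'   partial pressure assumption `po = o2_frac * atm_pressure`).
#' @return The implied cost parameter (dimensionless).
#' @export
invert_beta_cost <- function(chi, t_k, d_pa, params = phot_params()) {
  stopifnot(chi > 0, chi < 1, d_pa > 0)
  eta <- water_viscosity_rel(pmin(pmax(t_k - 273.15, 0), 50))
  xi <- chi / (1 - chi) * sqrt(d_pa)
  1.6 * eta * xi^2 / michaelis_k(t_k, params)
}

#' Gross primary production from absorbed light and CO2
#'
#' The electron-transport-limited light-use-efficiency form: under the
#' coordination hypothesis photosynthesis operates at the co-limitation
#' point, so GPP is predicted from absorbed light alone as
#' \deqn{GPP = M_C\, \varphi_0\, I\, \frac{\chi c_a - \Gamma^*}
#'                                        {\chi c_a + 2\Gamma^*}}
#' with \eqn{M_C} = 12.011 gC mol^-1 converting moles of carbon to grams.
#' `ca` and `gamma_star_ppm` must share units (ppm).
#'
#' When \eqn{\chi c_a < \Gamma^*} (below the compensation point) GPP is
#' clamped to zero with a warning.
#'
#' @param i_abs Absorbed photosynthetic photon flux
#'   (mol photon m^-2 month^-1), non-negative.
#' @param ca Ambient CO2 (ppm).
#' @param chi Ratio of leaf-internal to ambient CO2.
#' @param gamma_star_ppm Compensation point (ppm).
#' @param phi0 Intrinsic quantum efficiency (mol C mol photon^-1).
#' @return GPP in gC m^-2 month^-1.
#' @export
gpp <- function(i_abs, ca, chi, gamma_star_ppm, phi0 = 0.085) {
  if (any(i_abs < 0)) abort("`i_abs` must be non-negative.")
  cc <- chi * ca
  m <- (cc - gamma_star_ppm) / (cc + 2 * gamma_star_ppm)
  if (any(m < 0)) {
    warn(sprintf(
      "chi * ca below the compensation point for %d value(s); GPP clamped to 0.",
      sum(m < 0)
    ))
    m <- pmax(m, 0)
  }
  12.011 * phi0 * i_abs * m
}

#' Gridded GPP from monthly forcing
#'
#' Composes [optimal_chi()], [gamma_star()] and [gpp()] over every cell-month
#' of a forcing table. Absorbed light is `i0 * fapar`. Vapour pressure
#' deficits are floored at 1 Pa so that the least-cost optimum stays defined
#' in saturated cells (documented numerical guard).
#'
#' @param forcing A forcing tibble as produced by [make_forcing()] (columns
#'   `lat`, `lon`, `year`, `month`, `tair`, `vpd`, `i0`, `fapar`, `ca`, ...).
#' @param params A [phot_params()] object.
#' @return A tibble `lat, lon, year, month, chi, gpp` with GPP in
#'   gC m^-2 month^-1.
#' @export
gpp_field <- function(forcing, params = phot_params()) {
  need <- c("lat", "lon", "year", "month", "tair", "vpd", "i0", "fapar", "ca")
  miss <- setdiff(need, names(forcing))
  if (length(miss)) {
    abort(paste0("`forcing` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  t_k <- forcing$tair + 273.15
  gs_ppm <- pa_to_ppm(gamma_star(t_k, params), params)
  xi <- least_cost_xi(t_k, params)
  chi <- xi / (xi + sqrt(pmax(forcing$vpd, 1)))
  cc <- chi * forcing$ca
  m <- pmax((cc - gs_ppm) / (cc + 2 * gs_ppm), 0)
  out <- forcing |>
    select("lat", "lon", "year", "month") |>
    mutate(chi = chi, gpp = 12.011 * params$phi0 * forcing$i0 * forcing$fapar * m)
  if (any(!is.finite(out$gpp))) {
    bad <- out[!is.finite(out$gpp), c("lat", "lon", "year", "month")][1, ]
    abort(sprintf(
      "Non-finite GPP at lat %.2f, lon %.2f, %d-%02d.",
      bad$lat, bad$lon, bad$year, bad$month
    ))
  }
  out
}
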