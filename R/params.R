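#' Photosynthesis model parameters
#'
#' Bundles the constants of the light-use-efficiency photosynthesis model:
#' the intrinsic quantum efficiency, the least-cost parameter balancing the
#' unit costs of transpiration and carboxylation, and the Bernacchi-style
#' kinetic constants governing the temperature response of the
#' photorespiratory compensation point \eqn{\Gamma^*} and of the
#' Michaelis-Menten coefficients of Rubisco.
#'
#' Temperatures are carried in degrees Celsius at all I/O boundaries of the
#' package and converted to Kelvin once, inside the leaf-level functions.
#' Conversions between CO2 mole fraction (ppm) and partial pressure (Pa) use
#' the single configurable surface pressure `atm_pressure`; elevation effects
#' are ignored.
#'
#' @param phi0 Intrinsic quantum efficiency (mol C mol photon^-1). Must lie in
#'   (0, 0.125); the theoretical maximum is 0.125 (one C per 8 photons).
#' @param beta_cost Least-cost parameter (dimensionless ratio of the unit cost
#'   of carboxylation capacity to the unit cost of water transport).
#' @param atm_pressure Surface atmospheric pressure (Pa), used for ppm <-> Pa
#'   conversion of CO2 quantities.
#' @param o2_frac O2 mole fraction of air; the O2 partial pressure used in the
#'   effective Michaelis-Menten coefficient is `o2_frac * atm_pressure`.
#' @param gamma_star_x25,gamma_star_dH Value at 25 degC (Pa) and activation
#'   energy (J mol^-1) of the photorespiratory compensation point.
#' @param kc_x25,kc_dH Value at 25 degC (Pa) and activation energy (J mol^-1)
#'   of the Michaelis-Menten coefficient for carboxylation.
#' @param ko_x25,ko_dH Value at 25 degC (Pa) and activation energy (J mol^-1)
#'   of the Michaelis-Menten coefficient for oxygenation.
#' @param r_gas Molar gas constant (J mol^-1 K^-1).
#'
#' @return A list of class `"phot_params"`.
#' @export
#' @examples
#' p <- phot_params()
#' gamma_star(298.15, p) # 4.22 Pa at the reference temperature
phot_params <- function(phi0 = 0.085,
                        beta_cost = 356.51,
                        atm_pressure = 101325,
                        o2_frac = 0.21,
                        gamma_star_x25 = 4.22,
                        gamma_star_dH = 37830,
                        kc_x25 = 39.97,
                        kc_dH = 79430,
                        ko_x25 = 27480,
                        ko_dH = 36380,
                        r_gas = 8.314) {
  if (!is.numeric(phi0) || phi0 <= 0 || phi0 >= 0.125) {
    abort("`phi0` must lie strictly between 0 and 0.125 mol C mol photon^-1.")
  }
  vals <- list(
    phi0 = phi0, beta_cost = beta_cost, atm_pressure = atm_pressure,
    o2_frac = o2_frac, po = o2_frac * atm_pressure,
    gamma_star_x25 = gamma_star_x25, gamma_star_dH = gamma_star_dH,
    kc_x25 = kc_x25, kc_dH = kc_dH, ko_x25 = ko_x25, ko_dH = ko_dH,
    r_gas = r_gas
  )
  if (any(vapply(vals, function(x) any(!is.finite(x)) || any(x <= 0), logical(1)))) {
    abort("All photosynthesis parameters must be finite and positive.")
  }
  structure(vals, class = "phot_params")
}

#' Ecosystem respiration parameters
#'
#' The respiration model has two free parameters per plant functional type
#' (PFT): the activation energy `E0` (K) of the Lloyd-Taylor temperature
#' scalar and the proportional contribution `k` of GPP to respiration through
#' substrate availability. The reference temperature is 15 degC and the
#' Lloyd-Taylor zero is -46.02 degC.
#'
#' The default PFT table shipped with the package is a synthetic stand-in
#' (see [default_pft_params()]); any table with columns `pft`, `E0`, `k` can
#' be supplied.
#'
#' @param pft_table Data frame with columns `pft` (character), `E0` (K,
#'   positive) and `k` (dimensionless, in \[0, 1)).
#' @param tref Reference temperature (degC) at which the temperature scalar
#'   equals 1.
#' @param t0 Lloyd-Taylor zero temperature (degC).
#'
#' @return A list of class `"resp_params"`.
#' @export
resp_params <- function(pft_table = default_pft_params(), tref = 15, t0 = -46.02) {
  pft_table <- as_tibble(pft_table)
  stopifnot(all(c("pft", "E0", "k") %in% names(pft_table)))
  if (any(pft_table$E0 <= 0)) abort("`E0` must be positive for every PFT.")
  if (any(pft_table$k < 0 | pft_table$k >= 1)) abort("`k` must lie in [0, 1).")
  structure(list(pft_table = pft_table, tref = tref, t0 = t0),
            class = "resp_params")
}

#' Default per-PFT respiration parameters (synthetic stand-ins)
#'
#' The site-calibrated per-PFT values of `E0` and `k` used in the original
#' upscaling study are not reproduced here; this table is a documented
#' synthetic stand-in spanning the plausible ranges (E0 roughly 100-400 K,
#' k roughly 0.1-0.6). High-latitude types carry large activation energies
#' and small substrate coefficients, tropical types the reverse. No result
#' of the package depends on these specific values; they are fully
#' configurable through [resp_params()].
#'
#' @return A tibble with columns `pft`, `E0`, `k`.
#' @export
default_pft_params <- function() {
  tibble(
    pft = c("tropical_forest", "savanna", "grassland",
            "temperate_forest", "boreal_forest", "tundra"),
    E0  = c(100, 120, 150, 200, 300, 350),
    k   = c(0.50, 0.40, 0.35, 0.30, 0.15, 0.10)
  )
}
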