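#' Relative sensitivity of GPP to atmospheric CO2
#'
#' The closed-form relative sensitivity
#' \eqn{\beta_{CO2} = (\partial GPP/\partial c_a)(c_a/GPP)} of the
#' light-use-efficiency GPP model, holding \eqn{\chi} fixed:
#' \deqn{\beta_{CO2} = \frac{3\,\chi\,c_a\,\Gamma^*}
#'   {(\chi c_a - \Gamma^*)(\chi c_a + 2\Gamma^*)}.}
#' Expressed as a dimensionless fraction (0.37 = a 37% GPP increase per
#' proportional doubling rate of \eqn{c_a}). The treatment of \eqn{\chi} as a
#' constant (\eqn{\partial\chi/\partial c_a = 0}) follows the analytic
#' derivation; the weak dependence of the least-cost optimum on \eqn{c_a} is
#' deliberately excluded.
#'
#' @param ca Ambient CO2 (ppm).
#' @param chi Ratio of leaf-internal to ambient CO2 (default 0.8).
#' @param gamma_star Compensation point in ppm (default 43, the 25 degC
#'   value used in the analytic evaluation; note the flux model carries
#'   \eqn{\Gamma^*} in Pa, and 4.22 Pa is about 41.6 ppm at 101,325 Pa -- the
#'   two conventions are documented, not reconciled).
#' @return Sensitivity as a fraction.
#' @export
#' @examples
#' beta_co2(400) # ~0.37
#' beta_co2(800) # ~0.19
beta_co2 <- function(ca, chi = 0.8, gamma_star = 43) {
  cc <- chi * ca
  if (any(cc <= gamma_star)) {
    abort("`chi * ca` must exceed `gamma_star` (above the compensation point).")
  }
  3 * chi * ca * gamma_star / ((cc - gamma_star) * (cc + 2 * gamma_star))
}

#' Rate of decline of the CO2 sensitivity of GPP
#'
#' Analytic derivative \eqn{\partial\beta_{CO2}/\partial c_a}, obtained from
#' the logarithmic derivative of the closed form:
#' \deqn{\frac{\partial\beta_{CO2}}{\partial c_a} = \beta_{CO2}
#'   \left(\frac{1}{c_a} - \frac{\chi}{\chi c_a - \Gamma^*}
#'        - \frac{\chi}{\chi c_a + 2\Gamma^*}\right),}
#' negative for all admissible \eqn{c_a}: the sensitivity declines as CO2
#' rises, and the magnitude of the decline itself shrinks with \eqn{c_a}.
#'
#' @inheritParams beta_co2
#' @return Derivative in ppm^-1.
#' @export
beta_co2_derivative <- function(ca, chi = 0.8, gamma_star = 43) {
  b <- beta_co2(ca, chi, gamma_star)
  cc <- chi * ca
  b * (1 / ca - chi / (cc - gamma_star) - chi / (cc + 2 * gamma_star))
}

#' Sensitivity of GPP to CO2 over a concentration range
#'
#' Vectorised evaluation of [beta_co2()] and [beta_co2_derivative()].
#'
#' @param ca Vector of CO2 concentrations (ppm).
#' @param chi,gamma_star As in [beta_co2()].
#' @return A tibble `ca, chi, gamma_star, beta_co2, d_beta_d_ca`, with
#'   `beta_co2` monotonically decreasing in `ca`.
#' @export
sensitivity_curve <- function(ca, chi = 0.8, gamma_star = 43) {
  tibble(
    ca = ca, chi = chi, gamma_star = gamma_star,
    beta_co2 = beta_co2(ca, chi, gamma_star),
    d_beta_d_ca = beta_co2_derivative(ca, chi, gamma_star)
  )
}

#' Plot the CO2 sensitivity curve
#'
#' @param curve Output of [sensitivity_curve()].
#' @return A ggplot object.
#' @export
plot_sensitivity_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$ca, 100 * .data$beta_co2)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(c[a] ~ "(ppm)"),
      y = expression(beta[CO2] ~ "(%)"),
      title = "Declining sensitivity of GPP to atmospheric CO2"
    ) +
    ggplot2::theme_minimal()
}
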