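test_that("Arrhenius-scaled constants equal their x25 values at 298.15 K", {
  p <- phot_params()
  expect_identical(gamma_star(298.15, p), 4.22)
  expect_identical(arrhenius_rate(298.15, p$kc_x25, p$kc_dH), 39.97)
  expect_identical(arrhenius_rate(298.15, p$ko_x25, p$ko_dH), 27480)
  # hand-evaluated exp(dH (T - 298.15) / (298.15 R T)) at 288.15 K
  expect_equal(arrhenius_rate(288.15, 4.22, 37830), 2.48483126106,
               tolerance = 1e-10)
  # strictly increasing in T for positive activation energy
  tt <- seq(273.15, 313.15, by = 1)
  expect_true(all(diff(gamma_star(tt, p)) > 0))
  # Kelvin guard against silent Celsius input
  expect_error(arrhenius_rate(25, 4.22, 37830), "Kelvin")
})

test_that("effective Michaelis-Menten coefficient combines Kc, Ko and O2", {
  p <- phot_params()
  expect_equal(michaelis_k(298.15, p, po = 0), 39.97)
  # plug-in oracle: Kc25 * (1 + Po/Ko25)
  po <- 0.21 * 101325
  expect_equal(michaelis_k(298.15, p), 39.97 * (1 + po / 27480),
               tolerance = 1e-12)
  # increasing in O2 partial pressure at fixed T
  expect_gt(michaelis_k(298.15, p, po = 30000), michaelis_k(298.15, p, po = 20000))
  expect_gt(michaelis_k(298.15, p), p$kc_x25)
})

test_that("saturation vapour pressure follows the Magnus approximation", {
  expect_equal(sat_vapour_pressure(0), 611, tolerance = 0.01)
  tt <- seq(-60, 60, by = 5)
  expect_true(all(diff(sat_vapour_pressure(tt)) > 0))
  # evaluated from the chosen Magnus coefficients
  expect_gt(sat_vapour_pressure(20), 2 * sat_vapour_pressure(9))
  expect_error(sat_vapour_pressure(70), "Celsius")
})

test_that("VPD from temperature extremes averages the two saturation points", {
  es_mean <- (sat_vapour_pressure(10) + sat_vapour_pressure(20)) / 2
  expect_equal(vpd_from_tminmax(10, 20, es_mean), 0)
  expect_equal(vpd_from_tminmax(10, 20, 0), es_mean)
  expect_equal(vpd_from_tminmax(10, 20, 800), 979.730629061, tolerance = 1e-9)
  expect_error(vpd_from_tminmax(21, 20, 0), "tmin")
})

test_that("relative water viscosity is 1 at 25 degC and decreasing", {
  expect_identical(water_viscosity_rel(25), 1)
  # frozen from the Vogel correlation (the 0/25 degC viscosity ratio ~ 2.0)
  expect_equal(water_viscosity_rel(0), 1.96875673826, tolerance = 1e-9)
  tt <- seq(0, 50, by = 1)
  expect_true(all(diff(water_viscosity_rel(tt)) < 0))
  expect_error(water_viscosity_rel(-5), "degC")
})

test_that("least-cost chi hits its calibration point and responds to D", {
  expect_equal(optimal_chi(298.15, 1000), 0.8, tolerance = 0.01)
  expect_lt(optimal_chi(298.15, 4000), optimal_chi(298.15, 500))
  expect_error(optimal_chi(298.15, 0), "degenerate")
  # round trip: chi at the inverted beta reproduces the input chi exactly
  p <- phot_params()
  b <- invert_beta_cost(0.8, 298.15, 1000, p)
  p2 <- phot_params(beta_cost = b)
  expect_equal(optimal_chi(298.15, 1000, params = p2), 0.8, tolerance = 1e-12)
})

test_that("GPP vanishes at zero light and at the compensation point", {
  expect_identical(gpp(0, 400, 0.8, 43), 0)
  expect_equal(gpp(100, 43 / 0.8, 0.8, 43), 0)
  expect_warning(out <- gpp(100, 50, 0.8, 43), "clamped")
  expect_identical(out, 0)
  # plug-in oracle for the CO2 response factor ratio
  g1 <- gpp(100, 400, 0.8, 43)
  g2 <- gpp(100, 800, 0.8, 43)
  expect_equal(g2 / g1, 1.20526896799, tolerance = 1e-9)
  expect_equal(g1, 12.011 * 0.085 * 100 * 0.682266009852, tolerance = 1e-9)
})

test_that("GPP is monotone in its drivers via finite-difference sweeps", {
  p <- phot_params()
  ca <- seq(300, 900, by = 50)
  expect_true(all(diff(gpp(100, ca, 0.8, 43)) > 0))
  ii <- seq(0, 500, by = 50)
  expect_true(all(diff(gpp(ii, 400, 0.8, 43)) > 0))
  dd <- seq(200, 3000, by = 200)
  chi_d <- vapply(dd, function(d) optimal_chi(288.15, d, params = p), numeric(1))
  expect_true(all(diff(gpp(100, 400, chi_d, 41.6)) < 0))
})

test_that("gpp_field matches a naive per-cell loop and scales with fAPAR", {
  f <- quiet_forcing(1900:1901, nlat = 5, nlon = 5)
  p <- phot_params()
  g <- gpp_field(f, p)
  # independent naive loop over rows using the scalar building blocks
  ref <- vapply(seq_len(nrow(f)), function(i) {
    tk <- f$tair[i] + 273.15
    chi <- optimal_chi(tk, max(f$vpd[i], 1), f$ca[i], p)
    gs <- pa_to_ppm(gamma_star(tk, p), p)
    suppressWarnings(gpp(f$i0[i] * f$fapar[i], f$ca[i], chi, gs, p$phi0))
  }, numeric(1))
  expect_equal(g$gpp, ref, tolerance = 1e-10)
  # linear in absorbed light: doubling fAPAR doubles GPP
  f2 <- dplyr::mutate(f, fapar = pmin(fapar * 2, 1))
  keep <- f$fapar * 2 <= 1
  expect_equal(gpp_field(f2, p)$gpp[keep], 2 * g$gpp[keep], tolerance = 1e-12)
  # spatially uniform forcing gives spatially uniform GPP per month
  fu <- dplyr::mutate(f, tair = 20, vpd = 800, i0 = 400, fapar = 0.5,
                      alpha = 0.8)
  spread <- gpp_field(fu, p) |>
    dplyr::group_by(year, month) |>
    dplyr::summarise(n = dplyr::n_distinct(gpp), .groups = "drop")
  expect_true(all(spread$n == 1))
})

test_that("rising CO2 raises annual global GPP in trended forcing", {
  f <- quiet_forcing(1900:1909, trends = trend_spec(0, 0, 0, 0, 0, 2))
  tot <- global_flux_total(gpp_field(f), cell_areas(f))
  expect_true(all(diff(tot$gpp) > 0))
})
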