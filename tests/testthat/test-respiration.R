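test_that("Lloyd-Taylor scalar has its reference identities", {
  expect_identical(temperature_scalar(15, 250), 1)
  expect_identical(temperature_scalar(c(-10, 5, 30), 0), c(1, 1, 1))
  # direct substitution oracle at 5 degC, E0 = 308.56
  expect_equal(temperature_scalar(5, 308.56), 0.37116014116, tolerance = 1e-9)
  tt <- seq(-20, 35, by = 1)
  expect_true(all(diff(temperature_scalar(tt, 200)) > 0))
  expect_error(temperature_scalar(-50, 200), "T0")
})

test_that("respiration model honours its reference point and GPP coupling", {
  expect_identical(reco(15, 1, 0, r0 = 50, e0 = 200, k = 0.3), 50)
  # k = 0: independent of GPP
  expect_identical(reco(10, 0.8, 0, 40, 250, 0), reco(10, 0.8, 500, 40, 250, 0))
  # golden value frozen at first implementation of the alpha placement
  expect_equal(reco(10, 0.7, 100, 50, 200, 0.3), 41.7964777329,
               tolerance = 1e-9)
  # dReco/dGPP equals k * temperature scalar * alpha (finite difference)
  d <- (reco(10, 0.7, 100 + 1e-4, 50, 200, 0.3) -
          reco(10, 0.7, 100, 50, 200, 0.3)) / 1e-4
  expect_equal(d, 0.3 * temperature_scalar(10, 200) * 0.7, tolerance = 1e-6)
  expect_gt(reco(10, 0.7, 200, 50, 200, 0.3), reco(10, 0.7, 100, 50, 200, 0.3))
  expect_error(reco(10, 0.7, -5, 50, 200, 0.3), "non-negative")
  expect_error(reco(10, 1.4, 5, 50, 200, 0.3), "alpha")
})

test_that("R0 solve closes the preindustrial annual carbon balance", {
  f <- quiet_forcing(1900:1902, nlat = 8, nlon = 6, trends = no_trend_spec())
  r0 <- solve_r0(f)
  expect_true(all(r0$r0 >= 0))
  g <- gpp_field(f)
  nep <- nep_field(g, reco_field(f, g, r0))
  ann <- nep |>
    dplyr::group_by(lat, lon) |>
    dplyr::summarise(nep = sum(nep) / 3, .groups = "drop")
  expect_lt(max(abs(ann$nep)), 1e-8)
  # global total also vanishes
  tot <- global_flux_total(nep, cell_areas(f))
  expect_lt(max(abs(tot$nep)), 1e-6 * 1)
})

test_that("R0 solve reduces to the k = 0 algebra and is linear in GPP", {
  f <- quiet_forcing(1900:1901, nlat = 5, nlon = 4)
  tab0 <- dplyr::mutate(default_pft_params(), k = 0)
  r0 <- solve_r0(f, resp_params(tab0))
  # oracle: annual GPP over annual sum of the temperature-water scalar
  g <- gpp_field(f)
  ref <- f |>
    dplyr::left_join(g, by = c("lat", "lon", "year", "month")) |>
    dplyr::left_join(assign_pft_params(dplyr::distinct(f, lat, lon, pft), tab0),
                     by = c("lat", "lon", "pft")) |>
    dplyr::group_by(lat, lon) |>
    dplyr::summarise(
      ref = sum(gpp) / sum(temperature_scalar(tair, E0) * alpha),
      .groups = "drop"
    )
  cmp <- dplyr::left_join(r0, ref, by = c("lat", "lon"))
  expect_equal(cmp$r0, cmp$ref, tolerance = 1e-10)
  # doubling preindustrial GPP (via phi0) doubles R0 when k = 0
  p2 <- phot_params(phi0 = 0.085 * 1.4)
  r0b <- solve_r0(f, resp_params(tab0), p2)
  expect_equal(r0b$r0, r0$r0 * 1.4, tolerance = 1e-10)
})

test_that("PFT parameter assignment follows the map and names missing PFTs", {
  map <- make_pft_map(10, 4, n_pfts = 2, seed = 3, labels = c("a", "b"))
  tab <- tibble::tibble(pft = c("a", "b"), E0 = c(100, 300), k = c(0.5, 0.1))
  out <- assign_pft_params(map, tab)
  expect_true(all(out$E0[out$pft == "a"] == 100))
  expect_true(all(out$k[out$pft == "b"] == 0.1))
  expect_error(assign_pft_params(map, tab[1, ]), "b")
  # single-PFT map gives uniform parameters
  m1 <- make_pft_map(6, 4, n_pfts = 1, seed = 1, labels = "only")
  u <- assign_pft_params(m1, tibble::tibble(pft = "only", E0 = 150, k = 0.2))
  expect_equal(unique(u$E0), 150)
})

test_that("NEP is the exact GPP - Reco identity with area-weighted totals", {
  f <- quiet_forcing(1900:1901, nlat = 5, nlon = 4)
  g <- gpp_field(f)
  r0 <- solve_r0(f)
  r <- reco_field(f, g, r0)
  nep <- nep_field(g, r)
  expect_identical(nep$nep, nep$gpp - nep$reco)
  # naive-loop oracle for the area-weighted global total
  areas <- cell_areas(f)
  tot <- global_flux_total(nep, areas)
  y1 <- nep[nep$year == 1900, ]
  ref <- 0
  for (i in seq_len(nrow(y1))) {
    a <- areas$cell_area[areas$lat == y1$lat[i] & areas$lon == y1$lon[i]]
    ref <- ref + y1$nep[i] * a
  }
  expect_equal(tot$nep[tot$year == 1900], ref * 1e-15, tolerance = 1e-12)
  # grid mismatch errors
  expect_error(nep_field(g[-1, ], r), "mismatch")
})

test_that("rising CO2 creates a cumulative sink; warming offsets it", {
  years <- 1900:1929
  base <- quiet_forcing(years, nlat = 8, nlon = 6,
                        trends = trend_spec(0, 0, 0, 0, 0, 1))
  r0 <- solve_r0(dplyr::filter(base, year <= 1904))
  run_nep <- function(f) {
    g <- gpp_field(f)
    tot <- global_flux_total(nep_field(g, reco_field(f, g, r0)),
                             cell_areas(f))
    sum(tot$nep)
  }
  cum_ca <- run_nep(base)
  expect_gt(cum_ca, 0) # photosynthesis leads, respiration lags
  warm <- quiet_forcing(years, nlat = 8, nlon = 6,
                        trends = trend_spec(0.05, 0, 0, 0, 0, 1))
  expect_lt(run_nep(warm), cum_ca)
})
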