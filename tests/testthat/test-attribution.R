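test_that("detrending zeroes per-cell-month slopes and anchors the baseline", {
  f <- make_forcing(1900:1929, 5, 4, trends = trend_spec(tair = 0.05),
                    noise = noise_spec(0.3, 0, 0, 0, 0, 0), seed = 6)
  base <- c(1900, 1914)
  d <- detrend_driver(f, "tair", baseline = base)
  slopes <- d |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(
      b = sum((year - mean(year)) * (tair - mean(tair))) /
        sum((year - mean(year))^2),
      .groups = "drop"
    )
  expect_lt(max(abs(slopes$b)), 1e-10)
  # baseline-period mean preserved exactly
  m_old <- f |>
    dplyr::filter(year <= 1914) |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(m = mean(tair), .groups = "drop")
  m_new <- d |>
    dplyr::filter(year <= 1914) |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(m = mean(tair), .groups = "drop")
  expect_equal(m_new$m, m_old$m, tolerance = 1e-10)
  # untrended noiseless drivers pass through unchanged
  expect_identical(d$fapar, f$fapar)
  q <- quiet_forcing(1900:1919, trends = no_trend_spec())
  expect_equal(detrend_driver(q, "alpha")$alpha, q$alpha, tolerance = 1e-12)
  expect_error(detrend_driver(f, "humidity"), "Unknown driver")
})

test_that("fAPAR climatology replaces only pre-cutoff years", {
  f <- make_forcing(1975:1990, 4, 4, trends = trend_spec(fapar = 5e-4),
                    noise = noise_spec(0, 0, 0, 0.01, 0, 0), seed = 2)
  out <- apply_fapar_climatology(f, climatology_window = c(1981, 1990),
                                 cutoff_year = 1981)
  post <- out$year >= 1981
  expect_identical(out$fapar[post], f$fapar[post])
  # pre-cutoff values identical across years per cell and calendar month
  pre <- out |>
    dplyr::filter(year < 1981) |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(n = dplyr::n_distinct(fapar), .groups = "drop")
  expect_true(all(pre$n == 1))
  # and equal to the naive per-month mean oracle
  ref <- f |>
    dplyr::filter(year >= 1981) |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(clim = mean(fapar), .groups = "drop")
  got <- out |>
    dplyr::filter(year == 1975) |>
    dplyr::left_join(ref, by = c("lat", "lon", "month"))
  expect_equal(got$fapar, got$clim, tolerance = 1e-12)
  expect_error(apply_fapar_climatology(f, c(1991, 1995)), "no data years")
})

test_that("single-trend forcing makes that driver's experiment the full run", {
  f <- quiet_forcing(1900:1929, nlat = 6, nlon = 4,
                     trends = trend_spec(0, 0, 0, 0, 0, 1))
  full <- run_experiment(f, keep = "all")
  only_ca <- run_experiment(f, keep = "ca")
  expect_equal(only_ca$nep, full$nep, tolerance = 1e-12)
  # the control run is time-invariant: zero delta between any two periods
  ctrl <- run_experiment(f, keep = "none")
  d0 <- period_delta(ctrl, cell_areas(f), c(1901, 1910), c(1920, 1929))
  expect_lt(max(abs(d0$global$delta)), 1e-9)
})

test_that("driver experiments move fluxes in the expected directions", {
  f <- quiet_forcing(1900:1929, nlat = 8, nlon = 6,
                     trends = trend_spec(tair = 0.05, ca = 1))
  areas <- cell_areas(f)
  p1 <- c(1901, 1910)
  p2 <- c(1920, 1929)
  d_ca <- period_delta(run_experiment(f, keep = "ca"), areas, p1, p2)
  g <- d_ca$global
  expect_gt(g$delta[g$term == "gpp"], 0)
  expect_gt(g$delta[g$term == "nep"], 0)
  d_cl <- period_delta(run_experiment(f, keep = "climate"), areas, p1, p2)
  expect_gt(d_cl$global$delta[d_cl$global$term == "reco"], 0)
  # delta identity and zonal closure
  expect_equal(g$delta[g$term == "nep"],
               g$delta[g$term == "gpp"] - g$delta[g$term == "reco"],
               tolerance = 1e-9)
  zsum <- d_ca$zonal |>
    dplyr::group_by(term) |>
    dplyr::summarise(tot = sum(delta_pgc), .groups = "drop")
  expect_equal(sort(zsum$tot), sort(g$delta), tolerance = 1e-6)
})

test_that("period deltas match a hand-computed toy flux", {
  toy <- tidyr::expand_grid(lat = c(-5, 5), lon = c(0, 10),
                            year = 1901:1904, month = 1:12) |>
    dplyr::mutate(gpp = ifelse(year <= 1902, 100, 130),
                  reco = ifelse(year <= 1902, 90, 110),
                  nep = gpp - reco)
  areas <- tidyr::expand_grid(lat = c(-5, 5), lon = c(0, 10)) |>
    dplyr::mutate(cell_area = 1e12)
  d <- period_delta(toy, areas, c(1901, 1902), c(1903, 1904))
  # per month per cell +30 gC m^-2 GPP on 4e12 m^2 -> 12*30*4e12*1e-15 PgC/yr
  expect_equal(d$global$delta[d$global$term == "gpp"], 12 * 30 * 4e12 * 1e-15)
  expect_equal(d$global$delta[d$global$term == "nep"], 12 * 10 * 4e12 * 1e-15)
  # identical periods give zero delta
  d0 <- period_delta(toy, areas, c(1901, 1902), c(1901, 1902))
  expect_true(all(d0$global$delta == 0))
  expect_error(period_delta(toy, areas, c(1899, 1900), c(1903, 1904)), "within")
})

test_that("single-driver deltas approximately add up to the full run", {
  f <- quiet_forcing(1900:1929, nlat = 6, nlon = 4,
                     trends = trend_spec(tair = 0.02, ca = 0.5, fapar = 1e-4))
  areas <- cell_areas(f)
  p1 <- c(1901, 1910)
  p2 <- c(1920, 1929)
  keeps <- c("ca", "climate", "fapar", "alpha")
  singles <- lapply(setNames(keeps, keeps), function(k) {
    period_delta(run_experiment(f, keep = k), areas, p1, p2)
  })
  full <- period_delta(run_experiment(f, keep = "all"), areas, p1, p2)
  ad <- additivity_check(singles, full)
  expect_named(ad, c("term", "sum_single", "full", "remainder",
                     "remainder_frac"))
  gpp_row <- ad[ad$term == "gpp", ]
  expect_lt(abs(gpp_row$remainder), 0.1 * abs(gpp_row$full))
})
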