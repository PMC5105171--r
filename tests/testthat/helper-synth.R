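# Small noise-free fixtures shared across test files.

quiet_forcing <- function(years = 1900:1905, nlat = 6, nlon = 8, seed = 1,
                          trends = trend_spec(), seasonal = 1) {
  make_forcing(years, nlat, nlon, trends = trends, seasonal = seasonal,
               noise = noise_spec(0, 0, 0, 0, 0, 0), seed = seed)
}

no_trend_spec <- function() trend_spec(0, 0, 0, 0, 0, 0)

cell_areas <- function(forcing) {
  dplyr::distinct(forcing, lat, lon, cell_area)
}
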