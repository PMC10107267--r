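# Shared synthetic-world configurations for the test suite.
#
# compact_config: a scaled-down study (48 windows, 800 species, ~120k
# records) used wherever a full pipeline is needed but the default
# (acceptance-scale) world would be wasteful. tiny_config: a minimal
# landscape for exact algebraic checks.

compact_config <- function(seed = 1, ...) {
  defaults <- list(lon_range = c(-11, 11), gap_half_width = 1.5,
                   window_lon_margin = 2, lat_range = c(40, 58),
                   window_lat_range = c(47, 51),
                   n_species = 800, n0 = 12000, growth = 1.2, seed = seed)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

tiny_config <- function(seed = 1, ...) {
  defaults <- list(lon_range = c(-6, 6), gap_half_width = 1,
                   window_lon_margin = 0, lat_range = c(44, 54),
                   window_lat_range = c(47, 51),
                   n_species = 60, n0 = 800, growth = 1.2, n_cities = 3,
                   seed = seed)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

.world_cache <- new.env(parent = emptyenv())

# compact worlds analysed end to end, reused across files; distinct
# tracking fractions give the multi-taxon tests taxa with distinct trends
cached_compact <- function(seed = 1, lambda = 1) {
  key <- sprintf("ca%d_%g", seed, lambda)
  if (is.null(.world_cache[[key]])) {
    w <- simulate_world(compact_config(seed, lambda = lambda))
    a <- analyze_world(w)
    a$world <- w
    .world_cache[[key]] <- a
  }
  .world_cache[[key]]
}

# a three-"taxon" set with different community responses
cached_taxa <- function() {
  list(t1 = cached_compact(1)$trend_fit,
       t2 = cached_compact(2, lambda = 0.5)$trend_fit,
       t3 = cached_compact(3, lambda = 0.2)$trend_fit)
}

# all-land constant maps for window-construction tests
flat_maps <- function(lon_range, lat_range, res = 0.5, label = "A") {
  lon <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, res)
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, res)
  grid_raster(matrix(label, length(lat), length(lon)), lon, lat)
}

# constant-valued monthly series over given years
constant_series <- function(value, years = 1990:2019,
                            lon_range = c(0, 2), lat_range = c(40, 42),
                            res = 0.5) {
  lon <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, res)
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, res)
  climate_series(array(value, c(length(lat), length(lon),
                                12 * length(years))),
                 lon, lat, years)
}
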