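#' Configuration of the synthetic occurrence/climate world
#'
#' The synthetic world provides ground truth for every downstream stage: a
#' gridded landscape with a south-north temperature gradient, a seasonal
#' cycle, a (possibly spatially varying) linear warming trend, a human
#' influence surface, two rectangular continents separated by a sea channel,
#' latitudinal-band ecoregions, a pool of species with Gaussian thermal
#' niches, and presence-only sampling with exponentially growing, spatially
#' biased effort. Species ranges track shifting isotherms at a configurable
#' fraction `lambda` of the realised temperature change; `lambda` may decline
#' with human influence through `hii_effect`.
#'
#' @param lon_range,lat_range landscape extent (degrees). Two continents of
#'   equal width occupy the longitudinal ends, separated by a sea channel of
#'   half-width `gap_half_width` around the extent's longitudinal midpoint.
#' @param res grid resolution (degrees per cell).
#' @param years years covered (consecutive integers).
#' @param window_lat_range latitudinal span of the 1-degree sliding-window
#'   lattice (kept inside `lat_range` so that window buffers and species
#'   niches are not truncated by the landscape edge).
#' @param t_ref baseline annual-mean temperature (degC) at the central
#'   latitude of the western continent.
#' @param gradient south-north baseline gradient (degC per degree latitude;
#'   positive values mean the south is warmer).
#' @param continent_offset additive baseline offset (degC) of the eastern
#'   continent relative to the western one.
#' @param seasonal_amp amplitude of the seasonal cycle (degC); July is the
#'   warmest month.
#' @param warming warming rate w (degC/year). A single number applies
#'   everywhere; a length-2 range `c(w_min, w_max)` is laid out as a smooth
#'   longitudinal ramp on each continent (rising towards the sea channel), so
#'   sliding windows sample warming rates spanning the range.
#' @param temp_noise_sd standard deviation of independent cell-by-month
#'   temperature noise (degC); 0 gives exactly linear trends.
#' @param n_species number of species in the pool.
#' @param niche_sd thermal niche breadth sigma (degC) of the Gaussian
#'   occupancy curve.
#' @param p_max occupancy probability at the niche optimum.
#' @param optima_range range from which thermal optima are drawn (degC);
#'   `NULL` uses the landscape's baseline annual-mean range.
#' @param lambda tracking fraction in `[0, 1]`: the fraction of the local
#'   temperature change that the temperature field perceived by species
#'   realises (1 = perfect tracking, 0 = static ranges).
#' @param hii_effect strength of the decline of `lambda` with human
#'   influence: the effective fraction in a cell is
#'   `lambda * (1 - hii_effect * HII / 64)`.
#' @param n0 expected number of occurrence records in the first 5-year
#'   period.
#' @param growth effort growth factor g per 5-year period.
#' @param bias_strength spatial sampling bias: cells are sampled with weight
#'   `exp(bias_strength * HII / 64)` (accessible, anthropized areas are
#'   over-represented, as in opportunistic data).
#' @param provider_probs named probabilities of the record-provider labels
#'   (`"unknown"` entries are written as missing providers).
#' @param n_cities number of Gaussian human-influence hotspots.
#' @param region_size ecoregion block size, `c(lon, lat)` in degrees;
#'   blocks at the scale of the window buffers let ecoregion random
#'   intercepts absorb mesoscale spatial structure.
#' @param gap_half_width half-width (degrees) of the sea channel separating
#'   the continents.
#' @param window_lon_margin minimum distance (degrees) between window
#'   centroids and continent edges, keeping buffers longitudinally
#'   untruncated.
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return A list of class `world_config`.
#' @export
world_config <- function(lon_range = c(-17, 17),
                         lat_range = c(38, 60),
                         res = 0.5,
                         years = 1990:2019,
                         window_lat_range = c(46, 52),
                         t_ref = 10,
                         gradient = 0.6,
                         continent_offset = 1,
                         seasonal_amp = 8,
                         warming = c(0, 0.04),
                         temp_noise_sd = 0,
                         n_species = 4000,
                         niche_sd = 0.8,
                         p_max = 0.9,
                         optima_range = NULL,
                         lambda = 1,
                         hii_effect = 0,
                         n0 = 75000,
                         growth = 1.2,
                         bias_strength = 1,
                         provider_probs = c(unknown = 0.3, inst_a = 0.25,
                                            inst_b = 0.2, inst_c = 0.15,
                                            inst_d = 0.1),
                         n_cities = 6,
                         region_size = c(2, 2),
                         gap_half_width = 2.5,
                         window_lon_margin = 3,
                         seed = 1) {
  cfg <- list(lon_range = lon_range, lat_range = lat_range, res = res,
              years = years, window_lat_range = window_lat_range,
              t_ref = t_ref, gradient = gradient,
              continent_offset = continent_offset,
              seasonal_amp = seasonal_amp, warming = warming,
              temp_noise_sd = temp_noise_sd, n_species = n_species,
              niche_sd = niche_sd, p_max = p_max,
              optima_range = optima_range, lambda = lambda,
              hii_effect = hii_effect, n0 = n0, growth = growth,
              bias_strength = bias_strength,
              provider_probs = provider_probs, n_cities = n_cities,
              region_size = region_size,
              gap_half_width = gap_half_width,
              window_lon_margin = window_lon_margin,
              seed = as.integer(seed))
  if (res <= 0) stop("configuration error: resolution must be > 0")
  if (diff(lon_range) < 2 * res || diff(lat_range) < 2 * res) {
    stop("configuration error: extent must span at least 2 cells per axis")
  }
  if (lambda < 0 || lambda > 1) stop("configuration error: lambda must be in [0, 1]")
  if (growth <= 0) stop("configuration error: effort growth factor must be > 0")
  if (n_species < 2) stop("configuration error: n_species must be >= 2")
  if (niche_sd <= 0) stop("configuration error: niche_sd must be > 0")
  if (!length(warming) %in% 1:2) stop("configuration error: warming must have length 1 or 2")
  class(cfg) <- "world_config"
  cfg
}

cell_centres <- function(from, to, res) seq(from + res / 2, to - res / 2, by = res)

# continent label per cell centre: "west", "east" or NA (sea channel)
continent_of <- function(lon, cfg) {
  mid <- mean(cfg$lon_range)
  cw <- (diff(cfg$lon_range) - 2 * cfg$gap_half_width) / 2
  out <- rep(NA_character_, length(lon))
  out[lon >= cfg$lon_range[1] & lon <= cfg$lon_range[1] + cw] <- "west"
  out[lon >= cfg$lon_range[2] - cw & lon <= cfg$lon_range[2]] <- "east"
  out[lon > mid - cfg$gap_half_width & lon < mid + cfg$gap_half_width] <- NA
  out
}

baseline_annual_at <- function(lon, lat, cfg) {
  cont <- continent_of(lon, cfg)
  base <- cfg$t_ref - cfg$gradient * (lat - mean(cfg$lat_range))
  base + ifelse(!is.na(cont) & cont == "east", cfg$continent_offset, 0)
}

# Per-continent longitudinal warming ramp, rising towards the sea channel.
# The ramp is linear in longitude and spans [w_min, w_max] exactly across
# the window lattice zone (continent interior minus window_lon_margin), and
# extrapolates linearly into the margin cells. Linearity within every
# (untruncated) window buffer makes the buffer-mean temperature trend equal
# the trend governing the assemblage response, so the debt-model slope has
# no heterogeneity artefact.
warming_at <- function(lon, cfg) {
  if (length(cfg$warming) == 1) return(rep(cfg$warming, length(lon)))
  mid <- mean(cfg$lon_range)
  cw <- (diff(cfg$lon_range) - 2 * cfg$gap_half_width) / 2
  zone <- cw - 2 * cfg$window_lon_margin  # window-zone width per continent
  if (zone <= 0) zone <- cw               # degenerate: ramp over continent
  west_mid <- cfg$lon_range[1] + cw / 2
  east_mid <- cfg$lon_range[2] - cw / 2
  u <- ifelse(lon <= mid,
              0.5 + (lon - west_mid) / zone,
              0.5 + (east_mid - lon) / zone)
  cfg$warming[1] + diff(cfg$warming) * u
}

#' Generate the synthetic landscape
#'
#' Builds the monthly temperature series, the human influence index (HII)
#' surface, the continent map, the ecoregion map and the per-cell warming
#' rate implied by a [world_config()]. Monthly temperature in a land cell is
#' `baseline(lat) + seasonal(month) + w(cell) * (year - first year)` plus
#' optional Gaussian noise; sea cells are missing.
#'
#' @param config a [world_config()].
#' @return A list of class `landscape` with elements `temp`
#'   ([climate_series()]), `hii`, `continent`, `region`, `warming`,
#'   `baseline` (all [grid_raster()]) and `config`.
#' @export
generate_landscape <- function(config) {
  cfg <- config
  lon <- cell_centres(cfg$lon_range[1], cfg$lon_range[2], cfg$res)
  lat <- cell_centres(cfg$lat_range[1], cfg$lat_range[2], cfg$res)
  nlon <- length(lon); nlat <- length(lat)

  cont_row <- continent_of(lon, cfg)                       # per lon column
  cont <- matrix(rep(cont_row, each = nlat), nlat, nlon)
  land <- !is.na(cont)

  base <- outer(lat, lon, function(la, lo) baseline_annual_at(lo, la, cfg))
  base[!land] <- NA
  wmat <- matrix(rep(warming_at(lon, cfg), each = nlat), nlat, nlon)
  wmat[!land] <- NA

  # ecoregions: a mosaic of rectangular blocks per continent, at a scale
  # comparable to the window buffers, so the ecoregion random intercepts
  # can absorb mesoscale spatial structure
  lon_blk <- floor((matrix(rep(lon, each = nlat), nlat, nlon) -
                      cfg$lon_range[1]) / cfg$region_size[1])
  lat_blk <- floor((matrix(rep(lat, times = nlon), nlat, nlon) -
                      cfg$lat_range[1]) / cfg$region_size[2])
  region <- matrix(sprintf("%s-%02d-%02d", cont, lon_blk, lat_blk),
                   nlat, nlon)
  region[!land] <- NA

  seasonal <- cfg$seasonal_amp * cos(2 * pi * (1:12 - 7) / 12)
  y0 <- cfg$years[1]
  nyr <- length(cfg$years)
  vals <- array(NA_real_, dim = c(nlat, nlon, 12 * nyr))
  if (cfg$temp_noise_sd > 0) set.seed(cfg$seed + 7L)
  for (iy in seq_len(nyr)) {
    yr <- cfg$years[iy]
    for (m in 1:12) {
      layer <- base + seasonal[m] + wmat * (yr - y0)
      if (cfg$temp_noise_sd > 0) {
        noise <- matrix(stats::rnorm(nlat * nlon, 0, cfg$temp_noise_sd),
                        nlat, nlon)
        layer <- layer + noise
        layer[!land] <- NA
      }
      vals[, , (iy - 1L) * 12L + m] <- layer
    }
  }

  # human influence: a few smooth hotspots on land, scaled to [0, 64]
  set.seed(cfg$seed + 11L)
  land_idx <- which(land)
  centres <- land_idx[sample.int(length(land_idx), cfg$n_cities)]
  crow <- (centres - 1L) %% nlat + 1L
  ccol <- (centres - 1L) %/% nlat + 1L
  amp <- stats::runif(cfg$n_cities, 0.3, 0.8)
  scl <- stats::runif(cfg$n_cities, 1, 2.5)
  lonm <- matrix(rep(lon, each = nlat), nlat, nlon)
  latm <- matrix(rep(lat, times = nlon), nlat, nlon)
  hii <- matrix(0.03, nlat, nlon)
  for (k in seq_len(cfg$n_cities)) {
    d2 <- (lonm - lon[ccol[k]])^2 + (latm - lat[crow[k]])^2
    hii <- hii + amp[k] * exp(-d2 / (2 * scl[k]^2))
  }
  hii <- 64 * pmin(hii, 1)
  hii[!land] <- NA

  structure(list(
    temp = climate_series(vals, lon, lat, cfg$years),
    hii = grid_raster(hii, lon, lat),
    continent = grid_raster(cont, lon, lat),
    region = grid_raster(region, lon, lat),
    warming = grid_raster(wmat, lon, lat),
    baseline = grid_raster(base, lon, lat),
    config = cfg
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells (%d land), years %d-%d\n",
              length(x$temp$lat), length(x$temp$lon),
              sum(!is.na(x$continent$values)),
              min(x$temp$years), max(x$temp$years)))
  invisible(x)
}

#' Draw the species pool
#'
#' Thermal optima are drawn uniformly over `optima_range` (by default the
#' landscape's baseline annual-mean temperature range), with a common niche
#' breadth. All species may occur on both continents; occupancy is governed
#' by temperature alone.
#'
#' @param config a [world_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return data.frame with columns `species`, `optimum` (degC), `sigma`
#'   (degC), `continent`.
#' @export
generate_species_pool <- function(config, seed = config$seed) {
  cfg <- config
  if (cfg$n_species < 2) stop("n_species must be >= 2")
  rng <- cfg$optima_range
  if (is.null(rng)) {
    # optima cover the thermal band reachable from the window lattice
    # (buffer radius ~1.8 deg lat) plus a presence margin, so that window
    # assemblages are never truncated by the edges of the species pool
    buf <- 200 / 110.574
    margin <- 2.5 * cfg$niche_sd + 1
    lo <- cfg$t_ref - cfg$gradient *
      (cfg$window_lat_range[2] + buf - mean(cfg$lat_range)) - margin
    hi <- cfg$t_ref + cfg$continent_offset - cfg$gradient *
      (cfg$window_lat_range[1] - buf - mean(cfg$lat_range)) + margin
    rng <- c(lo, hi)
  }
  set.seed(seed + 23L)
  data.frame(
    species = sprintf("sp%04d", seq_len(cfg$n_species)),
    optimum = stats::runif(cfg$n_species, rng[1], rng[2]),
    sigma = rep(cfg$niche_sd, cfg$n_species),
    continent = "both",
    stringsAsFactors = FALSE
  )
}

# per-period annual-mean temperature fields actually realised (land vector),
# plus the first-year field used as the static reference
period_fields <- function(landscape, periods) {
  s <- landscape$temp
  a0 <- annual_mean_raster(s, s$years[1])$values
  ap <- lapply(seq_len(nrow(periods)), function(i) {
    annual_mean_raster(s, periods$start_year[i]:periods$end_year[i])$values
  })
  list(a0 = a0, ap = ap)
}

#' Sample presence-only occurrence records
#'
#' For each 5-year period, each species' occupancy probability in a cell is a
#' Gaussian function of the cell's *perceived* annual-mean temperature: the
#' first-year field plus `lambda` times the realised change since then
#' (cell-wise `lambda` may decline with human influence). Cell-level presence
#' uses a persistent uniform threshold per (species, cell), so composition
#' changes between periods are driven by temperature change. Records are then
#' drawn from occupied (species, cell) pairs with spatially biased,
#' exponentially growing effort; coordinates are cell centres jittered
#' uniformly within the cell.
#'
#' @param landscape a [generate_landscape()] result.
#' @param pool a [generate_species_pool()] result.
#' @param lambda,hii_effect,n0,growth,bias_strength override the
#'   corresponding [world_config()] entries.
#' @param seed RNG seed (defaults to the config seed).
#' @return data.frame of records: `species`, `lon`, `lat`, `year`, `month`,
#'   `provider` (`NA` where the provider label is `"unknown"`).
#' @export
sample_occurrences <- function(landscape, pool,
                               lambda = landscape$config$lambda,
                               hii_effect = landscape$config$hii_effect,
                               n0 = landscape$config$n0,
                               growth = landscape$config$growth,
                               bias_strength = landscape$config$bias_strength,
                               seed = landscape$config$seed) {
  if (nrow(pool) == 0) stop("empty species pool")
  cfg <- landscape$config
  periods <- period_defs(start = cfg$years[1],
                         n = ceiling(length(cfg$years) / 5))
  pf <- period_fields(landscape, periods)
  land <- which(!is.na(landscape$continent$values))
  nlat <- length(landscape$temp$lat)
  lon_c <- landscape$temp$lon[(land - 1L) %/% nlat + 1L]
  lat_c <- landscape$temp$lat[(land - 1L) %% nlat + 1L]
  hii <- landscape$hii$values[land]
  lam_cell <- pmin(pmax(lambda * (1 - hii_effect * hii / 64), 0), 1)
  bias_w <- exp(bias_strength * hii / 64)
  mu <- pool$optimum
  sg <- pool$sigma
  nsp <- length(mu)
  ncell <- length(land)

  set.seed(seed + 31L)
  u <- matrix(stats::runif(nsp * ncell), nsp, ncell)

  prov <- names(cfg$provider_probs)
  out <- vector("list", nrow(periods))
  a0 <- pf$a0[land]
  for (p in seq_len(nrow(periods))) {
    tp <- a0 + lam_cell * (pf$ap[[p]][land] - a0)
    pm <- cfg$p_max * exp(-(outer(mu, tp, "-"))^2 / (2 * sg^2))
    occ <- pm > u
    cnt <- colSums(occ)
    keep <- which(cnt > 0L)
    if (length(keep) == 0L) next
    n_p <- max(1L, as.integer(round(n0 * growth^(periods$index[p]))))
    # two-stage draw equivalent to sampling pairs with weight bias_w(cell):
    # cell with prob bias_w * n_occupied, then a uniform occupied species
    cells <- keep[sample.int(length(keep), n_p, replace = TRUE,
                             prob = bias_w[keep] * cnt[keep])]
    sp_of <- which(occ)                       # column-major: sorted by cell
    sp_row <- (sp_of - 1L) %% nsp + 1L
    offs <- cumsum(c(0L, cnt))                # start offset per cell
    pos <- offs[cells] + ceiling(stats::runif(n_p) * cnt[cells])
    spi <- sp_row[pos]
    yrs <- periods$start_year[p] + sample.int(5L, n_p, replace = TRUE) - 1L
    provider <- prov[sample.int(length(prov), n_p, replace = TRUE,
                                prob = cfg$provider_probs)]
    provider[provider == "unknown"] <- NA_character_
    out[[p]] <- data.frame(
      species = pool$species[spi],
      lon = lon_c[cells] + stats::runif(n_p, -cfg$res / 2, cfg$res / 2),
      lat = lat_c[cells] + stats::runif(n_p, -cfg$res / 2, cfg$res / 2),
      year = yrs,
      month = sample.int(12L, n_p, replace = TRUE),
      provider = provider,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: landscape + species pool + occurrence table, with the
#' ground truth (optima, warming field, tracking fraction) retained.
#'
#' @param config a [world_config()].
#' @return list of class `cti_world`: `landscape`, `pool`, `occurrences`,
#'   `config`.
#' @export
simulate_world <- function(config = world_config()) {
  landscape <- generate_landscape(config)
  pool <- generate_species_pool(config)
  occ <- sample_occurrences(landscape, pool)
  structure(list(landscape = landscape, pool = pool, occurrences = occ,
                 config = config), class = "cti_world")
}

#' @export
print.cti_world <- function(x, ...) {
  cat(sprintf("<cti_world> %d species, %d records, lambda = %g\n",
              nrow(x$pool), nrow(x$occurrences), x$config$lambda))
  invisible(x)
}

#' Occupancy-based expected CTI (generator truth)
#'
#' Independent of the sampling process, computes for every window and period
#' the expected community temperature index implied by the occupancy model
#' itself: each species' probability of being present somewhere in the window
#' (one minus the product of per-cell absence probabilities), used to weight
#' its true thermal optimum. The implied expected CTI drift (degC/year) is
#' the weighted mean of per-window least-squares slopes of expected CTI on
#' period median year.
#'
#' @param landscape,pool the synthetic world pieces.
#' @param windows a [build_windows()] table.
#' @param radius_km window radius.
#' @return list: `expected_cti` (window x period matrix), `drift`
#'   (expected CTI trend per window, degC/yr), `mean_drift`.
#' @export
expected_cti_truth <- function(landscape, pool, windows, radius_km = 200) {
  cfg <- landscape$config
  periods <- period_defs(start = cfg$years[1],
                         n = ceiling(length(cfg$years) / 5))
  pf <- period_fields(landscape, periods)
  land <- which(!is.na(landscape$continent$values))
  nlat <- length(landscape$temp$lat)
  lon_c <- landscape$temp$lon[(land - 1L) %/% nlat + 1L]
  lat_c <- landscape$temp$lat[(land - 1L) %% nlat + 1L]
  hii <- landscape$hii$values[land]
  lam_cell <- pmin(pmax(cfg$lambda * (1 - cfg$hii_effect * hii / 64), 0), 1)
  mu <- pool$optimum
  ecti <- matrix(NA_real_, nrow(windows), nrow(periods))
  a0 <- pf$a0[land]
  for (p in seq_len(nrow(periods))) {
    tp <- a0 + lam_cell * (pf$ap[[p]][land] - a0)
    pm <- cfg$p_max * exp(-(outer(mu, tp, "-"))^2 / (2 * pool$sigma^2))
    lq <- log1p(-pmin(pm, 1 - 1e-12))
    for (w in seq_len(nrow(windows))) {
      inw <- which(geosphere::distHaversine(
        cbind(lon_c, lat_c), c(windows$lon[w], windows$lat[w])) <=
          radius_km * 1000)
      if (length(inw) == 0) next
      q <- 1 - exp(rowSums(lq[, inw, drop = FALSE]))
      ecti[w, p] <- sum(q * mu) / sum(q)
    }
  }
  yrs <- periods$median_year
  drift <- apply(ecti, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2) return(NA_real_)
    stats::cov(yrs[ok], v[ok]) / stats::var(yrs[ok])
  })
  list(expected_cti = ecti, drift = drift,
       mean_drift = mean(drift, na.rm = TRUE))
}
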