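#' Period-mean seasonal temperature rasters
#'
#' Averages a monthly temperature series into one raster per 5-year period,
#' using the taxon's seasonal month set (all twelve months, March-September,
#' or the December-January winter). For the winter set, December is paired
#' with the following January and the pair belongs to that January's period,
#' mirroring the record-assignment convention; the December preceding the
#' series is unavailable, so the first period's first winter contributes only
#' its January.
#'
#' @param series a [climate_series()] covering the study years.
#' @param months seasonal month set (subset of 1:12).
#' @param periods a [period_defs()] table.
#' @return list of class `period_climate`: `rasters` (one [grid_raster()]
#'   per period), `months`, `periods`.
#' @export
build_period_rasters <- function(series, months = 1:12,
                                 periods = period_defs()) {
  months <- as.integer(months)
  if (length(months) == 0 || !all(months %in% 1:12)) {
    stop("month set must be a non-empty subset of 1:12")
  }
  winter <- identical(sort(months), c(1L, 12L))
  rasters <- vector("list", nrow(periods))
  for (i in seq_len(nrow(periods))) {
    yrs <- periods$start_year[i]:periods$end_year[i]
    if (winter) {
      ym <- rbind(cbind(yrs - 1L, 12L), cbind(yrs, 1L))
    } else {
      ym <- cbind(rep(yrs, each = length(months)),
                  rep(months, times = length(yrs)))
    }
    ym <- ym[ym[, 1] %in% series$years, , drop = FALSE]
    if (nrow(ym) == 0) stop("month set not available in the series")
    layers <- series_layer(series, ym[, 1], ym[, 2])
    m <- apply(series$values[, , layers, drop = FALSE], c(1, 2), mean)
    rasters[[i]] <- grid_raster(m, series$lon, series$lat)
  }
  structure(list(rasters = rasters, months = months, periods = periods),
            class = "period_climate")
}

#' Temperature at occurrence records
#'
#' Reads, for each record, the value of its period's mean-temperature raster
#' in the cell containing the record (location and observation period
#' together determine the extracted temperature). Records outside the raster
#' extent or on empty (sea) cells yield `NA` and are reported via the
#' `n_missing` attribute; they are excluded from STI computation downstream.
#'
#' @param records occurrence data.frame with `lon`, `lat` and `period`.
#' @param climate a [build_period_rasters()] result.
#' @return numeric vector of temperatures (degC), `NA` where unavailable,
#'   with attribute `n_missing`.
#' @export
extract_temperature <- function(records, climate) {
  if (is.null(records$period)) stop("records must carry a period column")
  out <- rep(NA_real_, nrow(records))
  for (p in unique(records$period)) {
    i <- which(records$period == p)
    r <- climate$rasters[[match(p, climate$periods$index)]]
    out[i] <- grid_value_at(r, records$lon[i], records$lat[i])
  }
  structure(out, n_missing = sum(is.na(out)))
}

# indices of grid cells whose centres lie within radius_km of (lon, lat);
# a bounding-box prefilter keeps the geodesic computation small
cells_within_radius <- function(r, lon, lat, radius_km) {
  dlat <- radius_km / 110.574 + 0.01
  lat_ok <- which(abs(r$lat - lat) <= dlat)
  if (length(lat_ok) == 0) return(integer(0))
  coslat <- cos(pmin(abs(lat) + dlat, 89) * pi / 180)
  dlon <- radius_km / (111.32 * coslat) + 0.01
  lon_ok <- which(abs(r$lon - lon) <= dlon)
  if (length(lon_ok) == 0) return(integer(0))
  cand <- cbind(rep(lon_ok, each = length(lat_ok)),
                rep(lat_ok, times = length(lon_ok)))
  d <- geosphere::distHaversine(cbind(r$lon[cand[, 1]], r$lat[cand[, 2]]),
                                c(lon, lat))
  inside <- cand[d <= radius_km * 1000, , drop = FALSE]
  # linear indices into the [lat, lon] value matrix
  (inside[, 1] - 1L) * length(r$lat) + inside[, 2]
}

#' Window-level climate covariates
#'
#' For each sliding window, computes the mean temperature per period over the
#' climate cells whose centres fall within the window radius (land cells
#' only), the overall mean temperature (mean of period means), the linear
#' temperature trend against period median years, and the mean human
#' influence index computed identically on the HII grid. Windows with no
#' land climate cell are flagged unusable.
#'
#' @param windows a [build_windows()] table.
#' @param climate a [build_period_rasters()] result.
#' @param hii a [grid_raster()] of the human influence index.
#' @param radius_km window radius (km).
#' @return data.frame: `window_id`, `mean_temp`, `temp_trend` (degC/yr),
#'   `hii`, `n_cells`, `usable`; per-period means in the
#'   `"period_means"` attribute (windows x periods matrix).
#' @export
window_climate <- function(windows, climate, hii = NULL, radius_km = 200) {
  np <- length(climate$rasters)
  pm <- matrix(NA_real_, nrow(windows), np)
  hmean <- rep(NA_real_, nrow(windows))
  ncells <- integer(nrow(windows))
  r1 <- climate$rasters[[1]]
  for (w in seq_len(nrow(windows))) {
    cells <- cells_within_radius(r1, windows$lon[w], windows$lat[w],
                                 radius_km)
    vals1 <- r1$values[cells]
    cells <- cells[!is.na(vals1)]
    ncells[w] <- length(cells)
    if (length(cells) == 0) next
    for (p in seq_len(np)) {
      pm[w, p] <- mean(climate$rasters[[p]]$values[cells], na.rm = TRUE)
    }
    if (!is.null(hii)) {
      hc <- cells_within_radius(hii, windows$lon[w], windows$lat[w],
                                radius_km)
      hmean[w] <- mean(hii$values[hc], na.rm = TRUE)
    }
  }
  yrs <- climate$periods$median_year
  trend <- apply(pm, 1, window_temp_trend, median_years = yrs)
  out <- data.frame(window_id = windows$window_id,
                    mean_temp = rowMeans(pm, na.rm = TRUE),
                    temp_trend = trend,
                    hii = hmean,
                    n_cells = ncells,
                    usable = ncells > 0)
  out$mean_temp[ncells == 0] <- NA_real_
  attr(out, "period_means") <- pm
  attr(out, "median_years") <- yrs
  out
}

#' Local temperature trend of one window
#'
#' Ordinary (unweighted) least-squares slope of the window's period mean
#' temperatures against the period median years; `NA` when fewer than two
#' period means are available (such windows are excluded from the debt
#' model).
#'
#' @param period_means numeric vector of per-period mean temperatures.
#' @param median_years matching period median years.
#' @return slope in degC/year, or `NA`.
#' @export
window_temp_trend <- function(period_means, median_years) {
  ok <- !is.na(period_means)
  if (sum(ok) < 2) return(NA_real_)
  x <- median_years[ok]
  y <- period_means[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
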