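#' Lightweight geographic grid containers
#'
#' `grid_raster()` wraps a numeric (or character) matrix of cell values on a
#' regular longitude/latitude grid. Rows index latitude (ascending), columns
#' index longitude (ascending); `lon` and `lat` hold cell-centre coordinates.
#' `climate_series()` stacks monthly layers of such a grid over a span of
#' years, with layer index `(year - years[1]) * 12 + month`.
#'
#' These containers are deliberately minimal: the package's climate inputs are
#' regular lat/lon grids (0.5 degrees by default) and all operations reduce to
#' cell-centre lookups and means, so a plain matrix plus coordinate vectors is
#' the whole contract. `write_grid_csv()` / `read_grid_csv()` serialise a grid
#' as long-format CSV (`lon,lat,value`).
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lon,lat cell-centre coordinates (decimal degrees), strictly
#'   increasing and evenly spaced.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, lon, lat) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be a length(lat) x length(lon) matrix")
  }
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("lon must be increasing")
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("lat must be increasing")
  structure(list(values = values, lon = lon, lat = lat),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              length(x$lat), length(x$lon),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

grid_res <- function(r) {
  if (length(r$lon) > 1) r$lon[2] - r$lon[1] else if (length(r$lat) > 1) r$lat[2] - r$lat[1] else 1
}

#' Locate grid cells containing points
#'
#' Returns, for each point, the row (latitude) and column (longitude) index of
#' the containing cell, or `NA` for points outside the grid extent. Points on
#' an interior cell boundary belong to the cell with the larger index (floor
#' convention on `(x - edge) / res`).
#'
#' @param r a [grid_raster()] (or any list with `lon`, `lat` centres).
#' @param lon,lat point coordinates (decimal degrees).
#' @return data.frame with columns `row`, `col`.
#' @export
cell_index <- function(r, lon, lat) {
  res <- grid_res(r)
  lon0 <- r$lon[1] - res / 2
  lat0 <- r$lat[1] - res / 2
  col <- floor((lon - lon0) / res) + 1L
  row <- floor((lat - lat0) / res) + 1L
  # points exactly on the outer max edge belong to the last cell
  col[!is.na(col) & col == length(r$lon) + 1L &
        abs(lon - (max(r$lon) + res / 2)) < 1e-9] <- length(r$lon)
  row[!is.na(row) & row == length(r$lat) + 1L &
        abs(lat - (max(r$lat) + res / 2)) < 1e-9] <- length(r$lat)
  col[col < 1L | col > length(r$lon)] <- NA_integer_
  row[row < 1L | row > length(r$lat)] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read grid values at point locations
#'
#' @inheritParams cell_index
#' @return vector of cell values (`NA` outside the extent or on empty cells).
#' @export
grid_value_at <- function(r, lon, lat) {
  idx <- cell_index(r, lon, lat)
  out <- rep(r$values[1][NA], length(lon))
  ok <- !is.na(idx$row) & !is.na(idx$col)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Monthly gridded series
#'
#' @param values numeric array `[lat, lon, month]` with one layer per month,
#'   ordered year-major (Jan of `years[1]` first).
#' @param lon,lat cell-centre coordinates.
#' @param years integer vector of consecutive years covered.
#' @return An object of class `climate_series`.
#' @rdname grid_raster
#' @export
climate_series <- function(values, lon, lat, years) {
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  if (dim(values)[3] != 12 * length(years)) {
    stop("third dimension must equal 12 * length(years)")
  }
  structure(list(values = values, lon = lon, lat = lat, years = years),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %d x %d cells, years %d-%d (%d monthly layers)\n",
              length(x$lat), length(x$lon), min(x$years), max(x$years),
              dim(x$values)[3]))
  invisible(x)
}

series_layer <- function(s, year, month) {
  (match(year, s$years) - 1L) * 12L + month
}

#' Annual-mean field of a monthly series
#'
#' Mean over the 12 months of each requested year, averaged across years.
#'
#' @param s a [climate_series()].
#' @param years years to average over (subset of `s$years`).
#' @return a [grid_raster()] of mean values.
#' @export
annual_mean_raster <- function(s, years = s$years) {
  if (!all(years %in% s$years)) stop("years outside the series")
  layers <- as.vector(vapply(years, function(y) series_layer(s, y, 1:12),
                             integer(12)))
  m <- apply(s$values[, , layers, drop = FALSE], c(1, 2), mean)
  grid_raster(m, s$lon, s$lat)
}

#' @rdname grid_raster
#' @param path file path for CSV serialisation.
#' @export
write_grid_csv <- function(r, path) {
  df <- data.frame(lon = rep(r$lon, each = length(r$lat)),
                   lat = rep(r$lat, times = length(r$lon)),
                   value = as.vector(r$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_raster
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  grid_raster(m, lon, lat)
}
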