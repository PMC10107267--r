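#' Build the sliding-window lattice
#'
#' Places a candidate window at every cell centre of a 1-degree lattice over
#' the requested extent, then keeps windows whose 200-km buffer contains at
#' least one land cell and whose centroid lies on a mapped continent.
#' Each window is labelled with the continent at its centroid and with the
#' ecoregion occupying the largest land area (cosine-latitude-weighted cell
#' count) inside its buffer.
#'
#' @param lon_range,lat_range lattice extent (degrees).
#' @param continent_map [grid_raster()] of continent labels (`NA` = sea).
#' @param region_map [grid_raster()] of ecoregion labels (`NA` = sea).
#' @param radius_km buffer radius (fixed at 200 km in the study design).
#' @param step lattice spacing (degrees).
#' @return data.frame: `window_id`, `lon`, `lat`, `continent`, `ecoregion`;
#'   the radius is kept in the `"radius_km"` attribute.
#' @export
build_windows <- function(lon_range, lat_range, continent_map, region_map,
                          radius_km = 200, step = 1) {
  lon <- cell_centres(lon_range[1], lon_range[2], step)
  lat <- cell_centres(lat_range[1], lat_range[2], step)
  grid <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  cont <- grid_value_at(continent_map, grid$lon, grid$lat)
  eco <- rep(NA_character_, nrow(grid))
  has_land <- logical(nrow(grid))
  nlat <- length(region_map$lat)
  for (i in seq_len(nrow(grid))) {
    cells <- cells_within_radius(region_map, grid$lon[i], grid$lat[i],
                                 radius_km)
    labs <- region_map$values[cells]
    ok <- !is.na(labs)
    has_land[i] <- any(ok)
    if (!has_land[i]) next
    rows <- (cells[ok] - 1L) %% nlat + 1L
    area <- tapply(cos(region_map$lat[rows] * pi / 180), labs[ok], sum)
    eco[i] <- names(area)[order(-area, names(area))][1]
  }
  keep <- has_land & !is.na(cont)
  out <- data.frame(window_id = seq_len(sum(keep)),
                    lon = grid$lon[keep], lat = grid$lat[keep],
                    continent = cont[keep], ecoregion = eco[keep])
  attr(out, "radius_km") <- radius_km
  out
}

#' Assign occurrence records to sliding windows
#'
#' A record belongs to every window whose centroid lies within the window
#' radius (geodesic distance); adjacent windows overlap by construction, so
#' most records belong to several windows.
#'
#' @param records occurrence data.frame (`lon`, `lat`).
#' @param windows a [build_windows()] table.
#' @param radius_km window radius (km).
#' @return data.frame: `record` (row index into `records`), `window_id`.
#' @export
assign_occurrences <- function(records, windows, radius_km = 200) {
  n <- nrow(records)
  res <- vector("list", nrow(windows))
  dlat <- radius_km / 110.574 + 0.01
  for (w in seq_len(nrow(windows))) {
    coslat <- cos(pmin(abs(windows$lat[w]) + dlat, 89) * pi / 180)
    dlon <- radius_km / (111.32 * coslat) + 0.01
    cand <- which(abs(records$lat - windows$lat[w]) <= dlat &
                    abs(records$lon - windows$lon[w]) <= dlon)
    if (length(cand) == 0) next
    d <- geosphere::distHaversine(
      cbind(records$lon[cand], records$lat[cand]),
      c(windows$lon[w], windows$lat[w]))
    hit <- cand[d <= radius_km * 1000]
    if (length(hit)) {
      res[[w]] <- data.frame(record = hit, window_id = windows$window_id[w])
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(record = integer(), window_id = integer())
  out
}

#' Assemblage membership table
#'
#' Collapses record-window membership into per (window, period, species)
#' record counts: the raw material for CTI, occupancy sets and turnover.
#'
#' @param records occurrence data.frame with `species` and `period`.
#' @param membership an [assign_occurrences()] table.
#' @return data.frame: `window_id`, `period`, `species`, `n` (records).
#' @export
build_assemblages <- function(records, membership) {
  if (nrow(membership) == 0) {
    return(data.frame(window_id = integer(), period = integer(),
                      species = character(), n = integer()))
  }
  df <- data.frame(window_id = membership$window_id,
                   period = records$period[membership$record],
                   species = records$species[membership$record])
  key <- paste(df$window_id, df$period, df$species, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$n <- tabulate(match(key, key[first]), nbins = sum(first))
  rownames(out) <- NULL
  out[order(out$window_id, out$period, out$species), , drop = FALSE]
}
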