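#' Five-year period definitions
#'
#' The 30-year study span is divided into consecutive non-overlapping 5-year
#' periods (by default 1990-1994 ... 2015-2019), indexed from 0. The median
#' year of each period (start + 2) is the time coordinate used by all trend
#' models.
#'
#' @param start first year covered.
#' @param n number of periods.
#' @param length_years period length in years.
#' @return data.frame: `index`, `start_year`, `end_year`, `median_year`.
#' @export
period_defs <- function(start = 1990, n = 6, length_years = 5) {
  idx <- seq_len(n) - 1L
  data.frame(index = idx,
             start_year = start + idx * length_years,
             end_year = start + idx * length_years + length_years - 1L,
             median_year = start + idx * length_years +
               (length_years - 1L) %/% 2L)
}

#' Taxon analysis profile
#'
#' Bundles the taxon-specific handling rules: the seasonal month set used
#' both for record filtering and for period temperature rasters (all months;
#' the March-September breeding season; or the December-January winter), and
#' a list of species to exclude (e.g. strictly synanthropic species).
#'
#' @param taxon_group label, e.g. `"ants"`.
#' @param season one of `"all"`, `"summer"` (months 3-9) or `"winter"`
#'   (December-January).
#' @param exclude character vector of species names to drop.
#' @return list of class `taxon_profile` with `taxon_group`, `season`,
#'   `months`, `exclude`.
#' @export
taxon_profile <- function(taxon_group, season = c("all", "summer", "winter"),
                          exclude = character()) {
  season <- match.arg(season)
  months <- switch(season, all = 1:12, summer = 3:9, winter = c(12L, 1L))
  structure(list(taxon_group = taxon_group, season = season,
                 months = months, exclude = exclude),
            class = "taxon_profile")
}

is_winter_profile <- function(profile) {
  !is.null(profile) && identical(sort(profile$months), c(1L, 12L))
}

#' Automatic coordinate cleaning
#'
#' Removes the recurrent coordinate errors of aggregated occurrence data:
#' records at exactly (0, 0) or with latitude equal to longitude, records
#' within a buffer of listed capital/country centroids or biodiversity
#' institutions, and records falling on non-land cells. All rules are
#' evaluated against the raw input, so the survivor set does not depend on
#' rule order.
#'
#' @param records occurrence data.frame with `lon`, `lat` columns (see
#'   [read_occurrences()]).
#' @param bad_points optional data.frame of centroid/institution coordinates
#'   (`lon`, `lat`) to buffer out.
#' @param land_mask a [grid_raster()] whose non-missing (and non-`FALSE`)
#'   cells are land; required.
#' @param radius_km buffer radius around `bad_points` (km).
#' @return list: `records` (survivors), `removed` (named per-rule counts;
#'   a record failing several rules is counted under each).
#' @export
clean_coordinates <- function(records, bad_points = NULL, land_mask = NULL,
                              radius_km = 1) {
  if (is.null(land_mask)) stop("a land mask is required")
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = c(zero_zero = 0L, equal_lat_lon = 0L,
                            centroid = 0L, sea = 0L)))
  }
  zero <- records$lon == 0 & records$lat == 0
  eq <- records$lat == records$lon
  cent <- rep(FALSE, nrow(records))
  if (!is.null(bad_points) && nrow(bad_points) > 0) {
    for (i in seq_len(nrow(bad_points))) {
      d <- geosphere::distHaversine(cbind(records$lon, records$lat),
                                    c(bad_points$lon[i], bad_points$lat[i]))
      cent <- cent | d <= radius_km * 1000
    }
  }
  lv <- grid_value_at(land_mask, records$lon, records$lat)
  sea <- is.na(lv)
  if (is.logical(lv)) sea <- sea | !lv
  drop <- zero | eq | cent | sea
  list(records = records[!drop, , drop = FALSE],
       removed = c(zero_zero = sum(zero), equal_lat_lon = sum(eq),
                   centroid = sum(cent), sea = sum(sea)))
}

#' Taxon-specific record filtering
#'
#' Drops excluded species, records outside the profile's seasonal month set,
#' and records outside the study years. Records with a missing month are kept
#' for all-month profiles (where season membership is irrelevant) and dropped
#' for seasonal profiles (where it is undecidable). For winter profiles,
#' December records are attributed to the winter of the following January, so
#' December of the final study year (whose winter ends outside the study
#' span) is dropped.
#'
#' @param records occurrence data.frame (`species`, `year`, optional `month`).
#' @param profile a [taxon_profile()].
#' @param years study year range.
#' @return filtered data.frame.
#' @export
filter_taxa <- function(records, profile, years = c(1990, 2019)) {
  keep <- !(records$species %in% profile$exclude)
  mo <- records$month
  if (identical(profile$season, "all")) {
    keep <- keep & (is.na(mo) | mo %in% profile$months)
  } else {
    keep <- keep & !is.na(mo) & mo %in% profile$months
  }
  eff_year <- records$year
  if (is_winter_profile(profile)) {
    eff_year <- eff_year + as.integer(!is.na(mo) & mo == 12L)
  }
  keep <- keep & eff_year >= years[1] & eff_year <= years[2]
  records[keep, , drop = FALSE]
}

#' Assign records to 5-year periods
#'
#' Each record receives the index of the period containing its year. For
#' winter profiles, December is grouped with the following January (one
#' biological winter) and assigned to that January's period.
#'
#' @param records occurrence data.frame (temporally filtered).
#' @param periods a [period_defs()] table.
#' @param profile optional [taxon_profile()]; only its winter convention is
#'   used.
#' @return `records` with a `period` column added.
#' @export
assign_periods <- function(records, periods = period_defs(), profile = NULL) {
  eff_year <- records$year
  if (is_winter_profile(profile)) {
    eff_year <- eff_year + as.integer(!is.na(records$month) &
                                        records$month == 12L)
  }
  i <- findInterval(eff_year, periods$start_year)
  bad <- i < 1L | eff_year > periods$end_year[pmax(i, 1L)]
  if (any(bad)) {
    stop(sprintf("%d record(s) fall outside all periods (years should be pre-filtered)",
                 sum(bad)))
  }
  records$period <- periods$index[i]
  records
}

# world cylindrical equal-area projection (authalic sphere), metres
cea_project <- function(lon, lat) {
  R <- 6371007.2
  list(x = R * lon * pi / 180, y = R * sin(lat * pi / 180))
}

#' Spatial thinning on a 5-km equal-area grid
#'
#' Within each (species, 5-km grid cell, period) group exactly one record is
#' retained, chosen uniformly at random with the given seed. The grid is
#' defined in the world cylindrical equal-area projection so that "5 km" is a
#' metric statement at all latitudes. Thinning a thinned table with the same
#' seed is the identity.
#'
#' @param records occurrence data.frame with `period` assigned.
#' @param cell_km thinning cell size (km).
#' @param seed RNG seed for the uniform tie-break.
#' @return thinned data.frame (original row order preserved).
#' @export
spatial_thin <- function(records, cell_km = 5, seed = 1) {
  if (nrow(records) == 0) return(records)
  if (is.null(records$period)) stop("records must carry a period column")
  p <- cea_project(records$lon, records$lat)
  cx <- floor(p$x / (cell_km * 1000))
  cy <- floor(p$y / (cell_km * 1000))
  key <- paste(records$species, cx, cy, records$period, sep = "\r")
  set.seed(seed)
  ord <- sample.int(nrow(records))
  keep <- ord[!duplicated(key[ord])]
  records[sort(keep), , drop = FALSE]
}

#' Data-characteristic summaries
#'
#' Reports how data quantity and provenance are distributed: records per
#' year, sliding windows containing data per year (when a window membership
#' table is supplied), and the proportion of records per provider in
#' decreasing order (top 10; missing providers are pooled as `"unknown"`).
#'
#' @param records occurrence data.frame (`year`, optional `provider`).
#' @param membership optional [assign_occurrences()] table used for the
#'   per-year window counts.
#' @param top number of provider ranks to keep.
#' @return list of data.frames: `occurrences_per_year`, `windows_per_year`
#'   (`NULL` without membership), `providers`.
#' @export
summarize_data <- function(records, membership = NULL, top = 10) {
  yr <- sort(unique(records$year))
  occ_per_year <- data.frame(year = yr,
                             n = as.integer(table(factor(records$year,
                                                         levels = yr))))
  windows_per_year <- NULL
  if (!is.null(membership)) {
    key <- unique(data.frame(year = records$year[membership$record],
                             window_id = membership$window_id))
    tab <- table(factor(key$year, levels = yr))
    windows_per_year <- data.frame(year = yr, n_windows = as.integer(tab))
  }
  prov <- records$provider
  if (is.null(prov)) prov <- rep(NA_character_, nrow(records))
  prov[is.na(prov)] <- "unknown"
  pt <- sort(table(prov), decreasing = TRUE)
  pt <- pt[seq_len(min(top, length(pt)))]
  providers <- data.frame(provider = names(pt),
                          proportion = as.numeric(pt) / nrow(records))
  list(occurrences_per_year = occ_per_year,
       windows_per_year = windows_per_year,
       providers = providers)
}

#' Read / write occurrence tables
#'
#' CSV interchange uses Darwin-Core-style column names
#' (`species,decimalLongitude,decimalLatitude,year,month,provider`); the
#' in-memory representation uses `lon`/`lat`.
#'
#' @param path CSV file path.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  nm[nm == "decimalLongitude"] <- "lon"
  nm[nm == "decimalLatitude"] <- "lat"
  names(df) <- nm
  req <- c("species", "lon", "lat", "year")
  if (!all(req %in% nm)) {
    stop("occurrence CSV must contain columns species, decimalLongitude/lon, decimalLatitude/lat, year")
  }
  if (is.null(df$month)) df$month <- NA_integer_
  if (is.null(df$provider)) df$provider <- NA_character_
  df
}

#' @rdname read_occurrences
#' @param records occurrence data.frame.
#' @export
write_occurrences <- function(records, path) {
  out <- records
  names(out)[names(out) == "lon"] <- "decimalLongitude"
  names(out)[names(out) == "lat"] <- "decimalLatitude"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
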