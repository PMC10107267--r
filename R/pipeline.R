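#' Run the occurrence-to-CTI pipeline on a synthetic world
#'
#' Executes the full analysis chain on a [simulate_world()] result:
#' coordinate cleaning, taxon filtering, period assignment, 5-km spatial
#' thinning, window construction on the 1-degree lattice, period climate
#' rasters for the profile's month set, temperature extraction, STI and CTI
#' computation, window climate covariates, and record-window membership.
#' The output feeds [fit_cti_time()], [fit_debt()], [turnover_events()] and
#' the sensitivity tools directly.
#'
#' @param world a [simulate_world()] result (or a list with `landscape` and
#'   `occurrences`).
#' @param profile a [taxon_profile()]; the synthetic taxon uses all months.
#' @param radius_km sliding-window radius.
#' @param thin_seed seed of the thinning tie-break.
#' @param min_species minimum species per assemblage.
#' @return list of class `cti_pipeline`: `records` (cleaned, thinned, with
#'   `period` and extracted `temp`), `windows`, `window_data` (windows plus
#'   climate covariates and total occurrence counts), `climate`
#'   (period rasters), `sti`, `assemblages`, `cti`, `membership`,
#'   `periods`, `removed` (cleaning report).
#' @export
run_cti_pipeline <- function(world,
                             profile = taxon_profile("synthetic", "all"),
                             radius_km = 200, thin_seed = 1,
                             min_species = 2) {
  cfg <- world$landscape$config
  periods <- period_defs(start = cfg$years[1],
                         n = ceiling(length(cfg$years) / 5))
  land_mask <- world$landscape$continent

  cleaned <- clean_coordinates(world$occurrences, bad_points = NULL,
                               land_mask = land_mask)
  rec <- filter_taxa(cleaned$records, profile,
                     years = range(cfg$years))
  rec <- assign_periods(rec, periods, profile)
  rec <- spatial_thin(rec, cell_km = 5, seed = thin_seed)
  rownames(rec) <- NULL

  windows <- build_windows(
    lon_range = cfg$lon_range,
    lat_range = cfg$window_lat_range,
    continent_map = world$landscape$continent,
    region_map = world$landscape$region,
    radius_km = radius_km)
  # keep the lattice away from continent edges so buffers are never
  # longitudinally truncated (see warming ramp notes in the generator)
  if (!is.null(cfg$window_lon_margin) && cfg$window_lon_margin > 0) {
    cw <- (diff(cfg$lon_range) - 2 * cfg$gap_half_width) / 2
    edges <- c(cfg$lon_range[1], cfg$lon_range[1] + cw,
               cfg$lon_range[2] - cw, cfg$lon_range[2])
    dist_edge <- apply(abs(outer(windows$lon, edges, "-")), 1, min)
    windows <- windows[dist_edge >= cfg$window_lon_margin - 1e-9, ,
                       drop = FALSE]
    windows$window_id <- seq_len(nrow(windows))
    rownames(windows) <- NULL
    attr(windows, "radius_km") <- radius_km
  }

  climate <- build_period_rasters(world$landscape$temp, profile$months,
                                  periods)
  rec$temp <- as.numeric(extract_temperature(rec, climate))
  sti <- compute_sti(rec, rec$temp)

  membership <- assign_occurrences(rec, windows, radius_km)
  assemblages <- build_assemblages(rec, membership)
  cti <- compute_cti(assemblages, sti, min_species = min_species,
                     periods = periods)

  wclim <- window_climate(windows, climate, world$landscape$hii, radius_km)
  tot <- tapply(cti$n_occ, cti$window_id, sum)
  window_data <- merge(windows, wclim, by = "window_id")
  window_data$n_occ_total <-
    as.integer(tot[as.character(window_data$window_id)])

  structure(list(records = rec, windows = windows,
                 window_data = window_data, climate = climate, sti = sti,
                 assemblages = assemblages, cti = cti,
                 membership = membership, periods = periods,
                 removed = cleaned$removed),
            class = "cti_pipeline")
}

#' @export
print.cti_pipeline <- function(x, ...) {
  cat(sprintf("<cti_pipeline> %d records, %d windows, %d species with STI, %d CTI values\n",
              nrow(x$records), nrow(x$windows), nrow(x$sti), nrow(x$cti)))
  invisible(x)
}

#' One-call debt analysis of a synthetic world
#'
#' Convenience wrapper used by the validation experiments: pipeline +
#' CTI-over-time fit + climatic-debt fit.
#'
#' @inheritParams run_cti_pipeline
#' @return list: `pipeline`, `trend_fit` ([fit_cti_time()]), `debt_fit`
#'   ([fit_debt()]).
#' @export
analyze_world <- function(world,
                          profile = taxon_profile("synthetic", "all"),
                          radius_km = 200, thin_seed = 1) {
  p <- run_cti_pipeline(world, profile, radius_km, thin_seed)
  tf <- fit_cti_time(p$cti, p$window_data)
  df <- fit_debt(tf, p$window_data)
  list(pipeline = p, trend_fit = tf, debt_fit = df)
}
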