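#' Species temperature index (STI)
#'
#' The STI of a species is the arithmetic mean of the temperatures extracted
#' at all of its cleaned, thinned occurrences (both continents pooled, all
#' periods): the average temperature experienced across its recorded range,
#' a proxy for its thermal adaptation. Species with no extractable
#' temperature are dropped (counted in the `"n_dropped"` attribute).
#'
#' @param records occurrence data.frame.
#' @param temperature vector of extracted temperatures, one per record (see
#'   [extract_temperature()]).
#' @return data.frame: `species`, `sti` (degC), `n_records`; attribute
#'   `n_dropped`.
#' @export
compute_sti <- function(records, temperature) {
  if (length(temperature) != nrow(records)) {
    stop("temperature must have one value per record")
  }
  ok <- !is.na(temperature)
  sp_all <- unique(records$species)
  f <- factor(records$species[ok])
  sti <- tapply(temperature[ok], f, mean)
  out <- data.frame(species = names(sti),
                    sti = as.numeric(sti),
                    n_records = as.integer(table(f)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out[order(out$species), , drop = FALSE],
            n_dropped = length(setdiff(sp_all, out$species)))
}

#' Community temperature index (CTI) per window and period
#'
#' The presence-only CTI of an assemblage is the unweighted arithmetic mean
#' of the STIs of the distinct species present (no abundance weighting).
#' A window x period record is produced only when at least `min_species`
#' species with an STI are present; each record carries the total thinned
#' occurrence count `n_occ` and the model weight `log(n_occ)` used by all
#' downstream fits.
#'
#' @param assemblages a [build_assemblages()] table.
#' @param sti a [compute_sti()] table.
#' @param min_species minimum number of STI-bearing species (default 2).
#' @param qualify `"period"` (default): a CTI exists for every window x
#'   period with `min_species` species, and a window is retained when at
#'   least one period qualifies. `"window"`: the species threshold is
#'   applied to the window's pooled species list instead, and CTIs are then
#'   computed for periods with at least 2 species.
#' @param periods a [period_defs()] table (supplies median years).
#' @return data.frame of class `cti_records`: `window_id`, `period`,
#'   `median_year`, `cti`, `n_species`, `n_occ`, `weight`.
#' @export
compute_cti <- function(assemblages, sti, min_species = 2,
                        qualify = c("period", "window"),
                        periods = period_defs()) {
  qualify <- match.arg(qualify)
  m <- merge(assemblages, sti[, c("species", "sti")], by = "species")
  key <- paste(m$window_id, m$period, sep = "\r")
  first <- !duplicated(key)
  agg <- data.frame(window_id = m$window_id[first],
                    period = m$period[first])
  idx <- match(key, key[first])
  agg$n_species <- tabulate(idx, nbins = sum(first))
  agg$n_occ <- as.integer(rowsum(m$n, idx)[, 1])
  agg$cti <- rowsum(m$sti, idx)[, 1] / agg$n_species
  if (qualify == "period") {
    agg <- agg[agg$n_species >= min_species, , drop = FALSE]
  } else {
    pooled <- tapply(m$species, m$window_id, function(s) length(unique(s)))
    ok_win <- as.integer(names(pooled))[pooled >= min_species]
    agg <- agg[agg$window_id %in% ok_win & agg$n_species >= 2, , drop = FALSE]
  }
  agg$median_year <- periods$median_year[match(agg$period, periods$index)]
  agg$weight <- log(agg$n_occ)
  out <- agg[order(agg$window_id, agg$period),
             c("window_id", "period", "median_year", "cti",
               "n_species", "n_occ", "weight")]
  rownames(out) <- NULL
  class(out) <- c("cti_records", "data.frame")
  out
}
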