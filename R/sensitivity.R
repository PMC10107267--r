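#' Data-quantity filtering of CTI records
#'
#' Keeps only sliding windows whose total thinned occurrence count (summed
#' over all periods) reaches `min_occurrences` and whose number of periods
#' with a CTI record reaches `min_periods`; all periods of surviving windows
#' are retained. The pair `(0, 1)` is the no-filtering baseline.
#'
#' @param cti a [compute_cti()] table.
#' @param min_occurrences minimum window total occurrence count.
#' @param min_periods minimum number of periods with a CTI record.
#' @return filtered `cti` table (same class), with dropped-window count in
#'   the `"n_dropped_windows"` attribute.
#' @export
filter_windows <- function(cti, min_occurrences = 0, min_periods = 1) {
  if (min_occurrences < 0 || min_periods < 0) stop("filter spec must be nonnegative")
  tot <- tapply(cti$n_occ, cti$window_id, sum)
  nper <- tapply(cti$period, cti$window_id, length)
  ok <- names(tot)[tot >= min_occurrences & nper >= min_periods]
  out <- cti[cti$window_id %in% as.integer(ok), , drop = FALSE]
  if (nrow(out) == 0) stop("filter removes all windows")
  attr(out, "n_dropped_windows") <-
    length(tot) - length(unique(out$window_id))
  out
}

#' Refit under a data filter and compare with the full fit
#'
#' Refits the CTI-over-time model for each taxon on the filtered records,
#' then quantifies estimate stability: the Pearson correlation between
#' filtered and full taxon-level time slopes (across taxa), and the
#' per-window absolute difference in local CTI trends for windows present
#' under both datasets (dropped windows are counted).
#'
#' @param fits named list of full [fit_cti_time()] objects, one per taxon.
#' @param min_occurrences,min_periods the filter spec.
#' @return An object of class `sensitivity_result`: `spec`, `taxon_slopes`
#'   (`taxon`, `slope_full`, `slope_filtered`), `pearson_r`, `deltas`
#'   (`taxon`, `window_id`, `abs_delta`), `n_dropped` per taxon.
#' @export
refit_and_compare <- function(fits, min_occurrences = 0, min_periods = 1) {
  if (is.null(names(fits))) names(fits) <- paste0("taxon", seq_along(fits))
  slopes <- deltas <- dropped <- list()
  for (tx in names(fits)) {
    f <- fits[[tx]]
    flt <- filter_windows(f$cti, min_occurrences, min_periods)
    ref <- fit_cti_time(flt, f$windows, center_year = f$center_year,
                        reml = f$reml)
    slopes[[tx]] <- data.frame(taxon = tx, slope_full = f$beta_year,
                               slope_filtered = ref$beta_year)
    common <- merge(f$local_trends, ref$local_trends, by = "window_id",
                    suffixes = c("_full", "_filtered"))
    deltas[[tx]] <- data.frame(taxon = tx, window_id = common$window_id,
                               abs_delta = abs(common$trend_filtered -
                                                 common$trend_full))
    dropped[[tx]] <- attr(flt, "n_dropped_windows")
  }
  slopes <- do.call(rbind, slopes)
  rownames(slopes) <- NULL
  r <- if (nrow(slopes) >= 2 &&
             stats::sd(slopes$slope_full) > 0 &&
             stats::sd(slopes$slope_filtered) > 0) {
    stats::cor(slopes$slope_full, slopes$slope_filtered)
  } else if (nrow(slopes) >= 2 &&
               isTRUE(all.equal(slopes$slope_full, slopes$slope_filtered))) {
    1
  } else NA_real_
  structure(list(spec = c(min_occurrences = min_occurrences,
                          min_periods = min_periods),
                 taxon_slopes = slopes, pearson_r = r,
                 deltas = do.call(rbind, deltas),
                 n_dropped = unlist(dropped)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity refit (min occurrences %d, min periods %d)\n",
              x$spec["min_occurrences"], x$spec["min_periods"]))
  cat(sprintf("  taxa: %d, Pearson r(full, filtered) = %.4f\n",
              nrow(x$taxon_slopes), x$pearson_r))
  cat(sprintf("  mean |delta local trend| = %.3g over %d windows\n",
              mean(x$deltas$abs_delta), nrow(x$deltas)))
  invisible(x)
}

#' Run the full data-quantity filter grid
#'
#' Applies [refit_and_compare()] over every combination of the occurrence
#' and period thresholds (the study grid is 50-150 occurrences by 2-5
#' periods, plus the (0, 1) baseline).
#'
#' @param fits named list of full [fit_cti_time()] objects.
#' @param min_occurrences,min_periods threshold grids.
#' @return list: `results` (one `sensitivity_result` per combination),
#'   `summary` (long data.frame of r per spec), `deltas` (long data.frame
#'   of per-window absolute trend differences).
#' @export
sensitivity_grid <- function(fits,
                             min_occurrences = c(50, 75, 100, 125, 150),
                             min_periods = 2:5) {
  grid <- expand.grid(min_occ = min_occurrences, min_per = min_periods,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  summ <- deltas <- list()
  for (i in seq_len(nrow(grid))) {
    res <- refit_and_compare(fits, grid$min_occ[i], grid$min_per[i])
    results[[i]] <- res
    summ[[i]] <- data.frame(min_occurrences = grid$min_occ[i],
                            min_periods = grid$min_per[i],
                            pearson_r = res$pearson_r)
    dd <- res$deltas
    dd$min_occurrences <- grid$min_occ[i]
    dd$min_periods <- grid$min_per[i]
    deltas[[i]] <- dd
  }
  list(results = results, summary = do.call(rbind, summ),
       deltas = do.call(rbind, deltas))
}

#' Three-way interaction test on trend differences
#'
#' Mixed model of the absolute difference in local CTI trends on taxon,
#' minimum occurrences and minimum periods (all as factors) with window
#' identity as a random intercept; the three-way interaction is tested by a
#' likelihood-ratio chi-square between ML fits with and without it.
#'
#' @param deltas long table with columns `taxon`, `window_id`,
#'   `min_occurrences`, `min_periods`, `abs_delta` (see
#'   [sensitivity_grid()]).
#' @return list: `chisq`, `df`, `p_value`, `model` (full ML fit),
#'   `anova` (the LRT table).
#' @export
fit_difference_model <- function(deltas) {
  d <- data.frame(abs_delta = deltas$abs_delta,
                  taxon = factor(deltas$taxon),
                  occ = factor(deltas$min_occurrences),
                  per = factor(deltas$min_periods),
                  window_id = factor(deltas$window_id))
  if (nlevels(d$taxon) < 2) stop("need at least two taxa")
  if (nlevels(d$occ) < 2 || nlevels(d$per) < 2) {
    stop("need at least two levels per filter factor")
  }
  cells <- table(d$taxon, d$occ, d$per)
  if (any(cells == 0)) {
    stop("rank-deficient design: empty taxon x occurrence x period cell(s)")
  }
  quiet <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
  }
  full <- quiet(lme4::lmer(abs_delta ~ taxon * occ * per + (1 | window_id),
                           data = d, REML = FALSE))
  red <- quiet(lme4::lmer(abs_delta ~ (taxon + occ + per)^2 + (1 | window_id),
                          data = d, REML = FALSE))
  an <- stats::anova(red, full)
  list(chisq = an$Chisq[2], df = an$Df[2], p_value = an$`Pr(>Chisq)`[2],
       model = full, anova = an)
}
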