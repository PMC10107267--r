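#' Species gained and lost between consecutive periods
#'
#' For every window and every pair of consecutive periods that both carry a
#' valid CTI record, compares the species sets (species with an STI, the
#' same sets that define the CTI) and emits one event per species gained
#' (absent at t-1, present at t) or lost (the reverse). Each event carries
#' its relative STI, `rSTI = STI - CTI(t-1)`: positive means the species is
#' warm-adapted relative to the assemblage it joins or leaves, negative
#' cold-adapted.
#'
#' @param cti a [compute_cti()] table (defines which window x period
#'   assemblages are valid and supplies `CTI(t-1)`).
#' @param assemblages a [build_assemblages()] table.
#' @param sti a [compute_sti()] table.
#' @return data.frame: `window_id`, `from_period`, `to_period`, `species`,
#'   `status` (`"gained"`/`"lost"`), `rsti`.
#' @export
turnover_events <- function(cti, assemblages, sti) {
  a <- assemblages[assemblages$species %in% sti$species, , drop = FALSE]
  cti_key <- paste(cti$window_id, cti$period)
  out <- list()
  for (w in unique(cti$window_id)) {
    pw <- sort(cti$period[cti$window_id == w])
    for (p in pw[-1]) {
      if (!((p - 1) %in% pw)) next
      s_prev <- a$species[a$window_id == w & a$period == p - 1]
      s_now <- a$species[a$window_id == w & a$period == p]
      gained <- setdiff(s_now, s_prev)
      lost <- setdiff(s_prev, s_now)
      if (length(gained) + length(lost) == 0) next
      cti_prev <- cti$cti[cti$window_id == w & cti$period == p - 1]
      sp <- c(gained, lost)
      out[[length(out) + 1]] <- data.frame(
        window_id = w, from_period = p - 1L, to_period = p,
        species = sp,
        status = rep(c("gained", "lost"),
                     c(length(gained), length(lost))),
        rsti = sti$sti[match(sp, sti$species)] - cti_prev,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(window_id = integer(), from_period = integer(),
                      to_period = integer(), species = character(),
                      status = character(), rsti = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Summarise turnover events
#'
#' Mean rSTI of gained and of lost species (events pooled across windows and
#' intervals by default, or window-level means averaged first), 95%
#' nonparametric bootstrap CIs over events, and the proportion of events
#' with positive rSTI per status. A status with no events yields missing
#' summary fields.
#'
#' @param events a [turnover_events()] table.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param pooled pool events across windows (default) or average
#'   window-level means first.
#' @return data.frame: `status`, `n_events`, `mean_rsti`, `lower`, `upper`,
#'   `prop_positive`.
#' @export
summarize_turnover <- function(events, n_boot = 1000, seed = 1,
                               pooled = TRUE) {
  set.seed(seed)
  one <- function(st) {
    e <- events[events$status == st, , drop = FALSE]
    if (nrow(e) == 0) {
      return(data.frame(status = st, n_events = 0L, mean_rsti = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        prop_positive = NA_real_))
    }
    vals <- if (pooled) e$rsti else
      as.numeric(tapply(e$rsti, e$window_id, mean))
    bm <- replicate(n_boot, mean(vals[sample.int(length(vals),
                                                 replace = TRUE)]))
    qs <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    data.frame(status = st, n_events = nrow(e), mean_rsti = mean(vals),
               lower = qs[1], upper = qs[2],
               prop_positive = mean(e$rsti > 0))
  }
  rbind(one("gained"), one("lost"))
}
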