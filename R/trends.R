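#' Fit the CTI-over-time mixed model
#'
#' Weighted linear mixed model of CTI against time, fitted separately per
#' taxon: fixed effects are the period median year (centred, continuous),
#' the continent, and the window's overall mean temperature; random effects
#' are a window-level intercept and year slope plus an ecoregion intercept
#' (crossed). Observations are weighted by `log(n_occ)`, the log of the
#' thinned occurrence count behind each CTI value, down-weighting poorly
#' sampled window x period combinations. The local CTI trend of a window is
#' the fixed year slope plus the window's random slope.
#'
#' If the crossed-random-effects fit fails, the documented fallback refits
#' with ecoregion as a fixed factor; the fallback is recorded in the fit
#' metadata.
#'
#' @param cti a [compute_cti()] table.
#' @param windows window covariate table carrying `window_id`, `continent`,
#'   `ecoregion` and `mean_temp` (see [window_climate()] /
#'   [run_cti_pipeline()]).
#' @param center_year year subtracted from median years before fitting
#'   (improves conditioning; does not change the slope).
#' @param reml fit by REML (default) or ML.
#' @return An object of class `cti_trend` with components `model` (the lme4
#'   fit), `beta` (fixed-effect table with Wald 95% CIs), `beta_year`,
#'   `se_year`, `ci_year`, `local_trends` (`window_id`, `trend`),
#'   `varcorr`, `n_obs`, `converged`, `fallback`, plus the inputs needed to
#'   refit under data filters.
#' @seealso [fit_debt()], [filter_windows()]
#' @export
fit_cti_time <- function(cti, windows, center_year = 2004.5, reml = TRUE) {
  d <- merge(as.data.frame(cti), windows, by = "window_id")
  if (length(unique(d$period)) < 2) {
    stop("CTI records cover a single period: the time slope is unidentifiable")
  }
  if (nrow(d) < 4 || length(unique(d$window_id)) < 2) {
    stop("need at least two windows and two periods to fit the model")
  }
  d$year_c <- d$median_year - center_year
  d$window_id <- factor(d$window_id)
  d$ecoregion <- factor(d$ecoregion)
  d$continent <- factor(d$continent)

  fixed <- "cti ~ year_c"
  if (!all(is.na(d$mean_temp)) && stats::sd(d$mean_temp, na.rm = TRUE) > 0) {
    fixed <- paste(fixed, "+ mean_temp")
  }
  if (nlevels(d$continent) > 1) fixed <- paste(fixed, "+ continent")
  use_eco <- nlevels(d$ecoregion) > 1
  form <- paste(fixed, "+ (year_c | window_id)",
                if (use_eco) "+ (1 | ecoregion)" else "")

  msgs <- character()
  fit_one <- function(f) {
    withCallingHandlers(
      lme4::lmer(stats::as.formula(f), data = d, weights = d$weight,
                 REML = reml),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
  }
  fallback <- NA_character_
  model <- tryCatch(fit_one(form), error = function(e) e)
  if (inherits(model, "error")) {
    fallback <- "ecoregion_fixed"
    msgs <- c(msgs, paste("primary fit failed:",
                          conditionMessage(model)))
    form <- paste(fixed, if (use_eco) "+ ecoregion" else "",
                  "+ (year_c | window_id)")
    model <- fit_one(form)
  }

  b <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  beta <- data.frame(term = names(b), estimate = as.numeric(b), se = se,
                     lower = as.numeric(b) - z * se,
                     upper = as.numeric(b) + z * se, row.names = NULL)
  re <- lme4::ranef(model)$window_id
  lt <- data.frame(window_id = as.integer(rownames(re)),
                   trend = b[["year_c"]] + re[["year_c"]])
  lt <- lt[order(lt$window_id), , drop = FALSE]
  rownames(lt) <- NULL

  structure(list(
    model = model, formula = form, beta = beta,
    beta_year = b[["year_c"]], se_year = se[["year_c"]],
    ci_year = c(lower = beta$lower[beta$term == "year_c"],
                upper = beta$upper[beta$term == "year_c"]),
    local_trends = lt,
    varcorr = as.data.frame(lme4::VarCorr(model)),
    n_obs = nrow(d), n_windows = nlevels(d$window_id),
    converged = length(msgs) == 0, messages = msgs, fallback = fallback,
    center_year = center_year, reml = reml,
    cti = cti, windows = windows
  ), class = "cti_trend")
}

#' @export
print.cti_trend <- function(x, ...) {
  cat("Community temperature index trend (weighted LMM)\n")
  cat(sprintf("  %d CTI values, %d windows%s\n", x$n_obs, x$n_windows,
              if (!is.na(x$fallback)) paste0(" [fallback: ", x$fallback, "]")
              else ""))
  cat(sprintf("  CTI trend: %.4f degC/yr  (95%% CI %.4f to %.4f)\n",
              x$beta_year, x$ci_year["lower"], x$ci_year["upper"]))
  invisible(x)
}

#' @export
summary.cti_trend <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  print(object$beta, digits = 4)
  cat("\nVariance components:\n")
  print(object$varcorr[, c("grp", "var1", "var2", "sdcor")], digits = 4)
  invisible(object)
}

#' @export
coef.cti_trend <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
confint.cti_trend <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$beta$estimate - z * object$beta$se,
               object$beta$estimate + z * object$beta$se)
  dimnames(out) <- list(object$beta$term,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.cti_trend <- function(object, ...) stats::fitted(object$model)

#' @export
residuals.cti_trend <- function(object, ...) stats::residuals(object$model)

#' @export
plot.cti_trend <- function(x, ...) {
  d <- merge(as.data.frame(x$cti), x$windows, by = "window_id")
  graphics::plot(d$median_year, d$cti, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "period median year",
                 ylab = "CTI (degC)", ...)
  for (w in unique(d$window_id)) {
    i <- d$window_id == w
    graphics::lines(d$median_year[i], d$cti[i], col = "grey80")
  }
  mid <- mean(range(d$cti))
  xs <- range(d$median_year)
  ys <- mid + x$beta_year * (xs - mean(xs))
  graphics::lines(xs, ys, lwd = 2, col = "firebrick")
  invisible(x)
}

#' Fit the climatic-debt model
#'
#' Models the local temporal CTI trend of each window (fixed year slope plus
#' window random slope from [fit_cti_time()]) as a function of the local
#' temperature trend, in interaction with the window's average temperature
#' (centred at its observed mean) and with the human influence index, plus a
#' continent covariate and an ecoregion random intercept. Windows are
#' weighted by the log of their total occurrence count. A slope of 1 between
#' CTI trend and temperature trend means communities track temperature
#' change perfectly; a slope below 1 is the climatic debt.
#'
#' @param trends local-trend table (`window_id`, `trend`), typically
#'   `fit$local_trends`, or a `cti_trend` object.
#' @param window_data per-window covariates: `window_id`, `temp_trend`,
#'   `mean_temp`, `hii`, `continent`, `ecoregion`, `n_occ_total` (see
#'   [run_cti_pipeline()]).
#' @param hii_probs quantile levels of observed HII at which marginal
#'   slopes are evaluated.
#' @param reml fit by REML (default) or ML.
#' @return An object of class `debt_fit`: `model`, `beta` (fixed effects
#'   with Wald CIs), `vcov`, `marginal` (slope, SE and 95% CI at each HII
#'   quantile, mean temperature held at its mean), `hii_quantiles`,
#'   `hii_range`, `n_windows`, `converged`, `fallback`.
#' @export
fit_debt <- function(trends, window_data, hii_probs = c(0.25, 0.5, 0.75),
                     reml = TRUE) {
  if (inherits(trends, "cti_trend")) trends <- trends$local_trends
  d <- merge(trends, window_data, by = "window_id")
  d <- d[!is.na(d$temp_trend) & !is.na(d$hii) & !is.na(d$mean_temp), ,
         drop = FALSE]
  if (nrow(d) < 5) stop("too few windows with defined trends for the debt model")
  if (stats::sd(d$temp_trend) == 0) {
    stop("degenerate design: temp_trend is constant across windows")
  }
  if (stats::sd(d$hii) == 0) {
    stop("degenerate design: hii is constant across windows")
  }
  d$mtc <- d$mean_temp - mean(d$mean_temp)
  d$w <- log(d$n_occ_total)
  d$ecoregion <- factor(d$ecoregion)
  d$continent <- factor(d$continent)

  fixed <- "trend ~ temp_trend * mtc + temp_trend * hii"
  if (nlevels(d$continent) > 1) fixed <- paste(fixed, "+ continent")
  use_eco <- nlevels(d$ecoregion) > 1

  msgs <- character()
  fallback <- NA_character_
  fit_lmm <- function() {
    withCallingHandlers(
      lme4::lmer(stats::as.formula(paste(fixed, "+ (1 | ecoregion)")),
                 data = d, weights = d$w, REML = reml),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
  }
  if (use_eco) {
    model <- tryCatch(fit_lmm(), error = function(e) e)
    if (inherits(model, "error")) {
      fallback <- "ecoregion_fixed"
      msgs <- c(msgs, paste("primary fit failed:", conditionMessage(model)))
      model <- stats::lm(stats::as.formula(paste(fixed, "+ ecoregion")),
                         data = d, weights = d$w)
    }
  } else {
    fallback <- "no_ecoregion"
    model <- stats::lm(stats::as.formula(fixed), data = d, weights = d$w)
  }

  if (inherits(model, "lmerMod")) {
    b <- lme4::fixef(model)
    V <- as.matrix(stats::vcov(model))
  } else {
    b <- stats::coef(model)
    V <- stats::vcov(model)
  }
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  beta <- data.frame(term = names(b), estimate = as.numeric(b), se = se,
                     lower = as.numeric(b) - z * se,
                     upper = as.numeric(b) + z * se, row.names = NULL)

  obj <- structure(list(
    model = model, beta = beta, vcov = V,
    hii_quantiles = stats::quantile(d$hii, hii_probs),
    hii_range = range(d$hii),
    n_windows = nrow(d), data = d,
    converged = length(msgs) == 0, messages = msgs, fallback = fallback
  ), class = "debt_fit")
  obj$marginal <- marginal_slopes(obj, obj$hii_quantiles)
  obj
}

#' Marginal CTI-trend slopes at chosen human-influence values
#'
#' Linear-combination estimates of the slope of CTI trend on temperature
#' trend, evaluated at given HII values with mean temperature held at its
#' observed mean (so only the HII interaction moves the slope). Wald CIs
#' come from the coefficient covariance.
#'
#' @param object a [fit_debt()] result.
#' @param hii HII values at which to evaluate the slope.
#' @param mean_temp_c centred mean-temperature value (default 0 = observed
#'   mean).
#' @return data.frame: `hii`, `slope`, `se`, `lower`, `upper`.
#' @export
marginal_slopes <- function(object, hii, mean_temp_c = 0) {
  if (any(hii < object$hii_range[1] - 1e-9 |
            hii > object$hii_range[2] + 1e-9)) {
    warning("some HII values lie outside the observed range")
  }
  b <- stats::setNames(object$beta$estimate, object$beta$term)
  V <- object$vcov
  z <- stats::qnorm(0.975)
  out <- lapply(hii, function(h) {
    a <- stats::setNames(numeric(length(b)), names(b))
    a["temp_trend"] <- 1
    if ("temp_trend:mtc" %in% names(a)) a["temp_trend:mtc"] <- mean_temp_c
    if ("temp_trend:hii" %in% names(a)) a["temp_trend:hii"] <- h
    est <- sum(a * b)
    v <- drop(t(a) %*% V %*% a)
    data.frame(hii = h, slope = est, se = sqrt(v),
               lower = est - z * sqrt(v), upper = est + z * sqrt(v))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.debt_fit <- function(x, ...) {
  cat("Climatic-debt model (local CTI trend ~ local temperature trend)\n")
  cat(sprintf("  %d windows%s\n", x$n_windows,
              if (!is.na(x$fallback)) paste0(" [fallback: ", x$fallback, "]")
              else ""))
  m <- x$marginal
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  slope at HII %.1f: %.3f  (95%% CI %.3f to %.3f)\n",
                m$hii[i], m$slope[i], m$lower[i], m$upper[i]))
  }
  invisible(x)
}

#' @export
summary.debt_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(object$beta, digits = 4)
  invisible(object)
}

#' @export
coef.debt_fit <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
confint.debt_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$beta$estimate - z * object$beta$se,
               object$beta$estimate + z * object$beta$se)
  dimnames(out) <- list(object$beta$term,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.debt_fit <- function(object, ...) stats::fitted(object$model)

#' @export
residuals.debt_fit <- function(object, ...) stats::residuals(object$model)

#' @export
plot.debt_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$temp_trend, d$trend, pch = 16, cex = 0.6,
                 xlab = "temperature trend (degC/yr)",
                 ylab = "CTI trend (degC/yr)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  s <- x$marginal$slope[which.min(abs(x$marginal$hii - x$hii_quantiles[2]))]
  graphics::abline(stats::median(d$trend) - s * stats::median(d$temp_trend),
                   s, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Random-effects meta-analysis across taxa
#'
#' Pools per-taxon estimates (e.g. CTI time slopes, or marginal debt slopes
#' at a given HII level) by DerSimonian-Laird random-effects meta-analysis:
#' between-taxon variance tau^2 from the Q statistic, inverse-variance
#' weights `1 / (SE^2 + tau^2)`, Wald 95% CI. With a single estimate the
#' estimate and its own CI are returned, flagged.
#'
#' @param estimates per-taxon point estimates.
#' @param ses matching standard errors (> 0).
#' @param labels optional taxon labels.
#' @return An object of class `cti_meta`: `estimate`, `se`, `ci`, `tau2`,
#'   `k`, `single` flag, and the underlying `metafor::rma` object (when
#'   `k >= 2`).
#' @export
meta_analyze <- function(estimates, ses, labels = NULL) {
  if (length(estimates) != length(ses)) stop("estimates and ses differ in length")
  if (any(ses <= 0)) stop("standard errors must be > 0")
  k <- length(estimates)
  z <- stats::qnorm(0.975)
  if (k == 1) {
    return(structure(list(estimate = estimates, se = ses,
                          ci = c(lower = estimates - z * ses,
                                 upper = estimates + z * ses),
                          tau2 = 0, k = 1L, single = TRUE, rma = NULL,
                          labels = labels), class = "cti_meta"))
  }
  fit <- metafor::rma(yi = estimates, sei = ses, method = "DL")
  structure(list(estimate = as.numeric(fit$b), se = fit$se,
                 ci = c(lower = fit$ci.lb, upper = fit$ci.ub),
                 tau2 = fit$tau2, k = k, single = FALSE, rma = fit,
                 labels = labels), class = "cti_meta")
}

#' @export
print.cti_meta <- function(x, ...) {
  cat(sprintf("Meta-analytic mean (DerSimonian-Laird, k = %d%s)\n", x$k,
              if (x$single) ", single estimate" else ""))
  cat(sprintf("  estimate %.4f  (95%% CI %.4f to %.4f), tau^2 = %.3g\n",
              x$estimate, x$ci["lower"], x$ci["upper"], x$tau2))
  invisible(x)
}
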