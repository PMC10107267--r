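# synthetic CTI tables with known structure, for direct model checks
make_cti_data <- function(n_win = 20, slope = 0.01, slope_sd = 0,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  pd <- period_defs()
  slopes <- rnorm(n_win, slope, slope_sd)
  cti <- expand.grid(window_id = seq_len(n_win), period = pd$index)
  cti$median_year <- pd$median_year[cti$period + 1]
  cti$cti <- 10 + slopes[cti$window_id] * (cti$median_year - 2004.5) +
    rnorm(nrow(cti), 0, noise_sd)
  cti$n_species <- 5L
  cti$n_occ <- 50L
  cti$weight <- log(50)
  windows <- data.frame(window_id = seq_len(n_win),
                        lon = seq_len(n_win), lat = 45,
                        continent = "west",
                        ecoregion = rep(c("e1", "e2", "e3", "e4"),
                                        length.out = n_win),
                        mean_temp = 10 + 0.1 * seq_len(n_win))
  list(cti = cti, windows = windows, slopes = slopes)
}

test_that("a noiseless common slope is recovered exactly", {
  d <- make_cti_data(slope = 0.01)
  fit <- fit_cti_time(d$cti, d$windows)
  expect_equal(fit$beta_year, 0.01, tolerance = 1e-6)
  vc <- fit$varcorr
  slope_var <- vc$vcov[vc$grp == "window_id" & !is.na(vc$var1) &
                         vc$var1 == "year_c" & is.na(vc$var2)]
  expect_lt(slope_var, 1e-8)
  expect_equal(nrow(fit$local_trends), 20)
  expect_lt(max(abs(fit$local_trends$trend - 0.01)), 1e-4)
})

test_that("single-period data cannot identify a time slope", {
  d <- make_cti_data()
  expect_error(fit_cti_time(d$cti[d$cti$period == 2, ], d$windows),
               "single period")
})

test_that("the Wald CI for the time slope has near-nominal coverage", {
  hits <- 0L
  for (i in 1:100) {
    d <- make_cti_data(n_win = 50, slope = 0.01, slope_sd = 0.005,
                       noise_sd = 0.05, seed = 1000 + i)
    fit <- fit_cti_time(d$cti, d$windows)
    hits <- hits + (fit$ci_year["lower"] <= 0.01 &
                      fit$ci_year["upper"] >= 0.01)
  }
  expect_gte(hits, 93L)
})

test_that("rescaling all weights leaves the fixed effects unchanged", {
  d <- make_cti_data(n_win = 30, slope_sd = 0.004, noise_sd = 0.05,
                     seed = 5)
  f1 <- fit_cti_time(d$cti, d$windows)
  d2 <- d$cti; d2$weight <- d2$weight * 7
  f2 <- fit_cti_time(d2, d$windows)
  # invariance holds at the REML optimum; comparison is to optimiser
  # tolerance, not machine precision
  expect_equal(coef(f1), coef(f2), tolerance = 1e-2)
  expect_equal(f1$local_trends$trend, f2$local_trends$trend,
               tolerance = 1e-3)
})

test_that("local trends are consistent with the fixed slope", {
  a <- cached_compact(1)
  fit <- a$trend_fit
  expect_lt(abs(mean(fit$local_trends$trend) - fit$beta_year), 2e-3)
})

test_that("the debt slope is null when CTI trends ignore temperature", {
  set.seed(8)
  n <- 60
  wd <- data.frame(window_id = 1:n, temp_trend = runif(n, 0, 0.04),
                   mean_temp = rnorm(n, 10), hii = runif(n, 0, 40),
                   continent = rep(c("west", "east"), n / 2),
                   ecoregion = rep(sprintf("e%d", 1:6), 10),
                   n_occ_total = 100L)
  trends <- data.frame(window_id = 1:n, trend = rnorm(n, 0, 0.005))
  fit <- fit_debt(trends, wd)
  m <- fit$marginal
  expect_lt(abs(m$slope[2]), 0.2)
  expect_true(m$lower[2] < 0 & m$upper[2] > 0)
})

test_that("degenerate debt designs fail with a named culprit", {
  wd <- data.frame(window_id = 1:10, temp_trend = 0.02,
                   mean_temp = rnorm(10, 10), hii = runif(10, 0, 40),
                   continent = "west", ecoregion = rep(c("a", "b"), 5),
                   n_occ_total = 50L)
  trends <- data.frame(window_id = 1:10, trend = rnorm(10, 0, 0.01))
  expect_error(fit_debt(trends, wd), "temp_trend")
  wd$temp_trend <- runif(10, 0, 0.04); wd$hii <- 5
  expect_error(fit_debt(trends, wd), "hii")
})

test_that("marginal slopes are the stated linear combinations", {
  terms <- c("(Intercept)", "temp_trend", "mtc", "hii",
             "temp_trend:mtc", "temp_trend:hii")
  beta <- data.frame(term = terms,
                     estimate = c(0, 0.1, 0, 0, 0, 0.02),
                     se = 0.01, lower = 0, upper = 0)
  V <- diag(1e-4, 6); dimnames(V) <- list(terms, terms)
  fake <- structure(list(beta = beta, vcov = V, hii_range = c(0, 64)),
                    class = "debt_fit")
  m <- marginal_slopes(fake, hii = 5)
  expect_equal(m$slope, 0.1 + 0.02 * 5)

  # no interaction: identical slopes at all HII values
  beta0 <- beta; beta0$estimate[6] <- 0
  fake0 <- structure(list(beta = beta0, vcov = V, hii_range = c(0, 64)),
                     class = "debt_fit")
  m0 <- marginal_slopes(fake0, hii = c(0, 20, 60))
  expect_equal(length(unique(m0$slope)), 1L)

  expect_warning(marginal_slopes(fake, hii = 100), "outside")
})

test_that("marginal-slope variance matches Monte-Carlo coefficient resampling", {
  skip_if_not_installed("MASS")
  terms <- c("(Intercept)", "temp_trend", "mtc", "hii",
             "temp_trend:mtc", "temp_trend:hii")
  set.seed(13)
  A <- matrix(rnorm(36), 6); V <- crossprod(A) * 1e-4
  dimnames(V) <- list(terms, terms)
  beta <- data.frame(term = terms, estimate = rnorm(6, 0, 0.1),
                     se = sqrt(diag(V)), lower = 0, upper = 0)
  fake <- structure(list(beta = beta, vcov = V, hii_range = c(0, 64)),
                    class = "debt_fit")
  h <- 12
  m <- marginal_slopes(fake, h)
  draws <- MASS::mvrnorm(1e5, beta$estimate, V)
  mc <- draws[, 2] + draws[, 6] * h
  expect_equal(m$slope, mean(mc), tolerance = 0.02 * m$se / abs(m$slope + 1e-9) + 0.01)
  expect_equal(m$se, sd(mc), tolerance = 0.02)
})

test_that("meta-analysis pools as DerSimonian-Laird prescribes", {
  # homogeneous estimates: pooled value, zero heterogeneity
  m0 <- meta_analyze(rep(0.01, 3), rep(0.002, 3))
  expect_equal(m0$estimate, 0.01, tolerance = 1e-12)
  expect_equal(m0$tau2, 0)

  # hand-computed DL oracle on a heterogeneous triple
  y <- c(0.02, 0.01, 0.00); se <- rep(0.001, 3)
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se_pooled <- sqrt(1 / sum(wstar))
  m <- meta_analyze(y, se)
  expect_equal(m$estimate, pooled, tolerance = 1e-10)
  expect_equal(m$tau2, tau2, tolerance = 1e-10)
  expect_equal(m$se, se_pooled, tolerance = 1e-10)
  expect_equal(unname(m$ci["lower"]), pooled - qnorm(0.975) * se_pooled,
               tolerance = 1e-10)

  # single estimate: returned as-is, flagged
  m1 <- meta_analyze(0.005, 0.002)
  expect_true(m1$single)
  expect_equal(m1$estimate, 0.005)
  expect_equal(unname(m1$ci["lower"]), 0.005 - qnorm(0.975) * 0.002)

  expect_error(meta_analyze(c(1, 2), c(0.1, 0)), "standard errors")
})

test_that("model objects expose the standard S3 surface", {
  d <- make_cti_data(n_win = 15, slope_sd = 0.003, noise_sd = 0.04,
                     seed = 3)
  fit <- fit_cti_time(d$cti, d$windows)
  expect_s3_class(fit, "cti_trend")
  expect_named(coef(fit))
  expect_true("year_c" %in% rownames(confint(fit)))
  expect_length(residuals(fit), nrow(d$cti))
  expect_length(fitted(fit), nrow(d$cti))
  expect_output(print(fit), "CTI trend")
  expect_output(summary(fit), "Variance components")

  a <- cached_compact(1)
  expect_s3_class(a$debt_fit, "debt_fit")
  expect_output(print(a$debt_fit), "slope at HII")
  expect_equal(nrow(a$debt_fit$marginal), 3)
  pdf(NULL); plot(a$trend_fit); plot(a$debt_fit); dev.off()
})
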