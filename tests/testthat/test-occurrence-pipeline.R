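make_records <- function(lon, lat, species = "sp1", year = 2000,
                         month = 6, provider = NA_character_) {
  data.frame(species = species, lon = lon, lat = lat, year = year,
             month = month, provider = provider,
             stringsAsFactors = FALSE)
}

# land mask covering lon/lat [-5, 5] including the (0, 0) cell
test_mask <- function() flat_maps(c(-5, 5), c(-5, 5), label = TRUE)

test_that("coordinate cleaning removes the canonical error classes", {
  recs <- make_records(
    lon = c(0,   3,    3,    2,      2.3, -20),
    lat = c(0,   3,    1,    4.5,    1.2,  0.5))
  # rules: (0,0); lat == lon; capital centroid at (2, 4.5); off-mask point
  caps <- data.frame(lon = 2, lat = 4.5)
  out <- clean_coordinates(recs, bad_points = caps, land_mask = test_mask(),
                           radius_km = 1)
  expect_equal(out$records$lon, c(3, 2.3))       # only untouched records
  expect_equal(unname(out$removed["zero_zero"]), 1L)
  expect_equal(unname(out$removed["equal_lat_lon"]), 2L)  # (0,0) and (3,3)
  expect_equal(unname(out$removed["centroid"]), 1L)
  expect_gte(unname(out$removed["sea"]), 1L)

  # survivor set equals input minus the union of individually flagged sets
  flag_zero <- recs$lon == 0 & recs$lat == 0
  flag_eq <- recs$lon == recs$lat
  flag_cap <- geosphere::distHaversine(cbind(recs$lon, recs$lat),
                                       c(2, 4.5)) <= 1000
  flag_sea <- is.na(grid_value_at(test_mask(), recs$lon, recs$lat))
  expect_equal(out$records,
               recs[!(flag_zero | flag_eq | flag_cap | flag_sea), ])
})

test_that("cleaning requires a land mask and passes empty input through", {
  expect_error(clean_coordinates(make_records(1, 1)), "land mask")
  out <- clean_coordinates(make_records(1, 1)[0, ], land_mask = test_mask())
  expect_equal(nrow(out$records), 0)
})

test_that("taxon filtering drops excluded species, off-season months and years", {
  recs <- rbind(
    make_records(1, 1, "Rattus norvegicus", 2005, 6),
    make_records(1, 1, "sp_a", 2005, 11),
    make_records(1, 1, "sp_b", 2005, 5),
    make_records(1, 1, "sp_c", 1989, 6),
    make_records(1, 1, "sp_d", 2005, NA))
  rodents <- taxon_profile("rodents", "all",
                           exclude = c("Rattus norvegicus", "Mus musculus"))
  out <- filter_taxa(recs, rodents)
  expect_false("Rattus norvegicus" %in% out$species)
  expect_true(all(c("sp_a", "sp_b", "sp_d") %in% out$species))  # all months
  expect_false("sp_c" %in% out$species)                         # 1989

  butterflies <- taxon_profile("butterflies", "summer")
  out2 <- filter_taxa(recs[-1, ], butterflies)
  expect_equal(out2$species, "sp_b")   # month 11 and missing month dropped

  # winter profile: December belongs to the following January's winter
  wrecs <- rbind(make_records(1, 1, "w1", 1989, 12),
                 make_records(1, 1, "w2", 2019, 12),
                 make_records(1, 1, "w3", 2005, 1))
  winter <- taxon_profile("winter birds", "winter")
  out3 <- filter_taxa(wrecs, winter)
  expect_setequal(out3$species, c("w1", "w3"))  # Dec 2019 has no study winter
})

test_that("period assignment follows containment and the winter convention", {
  pd <- period_defs()
  expect_equal(pd$median_year, c(1992, 1997, 2002, 2007, 2012, 2017))
  recs <- rbind(make_records(1, 1, "a", 1993, 6),
                make_records(1, 1, "b", 2019, 6))
  out <- assign_periods(recs, pd)
  expect_equal(out$period, c(0L, 5L))

  wrec <- make_records(1, 1, "w", 1994, 12)
  outw <- assign_periods(wrec, pd, profile = taxon_profile("wb", "winter"))
  expect_equal(outw$period, 1L)   # grouped with January 1995

  expect_error(assign_periods(make_records(1, 1, year = 1980), pd),
               "outside")
})

test_that("spatial thinning keeps one record per species, 5-km cell and period", {
  base <- make_records(lon = rep(2.0001, 3), lat = rep(1.0001, 3))
  base$period <- 0L
  expect_equal(nrow(spatial_thin(base, seed = 1)), 1)

  two_sp <- base[1:2, ]; two_sp$species <- c("sp1", "sp2")
  expect_equal(nrow(spatial_thin(two_sp, seed = 1)), 2)

  two_per <- base[1:2, ]; two_per$period <- c(0L, 1L)
  expect_equal(nrow(spatial_thin(two_per, seed = 1)), 2)
})

test_that("thinning is idempotent, seeded and exhaustive on a synthetic table", {
  a <- cached_compact(1)
  rec <- a$world$occurrences
  rec <- assign_periods(rec, period_defs())
  th1 <- spatial_thin(rec, seed = 7)
  expect_lt(nrow(th1), nrow(rec))
  expect_identical(spatial_thin(th1, seed = 7), th1)       # idempotence
  expect_identical(spatial_thin(rec, seed = 7), th1)       # determinism

  # exhaustive count bound: <= 1 record per (species, cell, period)
  p <- ctidebt:::cea_project(th1$lon, th1$lat)
  key <- paste(th1$species, floor(p$x / 5000), floor(p$y / 5000),
               th1$period)
  expect_lte(max(table(key)), 1L)
})

test_that("data summaries report counts and ranked provider proportions", {
  recs <- make_records(lon = runif(100), lat = runif(100),
                       species = "s", year = 1995)
  recs$provider <- c(rep(NA, 50), rep("A", 30), rep("B", 20))
  s <- summarize_data(recs)
  expect_equal(s$occurrences_per_year$year, 1995)
  expect_equal(s$occurrences_per_year$n, 100)
  expect_equal(s$providers$provider[1], "unknown")
  expect_equal(s$providers$proportion, c(0.5, 0.3, 0.2))
  expect_lte(sum(s$providers$proportion), 1 + 1e-12)

  recs2 <- make_records(lon = runif(100), lat = runif(100), year = 1995)
  recs2$provider <- rep(c("A", "B"), c(60, 40))
  s2 <- summarize_data(recs2)
  expect_equal(s2$providers$provider, c("A", "B"))
  expect_equal(s2$providers$proportion, c(0.6, 0.4))

  # with a membership table: windows containing data, per year
  recs3 <- make_records(lon = c(1, 1, 2), lat = c(1, 1, 2),
                        year = c(1995, 1996, 1995))
  memb <- data.frame(record = c(1L, 2L, 3L, 3L), window_id = c(1L, 1L, 1L, 2L))
  s3 <- summarize_data(recs3, membership = memb)
  expect_equal(s3$windows_per_year$n_windows,
               c(2L, 1L))                    # 1995: windows 1+2; 1996: window 1
})

test_that("occurrence CSV round-trips through Darwin-Core column names", {
  recs <- make_records(c(1, 2), c(3, 4), c("a", "b"), c(1999, 2005))
  path <- tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  header <- readLines(path, n = 1)
  expect_match(header, "decimalLongitude")
  back <- read_occurrences(path)
  expect_equal(back$lon, recs$lon)
  expect_equal(back$species, recs$species)
  unlink(path)
})
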