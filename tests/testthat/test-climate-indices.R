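toy_year <- function(tmean = NULL, precip = NULL, tmin = NULL, tmax = NULL,
                     year = 2001) {
  cal <- calendar_frame(year, 1, "standard")
  n <- nrow(cal)
  rep_or <- function(x) if (is.null(x)) NULL else rep_len(x, n)
  daily_series(cal$year, cal$month, cal$day, tmean = rep_or(tmean),
               tmin = rep_or(tmin), tmax = rep_or(tmax),
               precip = rep_or(precip))
}

test_that("diurnal temperature range averages tmax - tmin per season", {
  s <- toy_year(tmean = 10, tmin = 6, tmax = 14)
  expect_equal(diurnal_temperature_range(s), 8)
  expect_equal(diurnal_temperature_range(s, "JJA"), 8)
  s2 <- toy_year(tmean = 10, tmin = 10, tmax = 10)
  expect_equal(diurnal_temperature_range(s2), 0)
  obs <- gen_station_obs(climate_spec(seed = 44, n_years = 1))
  jja <- obs$month %in% 6:8
  expect_equal(diurnal_temperature_range(obs, "JJA"),
               mean(obs$tmax[jja] - obs$tmin[jja]), tolerance = 1e-12)
})

test_that("day counts use strict comparisons and per-year bookkeeping", {
  v <- c(0.05, 0.2, 1.5, 0, 12, 0.1, 3, 0.9, 0, 25)
  yrs <- rep(2000, 10)
  expect_equal(count_days(v, yrs, ">", 0.1)$mean, 6)   # 0.1 itself excluded
  expect_equal(count_days(v, yrs, ">", 1)$mean, 4)
  expect_equal(count_days(v, yrs, ">", 10)$mean, 2)
  frost <- toy_year(tmean = -3, tmin = -5, tmax = 0)
  expect_equal(count_days(frost$tmin, frost$year, "<", 0)$mean, 365)
  dry <- toy_year(precip = 0)
  expect_equal(count_days(dry$precip, dry$year, ">", 0.1)$mean, 0)
})

test_that("Rx1day takes monthly maxima and averages them over the period", {
  s <- toy_year(precip = 2)
  expect_equal(rx1day(s$precip, s$year, s$month)$mean, 2)
  p <- rep(0, 365); p[32] <- 30           # one 30 mm day in February
  s2 <- toy_year(precip = p)
  r <- rx1day(s2$precip, s2$year, s2$month)
  expect_equal(sort(unname(r$per_month), decreasing = TRUE), c(30, rep(0, 11)))
  expect_equal(r$mean, 2.5)
  expect_equal(rx1day(s2$precip, s2$year, s2$month, "annual_max")$mean, 30)
})

test_that("dry and wet spells truncate at year boundaries and match a scan oracle", {
  # 7-day toy pattern D D W W W D D embedded in a dry year
  p <- rep(0, 365)
  p[3:5] <- 2
  s <- toy_year(precip = p)
  expect_equal(max_spell(s$precip, s$year, "wet")$mean, 3)
  expect_equal(max_spell(s$precip, s$year, "dry")$mean, 360)
  dryyear <- toy_year(precip = 0)
  expect_equal(max_spell(dryyear$precip, dryyear$year, "dry")$mean, 365)
  expect_equal(max_spell(dryyear$precip, dryyear$year, "wet")$mean, 0)
  alt <- toy_year(precip = rep(c(0, 2), length.out = 365))
  expect_equal(max_spell(alt$precip, alt$year, "wet")$mean, 1)
  expect_equal(max_spell(alt$precip, alt$year, "dry")$mean, 1)
})

test_that("growing season length follows the warm-span/cold-span rule", {
  expect_equal(growing_season_length(toy_year(tmean = 10))$mean, 365)
  expect_equal(growing_season_length(toy_year(tmean = 0))$mean, 0)
  tm <- rep(0, 365)
  tm[100:289] <- 10          # warm span starts day 100; cold span starts day 290
  s <- toy_year(tmean = tm)
  expect_equal(growing_season_length(s)$mean, 190)
})

test_that("PRCPTOT and annual extremes match explicit sums and extremes", {
  s <- toy_year(precip = 2)
  expect_equal(prcptot(s$precip, s$year)$mean, 730)
  expect_equal(prcptot(toy_year(precip = 0)$precip, s$year)$mean, 0)
  obs <- gen_station_obs(climate_spec(seed = 19, n_years = 3))
  tt <- txx_tnn(obs)
  expect_equal(unname(tt$txx$per_year),
               unname(sapply(split(obs$tmax, obs$year), max)))
  expect_equal(unname(tt$tnn$per_year),
               unname(sapply(split(obs$tmin, obs$year), min)))
  expect_equal(prcptot(obs$precip, obs$year)$mean,
               mean(sapply(split(obs$precip, obs$year), sum)), tolerance = 1e-12)
})

test_that("index anomaly report is zero against itself and translates temperatures", {
  obs <- gen_station_obs(climate_spec(seed = 23, n_years = 2))
  rep0 <- index_anomaly_report(obs, obs)
  expect_true(all(rep0$delta == 0))
  shifted <- obs
  for (v in c("tmean", "tmin", "tmax")) shifted[[v]] <- obs[[v]] + 2
  rep2 <- index_anomaly_report(shifted, obs)
  d <- setNames(rep2$delta, rep2$index)
  expect_equal(unname(d[c("T", "TXx", "TNn")]), c(2, 2, 2), tolerance = 1e-12)
  expect_equal(unname(d["PRCPTOT"]), 0)
  expect_lte(d["frost_days"], 0)
  expect_gte(d["summer_days"], 0)
})

test_that("monotonicity under warming and precipitation scaling holds", {
  obs <- gen_station_obs(climate_spec(seed = 29, n_years = 2))
  warm <- obs
  for (v in c("tmean", "tmin", "tmax")) warm[[v]] <- obs[[v]] + 1.5
  i0 <- climate_index_set(obs); i1 <- climate_index_set(warm)
  expect_gte(i1["TXx"], i0["TXx"])
  expect_gte(i1["TNn"], i0["TNn"])
  expect_gte(i1["summer_days"], i0["summer_days"])
  expect_gte(i1["GSL"], i0["GSL"])
  expect_lte(i1["frost_days"], i0["frost_days"])

  wet <- obs; wet$precip <- obs$precip * 1.8
  i2 <- climate_index_set(wet)
  expect_gte(i2["PRCPTOT"], i0["PRCPTOT"])
  expect_gte(i2["Rx1day"], i0["Rx1day"])
  expect_gte(i2["R10mm"], i0["R10mm"])
  expect_gte(i2["CWD"], i0["CWD"])
  expect_lte(i2["CDD"], i0["CDD"])
  # drizzle-threshold ordering
  w01 <- count_days(obs$precip, obs$year, ">", 0.1)$mean
  w1 <- count_days(obs$precip, obs$year, ">", 1)$mean
  expect_gte(w01, w1)
})

test_that("partial years are rejected unless explicitly allowed", {
  obs <- gen_station_obs(climate_spec(seed = 31, n_years = 2))
  partial <- obs[1:400, ]
  partial <- structure(partial, class = class(obs), calendar = "standard")
  expect_error(climate_index_set(partial), "partial")
})

test_that("frost days support both the tmin and tmean comparators", {
  obs <- gen_station_obs(climate_spec(seed = 37, n_years = 1))
  fmin <- climate_index_set(obs, frost_on = "tmin")["frost_days"]
  fmean <- climate_index_set(obs, frost_on = "tmean")["frost_days"]
  expect_gte(fmin, fmean)   # tmin < tmean daily, so tmin-frost days dominate
})
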