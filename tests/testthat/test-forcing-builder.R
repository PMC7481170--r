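make_sub <- function(n_years = 1, seed = 5, start_year = 2001) {
  obs <- gen_station_obs(climate_spec(seed = seed, n_years = n_years,
                                      start_year = start_year))
  gen_subdaily(obs, seed = seed)
}

test_that("linear interpolation preserves knots and the straight line between them", {
  sub <- make_sub()
  st <- interpolate_linear(sub, 0.5)
  expect_identical(nrow(st), nrow(sub) * 6L)
  # knots preserved exactly
  knots <- st$hour %% 3 == 0
  expect_equal(st$tmean[knots][seq_len(nrow(sub))], sub$tmean, tolerance = 1e-12)
  expect_equal(st$wind[knots][seq_len(nrow(sub))], sub$wind, tolerance = 1e-12)
  # midpoint of a segment is the mean of its knots
  i <- 10   # inside the first day
  mid_val <- st$tmean[st$year == sub$year[i] & st$month == sub$month[i] &
                        st$day == sub$day[i] & st$hour == sub$hour[i] + 1.5]
  expect_equal(mid_val, (sub$tmean[i] + sub$tmean[i + 1]) / 2, tolerance = 1e-12)
  # two-point line formula oracle at every interior output point of day 1
  t_in <- seq(0, 21, by = 3)
  for (tt in seq(0.5, 20.5, by = 0.5)) {
    k <- findInterval(tt, t_in)
    frac <- (tt - t_in[k]) / 3
    expect_equal(st$mslp[st$month == sub$month[1] & st$day == sub$day[1] &
                           st$hour == tt][1],
                 sub$mslp[k] * (1 - frac) + sub$mslp[k + 1] * frac,
                 tolerance = 1e-9)
  }
  # a linear signal is interpolated exactly everywhere
  lin <- sub
  lin$tmean <- seq_len(nrow(sub)) * 0.25
  stl <- interpolate_linear(lin, 0.5)
  inner <- seq_len(nrow(stl) - 6)   # beyond the last knot the segment is held
  expect_equal(stl$tmean[inner], 0.25 + (inner - 1) * 0.25 / 6, tolerance = 1e-12)
})

test_that("irregular input steps are refused", {
  sub <- make_sub()
  broken <- sub[-3, ]
  broken <- structure(broken, class = class(sub), step_hours = 3,
                      calendar = "standard")
  expect_error(interpolate_linear(broken), "irregular")
})

test_that("uniform disaggregation conserves each accumulation", {
  expect_equal(disaggregate_precip(3), rep(0.5, 6))
  expect_equal(disaggregate_precip(0), rep(0, 6))
  set.seed(3)
  p <- rgamma(8, 0.5, scale = 3)
  d <- disaggregate_precip(p)
  expect_equal(colSums(matrix(d, nrow = 6)), p, tolerance = 1e-12)
  expect_error(disaggregate_precip(-0.1), "negative")
})

test_that("drizzle filter postpones sub-threshold amounts and conserves mass", {
  r <- drizzle_filter(c(0.4, 0.4, 0.4))
  expect_equal(r$released, c(0, 0, 1.2))
  expect_equal(r$buffer, 0)
  r2 <- drizzle_filter(c(1.5, 2.0, 1.0))
  expect_equal(r2$released, c(1.5, 2.0, 1.0))
  r3 <- drizzle_filter(c(0.3, 0.3))
  expect_equal(r3$released, c(0, 0))
  expect_equal(r3$buffer, 0.6)
  expect_error(drizzle_filter(c(0.1), threshold = 0), "threshold")
  set.seed(9)
  for (i in 1:25) {
    p <- rgamma(200, 0.4, scale = 1.2) * rbinom(200, 1, 0.5)
    out <- drizzle_filter(p)
    expect_lt(abs(sum(out$released) + out$buffer - sum(p)), 1e-12)
    released <- out$released[out$released > 0]
    if (length(released)) expect_gte(min(released), 1)
    expect_lt(out$buffer, 1)
  }
})

test_that("hydrostatic pressure reduction matches an independent evaluation", {
  expect_equal(surface_pressure_from_msl(101325, 0, 15), 101325)
  p <- surface_pressure_from_msl(101325, 43, 15)
  expect_equal(p, 101325 * exp(-9.80665 * 43 / (287.05 * 288.15)),
               tolerance = 1e-12)
  expect_equal(round(p), 100810)
  expect_lt(surface_pressure_from_msl(101325, 100, 15), p)
  expect_error(surface_pressure_from_msl(-5, 43, 15), "pressure")
})

test_that("humidity conversion round-trips and clips supersaturation", {
  q0 <- specific_humidity_from_relative(60, 20, 101325)
  expect_equal(as.numeric(relative_humidity_from_specific(q0, 20, 101325)),
               60, tolerance = 1e-6)
  expect_identical(as.numeric(relative_humidity_from_specific(0, 10, 90000)), 0)
  set.seed(21)
  rh <- runif(200, 2, 99); t <- runif(200, -20, 35); p <- runif(200, 85000, 104000)
  q <- specific_humidity_from_relative(rh, t, p)
  back <- as.numeric(relative_humidity_from_specific(q, t, p))
  expect_lt(max(abs(back - rh)), 1e-6)
  sup <- relative_humidity_from_specific(
    specific_humidity_from_relative(130, 25, 101325), 25, 101325)
  expect_identical(as.numeric(sup), 100)
  expect_identical(attr(sup, "n_clipped"), 1L)
  expect_error(relative_humidity_from_specific(-1e-4, 10, 101325), "negative")
})

test_that("assembled forcing tables have the right shape, mass balance and GHG attachment", {
  obs <- gen_station_obs(climate_spec(seed = 55, n_years = 6, start_year = 2000))
  run <- gen_model_run(climate_spec(seed = 55, n_years = 6, start_year = 2000),
                       bias_spec(), seed = 56, experiment = "rcp85",
                       subdaily = TRUE)
  windows <- structure(data.frame(threshold = c(1, 2), crossing = c(2001, 2004),
                                  start = c(2000L, 2003L), end = c(2002L, 2005L)),
                       class = c("warming_windows", "data.frame"),
                       reference = c(2000, 2002), length = 3)
  ghg <- ghg_table(2000:2005, co2 = seq(370, 380, by = 2),
                   ch4 = rep(1800, 6), n2o = rep(320, 6))
  ft <- assemble_forcing(run, windows, ghg)
  expect_named(ft, c("+1C", "+2C"))
  tab <- ft[["+2C"]]
  n_days <- sum(days_in_year(2003:2005, "standard"))
  expect_identical(nrow(tab), n_days * 48L)
  # precipitation mass balance against the 3-hourly input
  sl <- run$subdaily[run$subdaily$year %in% 2003:2005, ]
  expect_lt(abs(sum(tab$precip) + attr(tab, "residual_buffer") - sum(sl$precip)),
            1e-9)
  expect_lt(attr(tab, "residual_buffer"), 1)
  released <- tab$precip[tab$precip > 0]
  expect_gte(min(released), 1)
  # annual GHG step function
  expect_equal(unique(tab$co2[tab$year == 2003]), 376)
  expect_equal(unique(tab$co2[tab$year == 2005]), 380)
  expect_true(all(tab$relhum >= 0 & tab$relhum <= 100))
  # window outside coverage errors loudly
  w2 <- windows; w2$end[2] <- 2050L
  expect_error(assemble_forcing(run, w2, ghg), "coverage")
})
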