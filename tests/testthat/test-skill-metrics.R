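test_that("mean bias handles identity, offsets and annual precipitation units", {
  x <- rnorm(200)
  expect_identical(mean_bias(x, x), 0)
  expect_equal(mean_bias(x + 1, x), 1)
  expect_equal(mean_bias(x + 0.5, x, as_annual_precip = TRUE), 0.5 * 365.25)
  expect_error(mean_bias(c(NA, NA), c(1, 2)), "missing|overlap")
})

test_that("Perkins skill score spans [0, 1], is symmetric and matches a hand-binned oracle", {
  x <- c(0.2, 0.4, 0.9, 0.3)
  expect_identical(perkins_skill_score(x, x, 0.5), 1)
  expect_identical(perkins_skill_score(runif(40), 10 + runif(40), 0.5), 0)
  obs <- c(1, 1, 2, 3); mod <- c(1, 2, 2, 4)
  # hand binning with bin 1 from edge 1: bins [1,2) [2,3) [3,4]; see oracle
  expect_equal(perkins_skill_score(mod, obs, 1),
               oracle_pss(mod, obs, edges = 1:5))
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(30, sd = 2); b <- rnorm(35, mean = runif(1, -1, 1))
    expect_equal(perkins_skill_score(a, b, 0.7),
                 oracle_pss(a, b, seq(floor(min(c(a, b)) / 0.7) * 0.7,
                                      max(c(a, b)) + 0.7, by = 0.7)),
                 tolerance = 1e-12)
    expect_equal(perkins_skill_score(a, b, 0.7), perkins_skill_score(b, a, 0.7))
  }
})

test_that("PSS is non-increasing under growing additive offsets", {
  set.seed(7)
  a <- rnorm(500)
  scores <- sapply(seq(0, 5, by = 0.5), function(off)
    perkins_skill_score(a + off, a, 0.5))
  expect_true(all(diff(scores) <= 1e-12))
  expect_equal(scores[1], 1)
})

test_that("zero-inflated precipitation binning keeps drizzle in its own first bin", {
  obs <- c(0, 0, 0.05, 0.5, 2, 5)
  mod <- c(0, 0.02, 0.08, 0.7, 2.5, 4.9)
  s <- perkins_skill_score(mod, obs, 1, first_bin = c(0, 0.1))
  # [0,0.1): 3/6 both; [0.1,1.1): 1/6 both; 2 and 2.5 fall in different
  # bins (no overlap); [4.1,5.1]: 1/6 both
  expect_equal(s, 5 / 6)
  expect_error(perkins_skill_score(c(-1, 2), c(0, 1), 1, first_bin = c(0, 0.1)),
               "below")
})

test_that("seasonal cycle equals group-by-month means and its MAE is translation-exact", {
  obs <- gen_station_obs(climate_spec(seed = 21, n_years = 1))
  expect_equal(seasonal_cycle(obs$tmean, obs$month),
               oracle_seasonal_cycle(obs$tmean, obs$month))
  expect_identical(seasonal_cycle(rep(3.5, nrow(obs)), obs$month), rep(3.5, 12))
  expect_equal(seasonal_cycle_mae(obs$tmean + 1.3, obs$tmean, obs$month), 1.3)
  expect_equal(seasonal_cycle_mae(obs$tmean, obs$tmean, obs$month), 0)
  expect_error(seasonal_cycle(1:10, rep(1, 10)), "month")
})

test_that("percentile MAE matches the sorted-interpolation oracle", {
  set.seed(9)
  m <- rnorm(120); o <- rnorm(130)
  expect_equal(percentile_mae(m, o), oracle_percentile_mae(m, o),
               tolerance = 1e-12)
  expect_equal(percentile_mae(o + 2.5, o), 2.5, tolerance = 1e-12)
  expect_warning(percentile_mae(rnorm(20), rnorm(20)), "100")
})

test_that("RMSE matches an explicit loop and dominates the MAE", {
  set.seed(10)
  m <- rnorm(80); o <- rnorm(80)
  expect_equal(rmse(m, o), oracle_rmse(m, o), tolerance = 1e-12)
  expect_gte(rmse(m, o), mean(abs(m - o)))
  expect_identical(rmse(o, o), 0)
  expect_equal(rmse(o + 2, o), 2)
})

test_that("Spearman correlation honors monotone transforms, sign flips and ties", {
  o <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  expect_equal(spearman_daily(exp(o), o), 1)
  expect_equal(spearman_daily(-o, o), -1)
  set.seed(11)
  m <- sample(0:4, 10, replace = TRUE)
  expect_equal(spearman_daily(m, o), oracle_spearman(m, o), tolerance = 1e-12)
  expect_error(spearman_daily(rep(1, 10), o), "constant")
})

test_that("Brier skill score is 1 for a perfect categorical forecast and matches brute force", {
  o <- c(1.2, 5.3, 2.2, 8.8, 0.4, 6.1, 3.3, 7.7, 2.9, 4.4, 9.1, 1.8)
  expect_equal(brier_skill_score(o, o), 1)
  set.seed(12)
  m <- o + rnorm(12, sd = 2)
  expect_equal(brier_skill_score(m, o, 3), oracle_bss(m, o, 3),
               tolerance = 1e-12)
  expect_equal(brier_skill_score(m, o, 4), oracle_bss(m, o, 4),
               tolerance = 1e-12)
  expect_error(brier_skill_score(m, rep(2, 12)), "degenerate")
})

test_that("cross-variable correlation comparison is zero for identical runs and flips with RH sign", {
  obs <- gen_station_obs(climate_spec(seed = 13, n_years = 3))
  tab <- cross_correlation_table(obs, obs)
  expect_true(all(tab$abs_diff == 0))
  expect_identical(nrow(tab), 3L * 6L)   # 3 seasons x C(4,2) pairs

  flipped <- obs
  flipped$relhum <- 100 - obs$relhum     # sign-flips every RH correlation
  tab2 <- cross_correlation_table(flipped, obs, seasons = "annual")
  trh <- tab2[tab2$var1 == "tmean" & tab2$var2 == "relhum", ]
  r_obs <- cor(obs$tmean, obs$relhum)
  expect_equal(trh$abs_diff, abs(2 * r_obs), tolerance = 1e-12)

  # explicit pairwise-loop oracle on the JJA subset
  jja <- obs$month %in% 6:8
  for (pair in list(c("tmean", "precip"), c("relhum", "wind"))) {
    row <- tab[tab$season == "JJA" & tab$var1 == pair[1] & tab$var2 == pair[2], ]
    expect_equal(row$r_obs, cor(obs[[pair[1]]][jja], obs[[pair[2]]][jja]),
                 tolerance = 1e-12)
  }
})

test_that("metrics are translation-covariant for temperature-like series", {
  set.seed(14)
  m <- rnorm(400); o <- rnorm(400)
  mos <- rep(rep(1:12, length.out = 400))
  for (c_ in c(-2, 0.7)) {
    expect_equal(rmse(m + c_, o), rmse(m, o - c_), tolerance = 1e-12)
    expect_equal(seasonal_cycle_mae(m + c_, o, mos),
                 seasonal_cycle_mae(m, o - c_, mos), tolerance = 1e-12)
  }
})

test_that("evaluate_run includes day-by-day metrics only for reanalysis downscalings", {
  spec <- climate_spec(seed = 15, n_years = 2)
  obs <- gen_station_obs(spec)
  ev <- evaluate_run(gen_model_run(spec, bias_spec(), seed = 1), obs)
  gc <- evaluate_run(gen_model_run(spec, bias_spec(), seed = 2,
                                   experiment = "historical"), obs)
  expect_true(all(c("rmse", "spearman", "bss") %in% ev$metric))
  expect_false(any(c("rmse", "spearman", "bss") %in% gc$metric))
  expect_true(all(ev$value[ev$metric == "pss"] >= 0 &
                    ev$value[ev$metric == "pss"] <= 1))
  expect_true(all(ev$value[ev$metric == "bss"] <= 1))
})
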