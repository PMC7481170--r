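test_that("rank columns are permutations with stable tie handling", {
  r <- rank_column(c(5, -2, 0.5, -7), "zero_best")
  expect_identical(as.integer(r), c(3L, 2L, 1L, 4L))
  # ties: first occurrence wins the smaller rank
  r2 <- rank_column(c(3, 1, 1, 2), "lower_better")
  expect_identical(as.integer(r2), c(4L, 1L, 2L, 3L))
  r3 <- rank_column(c(0.2, 0.9, 0.5), "higher_better")
  expect_identical(as.integer(r3), c(3L, 1L, 2L))
  # argsort oracle on random values
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(10)
    expect_identical(as.integer(rank_column(v, "lower_better")),
                     as.integer(rank(v, ties.method = "first")))
    expect_identical(as.integer(rank_column(v, "zero_best")),
                     as.integer(rank(abs(v), ties.method = "first")))
  }
  # permutation property and invariance under positive rescaling
  v <- runif(9)
  expect_setequal(as.integer(rank_column(v, "lower_better")), 1:9)
  expect_identical(rank_column(v, "lower_better")[],
                   rank_column(v * 3.7, "lower_better")[])
  # missing runs are excluded and recorded
  rn <- rank_column(c(1, NA, 0.5), "lower_better")
  expect_identical(attr(rn, "excluded"), 2L)
  expect_identical(as.integer(rn), c(2L, NA, 1L))
})

test_that("composite rank scores are weighted means with renormalization for missing columns", {
  skill <- data.frame(
    run = rep(c("a", "b", "c"), each = 2),
    variable = rep(c("tmean", "precip"), 3),
    metric = "bias",
    value = c(1, 10, 2, 5, 3, NA),
    orientation = "zero_best")
  rt <- rank_table(skill)
  sc <- aggregate_ranks(rt)
  # tmean ranks a1 b2 c3; precip ranks (c missing) b1 a2
  expect_equal(unname(sc[["a"]]), mean(c(1, 2)))
  expect_equal(unname(sc[["c"]]), 3)      # only the tmean column available
  # single column: composite equals that column's ranks
  sc1 <- aggregate_ranks(rt, variables = "tmean")
  expect_equal(unname(sc1[c("a", "b", "c")]), c(1, 2, 3))
  # explicit weighted-mean oracle
  w <- c("tmean bias" = 2, "precip bias" = 1)
  sc2 <- aggregate_ranks(rt, weights = w)
  expect_equal(unname(sc2[["a"]]), (2 * 1 + 1 * 2) / 3)
  expect_error(aggregate_ranks(rt, weights = c("tmean bias" = 0),
                               variables = "tmean"), "zero total weight")
})

test_that("shortlisting removes exclusions and keeps the n best scores", {
  sc <- c(a = 2.5, b = 1.0, c = 4.0, d = 3.0)
  expect_identical(shortlist(sc), c("b", "a", "d", "c"))
  expect_identical(shortlist(sc, n = 2), c("b", "a"))
  expect_identical(shortlist(sc, n = 3, exclude = "c"), c("b", "a", "d"))
  expect_error(shortlist(sc, n = 0), "positive")
  set.seed(31)
  v <- setNames(runif(12), paste0("r", 1:12))
  expect_identical(shortlist(v, 5), names(sort(v))[1:5])
})

test_that("ensemble percentile positions interpolate the empirical CDF", {
  ens <- c(1.2, 1.5, 1.8, 2.0, 2.4, 2.9, 3.3, 3.6, 4.0)   # 9 runs
  expect_equal(ensemble_percentile_position(2.4, ens), 50)  # the median run
  expect_equal(ensemble_percentile_position(0.5, ens), 0)
  expect_equal(ensemble_percentile_position(9, ens), 100)
  set.seed(17)
  e <- rnorm(10)
  s <- sort(e)
  for (x in runif(5, min(e), max(e))) {
    # brute-force empirical-CDF oracle with order-statistic interpolation
    i <- max(which(s <= x))
    p_or <- if (x == s[i]) (i - 1) / 9 * 100 else
      ((i - 1) + (x - s[i]) / (s[i + 1] - s[i])) / 9 * 100
    expect_equal(ensemble_percentile_position(x, e), p_or, tolerance = 1e-12)
  }
  expect_error(ensemble_percentile_position(1, c(1, 2)), "ensemble size")
})

test_that("scenario anomalies are computed against each run's own reference period", {
  spec <- climate_spec(seed = 3, n_years = 40, start_year = 1991)
  run <- gen_model_run(spec, bias_spec(), seed = 9, experiment = "rcp85",
                       trend = 0.05)
  a <- scenario_anomaly(run$daily, "tmean", c(1991, 2000), c(2021, 2030))
  expect_gt(a, 0.05 * 30 - 1)   # 30-year separation, generous noise margin
  expect_lt(a, 0.05 * 30 + 1)
})

test_that("final selection is precipitation-bias decisive within the representativeness band", {
  cand <- data.frame(run = c("x", "y", "z"),
                     precip_bias = c(8, 24, 36),
                     p_t = c(50, 45, 60), p_p = c(40, 55, 52))
  sel <- select_final(cand, c("p_t", "p_p"))
  expect_identical(sel$chosen, "x")
  expect_identical(sel$widened, 0L)
  # an out-of-band run is eliminated before the bias comparison
  cand2 <- cand
  cand2$p_t[1] <- 95
  sel2 <- select_final(cand2, c("p_t", "p_p"))
  expect_identical(sel2$chosen, "y")
  expect_false(sel2$trace$in_band[sel2$trace$run == "x"])
  # single candidate selects itself
  expect_identical(select_final(cand[2, ], c("p_t", "p_p"))$chosen, "y")
  # band widening is applied symmetrically and recorded
  cand3 <- data.frame(run = c("u", "v"), precip_bias = c(100, 5),
                      p_t = c(10, 90), p_p = c(50, 50))
  sel3 <- select_final(cand3, c("p_t", "p_p"))
  expect_gt(sel3$widened, 0)
  expect_identical(sel3$chosen, "v")
  # permutation invariance in candidate order
  perm <- cand[c(3, 1, 2), ]
  expect_identical(select_final(perm, c("p_t", "p_p"))$chosen, "x")
})

test_that("published precipitation-bias ranking reproduces the printed rank column", {
  tab <- cordex_precip_biases()
  expect_identical(nrow(tab), 18L)
  computed <- rank_column(tab$p_bias_mm_yr, "zero_best")
  expect_identical(as.integer(computed), tab$published_rank)
})
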