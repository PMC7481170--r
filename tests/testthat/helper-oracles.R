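# Independent brute-force oracles: deliberately naive loop/scan
# implementations kept free of any package internals, used to pin down the
# metric and index functions on small random instances.

oracle_mean_bias <- function(m, o) {
  sm <- 0; so <- 0; n <- 0
  for (i in seq_along(m)) {
    if (!is.na(m[i]) && !is.na(o[i])) { sm <- sm + m[i]; so <- so + o[i]; n <- n + 1 }
  }
  sm / n - so / n
}

oracle_pss <- function(m, o, edges) {
  nb <- length(edges) - 1
  fm <- numeric(nb); fo <- numeric(nb)
  binof <- function(x) {
    for (b in seq_len(nb)) {
      hi <- if (b == nb) x <= edges[b + 1] else x < edges[b + 1]
      if (x >= edges[b] && hi) return(b)
    }
    NA_integer_
  }
  for (x in m) fm[binof(x)] <- fm[binof(x)] + 1 / length(m)
  for (x in o) fo[binof(x)] <- fo[binof(x)] + 1 / length(o)
  s <- 0
  for (b in seq_len(nb)) s <- s + min(fm[b], fo[b])
  s
}

oracle_seasonal_cycle <- function(values, months) {
  sapply(1:12, function(mo) mean(values[months == mo], na.rm = TRUE))
}

# type-7 quantile: linear interpolation between order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

oracle_percentile_mae <- function(m, o, levels = c(1, 10, 90, 99)) {
  tot <- 0
  for (l in levels)
    tot <- tot + abs(oracle_quantile(m, l / 100) - oracle_quantile(o, l / 100))
  tot / length(levels)
}

oracle_rmse <- function(m, o) {
  s <- 0; n <- 0
  for (i in seq_along(m)) { s <- s + (m[i] - o[i])^2; n <- n + 1 }
  sqrt(s / n)
}

oracle_ranks <- function(x) {   # average ranks for ties, by explicit counting
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracle_spearman <- function(m, o) {
  rm_ <- oracle_ranks(m); ro <- oracle_ranks(o)
  num <- sum((rm_ - mean(rm_)) * (ro - mean(ro)))
  den <- sqrt(sum((rm_ - mean(rm_))^2) * sum((ro - mean(ro))^2))
  num / den
}

oracle_bss <- function(m, o, k = 3) {
  breaks <- sapply(seq_len(k - 1) / k, function(p) oracle_quantile(o, p))
  cat_of <- function(x) {
    c <- 1
    for (b in breaks) if (x > b) c <- c + 1
    c
  }
  bs <- 0; bs_ref <- 0
  for (i in seq_along(o)) {
    oc <- cat_of(o[i]); mc <- cat_of(m[i])
    for (cc in seq_len(k)) {
      obs_ind <- as.numeric(cc == oc)
      bs <- bs + (as.numeric(cc == mc) - obs_ind)^2
      bs_ref <- bs_ref + (1 / k - obs_ind)^2
    }
  }
  1 - bs / bs_ref
}

# --- index oracles: explicit day scans ---------------------------------

oracle_count_per_year <- function(values, years, cmp, thr) {
  sapply(sort(unique(years)), function(y) {
    v <- values[years == y]
    n <- 0
    for (x in v) if (cmp(x, thr)) n <- n + 1
    n
  })
}

oracle_max_spell <- function(precip, years, dry = TRUE, thr = 1) {
  sapply(sort(unique(years)), function(y) {
    p <- precip[years == y]
    best <- 0; cur <- 0
    for (x in p) {
      hit <- if (dry) x < thr else x >= thr
      cur <- if (hit) cur + 1 else 0
      if (cur > best) best <- cur
    }
    best
  })
}

oracle_rx1day_monthly <- function(precip, years, months) {
  out <- c()
  for (y in sort(unique(years))) for (mo in sort(unique(months[years == y]))) {
    out <- c(out, max(precip[years == y & months == mo]))
  }
  out
}

oracle_gsl_one_year <- function(tmean, july1, t_thr = 5, span = 6) {
  n <- length(tmean)
  find_span <- function(flag, from) {
    run <- 0
    for (i in from:n) {
      run <- if (flag[i]) run + 1 else 0
      if (run == span) return(i - span + 1)
    }
    NA
  }
  ws <- find_span(tmean > t_thr, 1)
  if (is.na(ws)) return(0)
  cold <- tmean < t_thr
  cs <- if (july1 + 1 <= n) find_span(cold, july1 + 1) else NA
  # a span straddling july1 must restart the count after july1
  if (!is.na(cs) && cs <= july1) cs <- NA
  end <- if (is.na(cs)) n else cs - 1
  max(0, end - ws + 1)
}

# --- random instance generator for oracle-equivalence suites -----------

random_series <- function(seed, n_years = NULL) {
  set.seed(seed)
  if (is.null(n_years)) n_years <- sample(1:3, 1)
  spec <- climate_spec(seed = seed, n_years = n_years,
                       start_year = sample(1950:2050, 1),
                       tmean_mean = runif(1, 5, 15),
                       tmean_amp = runif(1, 3, 10),
                       ar1 = runif(1, 0.3, 0.9),
                       noise_sd = runif(1, 0.5, 3),
                       p01 = runif(1, 0.15, 0.5), p11 = runif(1, 0.4, 0.8),
                       gamma_shape = runif(1, 0.5, 1.2),
                       gamma_scale = runif(1, 2, 8))
  gen_station_obs(spec)
}
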