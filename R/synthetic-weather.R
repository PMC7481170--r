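## Seeded stochastic weather generation: a single-site generator with an
## annual harmonic plus AR(1) temperature anomalies, a two-state Markov
## chain for precipitation occurrence with gamma-distributed wet-day
## amounts, harmonic relative humidity and Weibull wind. Pseudo-model runs
## are the same generator with configurable biases and an independent noise
## realization, so every bias recovered downstream is known by construction.

## Fixed substream labels: each variable draws from its own derived seed so
## adding a variable never perturbs another variable's draws.
SUBSTREAMS <- c(tmean = 1L, dtr = 2L, precip_occ = 3L, precip_amt = 4L,
                relhum = 5L, wind = 6L, subdaily = 7L, gmt = 8L)

substream_seed <- function(seed, label) {
  (as.integer(seed) %% 199999999L) * 10L + SUBSTREAMS[[label]]
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic single-site climate specification
#'
#' Parameters of the stochastic weather generator. Defaults emulate a
#' temperate maritime lowland climate (Maastricht-like): ~10 degC annual
#' mean with a 7 degC seasonal amplitude, ~50% wet-day frequency with
#' drizzle-heavy gamma amounts giving roughly 770 mm/yr, humid winters and
#' moderate Weibull winds.
#'
#' @param seed integer seed; all draws are deterministic given it.
#' @param n_years number of calendar years to generate.
#' @param start_year first year.
#' @param calendar model calendar, see [month_lengths()].
#' @param tmean_mean,tmean_amp annual-mean temperature and seasonal
#'   (harmonic) amplitude, degC.
#' @param ar1 lag-1 autocorrelation of daily temperature anomalies, in \[0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) anomalies, degC.
#' @param dtr_mean,dtr_sd mean diurnal temperature range and its day-to-day
#'   standard deviation, degC.
#' @param p01,p11 Markov wet-day probabilities P(wet | dry) and P(wet | wet).
#' @param gamma_shape,gamma_scale gamma parameters of wet-day amounts (mm).
#' @param relhum_mean,relhum_amp,relhum_sd relative humidity mean, seasonal
#'   amplitude and daily noise sd, %.
#' @param wind_shape,wind_scale Weibull parameters for daily wind speed (m/s).
#' @return a `climate_spec` list.
#' @export
climate_spec <- function(seed = 1L, n_years = 30L, start_year = 1951L,
                         calendar = "standard",
                         tmean_mean = 10, tmean_amp = 7, ar1 = 0.7,
                         noise_sd = 1.5, dtr_mean = 8, dtr_sd = 1.5,
                         p01 = 0.35, p11 = 0.65,
                         gamma_shape = 0.8, gamma_scale = 5.3,
                         relhum_mean = 80, relhum_amp = 8, relhum_sd = 6,
                         wind_shape = 1.9, wind_scale = 4.5) {
  stopifnot(n_years >= 1, p01 >= 0, p01 <= 1, p11 >= 0, p11 <= 1,
            ar1 >= 0, ar1 < 1, gamma_shape > 0, gamma_scale > 0,
            tmean_amp >= 0, relhum_amp >= 0, noise_sd >= 0,
            wind_shape > 0, wind_scale > 0)
  check_calendar(calendar)
  structure(as.list(environment()), class = "climate_spec")
}

#' Per-run bias specification for pseudo-model runs
#'
#' @param t_bias additive air temperature bias, degC.
#' @param p_factor multiplicative factor on wet-day precipitation amounts
#'   (> 0); the long-run mean precipitation ratio converges to it.
#' @param rh_bias additive relative humidity bias, %.
#' @param wind_factor multiplicative factor on wind speeds (> 0).
#' @param var_inflation multiplicative factor on the temperature anomaly
#'   variance (> 0).
#' @return a `bias_spec` list.
#' @export
bias_spec <- function(t_bias = 0, p_factor = 1, rh_bias = 0,
                      wind_factor = 1, var_inflation = 1) {
  stopifnot(p_factor > 0, wind_factor > 0, var_inflation > 0)
  structure(list(t_bias = t_bias, p_factor = p_factor, rh_bias = rh_bias,
                 wind_factor = wind_factor, var_inflation = var_inflation),
            class = "bias_spec")
}

ar1_series <- function(n, ar, innov_sd) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, ar, method = "recursive"))
}

#' Generate synthetic daily station observations
#'
#' Deterministic given the spec's seed. Temperature is an annual harmonic
#' (peak around late July) plus AR(1) anomalies; `tmin`/`tmax` are
#' `tmean -/+ DTR/2` with independent day-to-day DTR noise and the ordering
#' `tmin <= tmean <= tmax` enforced. Precipitation occurrence follows the
#' two-state Markov chain, with gamma amounts on wet days and zero on dry
#' days.
#'
#' @param spec a [climate_spec()].
#' @return a [daily_series()] with all six variables.
#' @export
gen_station_obs <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  cal <- calendar_frame(spec$start_year, spec$n_years, spec$calendar)
  n <- nrow(cal)
  ylen <- days_in_year(cal$year, spec$calendar)
  phase <- 2 * pi * (cal$doy - 0.57 * ylen) / ylen   # warm peak ~late July

  anom <- with_seed(substream_seed(spec$seed, "tmean"),
                    ar1_series(n, spec$ar1, spec$noise_sd))
  tmean <- spec$tmean_mean + spec$tmean_amp * cos(phase) + anom

  dtr <- with_seed(substream_seed(spec$seed, "dtr"),
                   pmax(0.5, stats::rnorm(n, spec$dtr_mean, spec$dtr_sd)))
  tmin <- pmin(tmean, tmean - dtr / 2)
  tmax <- pmax(tmean, tmean + dtr / 2)

  wet <- with_seed(substream_seed(spec$seed, "precip_occ"), {
    u <- stats::runif(n)
    w <- logical(n)
    p_wet <- if (spec$p01 + (1 - spec$p11) > 0)
      spec$p01 / (1 + spec$p01 - spec$p11) else 0
    w[1] <- u[1] < p_wet
    for (i in seq_len(n)[-1])
      w[i] <- u[i] < (if (w[i - 1]) spec$p11 else spec$p01)
    w
  })
  precip <- numeric(n)
  precip[wet] <- with_seed(substream_seed(spec$seed, "precip_amt"),
                           stats::rgamma(sum(wet), shape = spec$gamma_shape,
                                         scale = spec$gamma_scale))

  relhum <- with_seed(substream_seed(spec$seed, "relhum"),
                      spec$relhum_mean - spec$relhum_amp * cos(phase) +
                        stats::rnorm(n, 0, spec$relhum_sd))
  relhum <- pmin(100, pmax(0, relhum))

  wind <- with_seed(substream_seed(spec$seed, "wind"),
                    stats::rweibull(n, shape = spec$wind_shape,
                                    scale = spec$wind_scale))

  daily_series(cal$year, cal$month, cal$day, tmean = tmean, tmin = tmin,
               tmax = tmax, precip = precip, relhum = relhum, wind = wind,
               calendar = spec$calendar)
}

#' Construct a model run object
#'
#' @param daily a [daily_series()].
#' @param rcm_name,gcm_name RCM and driving GCM names; evaluation
#'   (reanalysis-driven) runs must use `gcm_name = "reanalysis"`.
#' @param experiment one of `"evaluation"`, `"historical"`, `"rcp85"`.
#' @param member ensemble member label.
#' @param subdaily optional [subdaily_series] at 3-hourly step.
#' @return a `model_run` list.
#' @export
model_run <- function(daily, rcm_name = "SYN-RCM", gcm_name = "reanalysis",
                      experiment = c("evaluation", "historical", "rcp85"),
                      member = "r1i1p1", subdaily = NULL) {
  experiment <- match.arg(experiment)
  if (experiment == "evaluation" && gcm_name != "reanalysis")
    stop("evaluation runs are reanalysis-driven: gcm_name must be \"reanalysis\"",
         call. = FALSE)
  structure(list(rcm_name = rcm_name, gcm_name = gcm_name,
                 experiment = experiment, member = member,
                 calendar = series_calendar(daily),
                 daily = daily, subdaily = subdaily),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("Model run %s / %s (%s, member %s, calendar %s)\n",
              x$rcm_name, x$gcm_name, x$experiment, x$member, x$calendar))
  cat(sprintf("  daily: %d days %d-%d%s\n", nrow(x$daily), min(x$daily$year),
              max(x$daily$year),
              if (is.null(x$subdaily)) "" else
                sprintf("; sub-daily: %d steps at %g h", nrow(x$subdaily),
                        attr(x$subdaily, "step_hours"))))
  invisible(x)
}

run_id <- function(run) paste(run$rcm_name, run$gcm_name, sep = "/")

#' Generate a biased pseudo-model run
#'
#' Draws an independent realization from the same climatology as
#' `obs_spec`, shifted by the bias specification: additive temperature and
#' humidity offsets, multiplicative precipitation and wind factors, and a
#' temperature-variance inflation. An optional linear warming trend (degC/yr,
#' applied to all three temperatures) makes scenario runs with a known
#' climate-change signal.
#'
#' @param obs_spec the [climate_spec()] the observations were drawn from.
#' @param bias a [bias_spec()].
#' @param seed seed for this run's independent noise realization.
#' @param experiment experiment tag, see [model_run()].
#' @param rcm_name,gcm_name run metadata.
#' @param trend linear temperature trend, degC per year from `start_year`.
#' @param start_year,n_years optional overrides of the observation spec.
#' @param subdaily if `TRUE`, attach a 3-hourly series via [gen_subdaily()].
#' @return a [model_run()].
#' @export
gen_model_run <- function(obs_spec, bias = bias_spec(), seed,
                          experiment = "evaluation",
                          rcm_name = "SYN-RCM",
                          gcm_name = if (experiment == "evaluation") "reanalysis" else "SYN-GCM",
                          trend = 0, start_year = obs_spec$start_year,
                          n_years = obs_spec$n_years, subdaily = FALSE) {
  stopifnot(inherits(obs_spec, "climate_spec"), inherits(bias, "bias_spec"))
  spec <- obs_spec
  spec$seed <- seed
  spec$start_year <- start_year
  spec$n_years <- n_years
  spec$tmean_mean <- spec$tmean_mean + bias$t_bias
  spec$gamma_scale <- spec$gamma_scale * bias$p_factor
  spec$relhum_mean <- spec$relhum_mean + bias$rh_bias
  spec$wind_scale <- spec$wind_scale * bias$wind_factor
  spec$noise_sd <- spec$noise_sd * sqrt(bias$var_inflation)
  daily <- gen_station_obs(spec)
  if (trend != 0) {
    dt <- trend * (daily$year - start_year)
    daily$tmean <- daily$tmean + dt
    daily$tmin <- daily$tmin + dt
    daily$tmax <- daily$tmax + dt
  }
  sub <- if (subdaily) gen_subdaily(daily, seed = seed) else NULL
  model_run(daily, rcm_name = rcm_name, gcm_name = gcm_name,
            experiment = experiment, subdaily = sub)
}

#' Disaggregate a daily series to a synthetic 3-hourly series
#'
#' Produces the eight 3-hour steps per day a scenario extraction would
#' provide: temperature follows a diurnal harmonic between `tmin` and `tmax`
#' (peak 15:00); the daily precipitation total is split over the steps with
#' random gamma weights so the per-day sum is conserved exactly; mean sea
#' level pressure is an AR(1) walk around 1013.25 hPa; specific humidity is
#' derived from the daily relative humidity via the Magnus inverse so the
#' downstream conversion round-trips.
#'
#' @param daily a complete [daily_series()] with all six variables.
#' @param seed integer seed.
#' @return a `subdaily_series` data frame (attributes `step_hours = 3`,
#'   `calendar`) with columns year, month, day, hour, tmean, precip, mslp,
#'   spechum, wind.
#' @export
gen_subdaily <- function(daily, seed = 1L) {
  need <- c("tmean", "tmin", "tmax", "precip", "relhum", "wind")
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("daily series lacks ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyNA(daily[, need])) stop("missing daily values; gap-fill first", call. = FALSE)
  n <- nrow(daily)
  hours <- seq(0, 21, by = 3)
  idx <- rep(seq_len(n), each = 8L)
  hr <- rep(hours, times = n)

  mid <- (daily$tmin + daily$tmax) / 2
  amp <- (daily$tmax - daily$tmin) / 2
  tsub <- mid[idx] + amp[idx] * cos(2 * pi * (hr - 15) / 24)

  w <- with_seed(substream_seed(seed, "subdaily"), {
    wgt <- matrix(stats::rgamma(8L * n, shape = 0.5, scale = 1), nrow = 8L)
    wgt <- sweep(wgt, 2L, colSums(wgt), "/")
    list(wgt = wgt,
         mslp_day = 101325 + ar1_series(n, 0.85, 300),
         wind_mult = pmax(0.2, 1 + stats::rnorm(8L * n, 0, 0.15)))
  })
  psub <- as.vector(w$wgt) * daily$precip[idx]

  mslp <- w$mslp_day[idx] + 40 * cos(2 * pi * (hr - 4) / 24)
  spechum <- specific_humidity_from_relative(daily$relhum[idx], tsub,
                                             mslp * 0.995)
  wind <- daily$wind[idx] * w$wind_mult

  structure(data.frame(year = daily$year[idx], month = daily$month[idx],
                       day = daily$day[idx], hour = hr, tmean = tsub,
                       precip = psub, mslp = mslp, spechum = spechum,
                       wind = wind),
            class = c("subdaily_series", "data.frame"),
            step_hours = 3, calendar = series_calendar(daily))
}

#' Synthetic global-mean-temperature trajectory specification
#'
#' @param start_year first year.
#' @param n_years number of years (use >= 35 if the series will feed 30-year
#'   smoothing).
#' @param baseline GMT level in the first year, degC.
#' @param trend linear warming trend, degC/yr.
#' @param noise_sd interannual noise standard deviation, degC.
#' @param seed integer seed.
#' @return a `gmt_spec` list.
#' @export
gmt_spec <- function(start_year = 1921L, n_years = 180L, baseline = 14,
                     trend = 0.02, noise_sd = 0.1, seed = 1L) {
  stopifnot(n_years >= 1, noise_sd >= 0)
  structure(list(start_year = start_year, n_years = n_years,
                 baseline = baseline, trend = trend, noise_sd = noise_sd,
                 seed = seed), class = "gmt_spec")
}

#' Generate an annual GMT series
#'
#' `GMT(y) = baseline + trend * (y - start_year) + noise`, deterministic
#' given the seed.
#'
#' @param spec a [gmt_spec()].
#' @return data frame with columns `year`, `gmt` (degC).
#' @export
gen_gmt <- function(spec) {
  stopifnot(inherits(spec, "gmt_spec"))
  years <- seq.int(spec$start_year, length.out = spec$n_years)
  noise <- if (spec$noise_sd > 0)
    with_seed(substream_seed(spec$seed, "gmt"),
              stats::rnorm(spec$n_years, 0, spec$noise_sd))
  else numeric(spec$n_years)
  data.frame(year = years,
             gmt = spec$baseline + spec$trend * (years - spec$start_year) + noise)
}
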