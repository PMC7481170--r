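## ETCCDI-style climatological diagnostics used both for model evaluation
## and for characterizing warming-level forcing windows. Annual quantities
## are computed per calendar year (spells truncate at year boundaries) and
## summarized as the mean over years; Rx1day is the mean over monthly
## 1-day maxima.

per_year <- function(x, years, fun, ...) {
  vapply(split(x, years), fun, numeric(1), ...)
}

#' Mean diurnal temperature range
#'
#' Mean over the selected days of `tmax - tmin`, optionally restricted to
#' winter (DJF) or summer (JJA).
#'
#' @param series a [daily_series()] with `tmin` and `tmax`.
#' @param season one of `"annual"`, `"DJF"`, `"JJA"`.
#' @return mean DTR, degC.
#' @export
diurnal_temperature_range <- function(series, season = c("annual", "DJF", "JJA")) {
  season <- match.arg(season)
  if (any(series$tmax < series$tmin, na.rm = TRUE))
    stop("tmax < tmin: corrupt series", call. = FALSE)
  mask <- season_mask(series$year, series$month, season)
  mean(series$tmax[mask] - series$tmin[mask], na.rm = TRUE)
}

#' Threshold-exceedance day counts
#'
#' Counts days per calendar year satisfying a strict comparison, e.g. wet
#' days (`precip > 0.1` or `> 1` mm), frost days (`tmin < 0` degC), summer
#' days (`tmax > 25` degC), heavy-precipitation days (`precip > 10` mm).
#'
#' @param values daily values.
#' @param years calendar year of each value.
#' @param comparator `">"`, `"<"`, `">="` or `"<="`.
#' @param threshold threshold in the variable's units.
#' @return list with `per_year` (named counts) and `mean` (days/year).
#' @export
count_days <- function(values, years, comparator = ">", threshold = 0) {
  cmp <- match.fun(match.arg(comparator, c(">", "<", ">=", "<=")))
  py <- per_year(values, years, function(x) sum(cmp(x, threshold), na.rm = TRUE))
  list(per_year = py, mean = mean(py))
}

#' Monthly maximum 1-day precipitation (Rx1day)
#'
#' Maximum daily precipitation within each month. The period value is the
#' mean over all monthly maxima (an `"annual_max"` aggregation over yearly
#' maxima is available as a variant).
#'
#' @param precip daily precipitation, mm.
#' @param years,months date components of each value.
#' @param aggregate `"monthly_mean"` (default) or `"annual_max"` (period
#'   value is then the mean over annual maxima).
#' @return list with `per_month` (or `per_year`) and `mean` (mm/day).
#' @export
rx1day <- function(precip, years, months, aggregate = c("monthly_mean", "annual_max")) {
  aggregate <- match.arg(aggregate)
  if (anyNA(precip)) stop("missing precipitation values", call. = FALSE)
  if (aggregate == "monthly_mean") {
    key <- factor(years * 100L + months)
    pm <- vapply(split(precip, key), max, numeric(1))
    list(per_month = pm, mean = mean(pm))
  } else {
    py <- per_year(precip, years, max)
    list(per_year = py, mean = mean(py))
  }
}

#' Longest dry or wet spell (CDD / CWD)
#'
#' A dry day has precipitation < 1 mm; a wet day >= 1 mm. The annual value
#' is the longest run of such days within the calendar year (runs truncate
#' at year boundaries); the period value is the mean of annual maxima.
#'
#' @param precip daily precipitation, mm.
#' @param years calendar year of each value.
#' @param kind `"dry"` (CDD) or `"wet"` (CWD).
#' @param threshold spell threshold, mm (default 1).
#' @return list with `per_year` and `mean` (days).
#' @export
max_spell <- function(precip, years, kind = c("dry", "wet"), threshold = 1) {
  kind <- match.arg(kind)
  if (any(precip < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  flag <- if (kind == "dry") precip < threshold else precip >= threshold
  longest <- function(f) {
    if (!any(f)) return(0)
    r <- rle(f)
    max(r$lengths[r$values])
  }
  py <- per_year(flag, years, longest)
  list(per_year = py, mean = mean(py))
}

## First start index of a run of >= span consecutive TRUEs, NA if none.
first_span_start <- function(flag, span) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= span)
  if (!length(hit)) NA_integer_ else starts[hit[1]]
}

#' Growing season length
#'
#' For each calendar year: the count of days from the first day of the
#' first span of at least 6 days with mean air temperature above 5 degC, to
#' the day before the first day of the first such cold span (6 days below
#' 5 degC) starting after July 1. No warm span gives 0; no cold span ends
#' the season at the last day of the year.
#'
#' @param series a [daily_series()] with `tmean`, whole calendar years.
#' @param t_warm,t_cold temperature thresholds, degC (both default 5).
#' @param span minimum span length, days (default 6).
#' @return list with `per_year` and `mean` (days).
#' @export
growing_season_length <- function(series, t_warm = 5, t_cold = 5, span = 6L) {
  check_whole_years(series)
  if (anyNA(series$tmean)) stop("missing tmean values", call. = FALSE)
  cal <- series_calendar(series)
  gsl_one <- function(idx) {
    tm <- series$tmean[idx]
    yr <- series$year[idx][1]
    n <- length(tm)
    warm_start <- first_span_start(tm > t_warm, span)
    if (is.na(warm_start)) return(0)
    after <- july1_doy(yr, cal)              # cold span must start after Jul 1
    cold_flag <- tm < t_cold
    cold_flag[seq_len(min(after, n))] <- FALSE
    cold_start <- first_span_start(cold_flag, span)
    end_day <- if (is.na(cold_start)) n else cold_start - 1L
    max(0L, end_day - warm_start + 1L)
  }
  py <- vapply(split(seq_len(nrow(series)), series$year), gsl_one, numeric(1))
  list(per_year = py, mean = mean(py))
}

#' Annual accumulated precipitation (PRCPTOT)
#'
#' @param precip daily precipitation, mm.
#' @param years calendar year of each value.
#' @return list with `per_year` and `mean` (mm/yr).
#' @export
prcptot <- function(precip, years) {
  if (any(precip < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  py <- per_year(precip, years, sum)
  list(per_year = py, mean = mean(py))
}

#' Annual temperature extremes (TXx, TNn)
#'
#' Per-year maximum of daily maximum temperature and minimum of daily
#' minimum temperature; period values are means over the annual values.
#'
#' @param series a [daily_series()] with `tmin` and `tmax`, whole years.
#' @return list with `txx`, `tnn`, each holding `per_year` and `mean` (degC).
#' @export
txx_tnn <- function(series) {
  check_whole_years(series)
  if (anyNA(series$tmax) || anyNA(series$tmin))
    stop("missing temperature values", call. = FALSE)
  txx <- per_year(series$tmax, series$year, max)
  tnn <- per_year(series$tmin, series$year, min)
  list(txx = list(per_year = txx, mean = mean(txx)),
       tnn = list(per_year = tnn, mean = mean(tnn)))
}

## The index set reported per warming window (gradient characterization).
FORCING_INDEX_SET <- c("T", "TXx", "TNn", "frost_days", "summer_days", "GSL",
                       "PRCPTOT", "Rx1day", "R10mm", "CDD", "CWD")

#' Period means of the warming-gradient climate index set
#'
#' Computes the index set used to characterize each warming window: mean
#' air temperature (T), TXx, TNn, frost days (tmin < 0 degC), summer days
#' (tmax > 25 degC), growing season length, PRCPTOT, Rx1day, R10mm
#' (precip > 10 mm), CDD and CWD.
#'
#' @param series a [daily_series()] with all required variables, whole years.
#' @param frost_on `"tmin"` (default) or `"tmean"`: which temperature the
#'   frost-day comparison uses.
#' @return named numeric vector of period values.
#' @export
climate_index_set <- function(series, frost_on = c("tmin", "tmean")) {
  frost_on <- match.arg(frost_on)
  check_whole_years(series)
  c(T = mean(series$tmean),
    TXx = txx_tnn(series)$txx$mean,
    TNn = txx_tnn(series)$tnn$mean,
    frost_days = count_days(series[[frost_on]], series$year, "<", 0)$mean,
    summer_days = count_days(series$tmax, series$year, ">", 25)$mean,
    GSL = growing_season_length(series)$mean,
    PRCPTOT = prcptot(series$precip, series$year)$mean,
    Rx1day = rx1day(series$precip, series$year, series$month)$mean,
    R10mm = count_days(series$precip, series$year, ">", 10)$mean,
    CDD = max_spell(series$precip, series$year, "dry")$mean,
    CWD = max_spell(series$precip, series$year, "wet")$mean)
}

#' Climate index anomalies of a window relative to a reference period
#'
#' `delta = index(window) - index(reference)` for every index in
#' [climate_index_set()]; the absolute reference values are retained.
#'
#' @param window,reference [daily_series()] objects spanning whole years.
#' @param ... passed to [climate_index_set()].
#' @return an `index_anomaly_report` data frame: index, reference, window,
#'   delta.
#' @export
index_anomaly_report <- function(window, reference, ...) {
  iw <- climate_index_set(window, ...)
  ir <- climate_index_set(reference, ...)
  structure(data.frame(index = names(ir), reference = unname(ir),
                       window = unname(iw), delta = unname(iw - ir)),
            class = c("index_anomaly_report", "data.frame"))
}

#' @export
print.index_anomaly_report <- function(x, ...) {
  cat("Climate index anomalies (window minus reference):\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
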