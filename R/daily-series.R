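#' Daily meteorological series at a point
#'
#' The package's central daily container: one row per calendar day, with any
#' of mean/min/max air temperature (degC), precipitation (mm/day), relative
#' humidity (%) and surface wind speed (m/s). Missing values are `NA`. The
#' calendar (`"standard"`, `"365_day"` or `"360_day"`) is carried as an
#' attribute and never coerced implicitly.
#'
#' Internal units are fixed: degC, mm per day, %, m/s.
#'
#' @param year,month,day integer date components, strictly increasing, no
#'   duplicates, consistent with `calendar`.
#' @param tmean,tmin,tmax daily air temperatures, degC (optional).
#' @param precip daily precipitation, mm/day, non-negative (optional).
#' @param relhum daily mean relative humidity, %, in \[0, 100\] (optional).
#' @param wind daily mean surface wind speed, m/s, non-negative (optional).
#' @param calendar model calendar, see [month_lengths()].
#' @return a `daily_series` data frame.
#' @export
daily_series <- function(year, month, day, tmean = NULL, tmin = NULL,
                         tmax = NULL, precip = NULL, relhum = NULL,
                         wind = NULL, calendar = "standard") {
  check_calendar(calendar)
  n <- length(year)
  stopifnot(length(month) == n, length(day) == n)
  df <- data.frame(year = as.integer(year), month = as.integer(month),
                   day = as.integer(day))
  key <- df$year * 10000L + df$month * 100L + df$day
  if (anyDuplicated(key)) stop("duplicate dates in daily series", call. = FALSE)
  if (is.unsorted(key, strictly = TRUE)) {
    o <- order(key)
    df <- df[o, , drop = FALSE]
    reorder <- function(x) if (is.null(x)) NULL else x[o]
    tmean <- reorder(tmean); tmin <- reorder(tmin); tmax <- reorder(tmax)
    precip <- reorder(precip); relhum <- reorder(relhum); wind <- reorder(wind)
  }
  for (v in c("tmean", "tmin", "tmax", "precip", "relhum", "wind")) {
    val <- get(v)
    if (!is.null(val)) {
      if (length(val) != n) stop("length of ", v, " differs from dates", call. = FALSE)
      df[[v]] <- as.numeric(val)
    }
  }
  validate_daily_series(df)
  structure(df, class = c("daily_series", "data.frame"), calendar = calendar,
            row.names = seq_len(n))
}

validate_daily_series <- function(df) {
  if (!is.null(df$precip) && any(df$precip < 0, na.rm = TRUE))
    stop("negative precipitation in daily series", call. = FALSE)
  if (!is.null(df$relhum) && any(df$relhum < 0 | df$relhum > 100, na.rm = TRUE))
    stop("relative humidity outside [0, 100]", call. = FALSE)
  if (!is.null(df$wind) && any(df$wind < 0, na.rm = TRUE))
    stop("negative wind speed", call. = FALSE)
  if (!is.null(df$tmin) && !is.null(df$tmax)) {
    bad <- which(df$tmin > df$tmax + 1e-9)
    if (length(bad))
      stop("tmin > tmax on ", length(bad), " day(s)", call. = FALSE)
  }
  if (!is.null(df$tmean) && !is.null(df$tmin) && !is.null(df$tmax)) {
    bad <- which(df$tmean < df$tmin - 1e-9 | df$tmean > df$tmax + 1e-9)
    if (length(bad))
      stop("tmean outside [tmin, tmax] on ", length(bad), " day(s)", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.daily_series <- function(x, ...) {
  vars <- setdiff(names(x), c("year", "month", "day"))
  cat(sprintf("Daily meteorological series: %d days (%d-%d), calendar %s\n",
              nrow(x), x$year[1], x$year[nrow(x)], attr(x, "calendar")))
  cat("Variables:", if (length(vars)) paste(vars, collapse = ", ") else "(none)", "\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more days\n")
  invisible(x)
}

#' @export
summary.daily_series <- function(object, ...) {
  vars <- setdiff(names(object), c("year", "month", "day"))
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- object[[v]]
    data.frame(variable = v, n_missing = sum(is.na(x)),
               mean = mean(x, na.rm = TRUE),
               min = suppressWarnings(min(x, na.rm = TRUE)),
               max = suppressWarnings(max(x, na.rm = TRUE)))
  }))
  cat(sprintf("Daily series %d-%d (%s calendar), %d days\n",
              object$year[1], object$year[nrow(object)],
              attr(object, "calendar"), nrow(object)))
  print(out, row.names = FALSE)
  invisible(out)
}

#' Seasonal-cycle plot of a daily series
#'
#' Plots the twelve monthly climatological means of one variable, the same
#' cycle the seasonal-cycle mean absolute error compares.
#'
#' @param x a [daily_series()].
#' @param variable variable name to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.daily_series <- function(x, variable = "tmean", ...) {
  cyc <- seasonal_cycle(x[[variable]], x$month)
  graphics::plot(1:12, cyc, type = "b", xlab = "month",
                 ylab = paste("mean", variable), ...)
  invisible(cyc)
}

series_calendar <- function(x) {
  cal <- attr(x, "calendar")
  if (is.null(cal)) "standard" else cal
}

## Whole-calendar-year check used by annual indices.
check_whole_years <- function(x, allow_partial = FALSE) {
  cal <- series_calendar(x)
  cnt <- tapply(x$year, x$year, length)
  need <- days_in_year(as.integer(names(cnt)), cal)
  bad <- names(cnt)[cnt != need]
  if (length(bad) && !allow_partial)
    stop("series has partial year(s): ", paste(bad, collapse = ", "),
         " (pass allow_partial = TRUE to override)", call. = FALSE)
  invisible(x)
}

#' Subset a daily series to a range of calendar years
#'
#' @param x a [daily_series()].
#' @param start,end first and last year to keep (inclusive).
#' @return a `daily_series` covering the requested years.
#' @export
slice_years <- function(x, start, end) {
  if (min(x$year) > start || max(x$year) < end)
    stop(sprintf("series covers %d-%d but %d-%d requested",
                 min(x$year), max(x$year), start, end), call. = FALSE)
  out <- x[x$year >= start & x$year <= end, , drop = FALSE]
  structure(out, class = class(x), calendar = attr(x, "calendar"),
            row.names = seq_len(nrow(out)))
}
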