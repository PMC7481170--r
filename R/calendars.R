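#' @keywords internal
"_PACKAGE"

## Supported model calendars. Calendars are metadata: nothing in the package
## silently converts between them; day-of-year logic always uses the
## calendar's own year length.
CALENDARS <- c("standard", "365_day", "360_day")

check_calendar <- function(calendar) {
  if (!is.character(calendar) || length(calendar) != 1L || !calendar %in% CALENDARS)
    stop("calendar must be one of ", paste(CALENDARS, collapse = ", "),
         " (got ", deparse(calendar), ")", call. = FALSE)
  calendar
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Month lengths of a year under a model calendar
#'
#' @param year integer year.
#' @param calendar one of `"standard"`, `"365_day"`, `"360_day"`.
#' @return integer vector of 12 month lengths.
#' @export
month_lengths <- function(year, calendar = "standard") {
  check_calendar(calendar)
  switch(calendar,
    standard = c(31L, if (is_leap_year(year)) 29L else 28L,
                 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L),
    `365_day` = c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L),
    `360_day` = rep(30L, 12L))
}

#' @rdname month_lengths
#' @export
days_in_year <- function(year, calendar = "standard") {
  check_calendar(calendar)
  switch(calendar,
    standard = ifelse(is_leap_year(year), 366L, 365L),
    `365_day` = rep(365L, length(year)),
    `360_day` = rep(360L, length(year)))
}

## Full (year, month, day, doy) frame for a run of calendar years.
calendar_frame <- function(start_year, n_years, calendar = "standard") {
  check_calendar(calendar)
  years <- seq.int(start_year, length.out = n_years)
  parts <- lapply(years, function(y) {
    ml <- month_lengths(y, calendar)
    data.frame(year = y,
               month = rep.int(1:12, ml),
               day = unlist(lapply(ml, seq_len), use.names = FALSE))
  })
  out <- do.call(rbind, parts)
  out$doy <- unlist(lapply(years, function(y) seq_len(days_in_year(y, calendar))),
                    use.names = FALSE)
  out
}

## Day-of-year on which July falls; "after July 1" searches start past this.
july1_doy <- function(year, calendar) {
  sum(month_lengths(year, calendar)[1:6]) + 1L
}

## Offset arithmetic for CF time axes ("days since Y-m-d") under any
## supported calendar. `days` may be fractional; the date is taken from the
## integral part.
date_from_offset <- function(origin_year, origin_month, origin_day, days,
                             calendar = "standard") {
  check_calendar(calendar)
  origin_year <- as.integer(origin_year)
  whole <- as.integer(floor(days + 1e-9))
  doy0 <- as.integer(cumsum(c(0L, month_lengths(origin_year, calendar)))[origin_month] +
                       origin_day)
  out <- data.frame(year = integer(length(days)), month = integer(length(days)),
                    day = integer(length(days)))
  for (i in seq_along(days)) {
    y <- origin_year
    d <- doy0 + whole[i]          # 1-based doy in year y, may overflow
    while (d > days_in_year(y, calendar)) {
      d <- d - days_in_year(y, calendar)
      y <- y + 1L
    }
    while (d < 1L) {
      y <- y - 1L
      d <- d + days_in_year(y, calendar)
    }
    ml <- cumsum(month_lengths(y, calendar))
    m <- which.max(ml >= d)
    out$year[i] <- as.integer(y)
    out$month[i] <- as.integer(m)
    out$day[i] <- as.integer(d - c(0L, ml)[m])
  }
  out$hour <- (days - whole) * 24
  out
}

## Meteorological season membership. DJF groups December with the following
## January/February; the final year's December (which has no following
## winter) is dropped.
season_mask <- function(year, month, season = c("annual", "DJF", "JJA")) {
  season <- match.arg(season)
  if (season == "annual") return(rep(TRUE, length(month)))
  if (season == "JJA") return(month %in% 6:8)
  mask <- month %in% c(12L, 1L, 2L)
  mask[month == 12L & year == max(year)] <- FALSE
  mask
}
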