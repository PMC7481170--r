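## Conversion of extracted 3-hourly model output into the 30-min ecotron
## forcing table: linear interpolation of state variables, uniform
## precipitation disaggregation with drizzle accumulation, hydrostatic
## surface-pressure reduction, specific-to-relative humidity conversion and
## annual greenhouse-gas concentration attachment.

G_STD <- 9.80665        # m/s^2
R_DRY <- 287.05         # J/(kg K)
EPSILON <- 0.622        # molar mass ratio water vapor / dry air

subdaily_time_hours <- function(sub) {
  cal <- attr(sub, "calendar")
  if (is.null(cal)) cal <- "standard"
  ukey <- sub$year * 10000L + sub$month * 100L + sub$day
  day_index <- match(ukey, unique(ukey))
  (day_index - 1) * 24 + sub$hour
}

check_regular_step <- function(t, what = "series") {
  dt <- diff(t)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9)
    stop(what, " has an irregular time step", call. = FALSE)
  if (length(dt)) dt[1] else NA_real_
}

#' Linear interpolation of sub-daily state variables
#'
#' Interpolates the slowly varying state variables (temperature, pressure,
#' humidity, wind) from a regular 3-hourly grid to a finer step. Values at
#' the original knots are preserved exactly; between knots the value lies
#' on the straight line. Beyond the last knot of the series the final
#' segment is held constant so each day keeps a full complement of steps.
#' Precipitation (an accumulation) and heat fluxes are deliberately not
#' interpolated; see [disaggregate_precip()].
#'
#' @param sub a `subdaily_series` with a regular step.
#' @param target_step_hours output step, default 0.5 (30 min).
#' @param variables columns to interpolate; defaults to every state
#'   variable present.
#' @return a `subdaily_series` at the target step.
#' @export
interpolate_linear <- function(sub, target_step_hours = 0.5,
                               variables = intersect(c("tmean", "mslp", "surf_pressure",
                                                       "spechum", "relhum", "wind"),
                                                     names(sub))) {
  t_in <- subdaily_time_hours(sub)
  step <- check_regular_step(t_in, "input")
  if (is.na(step)) stop("need at least 2 steps", call. = FALSE)
  cal <- attr(sub, "calendar")
  ukey <- sub$year * 10000L + sub$month * 100L + sub$day
  udays <- sub[!duplicated(ukey), c("year", "month", "day")]
  n_days <- nrow(udays)
  per_day <- as.integer(24 / target_step_hours)
  t_out <- seq(0, n_days * 24 - target_step_hours, by = target_step_hours)
  idx <- rep(seq_len(n_days), each = per_day)
  out <- data.frame(year = udays$year[idx], month = udays$month[idx],
                    day = udays$day[idx],
                    hour = rep(seq(0, 24 - target_step_hours,
                                   by = target_step_hours), n_days))
  for (v in variables)
    out[[v]] <- stats::approx(t_in, sub[[v]], xout = t_out, rule = 2,
                              ties = "ordered")$y
  structure(out, class = c("subdaily_series", "data.frame"),
            step_hours = target_step_hours, calendar = cal)
}

#' Uniform precipitation disaggregation
#'
#' Splits each coarse-step precipitation accumulation uniformly over its
#' sub-steps. Interpolating an accumulation would destroy mass
#' conservation, so disaggregation is uniform and exact: each 3-h amount
#' becomes six equal 30-min amounts.
#'
#' @param precip precipitation per coarse step, mm, non-negative.
#' @param n_sub number of sub-steps per coarse step (6 for 3 h to 30 min).
#' @return precipitation per sub-step, mm.
#' @export
disaggregate_precip <- function(precip, n_sub = 6L) {
  if (any(precip < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  stopifnot(n_sub >= 1)
  rep(precip / n_sub, each = n_sub)
}

#' Drizzle accumulation filter
#'
#' Irrigation hardware cannot deliver sub-millimetre events, so drizzle is
#' postponed: scanning steps in time order, amounts are added to a
#' carry-over buffer and nothing is released while buffer + amount stays
#' below the threshold; once it reaches the threshold the whole
#' accumulation is released at that step and the buffer resets. The
#' terminal buffer is returned, never silently dropped, so mass is
#' conserved as released + buffer = input.
#'
#' @param precip precipitation per step, mm, non-negative.
#' @param threshold release threshold, mm (default 1).
#' @param buffer initial carry-over, mm (default 0), e.g. from a preceding
#'   window.
#' @return list with `released` (per-step output, every non-zero entry
#'   `>= threshold`) and `buffer` (terminal carry-over `< threshold`).
#' @export
drizzle_filter <- function(precip, threshold = 1, buffer = 0) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (any(precip < 0, na.rm = TRUE)) stop("negative precipitation", call. = FALSE)
  out <- numeric(length(precip))
  for (i in seq_along(precip)) {
    total <- buffer + precip[i]
    if (total >= threshold) {
      out[i] <- total
      buffer <- 0
    } else {
      buffer <- total
    }
  }
  list(released = out, buffer = buffer)
}

#' Surface pressure from mean sea level pressure
#'
#' Isothermal hydrostatic reduction
#' `p = mslp * exp(-g z / (R_d T_K))` with the concurrent air temperature;
#' over the tens of metres relevant here the difference from a lapse-rate
#' formula is below 1 Pa.
#'
#' @param mslp mean sea level pressure, Pa.
#' @param elevation site elevation, m above sea level (default 43, the
#'   ecotron facility).
#' @param tair concurrent air temperature, degC.
#' @return surface pressure, Pa.
#' @export
surface_pressure_from_msl <- function(mslp, elevation = 43, tair) {
  if (any(mslp <= 0, na.rm = TRUE)) stop("non-positive pressure", call. = FALSE)
  mslp * exp(-G_STD * elevation / (R_DRY * (tair + 273.15)))
}

#' Saturation vapor pressure over water (Magnus)
#'
#' `e_s(T) = 611.2 * exp(17.62 T / (243.12 + T))` Pa. Saturation is taken
#' over water only: the conversion feeds a controlled chamber, not an ice
#' surface.
#'
#' @param tair air temperature, degC.
#' @return saturation vapor pressure, Pa.
#' @export
saturation_vapor_pressure <- function(tair) {
  611.2 * exp(17.62 * tair / (243.12 + tair))
}

#' Relative humidity from specific humidity
#'
#' Vapor pressure `e = q p / (eps + (1 - eps) q)` with `eps = 0.622`, then
#' `RH = 100 e / e_s(T)`, clipped to \[0, 100\]; the number of clipped
#' steps is recorded in the `"n_clipped"` attribute.
#'
#' @param spechum specific humidity, kg/kg, in \[0, 0.1).
#' @param tair air temperature, degC.
#' @param pressure air pressure, Pa.
#' @return relative humidity, %, with attribute `n_clipped`.
#' @export
relative_humidity_from_specific <- function(spechum, tair, pressure) {
  if (any(spechum < 0, na.rm = TRUE)) stop("negative specific humidity", call. = FALSE)
  if (any(spechum >= 0.1, na.rm = TRUE)) stop("implausible specific humidity >= 0.1",
                                              call. = FALSE)
  if (any(pressure <= 0, na.rm = TRUE)) stop("non-positive pressure", call. = FALSE)
  e <- spechum * pressure / (EPSILON + (1 - EPSILON) * spechum)
  rh <- 100 * e / saturation_vapor_pressure(tair)
  n_clip <- sum(rh < 0 | rh > 100, na.rm = TRUE)
  structure(pmin(100, pmax(0, rh)), n_clipped = n_clip)
}

#' Specific humidity from relative humidity
#'
#' Algebraic inverse of [relative_humidity_from_specific()]:
#' `e = RH/100 * e_s(T)`, `q = eps e / (p - (1 - eps) e)`.
#'
#' @param relhum relative humidity, %.
#' @param tair air temperature, degC.
#' @param pressure air pressure, Pa.
#' @return specific humidity, kg/kg.
#' @export
specific_humidity_from_relative <- function(relhum, tair, pressure) {
  e <- relhum / 100 * saturation_vapor_pressure(tair)
  EPSILON * e / (pressure - (1 - EPSILON) * e)
}

#' Assemble the 30-min ecotron forcing tables
#'
#' For each warming window: slices the run's 3-hourly series, linearly
#' interpolates the state variables to 30 min, uniformly disaggregates and
#' drizzle-filters precipitation, derives surface pressure from mean sea
#' level pressure (using the concurrent interpolated air temperature) and
#' relative humidity from specific humidity, and attaches the annual
#' greenhouse-gas concentrations as a step function of the year. One
#' forcing table is produced per warming unit.
#'
#' @param run a [model_run()] carrying a 3-hourly `subdaily` series that
#'   covers every window.
#' @param windows a [warming_windows()] table.
#' @param ghg a [ghg_table()] covering all window years.
#' @param elevation site elevation, m a.s.l. (default 43).
#' @param drizzle_threshold release threshold, mm (default 1).
#' @return named list (one element per threshold, e.g. `"+2C"`) of
#'   `forcing_table` data frames with attributes `run`, `window`,
#'   `residual_buffer`.
#' @export
assemble_forcing <- function(run, windows, ghg, elevation = 43,
                             drizzle_threshold = 1) {
  stopifnot(inherits(run, "model_run"))
  if (is.null(run$subdaily)) stop("run has no sub-daily series", call. = FALSE)
  sub <- run$subdaily
  if (attr(sub, "step_hours") != 3)
    stop("expected 3-hourly sub-daily input", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (min(sub$year) > w$start || max(sub$year) < w$end)
      stop(sprintf("window %+g degC (%d-%d) outside sub-daily coverage %d-%d",
                   w$threshold, w$start, w$end, min(sub$year), max(sub$year)),
           call. = FALSE)
    sl <- sub[sub$year >= w$start & sub$year <= w$end, , drop = FALSE]
    sl <- structure(sl, class = class(sub), step_hours = attr(sub, "step_hours"),
                    calendar = attr(sub, "calendar"), row.names = seq_len(nrow(sl)))
    st <- interpolate_linear(sl, 0.5)
    dr <- drizzle_filter(disaggregate_precip(sl$precip, 6L),
                         threshold = drizzle_threshold)
    pres <- if ("surf_pressure" %in% names(st)) st$surf_pressure
            else surface_pressure_from_msl(st$mslp, elevation, st$tmean)
    rh <- if ("relhum" %in% names(st)) st$relhum
          else relative_humidity_from_specific(st$spechum, st$tmean, pres)
    conc <- ghg_lookup(ghg, st$year)
    tab <- data.frame(year = st$year, month = st$month, day = st$day,
                      hour = st$hour, tair = st$tmean, precip = dr$released,
                      relhum = as.numeric(rh), wind = st$wind,
                      pressure = pres, co2 = conc$co2, ch4 = conc$ch4,
                      n2o = conc$n2o)
    label <- if (w$threshold == 0) "0C" else sprintf("+%gC", w$threshold)
    out[[label]] <- structure(tab,
                              class = c("forcing_table", "data.frame"),
                              step_hours = 0.5,
                              calendar = attr(sub, "calendar"),
                              run = run_id(run),
                              window = c(threshold = w$threshold,
                                         start = w$start, end = w$end),
                              residual_buffer = dr$buffer,
                              rh_clipped = attr(rh, "n_clipped"))
  }
  out
}

#' @export
print.forcing_table <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Ecotron forcing table: %s, %+g degC window %d-%d\n",
              attr(x, "run"), w["threshold"], w["start"], w["end"]))
  cat(sprintf("  %d steps of %g h; residual drizzle buffer %.4f mm\n",
              nrow(x), attr(x, "step_hours"), attr(x, "residual_buffer")))
  print(utils::head(as.data.frame(x), 3), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
summary.forcing_table <- function(object, ...) {
  w <- attr(object, "window")
  ev <- object$precip[object$precip > 0]
  cat(sprintf("Forcing %s, %+g degC (%d-%d): %d steps\n", attr(object, "run"),
              w["threshold"], w["start"], w["end"], nrow(object)))
  cat(sprintf("  precip: %.1f mm released in %d events (min event %.3f mm), buffer %.4f mm\n",
              sum(object$precip), length(ev),
              if (length(ev)) min(ev) else NA_real_,
              attr(object, "residual_buffer")))
  cat(sprintf("  tair %.2f..%.2f degC, RH %.1f..%.1f %%, wind %.2f..%.2f m/s\n",
              min(object$tair), max(object$tair), min(object$relhum),
              max(object$relhum), min(object$wind), max(object$wind)))
  invisible(object)
}
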