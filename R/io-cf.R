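## CF-convention model output at a point. The grid may be rotated-pole: cell
## selection always happens in true geographic coordinates via great-circle
## distance to the cell centers. Units are converted on loading (K -> degC,
## precipitation flux kg m-2 s-1 -> mm per step); the calendar attribute is
## mandatory and carried as metadata, never coerced.

#' Kelvin / Celsius conversions
#'
#' @param x temperature values.
#' @return converted values.
#' @export
k_to_celsius <- function(x) x - 273.15

#' @rdname k_to_celsius
#' @export
celsius_to_k <- function(x) x + 273.15

#' Precipitation flux / accumulation conversions
#'
#' CF precipitation is a mass flux (kg m-2 s-1); 1 kg/m2 of water is 1 mm
#' depth, so `mm_step = flux * step_seconds`.
#'
#' @param flux precipitation flux, kg m-2 s-1.
#' @param step_seconds accumulation step length, s.
#' @return mm per step.
#' @export
flux_to_mm_step <- function(flux, step_seconds) flux * step_seconds

#' @rdname flux_to_mm_step
#' @param mm_step precipitation depth per step, mm.
#' @export
mm_step_to_flux <- function(mm_step, step_seconds) mm_step / step_seconds

#' Nearest grid cell in true geographic coordinates
#'
#' Great-circle distance from the target point to every cell center;
#' ties are broken by the lowest cell index.
#'
#' @param grid_lon,grid_lat true longitudes/latitudes of the cell centers
#'   (vectors or matrices of equal shape), decimal degrees.
#' @param lon,lat target point.
#' @return integer index into `grid_lon`/`grid_lat` (column-major for
#'   matrices).
#' @export
nearest_grid_cell <- function(grid_lon, grid_lat, lon, lat) {
  d <- geosphere::distHaversine(cbind(as.vector(grid_lon), as.vector(grid_lat)),
                                c(lon, lat))
  ## lowest-index tie break, robust to floating-point jitter in the
  ## great-circle evaluation
  which(d <= min(d) + max(1e-6, 1e-12 * min(d)))[1]
}

## Bounding-box containment check with a half-cell margin estimated from
## the center spacing.
point_in_grid <- function(grid_lon, grid_lat, lon, lat) {
  margin_lon <- if (length(unique(as.vector(grid_lon))) > 1)
    max(abs(diff(sort(unique(as.vector(grid_lon)))))) else 1
  margin_lat <- if (length(unique(as.vector(grid_lat))) > 1)
    max(abs(diff(sort(unique(as.vector(grid_lat)))))) else 1
  lon >= min(grid_lon) - margin_lon && lon <= max(grid_lon) + margin_lon &&
    lat >= min(grid_lat) - margin_lat && lat <= max(grid_lat) + margin_lat
}

#' Extract a point series from an in-memory CF-style grid
#'
#' The workhorse behind [read_cf_point_series()], usable directly on grids
#' already in memory: picks the cell whose center is nearest to the target
#' point, converts units to the package's internal conventions, and tags
#' the result with the (mandatory) calendar.
#'
#' @param values numeric array: cells x time (a matrix whose rows follow
#'   `grid_lon`), or a vector for a single-cell extract.
#' @param grid_lon,grid_lat true cell-center coordinates.
#' @param time_days CF time coordinate, days since the origin.
#' @param origin integer vector `c(year, month, day)` of the time origin.
#' @param calendar CF calendar attribute; required.
#' @param units CF units of `values` (`"K"`, `"degC"`, `"kg m-2 s-1"`,
#'   `"mm"`, `"%"`, `"m s-1"`, `"Pa"`, `"1"`).
#' @param lon,lat target point, decimal degrees.
#' @param step_seconds accumulation step for flux conversion; inferred from
#'   the time coordinate when omitted.
#' @return data frame `year`, `month`, `day`, `hour`, `value` with
#'   attributes `calendar`, `units` (converted), `cell`.
#' @export
extract_grid_point <- function(values, grid_lon, grid_lat, time_days, origin,
                               calendar, units, lon, lat,
                               step_seconds = NULL) {
  if (is.null(calendar) || is.na(calendar))
    stop("calendar attribute is required and absent", call. = FALSE)
  calendar <- check_calendar(calendar)
  if (!point_in_grid(grid_lon, grid_lat, lon, lat))
    stop(sprintf("point (%g, %g) outside the grid bounds", lon, lat),
         call. = FALSE)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  cell <- nearest_grid_cell(grid_lon, grid_lat, lon, lat)
  series <- values[cell, ]
  if (is.null(step_seconds))
    step_seconds <- if (length(time_days) > 1)
      round(stats::median(diff(time_days)) * 86400) else 86400
  out_units <- units
  if (units == "K") {
    series <- k_to_celsius(series); out_units <- "degC"
  } else if (units %in% c("kg m-2 s-1", "kg/m2/s")) {
    series <- flux_to_mm_step(series, step_seconds); out_units <- "mm/step"
  }
  dates <- date_from_offset(origin[1], origin[2], origin[3], time_days,
                            calendar = calendar)
  structure(data.frame(year = dates$year, month = dates$month,
                       day = dates$day, hour = dates$hour, value = series),
            calendar = calendar, units = out_units, cell = cell,
            step_seconds = step_seconds)
}

parse_cf_time_units <- function(units_string) {
  m <- regmatches(units_string,
                  regexec("^\\s*(\\w+)\\s+since\\s+(\\d{1,4})-(\\d{1,2})-(\\d{1,2})",
                          units_string))[[1]]
  if (!length(m)) stop("unparsable CF time units: ", units_string, call. = FALSE)
  list(unit = tolower(m[2]),
       origin = as.integer(c(m[3], m[4], m[5])))
}

cf_time_to_days <- function(time, unit) {
  switch(unit,
    days = time,
    hours = time / 24,
    minutes = time / 1440,
    seconds = time / 86400,
    stop("unsupported CF time unit: ", unit, call. = FALSE))
}

#' Read a point series from a CF-convention NetCDF file
#'
#' Opens a (possibly rotated-pole) CF NetCDF file, locates the grid cell
#' whose true-coordinate center is nearest to the requested point, and
#' returns that cell's series with units converted and the calendar
#' recorded. Requires the optional ncdf4 package; files without a calendar
#' attribute on the time coordinate are rejected.
#'
#' Grids are located through the auxiliary 2-D `lon`/`lat` coordinate
#' variables when present (rotated-pole output), falling back to 1-D
#' coordinate variables named `lon`/`longitude` and `lat`/`latitude`.
#'
#' @param path NetCDF file.
#' @param variable CF variable name (e.g. `"tas"`, `"pr"`).
#' @param lon,lat target point in true decimal degrees.
#' @return as [extract_grid_point()].
#' @export
read_cf_point_series <- function(path, variable, lon, lat) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading NetCDF requires the ncdf4 package; install it or use the CSV readers",
         call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop("variable ", variable, " not in file", call. = FALSE)
  cal_att <- ncdf4::ncatt_get(nc, "time", "calendar")
  if (!cal_att$hasatt)
    stop("time coordinate has no calendar attribute; refusing to guess",
         call. = FALSE)
  cal <- sub("^gregorian$|^proleptic_gregorian$", "standard", cal_att$value)
  cal <- sub("^noleap$", "365_day", cal)
  tu <- parse_cf_time_units(ncdf4::ncatt_get(nc, "time", "units")$value)
  time_days <- cf_time_to_days(ncdf4::ncvar_get(nc, "time"), tu$unit)
  units <- ncdf4::ncatt_get(nc, variable, "units")$value
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)

  grids <- names(nc$var)
  if (all(c("lon", "lat") %in% grids)) {          # 2-D auxiliary coordinates
    glon <- ncdf4::ncvar_get(nc, "lon")
    glat <- ncdf4::ncvar_get(nc, "lat")
  } else {
    dn <- names(nc$dim)
    lon_d <- intersect(c("lon", "longitude", "rlon", "x"), dn)[1]
    lat_d <- intersect(c("lat", "latitude", "rlat", "y"), dn)[1]
    if (is.na(lon_d) || is.na(lat_d))
      stop("cannot locate grid coordinates in file", call. = FALSE)
    glon <- matrix(nc$dim[[lon_d]]$vals,
                   nrow = length(nc$dim[[lon_d]]$vals),
                   ncol = length(nc$dim[[lat_d]]$vals))
    glat <- matrix(nc$dim[[lat_d]]$vals,
                   nrow = length(nc$dim[[lon_d]]$vals),
                   ncol = length(nc$dim[[lat_d]]$vals), byrow = TRUE)
  }
  n_cells <- length(glon)
  n_time <- length(time_days)
  vals <- matrix(vals, nrow = n_cells, ncol = n_time)
  extract_grid_point(vals, glon, glat, time_days, tu$origin, cal, units,
                     lon, lat)
}
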