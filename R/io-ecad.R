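## ECA&D blended daily station text. The dialect: a free-text header block,
## then a column-header line (STAID, SOUID, DATE, <VAR>, Q_<VAR>) and
## comma-separated data rows. Values are stored in tenths of the physical
## unit for temperatures, precipitation and wind (0.1 degC / 0.1 mm /
## 0.1 m/s) and whole percent for humidity; -9999 is the missing sentinel
## and quality flag 9 marks missing values.

ECAD_VARS <- data.frame(
  code = c("TG", "TN", "TX", "RR", "HU", "FG"),
  variable = c("tmean", "tmin", "tmax", "precip", "relhum", "wind"),
  scale = c(0.1, 0.1, 0.1, 0.1, 1, 0.1),
  stringsAsFactors = FALSE)

#' Read one variable from an ECA&D blended daily station file
#'
#' Supported element codes: TG/TN/TX (temperature), RR (precipitation),
#' HU (relative humidity), FG (wind speed). Values are rescaled to the
#' package's physical units on loading. Quality flag 9 always becomes
#' missing; flag 1 ("suspect") is kept by default and dropped with
#' `drop_suspect = TRUE`.
#'
#' @param path path to the ECA&D text file.
#' @param variable element code (e.g. `"TG"`) or internal name (e.g.
#'   `"tmean"`).
#' @param drop_suspect treat quality flag 1 as missing.
#' @return data frame with columns `year`, `month`, `day`, and the variable
#'   in physical units; attributes `station_id`, `variable`.
#' @export
read_ecad_series <- function(path, variable, drop_suspect = FALSE) {
  spec <- ECAD_VARS[ECAD_VARS$code == toupper(variable) |
                      ECAD_VARS$variable == variable, ]
  if (nrow(spec) != 1)
    stop("unsupported ECA&D variable: ", variable, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("STAID", lines)
  hdr <- hdr[grepl("DATE", lines[hdr])]
  if (!length(hdr))
    stop("not an ECA&D blended daily file: no STAID/DATE column header in ",
         path, call. = FALSE)
  hdr <- hdr[length(hdr)]
  df <- utils::read.csv(text = lines[hdr:length(lines)], strip.white = TRUE,
                        check.names = TRUE)
  names(df) <- toupper(trimws(names(df)))
  qcol <- paste0("Q_", spec$code)
  if (!all(c("DATE", spec$code, qcol) %in% names(df)))
    stop("file does not carry element ", spec$code, call. = FALSE)
  val <- df[[spec$code]] * spec$scale
  val[df[[spec$code]] == -9999] <- NA
  val[df[[qcol]] == 9] <- NA
  if (drop_suspect) val[df[[qcol]] == 1] <- NA
  date <- as.integer(df$DATE)
  out <- data.frame(year = date %/% 10000L, month = (date %/% 100L) %% 100L,
                    day = date %% 100L)
  out[[spec$variable]] <- val
  structure(out, station_id = if ("STAID" %in% names(df)) df$STAID[1] else NA,
            variable = spec$variable)
}

#' Write a series in the ECA&D blended daily layout
#'
#' Inverse of [read_ecad_series()]; mainly useful for building small test
#' fixtures and for exporting gap-filled series in a familiar dialect.
#'
#' @param df data frame with `year`, `month`, `day` and one variable column.
#' @param path output file.
#' @param variable element code or internal name.
#' @param station_id STAID to write.
#' @export
write_ecad_series <- function(df, path, variable, station_id = 1L) {
  spec <- ECAD_VARS[ECAD_VARS$code == toupper(variable) |
                      ECAD_VARS$variable == variable, ]
  if (nrow(spec) != 1) stop("unsupported ECA&D variable: ", variable, call. = FALSE)
  val <- df[[spec$variable]]
  raw <- ifelse(is.na(val), -9999L, as.integer(round(val / spec$scale)))
  q <- ifelse(is.na(val), 9L, 0L)
  lines <- c("EUROPEAN CLIMATE ASSESSMENT & DATASET (ECA&D) style daily series",
             "This is a synthetic series written by the climforce package.",
             "",
             sprintf("STAID, SOUID,    DATE,   %s, Q_%s", spec$code, spec$code),
             sprintf("%5d,%6d,%8d,%6d,%5d", station_id, station_id,
                     df$year * 10000L + df$month * 100L + df$day, raw, q))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a station record from ECA&D per-variable files
#'
#' @param paths named character vector or list: element code or internal
#'   variable name -> file path.
#' @param station_id,name,lon,lat,elevation station metadata; longitude and
#'   latitude in decimal degrees, elevation in m.
#' @param drop_suspect passed to [read_ecad_series()].
#' @return a `station_record` list with a [daily_series()] in `$series`.
#' @export
read_station_record <- function(paths, station_id = NA, name = "",
                                lon = NA_real_, lat = NA_real_,
                                elevation = NA_real_, drop_suspect = FALSE) {
  if (!is.na(lat) && (lat < -90 || lat > 90)) stop("latitude out of range", call. = FALSE)
  if (!is.na(lon) && (lon <= -180 || lon > 180)) stop("longitude out of range", call. = FALSE)
  parts <- lapply(names(paths), function(v)
    read_ecad_series(paths[[v]], v, drop_suspect = drop_suspect))
  merged <- Reduce(function(a, b) merge(a, b, by = c("year", "month", "day"),
                                        all = TRUE), parts)
  merged <- merged[order(merged$year, merged$month, merged$day), ]
  series <- do.call(daily_series, c(
    list(year = merged$year, month = merged$month, day = merged$day),
    merged[setdiff(names(merged), c("year", "month", "day"))]))
  structure(list(station_id = station_id, name = name, lon = lon, lat = lat,
                 elevation = elevation, series = series),
            class = "station_record")
}

#' @export
print.station_record <- function(x, ...) {
  cat(sprintf("Station %s (%s) at lon %.3f, lat %.3f, %s m\n",
              x$station_id, x$name, x$lon, x$lat, x$elevation))
  print(x$series)
  invisible(x)
}
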