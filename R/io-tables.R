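## CSV plumbing: the forcing table writer/reader, the annual greenhouse-gas
## concentration table, GMT series and the YAML run configuration.

#' Write a forcing table to CSV
#'
#' One row per 30-min step with an ISO-8601 timestamp column followed by
#' the controlled variables in fixed order. Refuses irregular step
#' spacing. Values are written with enough digits that a read-back
#' reproduces the table to better than 1e-9.
#'
#' @param table a `forcing_table` from [assemble_forcing()].
#' @param path output CSV path.
#' @export
write_forcing_table <- function(table, path) {
  step <- attr(table, "step_hours")
  t <- subdaily_time_hours(table)
  check_regular_step(t, "forcing table")
  cols <- intersect(c("tair", "precip", "relhum", "wind", "pressure",
                      "co2", "ch4", "n2o"), names(table))
  ts <- sprintf("%04d-%02d-%02dT%02d:%02d:00", table$year, table$month,
                table$day, floor(table$hour), round((table$hour %% 1) * 60))
  df <- cbind(data.frame(timestamp = ts),
              as.data.frame(lapply(table[cols], function(x)
                formatC(x, format = "g", digits = 15))))
  meta <- sprintf("# climforce forcing table; run=%s; threshold=%s; step_hours=%s; calendar=%s; residual_buffer_mm=%.12g",
                  attr(table, "run"), attr(table, "window")["threshold"],
                  step, attr(table, "calendar"), attr(table, "residual_buffer"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a forcing table written by [write_forcing_table()]
#'
#' @param path CSV path.
#' @return a `forcing_table` data frame.
#' @export
read_forcing_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# climforce forcing table"))
    stop("not a climforce forcing table: ", path, call. = FALSE)
  meta_of <- function(key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", first)
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  ts <- df$timestamp
  out <- data.frame(year = as.integer(substr(ts, 1, 4)),
                    month = as.integer(substr(ts, 6, 7)),
                    day = as.integer(substr(ts, 9, 10)),
                    hour = as.integer(substr(ts, 12, 13)) +
                      as.integer(substr(ts, 15, 16)) / 60)
  for (v in setdiff(names(df), "timestamp")) out[[v]] <- as.numeric(df[[v]])
  structure(out, class = c("forcing_table", "data.frame"),
            step_hours = as.numeric(meta_of("step_hours")),
            calendar = meta_of("calendar"),
            run = meta_of("run"),
            window = c(threshold = as.numeric(meta_of("threshold")),
                       start = if (nrow(out)) min(out$year) else NA_integer_,
                       end = if (nrow(out)) max(out$year) else NA_integer_),
            residual_buffer = as.numeric(meta_of("residual_buffer_mm")))
}

#' Annual greenhouse-gas concentration table
#'
#' @param year contiguous integer years.
#' @param co2 CO2 concentration, ppm.
#' @param ch4 CH4 concentration, ppb.
#' @param n2o N2O concentration, ppb.
#' @return a `ghg_table` data frame.
#' @export
ghg_table <- function(year, co2, ch4, n2o) {
  df <- data.frame(year = as.integer(year), co2 = co2, ch4 = ch4, n2o = n2o)
  df <- df[order(df$year), ]
  if (any(diff(df$year) != 1))
    stop("greenhouse-gas years must be contiguous", call. = FALSE)
  if (any(df$co2 <= 0 | df$ch4 <= 0 | df$n2o <= 0))
    stop("non-positive greenhouse-gas concentration", call. = FALSE)
  structure(df, class = c("ghg_table", "data.frame"),
            row.names = seq_len(nrow(df)))
}

#' Read an annual greenhouse-gas table from CSV
#'
#' Expects columns `year`, `co2` (ppm), `ch4` (ppb), `n2o` (ppb);
#' validates contiguity and positivity.
#'
#' @param path CSV path.
#' @return a [ghg_table()].
#' @export
read_ghg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "co2", "ch4", "n2o")
  if (!all(need %in% names(df)))
    stop("greenhouse-gas table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ghg_table(df$year, df$co2, df$ch4, df$n2o)
}

#' Look up greenhouse-gas concentrations by year
#'
#' @param ghg a [ghg_table()].
#' @param year integer year(s), all inside the covered range.
#' @return data frame of `co2`, `ch4`, `n2o` aligned with `year`.
#' @export
ghg_lookup <- function(ghg, year) {
  idx <- match(year, ghg$year)
  if (anyNA(idx))
    stop("year(s) outside the greenhouse-gas table range ",
         min(ghg$year), "-", max(ghg$year), ": ",
         paste(unique(year[is.na(idx)]), collapse = ", "), call. = FALSE)
  ghg[idx, c("co2", "ch4", "n2o")]
}

#' Read an annual GMT series from CSV
#'
#' @param path CSV with columns `year`, `gmt` (degC).
#' @return data frame `year`, `gmt`.
#' @export
read_gmt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "gmt") %in% names(df)))
    stop("GMT series needs columns year, gmt", call. = FALSE)
  df[order(df$year), c("year", "gmt")]
}

#' Write a skill or rank table to tidy CSV
#'
#' @param x a [skill_table()] or [rank_table()].
#' @param path CSV path.
#' @export
write_skill_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML file listing the station, site coordinates and elevation, candidate
#' runs, warming thresholds and window length. Light validation only: the
#' configuration carries paths and labels; each consumer validates its own
#' inputs.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("site")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("lon", "lat", "elevation") %in% names(cfg$site)))
    stop("site must declare lon, lat, elevation", call. = FALSE)
  cfg
}
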