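## Global-warming-level time sampling: smooth the driving GCM's annual GMT
## into climatological anomalies, find the first year each warming
## threshold is attained, and build experiment-length extraction windows.

#' Climatological GMT anomaly series
#'
#' Smooths an annual GMT series with a centered running mean of
#' `window` years (for even windows the extra year lies toward the past,
#' i.e. year `y` averages `y - w/2 .. y + w/2 - 1`) and subtracts the plain
#' mean of the raw series over the reference years. Years without a
#' complete smoothing window are dropped, not padded. A trailing alignment
#' is available for sensitivity checks.
#'
#' @param gmt data frame with columns `year` and `gmt` (degC), contiguous
#'   years.
#' @param reference reference year range `c(first, last)`, default
#'   1951-1955.
#' @param window smoothing window length in years, default 30.
#' @param align `"centered"` (default) or `"trailing"`.
#' @return a `gmt_anomaly` data frame with columns `year`, `anomaly`;
#'   attributes `reference`, `window`.
#' @export
gmt_anomaly <- function(gmt, reference = c(1951, 1955), window = 30,
                        align = c("centered", "trailing")) {
  align <- match.arg(align)
  stopifnot(all(c("year", "gmt") %in% names(gmt)), window >= 1)
  gmt <- gmt[order(gmt$year), ]
  if (any(diff(gmt$year) != 1)) stop("GMT years must be contiguous", call. = FALSE)
  if (!all(seq(reference[1], reference[2]) %in% gmt$year))
    stop("reference period outside the GMT series", call. = FALSE)
  n <- nrow(gmt)
  if (n < window) stop("series shorter than the smoothing window", call. = FALSE)
  sm <- as.numeric(stats::filter(gmt$gmt, rep(1 / window, window), sides = 2))
  if (align == "centered") {
    ## stats::filter centers even windows toward the future; shift one year
    ## so the extra year lies toward the past.
    if (window %% 2 == 0) sm <- c(NA, sm[-n])
  } else {
    sm <- as.numeric(stats::filter(gmt$gmt, rep(1 / window, window), sides = 1))
  }
  ref_mean <- mean(gmt$gmt[gmt$year >= reference[1] & gmt$year <= reference[2]])
  keep <- !is.na(sm)
  structure(data.frame(year = gmt$year[keep], anomaly = sm[keep] - ref_mean),
            class = c("gmt_anomaly", "data.frame"),
            reference = reference, window = window)
}

reference_midpoint <- function(reference) {
  as.integer(floor((reference[1] + reference[2]) / 2))
}

#' First year a warming threshold is attained
#'
#' Smallest year whose climatological GMT anomaly is at or above the
#' threshold (attainment, not interpolation). The 0 degC threshold maps by
#' convention to the reference-period midpoint, so the historical window is
#' the reference period itself.
#'
#' @param anomalies a [gmt_anomaly()] series.
#' @param threshold warming threshold, degC.
#' @return integer crossing year.
#' @export
first_crossing_year <- function(anomalies, threshold) {
  stopifnot(inherits(anomalies, "gmt_anomaly"), nrow(anomalies) > 0)
  if (threshold <= 0)
    return(reference_midpoint(attr(anomalies, "reference")))
  hit <- which(anomalies$anomaly >= threshold)
  if (!length(hit))
    stop(sprintf("threshold %+g degC never reached (maximum anomaly %+.3f degC in %d)",
                 threshold, max(anomalies$anomaly),
                 anomalies$year[which.max(anomalies$anomaly)]), call. = FALSE)
  as.integer(anomalies$year[hit[1]])
}

#' Extraction window for a crossing year
#'
#' Window of `length` years centered on the crossing year; for even
#' lengths the extra year lies toward the past.
#'
#' @param crossing integer crossing year.
#' @param length window length in years (the experimental period), default 5.
#' @return named integer vector `c(start, end)`.
#' @export
window_for_threshold <- function(crossing, length = 5) {
  stopifnot(length >= 1)
  start <- as.integer(crossing - length %/% 2)
  c(start = start, end = start + as.integer(length) - 1L)
}

#' Warming windows along a GMT anomaly gradient
#'
#' Builds the per-threshold extraction windows: first attainment year of
#' each warming level plus a centered window of the experiment length. An
#' error names any window extending beyond the scenario years available in
#' the GMT series (windows are never silently truncated).
#'
#' @param gmt annual GMT data frame (`year`, `gmt`).
#' @param thresholds warming levels in degC, default
#'   `c(0, 1, 1.5, 2, 3, 4)`.
#' @param length window length in years, default 5.
#' @param reference,window,align passed to [gmt_anomaly()].
#' @return a `warming_windows` data frame: threshold, crossing, start, end.
#' @export
warming_windows <- function(gmt, thresholds = c(0, 1, 1.5, 2, 3, 4),
                            length = 5, reference = c(1951, 1955),
                            window = 30, align = "centered") {
  anom <- gmt_anomaly(gmt, reference, window, align)
  rows <- lapply(thresholds, function(th) {
    cross <- first_crossing_year(anom, th)
    w <- window_for_threshold(cross, length)
    data.frame(threshold = th, crossing = cross, start = w["start"],
               end = w["end"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- out$start < min(gmt$year) | out$end > max(gmt$year)
  if (any(bad))
    stop("window(s) outside the GMT series: ",
         paste(sprintf("%+g degC (%d-%d)", out$threshold[bad], out$start[bad],
                       out$end[bad]), collapse = "; "), call. = FALSE)
  structure(out, class = c("warming_windows", "data.frame"),
            reference = reference, length = length)
}

#' @export
print.warming_windows <- function(x, ...) {
  cat(sprintf("Warming windows (%d-year, reference %d-%d):\n",
              attr(x, "length"), attr(x, "reference")[1],
              attr(x, "reference")[2]))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Window-length sensitivity of the index anomalies
#'
#' Recomputes every gradient index anomaly for windows of increasing
#' length at each warming threshold. For each length the reference is the
#' 0 degC window of that same length (centered on the reference midpoint),
#' so the threshold-0 row is identically zero and rows are comparable
#' within a length.
#'
#' @param series scenario [daily_series()] of the selected run, covering
#'   all windows.
#' @param gmt annual GMT data frame of the driving GCM.
#' @param thresholds warming levels, degC.
#' @param lengths window lengths to scan, default `1:20` years.
#' @param reference,window passed to [gmt_anomaly()].
#' @param ... passed to [climate_index_set()].
#' @return long data frame: length, threshold, index, reference, window
#'   value, delta.
#' @export
window_length_sensitivity <- function(series, gmt,
                                      thresholds = c(0, 1, 1.5, 2, 3, 4),
                                      lengths = 1:20,
                                      reference = c(1951, 1955), window = 30,
                                      ...) {
  out <- list()
  for (len in lengths) {
    ww <- warming_windows(gmt, thresholds, length = len,
                          reference = reference, window = window)
    ref_series <- slice_years(series, ww$start[ww$threshold == 0][1],
                              ww$end[ww$threshold == 0][1])
    ref_idx <- climate_index_set(ref_series, ...)
    for (i in seq_len(nrow(ww))) {
      win_idx <- climate_index_set(slice_years(series, ww$start[i], ww$end[i]), ...)
      out[[length(out) + 1L]] <- data.frame(
        length = len, threshold = ww$threshold[i], index = names(ref_idx),
        reference = unname(ref_idx), window = unname(win_idx),
        delta = unname(win_idx - ref_idx))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
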