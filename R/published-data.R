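## Published worked-example inputs shipped as plain-text extdata: the
## EURO-CORDEX GCM-downscaling precipitation biases over Maastricht Airport
## (1951-2005) with their published 1-best..18-worst ranks, and the ETCCDI
## gradient anomaly table of the selected CCLM4-8-17/EC-EARTH forcing.

#' Published precipitation biases of the EURO-CORDEX GCM downscalings
#'
#' Annual precipitation bias (mm/yr) over Maastricht Airport, 1951-2005,
#' for 18 RCM/GCM combinations, with the published absolute-bias rank
#' column. Used as the worked example for [rank_column()].
#'
#' @return data frame: rcm, gcm, p_bias_mm_yr, published_rank.
#' @export
cordex_precip_biases <- function() {
  utils::read.csv(system.file("extdata", "cordex_precip_bias_maastricht.csv",
                              package = "climforce"), stringsAsFactors = FALSE)
}

#' Published ETCCDI anomalies along the warming gradient
#'
#' Reference-period (1951-1955) absolute index values and per-warming-unit
#' anomalies of the selected CCLM4-8-17/EC-EARTH forcing at the ecotron
#' location, plus the corresponding 5-year extraction windows.
#'
#' @return list with data frames `anomalies` (index, reference, deltas per
#'   warming unit) and `windows` (threshold, start, end).
#' @export
etccdi_gradient_table <- function() {
  list(anomalies = utils::read.csv(
         system.file("extdata", "etccdi_gradient_anomalies.csv",
                     package = "climforce"), stringsAsFactors = FALSE,
         check.names = FALSE),
       windows = utils::read.csv(
         system.file("extdata", "gradient_windows.csv",
                     package = "climforce"), stringsAsFactors = FALSE))
}

#' Days of the year not favorable for growth
#'
#' Bookkeeping around the growing season: with a reference growing season
#' length and its anomaly at a warming level, the remaining days of the
#' (365-day) year are `365 - (GSL_ref + delta_GSL)`.
#'
#' @param gsl_ref reference growing season length, days.
#' @param delta_gsl growing-season-length anomaly, days.
#' @param year_length days in the year (default 365).
#' @return days not favorable for growth.
#' @export
days_not_favorable <- function(gsl_ref, delta_gsl, year_length = 365) {
  year_length - (gsl_ref + delta_gsl)
}
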