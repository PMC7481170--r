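## Per-variable skill scores comparing a model series against station
## observations: mean bias, Perkins skill score, seasonal-cycle MAE,
## percentile MAE, RMSE, Spearman rank correlation and Brier skill score,
## plus the cross-variable correlation comparison. All metrics operate on
## paired daily values; days missing in either series are dropped pairwise.

## Pairwise completion with a missingness guard. The 20% ceiling is a
## configurable policy: a comparison resting on fewer days is likely biased
## by the gap structure and should fail loudly.
pair_complete <- function(model, obs, max_missing = 0.2) {
  if (length(model) != length(obs))
    stop("model and obs must be paired series of equal length", call. = FALSE)
  ok <- !is.na(model) & !is.na(obs)
  if (!any(ok)) stop("no overlapping non-missing days", call. = FALSE)
  if (mean(!ok) > max_missing)
    stop(sprintf("%.1f%% of paired days missing exceeds the %.0f%% policy",
                 100 * mean(!ok), 100 * max_missing), call. = FALSE)
  list(model = model[ok], obs = obs[ok], keep = ok)
}

#' Mean bias of a modelled series
#'
#' Difference between the averages of the daily modelled and observed
#' values. For precipitation the bias is conventionally reported as an
#' annual total: set `as_annual_precip = TRUE` to scale the daily-mean
#' difference by 365.25.
#'
#' @param model,obs paired daily values.
#' @param as_annual_precip report in mm/yr instead of the variable's daily
#'   units.
#' @param max_missing maximum tolerated fraction of missing paired days.
#' @return scalar bias (model minus observed).
#' @export
mean_bias <- function(model, obs, as_annual_precip = FALSE, max_missing = 0.2) {
  p <- pair_complete(model, obs, max_missing)
  b <- mean(p$model) - mean(p$obs)
  if (as_annual_precip) b * 365.25 else b
}

#' Perkins skill score
#'
#' Overlap of the two binned empirical distributions: with shared bin edges
#' spanning the pooled range, `PSS = sum over bins of min(f_model, f_obs)`
#' where `f` are relative frequencies. 1 means identical binned
#' distributions, 0 disjoint support. Symmetric in its arguments.
#'
#' For zero-inflated variables (precipitation) a dedicated first bin can be
#' supplied, e.g. `first_bin = c(0, 0.1)` so dry days and drizzle occupy
#' their own bin.
#'
#' @param model,obs samples of daily values (need not be paired).
#' @param bin_width width of the histogram bins, in variable units.
#' @param first_bin optional `c(lower, upper)` for a leading irregular bin;
#'   regular bins of `bin_width` continue from its upper edge.
#' @return score in \[0, 1\].
#' @export
perkins_skill_score <- function(model, obs, bin_width = 1, first_bin = NULL) {
  model <- model[!is.na(model)]; obs <- obs[!is.na(obs)]
  if (!length(model) || !length(obs)) stop("empty sample", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  pool <- c(model, obs)
  if (is.null(first_bin)) {
    lo <- floor(min(pool) / bin_width) * bin_width
    edges <- seq(lo, max(pool) + bin_width, by = bin_width)
  } else {
    stopifnot(length(first_bin) == 2, first_bin[1] < first_bin[2])
    if (min(pool) < first_bin[1])
      stop("values below the lower edge of first_bin", call. = FALSE)
    edges <- c(first_bin[1],
               seq(first_bin[2], max(pool) + bin_width, by = bin_width))
  }
  ## left-closed bins [e_i, e_{i+1}), last bin closed on the right
  bin_of <- function(x) pmin(findInterval(x, edges), length(edges) - 1L)
  fm <- tabulate(bin_of(model), length(edges) - 1L) / length(model)
  fo <- tabulate(bin_of(obs), length(edges) - 1L) / length(obs)
  sum(pmin(fm, fo))
}

#' Monthly climatological seasonal cycle
#'
#' Entry `m` is the mean of all daily values falling in calendar month `m`
#' over the whole series.
#'
#' @param values daily values.
#' @param months calendar month (1-12) of each value.
#' @return numeric vector of 12 monthly means.
#' @export
seasonal_cycle <- function(values, months) {
  ok <- !is.na(values)
  values <- values[ok]; months <- months[ok]
  if (!all(1:12 %in% months))
    stop("month(s) with no data: ",
         paste(setdiff(1:12, unique(months)), collapse = ", "), call. = FALSE)
  as.numeric(tapply(values, factor(months, levels = 1:12), mean))
}

#' Mean absolute error between modelled and observed seasonal cycles
#'
#' @param model,obs daily values.
#' @param months calendar month of each day (shared by both series).
#' @return MAE over the 12 monthly means, variable units.
#' @export
seasonal_cycle_mae <- function(model, obs, months) {
  mean(abs(seasonal_cycle(model, months) - seasonal_cycle(obs, months)))
}

#' Mean absolute error of distribution percentiles
#'
#' Compares the tails of the daily distributions: mean over the requested
#' percentile levels of the absolute difference between model and observed
#' empirical quantiles (linear interpolation between order statistics,
#' [stats::quantile()] type 7).
#'
#' @param model,obs daily values.
#' @param levels percentile levels, default `c(1, 10, 90, 99)`.
#' @return MAE over levels, variable units.
#' @export
percentile_mae <- function(model, obs, levels = c(1, 10, 90, 99)) {
  model <- model[!is.na(model)]; obs <- obs[!is.na(obs)]
  if (!length(model) || !length(obs)) stop("empty sample", call. = FALSE)
  if (min(length(model), length(obs)) < 100)
    warning("fewer than 100 days; percentile estimates are noisy", call. = FALSE)
  qm <- stats::quantile(model, levels / 100, type = 7, names = FALSE)
  qo <- stats::quantile(obs, levels / 100, type = 7, names = FALSE)
  mean(abs(qm - qo))
}

#' Root mean square error of paired daily values
#'
#' @inheritParams mean_bias
#' @return non-negative scalar, variable units.
#' @export
rmse <- function(model, obs, max_missing = 0.2) {
  p <- pair_complete(model, obs, max_missing)
  sqrt(mean((p$model - p$obs)^2))
}

#' Spearman rank correlation of paired daily values
#'
#' Average-rank tie handling; errors on constant series, where rank
#' correlation is undefined.
#'
#' @inheritParams mean_bias
#' @return correlation in \[-1, 1\].
#' @export
spearman_daily <- function(model, obs, max_missing = 0.2) {
  p <- pair_complete(model, obs, max_missing)
  if (length(p$model) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(p$model) == 0 || stats::sd(p$obs) == 0)
    stop("constant series: rank correlation undefined", call. = FALSE)
  stats::cor(p$model, p$obs, method = "spearman")
}

#' Brier skill score against an equal-probability climatology
#'
#' The observed climatology is split into `n_categories` equiprobable
#' categories bounded by the observed quantiles. Each day's event is the
#' category the observed value falls in; the (deterministic) model forecast
#' assigns probability 1 to the category its own value falls in. The Brier
#' score is the mean squared probability error over days and categories;
#' the reference forecast assigns `1/K` everywhere. `BSS = 1 - BS/BS_ref`:
#' 1 for a model reproducing every observed category, 0 for the uniform
#' reference itself.
#'
#' @inheritParams mean_bias
#' @param n_categories number of equiprobable climatological categories.
#' @return skill score `<= 1`.
#' @export
brier_skill_score <- function(model, obs, n_categories = 3, max_missing = 0.2) {
  stopifnot(n_categories >= 2)
  p <- pair_complete(model, obs, max_missing)
  k <- n_categories
  breaks <- stats::quantile(p$obs, seq_len(k - 1) / k, type = 7, names = FALSE)
  if (anyDuplicated(breaks) || stats::sd(p$obs) == 0)
    stop("degenerate climatological quantiles; categories are not distinct",
         call. = FALSE)
  ## a value equal to a category bound belongs to the lower category
  cat_of <- function(x) findInterval(x, breaks, left.open = TRUE) + 1L
  co <- cat_of(p$obs); cm <- cat_of(p$model)
  n <- length(co)
  ## per day: sum_k (f_k - o_k)^2 = 2 * [category mismatch] for one-hot f
  bs <- mean(2 * (cm != co)) / k
  bs_ref <- mean(vapply(seq_len(n), function(i) {
    o <- numeric(k); o[co[i]] <- 1
    sum((1 / k - o)^2)
  }, numeric(1))) / k
  1 - bs / bs_ref
}

#' Cross-variable correlation comparison
#'
#' Pearson correlations of paired daily values for all variable pairs among
#' mean air temperature, precipitation, relative humidity and wind speed,
#' for the model run and the observations, with their absolute difference.
#' Seasonal physics differ (e.g. temperature-humidity anticorrelation in
#' summer heatwaves, wind-precipitation correlation in winter storms), so
#' the comparison is computed for the annual, DJF and JJA subsets.
#'
#' @param model_daily,obs_daily [daily_series()] objects on the same dates.
#' @param seasons subset of `c("annual", "DJF", "JJA")`.
#' @param variables variables to correlate.
#' @return data frame: season, var1, var2, r_obs, r_model, abs_diff.
#' @export
cross_correlation_table <- function(model_daily, obs_daily,
                                    seasons = c("annual", "DJF", "JJA"),
                                    variables = c("tmean", "precip", "relhum", "wind")) {
  stopifnot(nrow(model_daily) == nrow(obs_daily))
  pairs <- utils::combn(variables, 2)
  out <- list()
  for (season in seasons) {
    mask <- season_mask(obs_daily$year, obs_daily$month, season)
    if (!any(mask)) stop("season subset ", season, " is empty", call. = FALSE)
    for (j in seq_len(ncol(pairs))) {
      v1 <- pairs[1, j]; v2 <- pairs[2, j]
      ro <- stats::cor(obs_daily[[v1]][mask], obs_daily[[v2]][mask],
                       use = "complete.obs")
      rm_ <- stats::cor(model_daily[[v1]][mask], model_daily[[v2]][mask],
                        use = "complete.obs")
      out[[length(out) + 1L]] <- data.frame(season = season, var1 = v1,
                                            var2 = v2, r_obs = ro,
                                            r_model = rm_,
                                            abs_diff = abs(rm_ - ro))
    }
  }
  do.call(rbind, out)
}

## Orientation of each metric for ranking: "zero_best" ranks by |value|,
## "lower_better" by value, "higher_better" by -value.
METRIC_ORIENTATION <- c(bias = "zero_best", pss = "higher_better",
                        mae_seasonal = "lower_better",
                        mae_percentile = "lower_better",
                        rmse = "lower_better", spearman = "higher_better",
                        bss = "higher_better")

default_pss_bins <- function(variable) {
  switch(variable,
    precip = list(bin_width = 1, first_bin = c(0, 0.1)),
    relhum = list(bin_width = 5, first_bin = NULL),
    list(bin_width = 1, first_bin = NULL))
}

#' Evaluate one model run against observations
#'
#' Computes the per-variable skill metrics on the overlapping period. For
#' GCM-driven runs the day-by-day metrics (RMSE, Spearman, BSS) are skipped
#' because a coupled model's internal variability is not synchronized with
#' observations; reanalysis-driven (evaluation) runs include them.
#'
#' @param run a [model_run()].
#' @param obs observed [daily_series()] covering the run's daily dates.
#' @param variables variables to evaluate (those present in both series).
#' @param day_by_day include RMSE/Spearman/BSS; defaults to `TRUE` only for
#'   evaluation runs.
#' @param bin_widths optional named list overriding the per-variable Perkins
#'   bin defaults (1 degC, 1 mm/day with a \[0, 0.1) drizzle bin, 5%, 1 m/s).
#' @return a `skill_table` data frame: run, variable, metric, value,
#'   orientation.
#' @export
evaluate_run <- function(run, obs,
                         variables = c("tmean", "precip", "relhum", "wind"),
                         day_by_day = run$experiment == "evaluation",
                         bin_widths = list()) {
  stopifnot(inherits(run, "model_run"))
  daily <- run$daily
  if (nrow(daily) != nrow(obs))
    stop("run and observations must cover the same days; slice first",
         call. = FALSE)
  variables <- intersect(variables, intersect(names(daily), names(obs)))
  rows <- list()
  for (v in variables) {
    m <- daily[[v]]; o <- obs[[v]]
    bins <- utils::modifyList(default_pss_bins(v),
                              if (v %in% names(bin_widths)) bin_widths[[v]] else list())
    vals <- c(
      bias = mean_bias(m, o, as_annual_precip = v == "precip"),
      pss = perkins_skill_score(m, o, bin_width = bins$bin_width,
                                first_bin = bins$first_bin),
      mae_seasonal = seasonal_cycle_mae(m, o, obs$month),
      mae_percentile = percentile_mae(m, o))
    if (day_by_day)
      vals <- c(vals, rmse = rmse(m, o), spearman = spearman_daily(m, o),
                bss = brier_skill_score(m, o))
    rows[[v]] <- data.frame(run = run_id(run), variable = v,
                            metric = names(vals), value = unname(vals),
                            orientation = unname(METRIC_ORIENTATION[names(vals)]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("skill_table", "data.frame"))
}

#' Skill table for an ensemble of runs
#'
#' @param runs list of [model_run()] objects.
#' @param obs observed [daily_series()].
#' @param ... passed to [evaluate_run()].
#' @return a `skill_table` data frame over all runs.
#' @export
skill_table <- function(runs, obs, ...) {
  out <- do.call(rbind, lapply(runs, evaluate_run, obs = obs, ...))
  rownames(out) <- NULL
  structure(out, class = c("skill_table", "data.frame"))
}

#' @export
print.skill_table <- function(x, ...) {
  cat(sprintf("Skill table: %d run(s), %d variable(s), %d metric(s)\n",
              length(unique(x$run)), length(unique(x$variable)),
              length(unique(x$metric))))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
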