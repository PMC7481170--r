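## Turning skill scores and diagnostics into reproducible 1-best..N-worst
## rankings, shortlisting, ensemble-representativeness screening and the
## precipitation-bias-decisive final selection.

#' Rank runs on one metric column
#'
#' Rank 1 is best. Orientation decides the sort key: `"zero_best"` ranks by
#' absolute value (biases and diagnostic differences), `"lower_better"` by
#' value (error metrics), `"higher_better"` by negated value (skill
#' scores). Ties take the smallest available rank in stable input order;
#' missing values get `NA` rank and are recorded in the `"excluded"`
#' attribute.
#'
#' @param values numeric scores, one per run.
#' @param orientation `"zero_best"`, `"lower_better"` or `"higher_better"`.
#' @return integer ranks (1 = best) aligned with `values`.
#' @export
rank_column <- function(values, orientation = c("zero_best", "lower_better",
                                                "higher_better")) {
  orientation <- match.arg(orientation)
  if (sum(!is.na(values)) < 2) stop("need at least 2 runs to rank", call. = FALSE)
  key <- switch(orientation, zero_best = abs(values),
                lower_better = values, higher_better = -values)
  ranks <- rep(NA_integer_, length(values))
  ok <- which(!is.na(key))
  ranks[ok[order(key[ok])]] <- seq_along(ok)   # order() is stable: ties keep input order
  structure(ranks, excluded = which(is.na(key)))
}

#' Rank table from a skill table
#'
#' Adds a rank column to a tidy skill table, ranking the runs within every
#' (variable, metric) column using each metric's declared orientation.
#'
#' @param skill a [skill_table()] (columns run, variable, metric, value,
#'   orientation).
#' @return a `rank_table` data frame with an added integer `rank` column.
#' @export
rank_table <- function(skill) {
  stopifnot(all(c("run", "variable", "metric", "value", "orientation") %in%
                  names(skill)))
  skill <- as.data.frame(skill)
  skill$rank <- NA_integer_
  for (key in unique(paste(skill$variable, skill$metric))) {
    idx <- which(paste(skill$variable, skill$metric) == key)
    skill$rank[idx] <- rank_column(skill$value[idx],
                                   skill$orientation[idx][1])
  }
  structure(skill, class = c("rank_table", "data.frame"))
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Rank table: %d run(s) over %d (variable, metric) column(s)\n",
              length(unique(x$run)),
              length(unique(paste(x$variable, x$metric)))))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Composite rank score per run
#'
#' Weighted mean rank over the table's (variable, metric) columns; lower is
#' better, and with unit weights this is the plain mean rank. Runs missing
#' a column (variable not available for that model) are averaged over their
#' available columns with renormalized weights.
#'
#' @param ranks a [rank_table()].
#' @param weights optional named weights per `"variable metric"` column (or
#'   a single number recycled); default unit weights.
#' @param variables optional subset of variables to aggregate over.
#' @return named numeric vector of composite scores, sorted best first.
#' @export
aggregate_ranks <- function(ranks, weights = NULL, variables = NULL) {
  df <- as.data.frame(ranks)
  if (!is.null(variables)) df <- df[df$variable %in% variables, , drop = FALSE]
  df$column <- paste(df$variable, df$metric)
  cols <- unique(df$column)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(cols)), cols)
  if (is.null(names(weights)) && length(weights) == 1)
    weights <- stats::setNames(rep(weights, length(cols)), cols)
  w <- weights[df$column]
  if (anyNA(w)) stop("weights missing for column(s): ",
                     paste(setdiff(cols, names(weights)), collapse = ", "),
                     call. = FALSE)
  runs <- unique(df$run)
  score <- vapply(runs, function(r) {
    i <- df$run == r & !is.na(df$rank)
    tw <- sum(w[i])
    if (tw <= 0) stop("zero total weight for run ", r, call. = FALSE)
    sum(df$rank[i] * w[i]) / tw
  }, numeric(1))
  sort(stats::setNames(score, runs))
}

#' Shortlist the best runs
#'
#' @param scores named composite scores from [aggregate_ranks()] (lower is
#'   better).
#' @param n number of candidates to keep.
#' @param exclude run ids removed before selection (e.g. models disqualified
#'   in the reanalysis evaluation).
#' @return character vector of candidate run ids, best first.
#' @export
shortlist <- function(scores, n = length(scores), exclude = character()) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  scores <- scores[!names(scores) %in% exclude]
  if (n > length(scores)) stop("n exceeds the number of remaining runs", call. = FALSE)
  names(sort(scores))[seq_len(n)]
}

#' Percentile position of a candidate within the ensemble anomaly spread
#'
#' Converts a candidate run's horizon-mean scenario anomaly into a
#' percentile of the ensemble's horizon-mean anomaly distribution, using
#' linear interpolation between order statistics (the ensemble median run
#' sits at 50; values outside the ensemble range clamp to 0 or 100).
#' Anomalies must be computed against each run's own reference-period mean.
#'
#' @param candidate scalar horizon-mean anomaly of the candidate.
#' @param ensemble numeric vector of horizon-mean anomalies of all runs.
#' @return percentile in \[0, 100\].
#' @export
ensemble_percentile_position <- function(candidate, ensemble) {
  ensemble <- ensemble[!is.na(ensemble)]
  if (length(ensemble) < 3) stop("ensemble size < 3", call. = FALSE)
  s <- sort(ensemble)
  p <- (seq_along(s) - 1) / (length(s) - 1) * 100
  if (candidate <= s[1]) return(0)
  if (candidate >= s[length(s)]) return(100)
  stats::approx(s, p, xout = candidate, ties = "ordered")$y
}

#' Horizon-mean scenario anomaly of one run
#'
#' Mean of a variable over the horizon years minus its mean over the run's
#' own reference years.
#'
#' @param series a [daily_series()] covering both periods.
#' @param variable variable name.
#' @param reference,horizon year ranges `c(first, last)`.
#' @return scalar anomaly in the variable's units.
#' @export
scenario_anomaly <- function(series, variable, reference, horizon) {
  ref <- slice_years(series, reference[1], reference[2])
  hor <- slice_years(series, horizon[1], horizon[2])
  mean(hor[[variable]], na.rm = TRUE) - mean(ref[[variable]], na.rm = TRUE)
}

#' Final precipitation-bias-decisive selection
#'
#' Among shortlisted candidates whose ensemble percentile positions fall
#' inside a central representativeness band for every screened variable,
#' the run with the smallest absolute precipitation bias is chosen
#' (precipitation being the variable most likely to constrain the
#' ecosystem). If no candidate lies in the band it is widened symmetrically
#' in `widen_step` increments until one does, and the widening is recorded.
#'
#' @param candidates data frame with columns `run`, `precip_bias` (mm/yr)
#'   and one percentile column per screened variable (values in \[0, 100\]).
#' @param percentile_cols names of the percentile columns.
#' @param band central percentile band, default `c(25, 75)`.
#' @param widen_step band widening increment (percentile points).
#' @return an `rcm_selection` list: `chosen`, `chosen_bias`, `band_used`,
#'   `widened`, `trace` (per-candidate elimination record).
#' @export
select_final <- function(candidates, percentile_cols,
                         band = c(25, 75), widen_step = 5) {
  stopifnot(is.data.frame(candidates), nrow(candidates) > 0,
            all(c("run", "precip_bias") %in% names(candidates)),
            all(percentile_cols %in% names(candidates)))
  pm <- as.matrix(candidates[, percentile_cols, drop = FALSE])
  b <- band
  widened <- 0L
  repeat {
    in_band <- apply(pm >= b[1] & pm <= b[2], 1, all)
    if (any(in_band)) break
    b <- c(max(0, b[1] - widen_step), min(100, b[2] + widen_step))
    widened <- widened + 1L
    if (b[1] <= 0 && b[2] >= 100) { in_band <- rep(TRUE, nrow(pm)); break }
  }
  pool <- candidates[in_band, , drop = FALSE]
  chosen <- pool$run[which.min(abs(pool$precip_bias))]
  trace <- data.frame(run = candidates$run,
                      precip_bias = candidates$precip_bias,
                      in_band = in_band,
                      selected = candidates$run == chosen)
  structure(list(chosen = chosen,
                 chosen_bias = candidates$precip_bias[candidates$run == chosen],
                 band_used = b, widened = widened, trace = trace),
            class = "rcm_selection")
}

#' @export
print.rcm_selection <- function(x, ...) {
  cat(sprintf("Selected run: %s (precipitation bias %+.4g mm/yr)\n",
              x$chosen, x$chosen_bias))
  cat(sprintf("Representativeness band [%g, %g]%s\n", x$band_used[1],
              x$band_used[2],
              if (x$widened > 0) sprintf(" (widened %d time(s))", x$widened) else ""))
  invisible(x)
}

#' @export
summary.rcm_selection <- function(object, ...) {
  print(object)
  cat("Elimination trace:\n")
  print(object$trace, row.names = FALSE, digits = 4)
  invisible(object$trace)
}
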