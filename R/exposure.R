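# Exposure module: screening of daily particulate series, annual-mean
# completeness rule, and PM10-based gap filling of missing PM2.5.

#' Construct a daily particulate series
#'
#' A daily series is a tibble with one row per monitoring day holding a
#' single pollutant for a single station. All concentrations are in
#' micrograms per cubic metre.
#'
#' @param station_id,city_id Identifiers (scalar character).
#' @param pollutant `"PM10"` or `"PM2.5"`.
#' @param date Vector of `Date`s (or ISO-8601 strings), one per record.
#' @param value Daily mean concentrations, same length as `date`.
#' @return A tibble with columns `station_id`, `city_id`, `pollutant`,
#'   `date`, `value`.
#' @export
#' @examples
#' daily_pm_series("S1", "Delhi", "PM2.5",
#'                 as.Date("2017-01-01") + 0:2, c(110, 140, 95))
daily_pm_series <- function(station_id, city_id, pollutant, date, value) {
  pollutant <- match.arg(pollutant, c("PM10", "PM2.5"))
  date <- as.Date(date)
  if (length(date) != length(value)) {
    stop("`date` and `value` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(date)) {
    stop("dates must be unique within a daily series", call. = FALSE)
  }
  tibble(
    station_id = as.character(station_id),
    city_id    = as.character(city_id),
    pollutant  = pollutant,
    date       = date,
    value      = as.numeric(value)
  )
}

check_daily_pm <- function(series, arg = "series") {
  needed <- c("station_id", "city_id", "pollutant", "date", "value")
  if (!is.data.frame(series) || !all(needed %in% names(series))) {
    stop(sprintf("`%s` must be a daily series with columns %s", arg,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  invisible(series)
}

#' Screen a daily series against a plausibility window
#'
#' Removes daily averages outside the closed interval `[lo, hi]` (defaults
#' 2 and 1000 ug/m3) together with non-finite values. The number of removed
#' records is attached as attribute `n_removed` and reported via `message()`.
#' Screening is idempotent and an empty input yields an empty result.
#'
#' @param series A daily series (see [daily_pm_series()]).
#' @param lo,hi Window bounds in ug/m3; `lo < hi` required.
#' @param quiet Suppress the removal message.
#' @return The screened series (same columns), attribute `n_removed`.
#' @export
screen_daily <- function(series, lo = 2, hi = 1000, quiet = FALSE) {
  check_daily_pm(series)
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi)) {
    stop("`lo` must be strictly less than `hi`", call. = FALSE)
  }
  keep <- is.finite(series$value) & series$value >= lo & series$value <= hi
  out <- series[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (!quiet && n_removed > 0) {
    message(sprintf("screen_daily: removed %d of %d records outside [%g, %g] ug/m3",
                    n_removed, length(keep), lo, hi))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Annual mean under the completeness rule
#'
#' Computes the arithmetic annual mean of a screened daily series when at
#' least `min_days` valid days are available (default 104, the completeness
#' convention for one valid day in roughly every 3.5). Otherwise an
#' insufficiency row is returned: `pm25_annual` is `NA` and `provenance` is
#' `"insufficient"`, with `n_valid_days` carried for diagnostics.
#'
#' @param series A screened daily series covering a single calendar year and
#'   a single pollutant.
#' @param min_days Minimum number of valid days (inclusive).
#' @return One-row tibble with columns `city_id`, `year`, `pollutant`,
#'   `pm25_annual`, `n_valid_days`, `provenance`. For a PM10 series the
#'   `pm25_annual` column holds the PM10 annual mean (used as the input to
#'   [impute_pm25()] or [ratio_convert()]).
#' @export
annual_mean <- function(series, min_days = 104) {
  check_daily_pm(series)
  if (length(unique(series$pollutant)) > 1) {
    stop("`series` mixes pollutants; split before averaging", call. = FALSE)
  }
  if (nrow(series) == 0) {
    stop("cannot compute an annual mean of an empty series", call. = FALSE)
  }
  yr <- unique(as.integer(format(series$date, "%Y")))
  if (length(yr) > 1) {
    stop("`series` spans more than one calendar year", call. = FALSE)
  }
  n_valid <- length(unique(series$date))
  ok <- n_valid >= min_days
  tibble(
    city_id      = series$city_id[[1]],
    year         = yr,
    pollutant    = series$pollutant[[1]],
    pm25_annual  = if (ok) mean(series$value) else NA_real_,
    n_valid_days = n_valid,
    provenance   = if (ok) "measured" else "insufficient"
  )
}

#' Fit the PM10 to PM2.5 linear relation
#'
#' Ordinary least squares of PM2.5 on PM10 over date-matched screened daily
#' pairs, used to fill missing PM2.5 from PM10. A warning is attached when
#' the Pearson correlation falls below `r_floor` (default 0.6); the fit is
#' still returned so the caller can decide.
#'
#' @param pm10,pm25 Screened daily series for the two pollutants.
#' @param r_floor Acceptance floor for the Pearson correlation (warn only).
#' @return An object of class `pm_relation`: list with `slope`, `intercept`,
#'   `se_slope`, `df` (residual degrees of freedom), `pearson_r`, `n_pairs`,
#'   `r_floor`, `below_floor`.
#' @export
fit_pm_relation <- function(pm10, pm25, r_floor = 0.6) {
  check_daily_pm(pm10, "pm10")
  check_daily_pm(pm25, "pm25")
  pairs <- inner_join(
    select(pm10, date, pm10 = value),
    select(pm25, date, pm25 = value),
    by = "date"
  )
  if (nrow(pairs) < 3) {
    stop(sprintf("need at least 3 date-matched pairs, got %d", nrow(pairs)),
         call. = FALSE)
  }
  if (stats::sd(pairs$pm10) == 0) {
    stop("PM10 values have zero variance; slope is undefined", call. = FALSE)
  }
  fit <- lm(pm25 ~ pm10, data = pairs)
  r <- cor(pairs$pm10, pairs$pm25)
  below <- r < r_floor
  if (below) {
    warning(sprintf("PM10-PM2.5 correlation r = %.3f is below the acceptance floor %.2f",
                    r, r_floor), call. = FALSE)
  }
  structure(
    list(
      slope       = unname(coef(fit)[["pm10"]]),
      intercept   = unname(coef(fit)[["(Intercept)"]]),
      # summary.lm warns on an exactly collinear (noise-free) fit; the zero
      # standard error it returns is still the right answer there
      se_slope    = unname(suppressWarnings(
        summary(fit)$coefficients["pm10", "Std. Error"])),
      df          = fit$df.residual,
      pearson_r   = r,
      n_pairs     = nrow(pairs),
      r_floor     = r_floor,
      below_floor = below
    ),
    class = "pm_relation"
  )
}

#' @export
print.pm_relation <- function(x, ...) {
  cat(sprintf("PM10-PM2.5 relation: pm25 = %.4f * pm10 + %.4f  (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$n_pairs))
  if (isTRUE(x$below_floor)) {
    cat(sprintf("  note: r below acceptance floor %.2f\n", x$r_floor))
  }
  invisible(x)
}

#' Impute an annual PM2.5 value from PM10 via a fitted relation
#'
#' `pm25 = slope * pm10 + intercept`; negative predictions are clipped to 0
#' with a warning. Provenance is recorded as `"regression_imputed"`.
#'
#' @param pm10_annual Annual PM10 mean in ug/m3.
#' @param relation A [fit_pm_relation()] result.
#' @param city_id,year Carried into the output row.
#' @return One-row annual-exposure tibble (see [annual_mean()]).
#' @export
impute_pm25 <- function(pm10_annual, relation, city_id = NA_character_,
                        year = NA_integer_) {
  if (!inherits(relation, "pm_relation")) {
    stop("`relation` must come from fit_pm_relation()", call. = FALSE)
  }
  stopifnot(is.numeric(pm10_annual), length(pm10_annual) == 1, pm10_annual >= 0)
  pred <- relation$slope * pm10_annual + relation$intercept
  if (pred < 0) {
    warning(sprintf("imputed PM2.5 was negative (%.2f); clipped to 0", pred),
            call. = FALSE)
    pred <- 0
  }
  tibble(
    city_id      = as.character(city_id),
    year         = as.integer(year),
    pollutant    = "PM2.5",
    pm25_annual  = pred,
    n_valid_days = NA_integer_,
    provenance   = "regression_imputed"
  )
}

#' Convert annual PM10 to PM2.5 by a fixed ratio
#'
#' Direct conversion `pm25 = ratio * pm10` with a literature ratio factor in
#' `(0, 1]`, for cities where no co-located PM2.5 monitoring supports a
#' regression. Provenance is recorded as `"ratio_converted"`.
#'
#' @param pm10_annual Annual PM10 mean in ug/m3.
#' @param ratio PM2.5/PM10 ratio, in `(0, 1]`.
#' @param city_id,year Carried into the output row.
#' @return One-row annual-exposure tibble.
#' @export
ratio_convert <- function(pm10_annual, ratio, city_id = NA_character_,
                          year = NA_integer_) {
  stopifnot(is.numeric(pm10_annual), length(pm10_annual) == 1, pm10_annual >= 0)
  if (!(is.numeric(ratio) && length(ratio) == 1 && ratio > 0 && ratio <= 1)) {
    stop("`ratio` must lie in (0, 1]", call. = FALSE)
  }
  tibble(
    city_id      = as.character(city_id),
    year         = as.integer(year),
    pollutant    = "PM2.5",
    pm25_annual  = ratio * pm10_annual,
    n_valid_days = NA_integer_,
    provenance   = "ratio_converted"
  )
}

# provenance quality ordering: measured best, ratio_converted worst
.provenance_levels <- c("measured", "regression_imputed", "ratio_converted")

#' Aggregate station annual exposures to one city value
#'
#' Unweighted mean across stations per city-year. The reported provenance is
#' the worst present (measured < regression_imputed < ratio_converted).
#' Rows flagged `"insufficient"` must be resolved (imputed or dropped)
#' before aggregation.
#'
#' @param stations Tibble of annual-exposure rows.
#' @return Tibble with one row per city-year.
#' @export
city_annual <- function(stations) {
  if (!is.data.frame(stations) || nrow(stations) == 0) {
    stop("`stations` must contain at least one annual exposure row", call. = FALSE)
  }
  if (any(stations$provenance == "insufficient")) {
    stop("`stations` contains insufficient-data rows; impute or drop them first",
         call. = FALSE)
  }
  if (!all(stations$provenance %in% .provenance_levels)) {
    stop("unknown provenance value in `stations`", call. = FALSE)
  }
  stations %>%
    group_by(city_id, year) %>%
    summarise(
      pm25_annual  = mean(pm25_annual),
      n_valid_days = if (all(is.na(n_valid_days))) NA_integer_ else
        as.integer(min(n_valid_days, na.rm = TRUE)),
      provenance   = .provenance_levels[max(match(provenance, .provenance_levels))],
      n_stations   = dplyr::n(),
      .groups = "drop"
    )
}

utils::globalVariables(c(
  "date", "value", "pm25", "pm10", "city_id", "year", "pm25_annual",
  "n_valid_days", "provenance"
))
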