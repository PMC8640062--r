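# Attribution module: relative risks -> attributable fractions ->
# attributable premature mortality with confidence bounds, attributable
# shares, and grouped (city/cause/class/zone/total) aggregates.

#' Attributable fraction of baseline mortality
#'
#' `AF = (RR - 1) / RR`, the proportion of baseline deaths among the
#' exposed attributable to the exposure. Relative risks below 1 clamp the
#' fraction to 0 with a warning (no negative burden); `RR <= 0` is an
#' error.
#'
#' @param rr Relative risk(s), dimensionless.
#' @return Attributable fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' attributable_fraction(c(1, 1.25, 2)) # 0, 0.2, 0.5
attributable_fraction <- function(rr) {
  stopifnot(is.numeric(rr))
  if (any(rr <= 0, na.rm = TRUE)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  if (any(rr < 1, na.rm = TRUE)) {
    warning(sprintf("%d relative risk(s) below 1; attributable fraction clamped to 0",
                    sum(rr < 1, na.rm = TRUE)), call. = FALSE)
  }
  pmax(0, (rr - 1) / rr)
}

#' Attributable premature mortality with bounds
#'
#' Converts a relative-risk triple into attributable deaths per city and
#' cause: `delta_e = AF(RR) * B_i` for each of central/low/high. Bounds
#' inherit their ordering from the RR triple.
#'
#' @param rr Tibble with columns `central`, `low`, `high` (e.g. from
#'   [gemm_rr_ci()]); rows aligned with `b_i`. Columns `city_id` and
#'   `cause` are carried through when present.
#' @param b_i Baseline deaths: a numeric vector aligned with `rr`, or a
#'   baseline tibble with a `deaths` column aligned row-wise.
#' @return Tibble with `city_id`/`cause` (when available), `delta_e`,
#'   `low`, `high`.
#' @export
attributable_mortality <- function(rr, b_i) {
  stopifnot(is.data.frame(rr), all(c("central", "low", "high") %in% names(rr)))
  if (is.data.frame(b_i)) {
    stopifnot("deaths" %in% names(b_i), nrow(b_i) == nrow(rr))
    b <- b_i$deaths
  } else {
    b <- as.numeric(b_i)
  }
  if (any(b < 0)) stop("baseline deaths must be non-negative", call. = FALSE)
  out <- tibble(
    delta_e = attributable_fraction(rr$central) * b,
    low     = attributable_fraction(rr$low) * b,
    high    = attributable_fraction(rr$high) * b
  )
  keep <- intersect(c("city_id", "cause"), names(rr))
  if (length(keep)) out <- dplyr::bind_cols(rr[keep], out)
  out
}

#' Percentage of all-cause mortality attributable to PM2.5
#'
#' `100 * delta_all / b_all`: the attributable share of a city's all-cause
#' adult baseline mortality, in percent.
#'
#' @param delta_all Attributable all-cause (NCD+LRI) deaths.
#' @param b_all All-cause baseline deaths; must be positive.
#' @return Share(s) in percent.
#' @export
pm_share <- function(delta_all, b_all) {
  stopifnot(is.numeric(delta_all), is.numeric(b_all))
  if (any(b_all <= 0)) {
    stop("all-cause baseline deaths must be positive", call. = FALSE)
  }
  100 * delta_all / b_all
}

#' Aggregate attributable-mortality (or loss) estimates
#'
#' Sums central/low/high within the requested grouping and reports each
#' group's percentage share of the grand total (on the central estimate).
#' Confidence bounds are summed per city (perfect-dependence convention).
#'
#' @param estimates Tibble with `city_id`, value columns (`delta_e`, `low`,
#'   `high` -- or `loss` in place of `delta_e`), optionally `cause`.
#' @param by One of `"city"`, `"cause"`, `"class"`, `"zone"`, `"total"`.
#' @param meta City metadata tibble with `city_id` and (for class/zone
#'   grouping) `class`/`zone` columns covering every city in `estimates`.
#' @return Tibble of grouped sums with a `share_pct` column.
#' @export
aggregate_estimates <- function(estimates,
                                by = c("city", "cause", "class", "zone", "total"),
                                meta = NULL) {
  by <- match.arg(by)
  value_col <- if ("delta_e" %in% names(estimates)) "delta_e" else "loss"
  stopifnot(all(c(value_col, "low", "high") %in% names(estimates)))
  est <- estimates
  if (by %in% c("class", "zone")) {
    if (is.null(meta) || !all(c("city_id", by) %in% names(meta))) {
      stop(sprintf("`meta` with columns city_id and %s is required", by),
           call. = FALSE)
    }
    unknown <- setdiff(unique(est$city_id), meta$city_id)
    if (length(unknown)) {
      stop("no metadata for city(ies): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    est <- left_join(est, distinct(meta[, c("city_id", by)]), by = "city_id")
  }
  key <- switch(by, city = "city_id", cause = "cause", class = "class",
                zone = "zone", total = character(0))
  grouped <- est %>%
    group_by(across(all_of(key))) %>%
    summarise(
      central = sum(.data[[value_col]]),
      low     = sum(low),
      high    = sum(high),
      .groups = "drop"
    )
  grouped$share_pct <- 100 * grouped$central / sum(grouped$central)
  grouped
}

utils::globalVariables(c("low", "high", ".data"))
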