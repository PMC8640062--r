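# Scenario module: NCAP-style fractional PM2.5 reduction with projected
# population and frozen (base-year) incidence rates.

#' Apply a fractional PM2.5 reduction
#'
#' `c_scn = (1 - reduction_fraction) * c_base`: the policy target applied
#' uniformly to each city's annual mean.
#'
#' @param c_base Base-year annual PM2.5 concentration(s), ug/m3.
#' @param reduction_fraction Fraction removed, in `[0, 1]` (default 0.30,
#'   the upper national target).
#' @return Scenario concentration(s).
#' @export
apply_reduction <- function(c_base, reduction_fraction = 0.30) {
  stopifnot(is.numeric(c_base), all(c_base >= 0),
            is.numeric(reduction_fraction), length(reduction_fraction) == 1,
            reduction_fraction >= 0, reduction_fraction <= 1)
  (1 - reduction_fraction) * c_base
}

#' Rescale baseline mortality to a projected population
#'
#' Freezes the base-year incidence rate and rescales deaths with the adult
#' population: `B_target = (b_base / pop_base) * pop_target`.
#'
#' @param b_base Base-year baseline deaths (vectorized).
#' @param pop_base,pop_target Adult (age > 25) populations, base and
#'   target year; positive, aligned with `b_base`.
#' @return Target-year baseline deaths.
#' @export
scenario_baseline <- function(b_base, pop_base, pop_target) {
  stopifnot(all(pop_base > 0), all(pop_target > 0), all(b_base >= 0))
  b_base / pop_base * pop_target
}

#' Signed percent change between a base and a scenario value
#'
#' `100 * (x_scn - x_base) / x_base`; positive means an increase under the
#' scenario.
#'
#' @param x_base Base value(s); must be non-zero.
#' @param x_scn Scenario value(s).
#' @return Percent change(s).
#' @export
percent_change <- function(x_base, x_scn) {
  stopifnot(is.numeric(x_base), is.numeric(x_scn))
  if (any(x_base == 0)) {
    stop("percent change is undefined for a zero base value", call. = FALSE)
  }
  100 * (x_scn - x_base) / x_base
}
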