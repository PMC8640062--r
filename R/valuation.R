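# Valuation module: benefit transfer of a national Value of Statistical
# Life (VSL) to the state level, and monetization of attributable deaths.

#' Benefit-transfer a national VSL to state level
#'
#' `ec_k = ec_ind * (g_k / g_ind)^epsilon * (1 + pct_dg + pct_dcpi)^beta /
#' ppp_factor`. The base VSL `ec_ind` is in rupees; the income ratio is
#' raised to the willingness-to-pay elasticity `epsilon` (default 1.0); the
#' one-year growth bracket (GDP-per-capita change plus CPI change, entered
#' additively) is raised to the income elasticity `beta` (default 0.8); the
#' result is converted to US$ by dividing by the configured exchange
#' factor.
#'
#' @param g_k State GDP per capita (rupees), valuation year; vectorized
#'   over states.
#' @param pct_dg,pct_dcpi Fractional one-year changes in state GDP per
#'   capita and CPI (0.08 means +8%).
#' @param ec_ind National base VSL in rupees (default 44.69 million, 2016).
#' @param g_ind National GDP per capita (rupees) in the base-VSL year.
#' @param epsilon Willingness-to-pay elasticity (default 1.0).
#' @param beta Income elasticity (default 0.8).
#' @param ppp_factor Rupees-per-US$ conversion divisor for the valuation
#'   year.
#' @return State VSL(s) in US$ per statistical life.
#' @export
benefit_transfer_vsl <- function(g_k, pct_dg, pct_dcpi,
                                 ec_ind = 44.69e6, g_ind,
                                 epsilon = 1.0, beta = 0.8, ppp_factor) {
  stopifnot(is.numeric(g_k), is.numeric(pct_dg), is.numeric(pct_dcpi),
            all(ec_ind > 0), all(g_ind > 0), all(g_k > 0), all(ppp_factor > 0))
  bracket <- 1 + pct_dg + pct_dcpi
  if (any(bracket <= 0)) {
    stop("growth bracket (1 + pct_dg + pct_dcpi) must be positive",
         call. = FALSE)
  }
  ec_ind * (g_k / g_ind)^epsilon * bracket^beta / ppp_factor
}

#' Economic loss from attributable mortality
#'
#' Values attributable deaths at the (state) VSL:
#' `loss = ec_k * deaths`, reported in million US$ for central, low and
#' high bounds.
#'
#' @param ec_k VSL in US$ per statistical life: a scalar, or a vector
#'   aligned with the rows of `mc`.
#' @param mc Mortality-estimate tibble with `delta_e`, `low`, `high`
#'   (columns `city_id`/`cause` carried through when present).
#' @return Tibble with `loss`, `low`, `high` in million US$.
#' @export
economic_loss <- function(ec_k, mc) {
  stopifnot(is.data.frame(mc), all(c("delta_e", "low", "high") %in% names(mc)))
  if (any(ec_k <= 0)) stop("`ec_k` must be positive", call. = FALSE)
  stopifnot(length(ec_k) == 1 || length(ec_k) == nrow(mc))
  out <- tibble(
    loss = ec_k * mc$delta_e / 1e6,
    low  = ec_k * mc$low / 1e6,
    high = ec_k * mc$high / 1e6
  )
  keep <- intersect(c("city_id", "cause"), names(mc))
  if (length(keep)) out <- dplyr::bind_cols(mc[keep], out)
  out
}
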