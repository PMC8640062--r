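# GEMM module: the Global Exposure Mortality Model exposure-response
# function RR(z) = exp{ theta * log(z/alpha + 1) / [1 + exp(-(z - mu)/nu)] }
# evaluated per cause for adults (age > 25), with uncertainty carried
# through theta's published standard error.

#' Load the packaged GEMM exposure-response constants
#'
#' Returns the per-cause constants (theta, se_theta, alpha, mu, nu) for the
#' single adult (age > 25) stratum of each modelled cause, read from the
#' parameter CSV shipped with the package (or a user-supplied file with the
#' same columns). The counterfactual concentration below which no excess
#' risk is modelled is attached as attribute `counterfactual` (default
#' 2.4 ug/m3).
#'
#' @param path Optional path to an alternative parameter CSV.
#' @param counterfactual Counterfactual PM2.5 concentration c0 in ug/m3.
#' @param causes Optional subset of causes to keep.
#' @return Tibble with columns `cause`, `theta`, `se_theta`, `alpha`, `mu`,
#'   `nu`; attribute `counterfactual`.
#' @export
#' @examples
#' p <- gemm_params()
#' gemm_rr(100, p$theta[1], p$alpha[1], p$mu[1], p$nu[1])
gemm_params <- function(path = NULL, counterfactual = 2.4, causes = NULL) {
  path <- path %||% system.file("extdata", "gemm_params.csv",
                                package = "pmburden", mustWork = TRUE)
  p <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  needed <- c("cause", "theta", "se_theta", "alpha", "mu", "nu")
  if (!all(needed %in% names(p))) {
    stop("parameter CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  p <- as_tibble(p[needed])
  if (!is.null(causes)) {
    missing <- setdiff(causes, p$cause)
    if (length(missing)) {
      stop("no parameters for cause(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    p <- p[p$cause %in% causes, ]
  }
  with(p, stopifnot(all(alpha > 0), all(nu > 0), all(se_theta >= 0)))
  stopifnot(is.numeric(counterfactual), counterfactual >= 0)
  attr(p, "counterfactual") <- counterfactual
  p
}

#' Excess concentration above the counterfactual
#'
#' `z = max(0, c - c0)`: the exposure increment that carries risk. Negative
#' excesses clamp to zero (no protective effect below the counterfactual).
#'
#' @param c Ambient PM2.5 concentration(s), ug/m3, non-negative.
#' @param c0 Counterfactual concentration, ug/m3 (default 2.4).
#' @return Excess concentration(s), same length as `c`.
#' @export
excess_concentration <- function(c, c0 = 2.4) {
  stopifnot(is.numeric(c), is.numeric(c0), length(c0) == 1, c0 >= 0)
  if (any(c < 0, na.rm = TRUE)) {
    stop("ambient concentrations must be non-negative", call. = FALSE)
  }
  pmax(0, c - c0)
}

#' GEMM relative risk
#'
#' Evaluates `RR = exp{ theta * log(z/alpha + 1) / [1 + exp(-(z - mu)/nu)] }`
#' at excess concentration `z` (ug/m3). By construction `RR(0) = 1` exactly,
#' and RR is continuous and non-decreasing in `z` for `theta >= 0`.
#' All arguments are vectorized with recycling.
#'
#' @param z Excess concentration(s) above the counterfactual, `z >= 0`.
#' @param theta,alpha,mu,nu GEMM constants for one cause/stratum.
#' @return Relative risk(s), dimensionless.
#' @export
gemm_rr <- function(z, theta, alpha, mu, nu) {
  if (!all(is.finite(theta), is.finite(alpha), is.finite(mu), is.finite(nu))) {
    stop("GEMM parameters must be finite", call. = FALSE)
  }
  stopifnot(all(alpha > 0), all(nu > 0))
  if (any(z < 0, na.rm = TRUE)) {
    stop("`z` must be non-negative (use excess_concentration())", call. = FALSE)
  }
  exp(theta * log(z / alpha + 1) / (1 + exp(-(z - mu) / nu)))
}

#' GEMM relative risk with a 95% uncertainty band
#'
#' Central, low and high relative risks obtained by re-evaluating the GEMM
#' function at `theta`, `theta - zscore * se_theta` and
#' `theta + zscore * se_theta` respectively, with `alpha`, `mu`, `nu` held
#' fixed. The low bound can drop below 1 only when the shifted theta is
#' negative.
#'
#' @param z Excess concentration(s), `z >= 0`.
#' @param params A one-row slice of [gemm_params()] (or any list with
#'   `theta`, `se_theta`, `alpha`, `mu`, `nu`, optionally `cause`), or the
#'   full parameter table, in which case one block of rows per cause is
#'   returned.
#' @param zscore Normal quantile multiplier (default 1.96, the two-sided
#'   95% level).
#' @return Tibble with columns `cause` (if available), `z`, `central`,
#'   `low`, `high`.
#' @export
gemm_rr_ci <- function(z, params, zscore = 1.96) {
  stopifnot(is.numeric(zscore), length(zscore) == 1, zscore > 0)
  if (is.data.frame(params) && nrow(params) > 1) {
    out <- lapply(seq_len(nrow(params)), function(i) {
      gemm_rr_ci(z, params[i, ], zscore = zscore)
    })
    return(bind_rows(out))
  }
  p <- as.list(params)
  tibble(
    cause   = p$cause %||% NA_character_,
    z       = z,
    central = gemm_rr(z, p$theta, p$alpha, p$mu, p$nu),
    low     = gemm_rr(z, p$theta - zscore * p$se_theta, p$alpha, p$mu, p$nu),
    high    = gemm_rr(z, p$theta + zscore * p$se_theta, p$alpha, p$mu, p$nu)
  )
}
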