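# Demography module: city-level adult (age > 25) baseline mortality built
# from district urban registry deaths, a state age share, and population
# scaling; cause split via state cause-of-death shares; NCD-other
# segregation; crude-rate plausibility screen.

check_demography <- function(d) {
  needed <- c("city_id", "population", "adult_share", "district_urban_deaths",
              "district_urban_population", "state_age_share_25plus")
  if (!is.data.frame(d) || !all(needed %in% names(d))) {
    stop("city demography needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  with(d, {
    stopifnot(all(population > 0), all(district_urban_population > 0),
              all(adult_share > 0 & adult_share < 1),
              all(state_age_share_25plus > 0 & state_age_share_25plus <= 1),
              all(district_urban_deaths >= 0))
  })
  invisible(d)
}

#' All-cause adult baseline mortality for each city
#'
#' Disaggregates district urban registry deaths to the city and the adult
#' (age > 25) stratum:
#' `B_all = district_urban_deaths * state_age_share_25plus *
#'  (city population / district urban population)`.
#' The state-level age share of deaths is applied to the district (the
#' study's stated assumption, since district age splits are unavailable).
#'
#' @param demog City demography tibble, one row per city(-year), with
#'   columns `city_id`, `population`, `adult_share`,
#'   `district_urban_deaths`, `district_urban_population`,
#'   `state_age_share_25plus` (plus any metadata such as `state_id`,
#'   `class`, `zone`, carried through).
#' @param year Optional filter applied when `demog` has a `year` column.
#' @return Tibble with `city_id`, `cause = "all"`, `deaths`, plus carried
#'   metadata columns.
#' @export
allcause_baseline <- function(demog, year = NULL) {
  if (!is.null(year) && "year" %in% names(demog)) {
    demog <- demog[demog$year == year, , drop = FALSE]
  }
  check_demography(demog)
  if (any(demog$population > demog$district_urban_population)) {
    bad <- demog$city_id[demog$population > demog$district_urban_population]
    stop("city population exceeds district urban population for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  meta <- setdiff(names(demog),
                  c("district_urban_deaths", "district_urban_population",
                    "state_age_share_25plus"))
  out <- demog %>%
    mutate(
      cause  = "all",
      deaths = district_urban_deaths * state_age_share_25plus *
        population / district_urban_population
    )
  out[, c(meta, "cause", "deaths")]
}

check_cause_shares <- function(shares) {
  needed <- c("state_id", "cause", "share")
  if (!is.data.frame(shares) || !all(needed %in% names(shares))) {
    stop("cause-share table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(shares$share >= 0 & shares$share <= 1))
  wide <- tidyr::pivot_wider(shares[needed], names_from = "cause",
                             values_from = "share")
  missing <- setdiff(gemm_causes(), names(wide))
  if (length(missing)) {
    stop("cause-share table is missing cause(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cod5_sum <- rowSums(wide[cod5_causes()])
  bad <- wide$state_id[cod5_sum > wide$NCD_LRI + 1e-12]
  if (length(bad)) {
    stop("5-COD shares exceed the NCD+LRI share for state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(shares)
}

#' Cause-specific baseline mortality from state shares
#'
#' Applies state-level cause-of-death shares (fractions of all-cause adult
#' deaths) directly to each city's all-cause baseline:
#' `B_i = share_i * B_all`. The share table must cover all six modelled
#' causes, and within every state the five specific-cause shares may not
#' exceed the NCD+LRI aggregate share.
#'
#' @param b_all Output of [allcause_baseline()]; must carry `state_id`.
#' @param shares Long tibble `state_id`, `cause`, `share`.
#' @return Tibble `city_id`, `cause`, `deaths` (six rows per city), plus
#'   carried metadata.
#' @export
cause_baseline <- function(b_all, shares) {
  if (!"state_id" %in% names(b_all)) {
    stop("`b_all` must carry a `state_id` column to join state shares",
         call. = FALSE)
  }
  check_cause_shares(shares)
  shares <- shares[shares$cause %in% gemm_causes(),
                   c("state_id", "cause", "share")]
  out <- b_all %>%
    select(-cause) %>%
    rename(b_all = deaths) %>%
    inner_join(shares, by = "state_id", relationship = "many-to-many") %>%
    mutate(deaths = share * b_all) %>%
    select(-share, -b_all)
  if (nrow(out) != nrow(b_all) * length(gemm_causes())) {
    missing <- setdiff(b_all$state_id, shares$state_id)
    stop("no cause shares for state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Segregate NCD-other from the NCD+LRI aggregate
#'
#' The five specific causes are nested in the NCD+LRI aggregate; to avoid
#' double counting, their attributable deaths are subtracted from the
#' aggregate and the remainder reported as NCD-other:
#' `max(0, delta_ncd_lri - delta_5cod_sum)`. Negative differences (possible
#' because each cause uses its own exposure-response constants) clamp to 0
#' with a warning.
#'
#' @param delta_ncd_lri Attributable deaths under the NCD+LRI aggregate.
#' @param delta_5cod_sum Sum of attributable deaths over the five specific
#'   causes, same length (or recyclable).
#' @return NCD-other attributable deaths (vectorized).
#' @export
#' @examples
#' ncd_other(80447, 72903) # 7544
ncd_other <- function(delta_ncd_lri, delta_5cod_sum) {
  stopifnot(all(delta_ncd_lri >= 0), all(delta_5cod_sum >= 0))
  diff <- delta_ncd_lri - delta_5cod_sum
  if (any(diff < 0)) {
    warning(sprintf("%d NCD-other value(s) were negative and clamped to 0",
                    sum(diff < 0)), call. = FALSE)
  }
  pmax(0, diff)
}

#' Crude-rate plausibility screen against a survey band
#'
#' Compares each city's crude adult mortality rate `B_all / population`
#' with a configured plausibility band (for instance a Sample Registration
#' Survey state band). Out-of-band cities are flagged, never rejected: the
#' screen is diagnostic only.
#'
#' @param b_all Output of [allcause_baseline()].
#' @param population Adult (age > 25) population per city, aligned with
#'   `b_all` rows.
#' @param low,high Band bounds as deaths per person per year (closed
#'   interval).
#' @return Tibble `city_id`, `rate`, `in_band`.
#' @export
srs_plausibility <- function(b_all, population, low, high) {
  stopifnot(all(population > 0), is.numeric(low), is.numeric(high), low <= high)
  rate <- b_all$deaths / population
  tibble(
    city_id = b_all$city_id,
    rate    = rate,
    in_band = rate >= low & rate <= high
  )
}

utils::globalVariables(c(
  "district_urban_deaths", "state_age_share_25plus", "population",
  "district_urban_population", "adult_share", "cause", "deaths", "share",
  "b_all", "state_id"
))
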