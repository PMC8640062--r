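# Pipeline module: orchestrates exposure -> baseline -> GEMM -> attribution
# -> valuation (-> scenario) from a bundle or a config file, and writes
# tidy CSV outputs plus a JSON summary.

.config_keys <- c("paths", "synthetic", "counterfactual", "min_days",
                  "screen", "vsl", "scenario", "out_dir", "seed", "log_level")
.path_keys <- c("exposure", "demography", "cause_shares", "econ", "scenario")

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON. Recognised top-level keys: `paths` (input CSVs:
#' exposure, demography, cause_shares, econ, scenario), `synthetic`
#' (hyper-parameters forwarded to [synthetic_spec()], used when no paths
#' are given), `counterfactual`, `min_days`, `screen` (`lo`, `hi`), `vsl`
#' (`ec_ind`, `g_ind`, `epsilon`, `beta`, `ppp_factor`), `scenario`
#' (`reduction_fraction`, `target_year`), `out_dir`, `seed`, `log_level`.
#' Unknown keys are rejected and referenced files must exist.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file, or an
#'   already-parsed list.
#' @return Validated config list of class `pm_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$paths)) {
    bad_keys <- setdiff(names(cfg$paths), .path_keys)
    if (length(bad_keys)) {
      stop("unknown paths key(s): ", paste(bad_keys, collapse = ", "),
           call. = FALSE)
    }
    missing <- unlist(cfg$paths)[!file.exists(unlist(cfg$paths))]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(cfg, class = "pm_run_config")
}

# Materialise a pm_bundle from a validated config: either reads the input
# CSVs, or generates a synthetic bundle.
bundle_from_config <- function(cfg) {
  vsl <- cfg$vsl %||% list()
  conf <- list(
    counterfactual = cfg$counterfactual %||% 2.4,
    ec_ind = vsl$ec_ind %||% 44.69e6,
    g_ind = vsl$g_ind %||% 103870,
    epsilon = vsl$epsilon %||% 1.0,
    beta = vsl$beta %||% 0.8,
    ppp_factor = vsl$ppp_factor %||% 65.12,
    reduction_fraction = cfg$scenario$reduction_fraction %||% 0.30,
    base_year = 2017,
    target_year = cfg$scenario$target_year %||% 2024
  )
  if (is.null(cfg$paths)) {
    args <- cfg$synthetic %||% list()
    if (!is.null(cfg$seed) && is.null(args$seed)) args$seed <- cfg$seed
    args$counterfactual <- conf$counterfactual
    args$reduction_fraction <- conf$reduction_fraction
    spec <- do.call(synthetic_spec, args)
    return(generate_city_table(spec))
  }
  read1 <- function(key) {
    if (is.null(cfg$paths[[key]])) return(NULL)
    readr::read_csv(cfg$paths[[key]], comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  demography <- read1("demography")
  if (is.null(demography) || nrow(demography) == 0) {
    stop("config data error: the demography/city input is empty or missing",
         call. = FALSE)
  }
  exposure <- read1("exposure")
  if (is.null(exposure) || nrow(exposure) == 0) {
    stop("config data error: the exposure input is empty or missing",
         call. = FALSE)
  }
  meta_cols <- intersect(c("city_id", "class", "zone", "state_id", "population"),
                         names(demography))
  structure(list(
    cities = distinct(demography[meta_cols]),
    exposure = exposure,
    demography = demography,
    cause_shares = read1("cause_shares"),
    econ = read1("econ"),
    scenario = read1("scenario"),
    config = conf
  ), class = "pm_bundle")
}

#' Run the burden and valuation chain
#'
#' Executes the full assessment on one input bundle: all-cause and
#' cause-specific adult baselines, excess concentration, GEMM relative
#' risks with 95% bounds, attributable mortality, NCD-other segregation,
#' attributable shares, VSL benefit transfer and monetization, and
#' class/zone/cause/total aggregates. NCD-other is reported central-only
#' (its bounds are not defined by the theta-propagation convention) and is
#' excluded from bound sums; all-cause totals use the NCD+LRI rows.
#'
#' @param x A `pm_bundle` (see [generate_city_table()]), a
#'   `pm_run_config`, or a path to a config file.
#' @param out_dir Optional output directory; when given, tidy CSVs and a
#'   `summary.json` are written (deaths rounded to integers and money to
#'   0.1 million US$ on disk; returned objects keep full precision).
#' @param params GEMM parameter table override.
#' @return List of class `pm_burden_run`: `exposure`, `baseline_all`,
#'   `baseline_cause`, `mortality`, `city_summary`, `losses`, `aggregates`,
#'   `summary`.
#' @export
run_burden <- function(x, out_dir = NULL, params = NULL) {
  bundle <- as_pm_bundle(x)
  cfg <- bundle$config
  params <- params %||% gemm_params(counterfactual = cfg$counterfactual)
  cf <- attr(params, "counterfactual")

  if (nrow(bundle$cities) == 0) {
    stop("data error: the city table is empty", call. = FALSE)
  }
  b_all <- allcause_baseline(bundle$demography)
  b_cause <- cause_baseline(b_all, bundle$cause_shares)

  expo <- bundle$exposure[, c("city_id", "pm25_annual")]
  tab <- b_cause %>%
    inner_join(expo, by = "city_id") %>%
    inner_join(params, by = "cause") %>%
    mutate(
      z = excess_concentration(pm25_annual, cf),
      central = gemm_rr(z, theta, alpha, mu, nu),
      low = gemm_rr(z, theta - 1.96 * se_theta, alpha, mu, nu),
      high = gemm_rr(z, theta + 1.96 * se_theta, alpha, mu, nu)
    )
  if (nrow(tab) != nrow(b_cause)) {
    missing <- setdiff(b_cause$city_id, expo$city_id)
    stop("data error: no exposure for city(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  est <- attributable_mortality(
    tab[, c("city_id", "cause", "central", "low", "high")],
    tab$deaths
  )

  # NCD-other: aggregate minus five specific causes, central only
  wide <- est %>%
    select(city_id, cause, delta_e) %>%
    tidyr::pivot_wider(names_from = cause, values_from = delta_e)
  other <- tibble(
    city_id = wide$city_id,
    cause = "NCD_other",
    delta_e = ncd_other(wide$NCD_LRI, rowSums(wide[cod5_causes()])),
    low = NA_real_,
    high = NA_real_
  )
  mortality <- bind_rows(est, other) %>% arrange(city_id, cause)

  ncd <- est[est$cause == "NCD_LRI", ]
  city_summary <- b_all %>%
    select(city_id, b_all = deaths) %>%
    inner_join(ncd[, c("city_id", "delta_e", "low", "high")], by = "city_id") %>%
    inner_join(other[, c("city_id", "delta_e")] %>%
                 rename(ncd_other = delta_e), by = "city_id") %>%
    mutate(pm_share_pct = pm_share(delta_e, b_all))

  state_vsl <- bundle$econ %>%
    mutate(vsl_usd = benefit_transfer_vsl(
      g_k, pct_dg, pct_dcpi,
      ec_ind = cfg$ec_ind, g_ind = cfg$g_ind,
      epsilon = cfg$epsilon, beta = cfg$beta, ppp_factor = cfg$ppp_factor
    )) %>%
    select(state_id, vsl_usd)
  city_vsl <- bundle$cities %>%
    select(city_id, state_id) %>%
    inner_join(state_vsl, by = "state_id")
  mort_vsl <- mortality %>% inner_join(city_vsl, by = "city_id")
  losses <- economic_loss(mort_vsl$vsl_usd, mort_vsl)

  meta <- bundle$cities
  agg <- function(e) list(
    total = aggregate_estimates(e, by = "total"),
    class = aggregate_estimates(e, by = "class", meta = meta),
    zone  = aggregate_estimates(e, by = "zone", meta = meta)
  )
  loss_ncd <- losses[losses$cause == "NCD_LRI", ]
  aggregates <- list(
    deaths = agg(ncd),
    losses = agg(loss_ncd),
    deaths_by_cause = aggregate_estimates(mortality, by = "cause"),
    losses_by_cause = aggregate_estimates(losses, by = "cause")
  )

  summary <- list(
    n_cities = nrow(bundle$cities),
    causes = sort(unique(mortality$cause)),
    counterfactual = cf,
    total_deaths = as.list(aggregates$deaths$total[c("central", "low", "high")]),
    total_loss_musd = as.list(aggregates$losses$total[c("central", "low", "high")]),
    ncd_other_deaths = sum(other$delta_e),
    pm_share_pct = list(min = min(city_summary$pm_share_pct),
                        max = max(city_summary$pm_share_pct)),
    class_share_pct = setNames(as.list(aggregates$deaths$class$share_pct),
                               aggregates$deaths$class$class),
    zone_share_pct = setNames(as.list(aggregates$deaths$zone$share_pct),
                              aggregates$deaths$zone$zone)
  )

  run <- structure(list(
    exposure = bundle$exposure,
    baseline_all = b_all,
    baseline_cause = b_cause,
    mortality = mortality,
    city_summary = city_summary,
    vsl = city_vsl,
    losses = losses,
    aggregates = aggregates,
    summary = summary,
    bundle = bundle
  ), class = "pm_burden_run")
  if (!is.null(out_dir)) write_burden_run(run, out_dir)
  run
}

as_pm_bundle <- function(x) {
  if (inherits(x, "pm_bundle")) return(x)
  if (inherits(x, "pm_run_config")) return(bundle_from_config(x))
  if (is.character(x) || is.list(x)) {
    return(bundle_from_config(read_run_config(x)))
  }
  stop("`x` must be a pm_bundle, a pm_run_config, or a config path",
       call. = FALSE)
}

# On-disk reporting granularity: deaths as integers, money at 0.1 MUS$.
write_burden_run <- function(run, out_dir, prefix = "") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(out_dir, paste0(prefix, name))
  round_cols <- function(d, cols, digits) {
    d[cols] <- lapply(d[cols], round, digits = digits)
    d
  }
  readr::write_csv(run$exposure, p("exposure.csv"))
  readr::write_csv(round_cols(run$baseline_cause, "deaths", 0), p("baseline.csv"))
  readr::write_csv(round_cols(run$mortality, c("delta_e", "low", "high"), 0),
                   p("mortality.csv"))
  readr::write_csv(round_cols(run$losses, c("loss", "low", "high"), 1),
                   p("losses.csv"))
  readr::write_csv(
    round_cols(run$city_summary,
               c("b_all", "delta_e", "low", "high", "ncd_other"), 0),
    p("city_summary.csv"))
  for (grp in c("class", "zone")) {
    readr::write_csv(round_cols(run$aggregates$deaths[[grp]],
                                c("central", "low", "high"), 0),
                     p(sprintf("deaths_by_%s.csv", grp)))
    readr::write_csv(round_cols(run$aggregates$losses[[grp]],
                                c("central", "low", "high"), 1),
                     p(sprintf("losses_by_%s.csv", grp)))
  }
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pm_burden_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PM2.5 burden run: %d cities\n", s$n_cities))
  cat(sprintf("  total attributable deaths (NCD+LRI): %.0f [%.0f-%.0f]\n",
              s$total_deaths$central, s$total_deaths$low, s$total_deaths$high))
  cat(sprintf("  total economic loss: %.1f [%.1f-%.1f] million US$\n",
              s$total_loss_musd$central, s$total_loss_musd$low,
              s$total_loss_musd$high))
  cat(sprintf("  attributable share range: %.1f-%.1f%%\n",
              s$pm_share_pct$min, s$pm_share_pct$max))
  invisible(x)
}

#' Run the policy scenario against the base year
#'
#' Re-runs the whole chain with the scenario PM2.5 (fractional reduction
#' applied to every city) and target-year baselines (2017 incidence rates
#' frozen, deaths rescaled with the projected adult population). Economic
#' parameters are held at base-year values, so losses are in base-year
#' million US$. Returns both runs plus signed percent-change tables.
#'
#' @inheritParams run_burden
#' @return List of class `pm_scenario_run`: `base`, `scenario`,
#'   `change_city`, `change_total`.
#' @export
run_scenario <- function(x, out_dir = NULL, params = NULL) {
  bundle <- as_pm_bundle(x)
  if (is.null(bundle$scenario)) {
    stop("config data error: no scenario block/table in the inputs",
         call. = FALSE)
  }
  base <- run_burden(bundle, params = params)

  scn_bundle <- bundle
  scn_bundle$exposure$pm25_annual <-
    apply_reduction(bundle$exposure$pm25_annual,
                    bundle$config$reduction_fraction)
  growth <- bundle$scenario %>%
    mutate(factor = population_target / bundle$cities$population[
      match(city_id, bundle$cities$city_id)])
  f <- growth$factor[match(scn_bundle$demography$city_id, growth$city_id)]
  # scale the whole registry block so the disaggregated baseline rescales
  # exactly with the adult population (incidence rate frozen)
  scn_bundle$demography$population <- scn_bundle$demography$population * f
  scn_bundle$demography$district_urban_population <-
    scn_bundle$demography$district_urban_population * f
  scn_bundle$demography$district_urban_deaths <-
    scn_bundle$demography$district_urban_deaths * f
  scn_bundle$cities$population <- scn_bundle$cities$population *
    growth$factor[match(scn_bundle$cities$city_id, growth$city_id)]
  if ("year" %in% names(scn_bundle$demography)) {
    scn_bundle$demography$year <- bundle$config$target_year
  }
  scn_bundle$exposure$year <- bundle$config$target_year
  scn <- run_burden(scn_bundle, params = params)

  base_city <- base$city_summary
  scn_city <- scn$city_summary
  change_city <- tibble(
    city_id = base_city$city_id,
    deaths_change_pct = percent_change(base_city$delta_e,
                                       scn_city$delta_e[
                                         match(base_city$city_id,
                                               scn_city$city_id)])
  )
  loss_base <- base$losses[base$losses$cause == "NCD_LRI", ]
  loss_scn <- scn$losses[scn$losses$cause == "NCD_LRI", ]
  change_city$loss_change_pct <- percent_change(
    loss_base$loss[match(change_city$city_id, loss_base$city_id)],
    loss_scn$loss[match(change_city$city_id, loss_scn$city_id)]
  )
  change_total <- list(
    deaths_pct = percent_change(base$summary$total_deaths$central,
                                scn$summary$total_deaths$central),
    loss_pct = percent_change(base$summary$total_loss_musd$central,
                              scn$summary$total_loss_musd$central)
  )
  out <- structure(list(
    base = base, scenario = scn,
    change_city = change_city, change_total = change_total
  ), class = "pm_scenario_run")
  if (!is.null(out_dir)) {
    write_burden_run(base, out_dir, prefix = "base_")
    write_burden_run(scn, out_dir, prefix = "scenario_")
    readr::write_csv(
      dplyr::mutate(change_city, across(c(deaths_change_pct, loss_change_pct),
                                        ~ round(.x, 2))),
      file.path(out_dir, "percent_change.csv"))
    jsonlite::write_json(change_total, file.path(out_dir, "percent_change.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pm_scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run (reduction %.0f%%):\n",
              100 * x$base$bundle$config$reduction_fraction))
  cat(sprintf("  deaths: %+.2f%%   loss: %+.2f%%\n",
              x$change_total$deaths_pct, x$change_total$loss_pct))
  invisible(x)
}

utils::globalVariables(c(
  "theta", "se_theta", "alpha", "mu", "nu", "z", "central", "delta_e",
  "g_k", "pct_dg", "pct_dcpi", "vsl_usd", "loss", "deaths_change_pct",
  "loss_change_pct", "factor"
))
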