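# Independent brute-force transcription of the burden chain, used as the
# oracle against the package's vectorized pipeline (and against the naive
# in-package ledger). Deliberately shares no code with the package:
# the risk function is written via log1p/plogis, the attributable fraction
# as 1 - 1/RR, and the loop structure differs from both package paths.

o_rr <- function(z, theta, alpha, mu, nu) {
  exp(theta * log1p(z / alpha) * stats::plogis((z - mu) / nu))
}

o_af <- function(rr) pmax(0, 1 - 1 / rr)

oracle_burden <- function(bundle, params) {
  cf <- attr(params, "counterfactual")
  d <- as.data.frame(bundle$demography)
  e <- as.data.frame(bundle$exposure)
  sh <- as.data.frame(bundle$cause_shares)
  ec <- as.data.frame(bundle$econ)
  cfg <- bundle$config
  rows <- lapply(seq_len(nrow(d)), function(i) {
    cid <- d$city_id[i]
    z <- max(0, e$pm25_annual[e$city_id == cid] - cf)
    b_all <- d$district_urban_deaths[i] * d$state_age_share_25plus[i] *
      d$population[i] / d$district_urban_population[i]
    eci <- ec[ec$state_id == d$state_id[i], ]
    vsl <- cfg$ec_ind * (eci$g_k / cfg$g_ind)^cfg$epsilon *
      (1 + eci$pct_dg + eci$pct_dcpi)^cfg$beta / cfg$ppp_factor
    per_cause <- lapply(seq_len(nrow(params)), function(j) {
      p <- params[j, ]
      s <- sh$share[sh$state_id == d$state_id[i] & sh$cause == p$cause]
      th3 <- p$theta + c(0, -1.96, 1.96) * p$se_theta
      de <- o_af(o_rr(z, th3, p$alpha, p$mu, p$nu)) * s * b_all
      data.frame(city_id = cid, cause = p$cause,
                 delta_e = de[1], low = de[2], high = de[3],
                 loss = vsl * de[1] / 1e6, b_i = s * b_all,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_cause)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Convenience: a small deterministic bundle for pipeline tests.
small_bundle <- function(seed = 42, n_cities = 5) {
  generate_city_table(synthetic_spec(n_cities = n_cities, seed = seed))
}
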