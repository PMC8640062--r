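---
title: "Methods: PM2.5 mortality burden, valuation, and policy scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5 mortality burden, valuation, and policy scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmburden)
```

## The assessment chain

`pmburden` implements the standard health-impact-assessment chain used to
quantify premature adult mortality attributable to ambient fine
particulate matter (PM2.5) in data-sparse urban settings, and to put a
monetary value on it:

1. **Exposure.** Daily station data are screened to the plausibility
   window 2–1000 µg/m³, annual means are accepted only with at least 104
   valid days, and missing PM2.5 is completed from PM10 by station-level
   ordinary least squares or, where no co-located pair exists, by a
   literature ratio factor. Station values are averaged (unweighted) to
   one city-year value.
2. **Risk.** The Global Exposure Mortality Model (GEMM) relative risk

   $$RR(z) = \exp\!\left\{ \frac{\theta \,\log(z/\alpha + 1)}
   {1 + \exp\{-(z-\mu)/\nu\}} \right\},
   \qquad z = \max(0,\, C - C_0),$$

   is evaluated per cause for a single adult (age > 25) stratum, with the
   counterfactual $C_0 = 2.4$ µg/m³ below which no excess risk is
   modelled. The constants $(\theta, \sigma_\theta, \alpha, \mu, \nu)$
   ship in `inst/extdata/gemm_params.csv` for the NCD+LRI aggregate
   (non-communicable disease plus lower respiratory infection) and the
   five specific causes IHD, stroke, COPD, lung cancer, and LRI; their
   provenance is recorded in the file header.
3. **Baseline mortality.** City all-cause adult deaths are disaggregated
   from district urban registry counts as
   $B_{all} = D_{district} \times s_{25+} \times P_{city}/P_{district}$,
   where $s_{25+}$ is the state share of deaths above age 25 (applied to
   the district, since district age splits are unavailable). State
   cause-of-death shares then give $B_i = \text{share}_i \times B_{all}$.
4. **Attribution.** Attributable deaths are
   $\Delta E_i = \frac{RR_i - 1}{RR_i} B_i$ per city and cause, with 95%
   bounds obtained by re-evaluating the GEMM function at
   $\theta \pm 1.96\,\sigma_\theta$. Because the five specific causes are
   nested in the NCD+LRI aggregate, their sum is subtracted from the
   aggregate and the remainder reported as **NCD-other**.
5. **Valuation.** A national Value of Statistical Life (VSL) is
   benefit-transferred to each state,
   $$EC_k = EC_{Ind}\left(\frac{G_k}{G_{Ind}}\right)^{\varepsilon}
   (1 + \%\Delta G + \%\Delta CPI)^{\beta} / PPP,$$
   and attributable deaths are valued as $EC_k \times \Delta E$, reported
   in million US$.
6. **Scenario.** A fractional PM2.5 reduction (the national 20–30% policy
   target; default 30%) is applied to every city, baseline incidence
   rates are frozen at the base year and deaths rescaled with the
   projected adult population, economics are held at base-year values,
   and signed percent changes are reported per city and in total.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| screening window | 2–1000 | µg/m³ | plausibility limits for daily means; closed interval |
| completeness `min_days` | 104 | days | at least 104 valid days; the inclusive reading is the standard convention for "more than 104 days" of a completeness rule, and it is configurable |
| correlation floor `r_floor` | 0.6 | — | PM10–PM2.5 fits below this warn (never reject); accepted fits in practice show r of 0.65–0.97 |
| counterfactual `c0` | 2.4 | µg/m³ | lowest exposure with modelled excess risk |
| CI multiplier `zscore` | 1.96 | — | two-sided 95% band on θ |
| base VSL `ec_ind` | 44.69×10⁶ | ₹ (2016) | most recent national hedonic-wage estimate |
| WTP elasticity `epsilon` | 1.0 | — | unit income elasticity of willingness to pay across states |
| income elasticity `beta` | 0.8 | — | recommended elasticity for the one-year growth bracket |
| exchange divisor `ppp_factor` | 65.12 | ₹/US$ | 2017 conversion; a plain configurable number (see below) |
| reduction | 0.30 | — | upper national policy target for 2024 |

## Numerical and design choices

* **Uncertainty propagates through θ only.** α, µ, ν have no published
  standard errors; the low/high bounds re-evaluate the full nonlinear
  function at the shifted θ rather than linearising. The low bound can
  fall below RR = 1 only when the shifted θ itself is negative; the
  attributable fraction then clamps at 0 with a warning, so burdens are
  never negative.
* **CI aggregation sums per-city bounds** (perfect-dependence
  convention): θ is shared across cities within a cause, so city errors
  are fully dependent and interval sums are coherent. No Monte-Carlo
  propagation is attempted.
* **NCD-other is reported central-only.** The difference of two
  per-bound intervals has no defined ordering under θ-propagation, so
  bounds for the segregated remainder would be artefacts; its low/high
  are `NA` and it is excluded from bound sums. Negative remainders clamp
  to 0 with a warning — this genuinely occurs at low exposures, where the
  steep specific-cause risk functions outweigh the flatter aggregate.
* **Currency conversion divides by the exchange factor.** The
  benefit-transfer bracket yields rupees; dividing by a ₹/US$ factor is
  the only dimensionally consistent reading, and the factor is a plain
  config number whose provenance (market rate vs PPP) is left to the
  user.
* **The 104-day completeness rule applies to measured days only**, before
  any PM10-based gap filling; imputed annual values carry their
  provenance (`regression_imputed`, `ratio_converted`) and a city-year
  inherits the worst provenance among its stations.
* **Degenerate inputs** are handled explicitly: empty daily series screen
  to empty results; zero-variance PM10 and fewer than three matched pairs
  are errors; negative imputed PM2.5 clips to 0 with a warning; a zero
  base value makes a percent change an error rather than an Inf.
* **Scenario chain.** The target-year run reduces concentrations first,
  recomputes RR, rescales baselines with the adult population at frozen
  incidence, and revalues at base-year economics. With the published
  adult-population growth band (44.1–59.9%) and a 30% cut, the product
  $(1+g)\,AF_{scn}/AF_{base}$ exceeds 1 for every city on the GEMM
  curvature, so total scenario mortality *rises* (~+33% on the synthetic
  bundle). Published accounts of the same intervention report a small
  net decrease with mixed-sign city changes; that outcome is not
  reachable from the stated assumptions, and the package reports what
  the chain computes rather than targeting the published sign. The
  printed 2017/2024 totals are instead used as transcription inputs to
  arithmetic-consistency checks.

## What the synthetic generator emulates — and what it does not

`generate_city_table()` draws a full input bundle under one seed fan-out:
31 cities split 7 X-class (population 5–20 million, log-uniform) and 24
Y-class (1–5 million), five zones, paired states, annual PM2.5 uniform on
33–194 µg/m³, registry demography (district urban crude death rates
0.006–0.008, state age-25+ death shares 0.75–0.90, city/district
population ratios 0.60–0.95 — jointly giving adult crude mortality rates
near 11 per 1000), and state economics (GDP ratios 1.0–2.0 over a
national 103,870 ₹ per capita, growth brackets of +5–12% GDP and +2–6%
CPI).

The cause-share hyper-parameters were calibrated once by inverting the
GEMM attributable fraction at a representative excess concentration
against the published aggregate outcomes of the 31-city study (total
attributable share 7.2–18.4%; cause mix IHD 47%, COPD 17%, stroke 14.7%,
LRI 9.9%, LC 1.9%, NCD-other 9.3%): the *effective* NCD+LRI share of
all-cause adult deaths consistent with those outcomes is ~0.30–0.42, with
IHD 0.08–0.13, COPD 0.040–0.065, stroke 0.030–0.055, LRI 0.012–0.025 and
LC 0.004–0.007. These are deliberately not generic global cause-of-death
fractions: they absorb whatever age- and urban-specific adjustment the
registry data implies, which is why the `paper_like_fixture()` run lands
close to the published totals without using any unpublished inputs.

The generator does **not** emulate spatial station placement, meteorology
or seasonality (daily PM10 is an i.i.d. gamma draw with cv 0.4),
correlated errors between cities, reporting gaps in death registries, or
year-to-year exposure trends. Passing tests therefore demonstrate the
correctness and internal consistency of the chain — not that any real
city's registry or monitoring data satisfy the model's assumptions.

`paper_like_fixture()` pins the 31 real city names, classes, zones and
states from the packaged transcription of published per-city results,
uses the ten published annual PM2.5 values verbatim (e.g. Delhi 121,
Ghaziabad 194 µg/m³) and draws the remaining cities from their zone's
published concentration range, under a pinned seed.

## Problem sizes and verification

The test suite runs three independent evaluation routes against each
other: the vectorized pipeline, the plain loop transcription that fills
each bundle's ground-truth ledger, and a third brute-force transcription
kept in the test tree (written via `log1p`/`plogis` so it shares no code
with either). End-to-end agreement is required to 10⁻⁹ relative
tolerance on a 31-city bundle. Risk-function properties (unit anchoring
at z = 0, monotonicity, the log-linear tail limit) are checked on a 0–300
µg/m³ grid for every packaged parameter row. Regression recovery uses
200 replicates of 300-day noisy station pairs (the slope must fall inside
its own 95% CI at nominal frequency, at least 93%), and CI coverage is
additionally checked over 500 replicates at 150 days. Bundle invariants
are validated over 100 random generator specifications. These sizes keep
the whole suite under a minute on one CPU while leaving the binomial
noise of the coverage checks well inside their acceptance bands.

```{r}
run <- suppressWarnings(run_burden(paper_like_fixture()))
run
```

## Known limitations

* A single adult stratum per cause: no 5-year age stratification, no
  morbidity endpoints, no years-of-life-lost.
* Baseline disaggregation assumes the state age share applies to the
  district and that city deaths scale with resident population; both are
  conventions forced by registry granularity, flagged by the
  `srs_plausibility()` screen rather than corrected.
* Exposure is one number per city-year; spatial misclassification within
  a city is not modelled.
* The reported intervals reflect exposure-response uncertainty only —
  not baseline-mortality, exposure, or valuation uncertainty.
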