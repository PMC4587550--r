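---
title: "Model and methods: maternal-care cost-effectiveness under the Kwara State Health Insurance program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kwaracea)
```

## The decision problem

The package implements a decision-analytic cohort model of maternal care in
rural Nigeria. Two arms are compared for a cohort of 10,000 pregnant women
followed through one pregnancy until delivery: the current standard of care
(SoC), and care under the Kwara State Health Insurance program (KSHI),
which raises utilization (antenatal care, facility delivery, emergency
obstetric care) and quality (universal EOC in facilities, hypertensive-
disorder prophylaxis during ANC), at the price of service costs plus an
above-service insurer mark-up. The primary outcome is the incremental cost
per DALY averted.

## Pathway structure

Each woman passes through three utilization nodes — ANC attendance,
delivery location (facility/home), EOC access — and one clinical node with
five mutually exclusive delivery outcomes: post-partum haemorrhage (PPH),
sepsis, hypertensive disorders (HTD), obstructed labour (OL), or an
uncomplicated delivery. Mutual exclusivity matches the published cohort
table, in which per-stratum complication counts sum to the complications
total, so no competing-risk ordering is needed. Effect modifiers:

* PPH and OL incidence are independent of care.
* Sepsis incidence is lower for facility ("hospital") deliveries,
  relative risk 0.54.
* HTD incidence is reduced (relative risk 0.41) for ANC attendees who
  receive prophylaxis: all of them in the insured arm, a configurable
  fraction (default 0.299, see calibrations) in the SoC.
* Case fatality: PPH death probability is multiplied by 0.34 under EOC; OL
  death (probability 0.007) is defined for the no-EOC pathway only, so OL
  with EOC is non-fatal; sepsis and HTD case fatality are not modified by
  EOC — their benefit flows through incidence and prophylaxis. This is the
  only reading under which the published per-stratum death counts
  reconcile (e.g. the SoC no-ANC EOC cell:
  30·0.1505·0.34 + 10·0.3635 + 50·0.083 ≈ 9).
* Sequelae among survivors: anaemia after PPH (0.12, halved by EOC),
  secondary infertility after sepsis (0.05–0.1), fistula after OL without
  EOC (0.14).

The engine propagates expected counts (real-valued, never rounded
internally); comparisons against the published table round half away from
zero at the end. Conservation of the cohort across every split is enforced
by tests to 1e-9.

## Input parameters and distributions

`default_parameters()` carries every published input with its uncertainty
distribution; `load_parameters()` reads the same content from the shipped
YAML configuration. Conventions, following the published parameterisation:

* **beta** by mean and standard deviation, converted by method of moments
  (`beta_from_moments()`), which reproduces both declared moments exactly;
* **uniform** by minimum and maximum (point estimate: the midpoint — e.g.
  sepsis case fatality 0–0.727 evaluates at 0.3635);
* **triangular** by mean, minimum and maximum, with the mode solved as
  `3·mean − min − max` so the declared mean is preserved. One row (the
  anaemia DALY weight, 0.09 on 0.08–0.09) is infeasible under that reading
  because the printed mean is rounded; for such rows the printed central
  value is used as the mode and the point estimate becomes the analytic
  mean of that triangle ((0.08+0.09+0.09)/3 ≈ 0.0867). The effect is
  negligible (the weight multiplies ~37 cases).

Relative risks with beta distributions are sampled on (0, 1), so sampled
risk reductions never invert. Probabilities formed as products of a sampled
probability and a sampled relative risk are clamped to [0, 1] with a
warning; if an extreme draw pushes the four complication probabilities
above a sum of 1, they are renormalised (again with a warning) — neither
event occurs under the default distributions.

The DALY weight per death (23.43, range 21.09–25.77) equals a discounted
stream of healthy life over the remaining life expectancy at 3% per annum:
`discounted_years(L, r) = (1 − exp(−r·L))/r`, with L ≈ 40.5 years.

## Calibrated structural quantities

The exact pathway tree behind the published cohort table is not part of the
printed inputs. Five structural quantities are therefore calibrated so that
the printed table is reproduced, and are exposed as configuration (all in
`pathway_defaults()` and overridable per `scenario_config()`). They are
reconstructions, not published parameters:

* **Facility share without prior ANC** — solved from the EOC split of
  obstructed labour (whose incidence is location-independent, so its EOC
  split equals the women-level split): SoC (1/6 − 0.136)/(0.925 − 0.136) ≈
  0.0389; KSHI (65/321 − 0.136)/(1 − 0.136) ≈ 0.077.
* **Home-delivery share among insured ANC attendees** — the published
  facility/home split given prior ANC (0.96/0.05, renormalised to sum 1) is
  used for the SoC; the insured column is blank and the published no-EOC
  cells imply a smaller home share, calibrated to 0.025.
* **Home-delivery sepsis rate** 0.01875 — a single shared value that
  reproduces both scenario sepsis totals (133 and 115 per 10,000); the
  published cohort-level rate 0.017 cannot, because the no-ANC subgroup
  alone implies 65/3,500 ≈ 0.0186. The sampled sepsis probability scales
  this rate proportionally (`draw/0.017`) in the PSA, so the published
  uncertainty still propagates.
* **SoC HTD-prophylaxis coverage** 0.299 — the SoC ANC stratum shows a
  partial prophylaxis effect (455/6,500 = 0.07 against a baseline 0.085);
  coverage solves (0.085 − 0.07)/(0.085·(1 − 0.41)).
* **Extended HTD morbidity weight** 21.33 DALYs per surviving HTD case and
  **ledger baseline** 38.13 healthy years per woman — see next section.

## Health accounting

Deaths contribute years of life lost (deaths × 23.43); sequelae contribute
years lived with disability at their per-event weights. The published
scenario-level "total DALYs" column, however, sits at ~36–37 per woman and
its between-arm difference (7,724) far exceeds what deaths and the three
printed sequela weights yield (≈1,294). The residual morbidity most
plausibly attaches to hypertensive disease in the unpublished supplementary
structure. The package therefore:

* adds an **extended HTD sequela weight**, calibrated as
  (7,724 − 1,294)/(difference in surviving HTD cases, 301.5) ≈ 21.33 DALYs
  per surviving case; and
* offers two accounting modes in `compute_health()`: **loss mode** (the
  DALY burden itself; used by all invariant tests) and **ledger mode**
  (default; healthy years remaining = 38.13·N − burden, which reproduces
  the published column scale; the baseline solves the published SoC total).

The two modes agree exactly on the between-arm difference, hence on every
ICER. Both calibrated constants are configuration, documented here as
reconstructions; conclusions that depend only on printed inputs (deaths
averted, cost totals) are unaffected by them.

Sequela treatment costs are treated as incurred in year 0 (no timing is
specified), so no additional discounting applies beyond the 3% embedded in
the lifetime DALY weights.

## Costing rules

Provider perspective, US$ 2012. ANC attendees incur the per-pregnancy ANC
cost (12.4–61.5; the per-visit alternative of 4.0–12.5 over 3.1–5 visits
spans the same range and is not used). Facility uncomplicated deliveries
incur 9.65–27.2; complicated deliveries with EOC incur 46.7–53.3 wherever
the EOC is delivered (emergency referrals from home are costed);
complicated facility deliveries without EOC fall back to the uncomplicated
unit cost; home deliveries without EOC are uncosted to the provider.
Fistula (190.9–382.7) and anaemia (9.81–13.79) survivors incur treatment
costs. The insured arm adds the above-service mark-up, US$ 24.1 per
enrolee, to every cohort member. These rules reproduce the published
scenario totals within about 2%.

## Uncertainty analysis

`run_psa()` draws every parameter from its distribution, one draw feeding
both arms per iteration (common random numbers — the published inputs are
shared between arms, and pairing stabilises the incremental distribution).
Per draw it computes incremental cost, DALYs averted, and their ratio.
Summaries are the median and 2.5/97.5 percentiles of the per-draw ratio;
cost-saving draws are placed below the smallest ratio for ranking (type-1,
non-interpolating quantiles, so the infinite sentinels never mix into
finite values) and reported separately, matching the convention of printing
"CS" inside a credible interval. The acceptability curve counts a draw as
cost-effective at threshold w if it is cost-saving or its ratio is at most
w; it is non-decreasing in w by construction.

`one_way_sa()` moves one parameter at a time to the outer limits of its
uncertainty: the support for uniform and triangular parameters, mean ± 1.96
standard deviations truncated to [0, 1] for beta parameters. Two point
inputs receive documented ranges: the above-service cost ±50% (its
published description calls only for "a large variation"), and the discount
rate 0–6%, implemented by rescaling the lifetime DALY weights (death,
fistula, extended HTD) with the discounted-years ratio at the implied
40.5-year horizon. Parameters are ranked by absolute ICER swing. Under this
model the HTD incidence, the discount rate and the above-service cost
dominate; the sepsis case-fatality swing is structurally small here because
sepsis deaths differ between arms by only ~18 cases, whereas the published
ranking places it higher — additional sepsis morbidity in the unpublished
supplementary structure would explain the difference, but cannot be
reconstructed from the printed tables.

## Alternative base cases

Three comparators probe the base case (`scenario_analysis()`): **SoC1**
raises utilization to the insured arm's level (its structure is fully
determined by published inputs); **SoC2** keeps SoC utilization but sets
quality indicators to their high bounds (EOC in facility 0.95, full
prophylaxis) and raises service unit costs to literature levels; **SoC3**
combines both. The literature unit costs are not printed anywhere in the
inputs; they are represented by a single multiplier on ANC and delivery
unit costs whose default (1.686) is solved so the raised-cost base case
reproduces the published alternative-scenario cost total — a documented
reconstruction, so the alternative-base-case ratios are approximate by
construction. SoC3's slightly lower quality than the insured arm leaves it
marginally less effective and more expensive, which lands the comparison in
the cost-saving region, as published.

## Budget impact

`annual_scaleup_cost()` projects the incremental annual cost of scaling the
program to 60/80/100% of the population in need over five years:
population (compounded at the rate of natural increase) × per-woman
expected insured-care cost (from the cohort engine, above-service included)
× coverage − current expenditure, excluding cost-sharing revenue.
Historical unit costs can be brought to 2012 prices with `inflate()`
(12.33% per annum). The Kwara population-in-need and current-expenditure
figures are not part of the printed inputs, so the packaged example values
(250,000 women; US$ 3M) are synthetic placeholders: the state-wide dollar
figure is **not** reproducible from the package alone, and the tests cover
this module through its linearity and monotonicity properties instead.

## Microsimulation

`simulate_individuals()` draws one record per pregnancy through the same
pathway by sequential sampling, consuming the random stream in a fixed
documented order (ANC, visit count, location, EOC, complication, death,
sequela) so a seed reproduces the record stream exactly. ANC attendees
receive 3–5 visits, uniformly. Per-record costs and DALYs follow exactly
the cohort accounting rules, and tests verify (i) exact agreement between
summed per-record costs and the aggregate costing rules, and (ii)
convergence of every cohort-table cell to the expectation engine within 3
binomial standard errors at n = 200,000. The generator emulates the
*structure* of insurance-claims records (one row per pregnancy with
utilization, complication, outcome and cost fields); it does not emulate
features of real claims data such as coding error, incomplete capture,
repeat pregnancies, seasonality or facility-level clustering — so passing
validation shows internal consistency of the two engines, not fidelity to
any real claims stream.

## Problem sizes and numerical choices

The test suite exercises the deterministic engine at cohort sizes 0–50,000,
the PSA at 10,000 iterations (three seeds) and the microsimulation at
200,000 records; the full suite runs in well under a minute on a single
core because every engine is vectorised across draws. Expected-count
conservation is asserted to 1e-9, moment round-trips to 1e-12. Degenerate
inputs are defined rather than erroneous: zero-size strata yield zero
counts, an all-point parameter set collapses the PSA to a width-zero
credible interval, equal-effect comparisons return an undefined-ratio flag
rather than dividing by zero.

## Limitations

No within-pregnancy time dynamics, neonatal pathway, repeat pregnancies, or
patient/societal-perspective costs; no value-of-information analysis; no
health-workforce or infrastructure constraints in the scale-up projection.
The calibrated structural quantities above are reconstructions of an
unpublished tree: alternative reconstructions reproducing the same printed
tables could differ in their sensitivity-analysis behaviour, which is why
each is exposed as configuration rather than hard-coded.
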