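test_that("stratification reproduces the published ANC split", {
  soc <- stratify(10000, fx_point, soc_scenario())
  by_anc <- dplyr::count(soc, anc, wt = n_women)
  expect_equal(by_anc$n[by_anc$anc], 6500)
  expect_equal(by_anc$n[!by_anc$anc], 3500)

  kshi <- stratify(10000, fx_point, kshi_scenario())
  by_anc <- dplyr::count(kshi, anc, wt = n_women)
  expect_equal(by_anc$n[by_anc$anc], 8500)
  expect_equal(by_anc$n[!by_anc$anc], 1500)

  # conservation to numerical precision
  expect_equal(sum(soc$n_women), 10000, tolerance = 1e-12)
  expect_equal(sum(kshi$n_women), 10000, tolerance = 1e-12)
})

test_that("universal ANC access collapses to a single stratum", {
  params <- fx_set_param(fx_params, "anc_access", "soc", "point", mean = 1)
  s <- stratify(10000, point_estimates(params), soc_scenario())
  expect_equal(sum(s$n_women[s$anc]), 10000)
  expect_equal(sum(s$n_women[!s$anc]), 0)
})

test_that("complication incidence matches the published cohort table", {
  soc <- run_cohort(fx_params, soc_scenario())
  tot <- cohort_totals(soc)
  expect_equal(tot$pph, 510, tolerance = 1e-9)   # 10000 * 0.051, care-independent
  expect_equal(tot$ol, 600, tolerance = 1e-9)
  expect_equal(round(tot$sepsis), 133)
  expect_equal(round(tot$htd), 752, tolerance = 1) # 752.5 at point estimates

  kshi <- run_cohort(fx_params, kshi_scenario())
  ktot <- cohort_totals(kshi)
  expect_equal(ktot$pph, 510, tolerance = 1e-9)
  expect_equal(ktot$ol, 600, tolerance = 1e-9)
  expect_equal(round(ktot$sepsis), 115)

  # prophylaxis for all insured ANC attendees: 8,500 x 0.085 x 0.41
  anc_htd <- cohort_totals(kshi, by = "anc")
  expect_equal(anc_htd$htd[anc_htd$anc], 8500 * 0.085 * 0.41, tolerance = 1e-9)
})

test_that("a zero-size stratum yields all-zero counts", {
  s <- stratify(0, fx_point, soc_scenario())
  comp <- complication_incidence(s, fx_point, soc_scenario())
  out <- outcome_resolution(comp, fx_point, soc_scenario())
  expect_true(all(out$n_women == 0))
  expect_true(all(out$deaths == 0))
  expect_true(all(out$fistula == 0))
})

test_that("deaths resolve with the published EOC effect modifiers", {
  soc <- run_cohort(fx_params, soc_scenario())
  sub <- cohort_totals(soc, by = c("anc", "eoc"))
  # no-ANC sub-strata of the published table: 64 deaths without EOC, 9 with
  expect_equal(sub$deaths[!sub$anc & !sub$eoc], 64, tolerance = 0.5)
  expect_equal(sub$deaths[!sub$anc & sub$eoc], 9, tolerance = 0.5)
  # obstructed-labour death is defined only without EOC: force OL-only cohort
  only_ol <- fx_point
  for (nm in c("p_pph", "p_htd")) only_ol[[nm]] <- 0
  only_ol$p_sepsis <- 0.0100001 # lowest feasible sepsis anchor
  sc <- soc_scenario()
  sc$sepsis_home_rate <- 0
  cohort <- run_cohort(only_ol, sc)
  expect_equal(sum(cohort$deaths[cohort$eoc]), 0)
  expect_gt(sum(cohort$deaths[!cohort$eoc]), 0)
})

test_that("scenario totals reproduce the published death counts", {
  soc <- cohort_totals(run_cohort(fx_params, soc_scenario()))
  kshi <- cohort_totals(run_cohort(fx_params, kshi_scenario()))
  expect_equal(soc$deaths, 157, tolerance = 0.01)  # 156.98 expected
  expect_equal(kshi$deaths, 110, tolerance = 0.01) # 110.65 expected
  expect_equal(soc$deaths - kshi$deaths, 47, tolerance = 0.02)
})

test_that("expected counts are conserved at every stage", {
  for (sc in list(soc_scenario(), kshi_scenario())) {
    cohort <- run_cohort(fx_params, sc)
    expect_equal(sum(cohort$n_women), 10000, tolerance = 1e-9)
    comp_sum <- with(cohort, pph + sepsis + htd + ol + uncomplicated)
    expect_equal(comp_sum, cohort$n_women, tolerance = 1e-9)
    # deaths cannot exceed complicated deliveries; sequelae bounded by survivors
    expect_true(all(cohort$deaths <= cohort$pph + cohort$sepsis +
                      cohort$htd + cohort$ol + 1e-12))
    expect_true(all(cohort$fistula <= cohort$ol + 1e-12))
    expect_true(all(cohort$anaemia <= cohort$pph + 1e-12))
  }
})

test_that("the engine is scale equivariant in cohort size", {
  base <- cohort_totals(run_cohort(fx_params, soc_scenario(), cohort_size = 10000))
  scaled <- cohort_totals(run_cohort(fx_params, soc_scenario(), cohort_size = 35000))
  for (v in c("pph", "sepsis", "htd", "ol", "deaths", "fistula")) {
    expect_equal(scaled[[v]], 3.5 * base[[v]], tolerance = 1e-9)
  }
})

test_that("more EOC access never increases deaths; more ANC never increases insured HTD", {
  deaths_at_eoc <- function(p_eoc) {
    params <- fx_set_param(fx_params, "eoc_facility", "soc", "point", mean = p_eoc)
    cohort_totals(run_cohort(params, soc_scenario()))$deaths
  }
  d <- vapply(c(0.2, 0.5, 0.925, 1), deaths_at_eoc, numeric(1))
  expect_true(all(diff(d) <= 1e-9))

  htd_at_anc <- function(p_anc) {
    params <- fx_set_param(fx_params, "anc_access", "kshi", "point", mean = p_anc)
    cohort_totals(run_cohort(params, kshi_scenario()))$htd
  }
  h <- vapply(c(0.5, 0.7, 0.85, 1), htd_at_anc, numeric(1))
  expect_true(all(diff(h) <= 1e-9))
})

test_that("pathological draws are clamped with a warning", {
  bad <- fx_point
  bad$p_death_pph <- 1.4
  expect_warning(
    out <- outcome_resolution(
      complication_incidence(stratify(10000, bad, soc_scenario()), bad, soc_scenario()),
      bad, soc_scenario()
    ),
    "clamped"
  )
  expect_true(all(out$deaths <= out$n_women))
})
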