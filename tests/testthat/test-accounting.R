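test_that("discounting follows the continuous closed form", {
  expect_equal(discounted_years(12.5, 0), 12.5)
  expect_equal(discounted_years(0, 0.03), 0)
  # oracle: numerical integration of exp(-r t) over the horizon
  num <- stats::integrate(function(t) exp(-0.03 * t), 0, 40.5)$value
  expect_equal(discounted_years(40.5, 0.03), num, tolerance = 1e-8)
  expect_equal(discounted_years(40.5, 0.03), 23.43, tolerance = 0.001)
  # increasing in horizon, decreasing in rate
  expect_true(all(diff(discounted_years(seq(0, 60, 5), 0.03)) > 0))
  expect_gt(discounted_years(40, 0.01), discounted_years(40, 0.06))
  expect_error(discounted_years(-1, 0.03), "non-negative")
  expect_error(discounted_years(10, -0.03), "non-negative")
})

test_that("mortality dominates the health difference between scenarios", {
  soc <- run_cohort(fx_params, soc_scenario())
  kshi <- run_cohort(fx_params, kshi_scenario())
  hs <- compute_health(soc, mode = "loss")
  hk <- compute_health(kshi, mode = "loss")
  deaths_diff <- cohort_totals(soc)$deaths - cohort_totals(kshi)$deaths
  expect_equal(hs$yll - hk$yll, deaths_diff * 23.43, tolerance = 1e-9)
  expect_equal(hs$yll - hk$yll, 47 * 23.43, tolerance = 0.02 * 23.43)
  # the insured arm dominates on health at point estimates
  expect_gt(hs$losses, hk$losses)
})

test_that("ledger and loss modes agree on the effect difference", {
  soc <- run_cohort(fx_params, soc_scenario())
  kshi <- run_cohort(fx_params, kshi_scenario())
  ledger <- compute_health(kshi, mode = "ledger")$total_effect -
    compute_health(soc, mode = "ledger")$total_effect
  loss <- compute_health(soc, mode = "loss")$total_effect -
    compute_health(kshi, mode = "loss")$total_effect
  expect_equal(ledger, loss, tolerance = 1e-9)
  # ledger mode reproduces the published effect scale
  expect_equal(compute_health(soc)$total_effect, 362581, tolerance = 0.001)
  expect_equal(compute_health(kshi)$total_effect, 370305, tolerance = 0.001)
})

test_that("zero outcomes produce zero burden", {
  cohort <- run_cohort(fx_point, soc_scenario(), cohort_size = 0)
  h <- compute_health(cohort, mode = "loss")
  expect_equal(h$losses, 0)
  expect_equal(compute_cost(cohort)$cost_total, 0)
})

test_that("provider costs reproduce the published scenario totals", {
  cs <- compute_cost(run_cohort(fx_params, soc_scenario()))
  ck <- compute_cost(run_cohort(fx_params, kshi_scenario()))
  expect_equal(cs$cost_total, 397618, tolerance = 0.03)
  expect_equal(ck$cost_total, 755690, tolerance = 0.03)
  # the above-service component is exactly cohort x 24.1, insured arm only
  expect_equal(ck$cost_above_service, 241000)
  expect_equal(cs$cost_above_service, 0)
  # ANC attendees at the mean per-pregnancy cost
  expect_equal(cs$cost_anc, 6500 * (12.4 + 61.5) / 2, tolerance = 1e-9)
})

test_that("costs are additive and respond exactly to the insurance flag", {
  kshi <- run_cohort(fx_params, kshi_scenario())
  ck <- compute_cost(kshi)
  expect_equal(
    ck$cost_total,
    ck$cost_anc + ck$cost_uncomplicated + ck$cost_complicated +
      ck$cost_fistula + ck$cost_anaemia + ck$cost_above_service,
    tolerance = 1e-12
  )
  uninsured <- kshi_scenario()
  uninsured$above_service <- FALSE
  ck0 <- compute_cost(kshi, scenario = uninsured)
  expect_equal(ck$cost_total - ck0$cost_total, 10000 * 24.1, tolerance = 1e-9)
})

test_that("negative unit costs and missing DALY weights are rejected", {
  bad <- fx_point
  bad$cost_fistula <- -1
  cohort <- run_cohort(fx_point, soc_scenario())
  expect_error(compute_cost(cohort, draws = bad), "non-negative")
  bad2 <- fx_point
  bad2$daly_death <- -5
  expect_error(compute_health(cohort, draws = bad2), "non-negative")
  expect_error(compute_health(cohort, draws = fx_point[, -match("daly_death", names(fx_point))]),
               "missing parameter")
})
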