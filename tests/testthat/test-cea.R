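fake_eval <- function(cost, losses, name = "X") {
  tibble::tibble(scenario = name, draw = seq_along(cost),
                 cost_total = cost, losses = losses,
                 total_effect = -losses, n_women = 10000)
}

test_that("the deterministic ICER reproduces the headline estimate", {
  res <- cea_point(fx_params)
  expect_s3_class(res, "cea_result")
  expect_equal(res$status, "ratio")
  expect_equal(res$icer, 46.4, tolerance = 0.05)
  expect_equal(res$verdict, "very cost-effective")
  expect_equal(res$delta_cost, 755690 - 397618, tolerance = 0.03)
  g <- glance(res)
  expect_equal(g$icer, res$icer)
})

test_that("dominance and degenerate comparisons are flagged, not ratioed", {
  base <- fake_eval(500, 100)
  expect_equal(icer(base, fake_eval(400, 80))$status, "cost_saving")
  expect_equal(icer(base, fake_eval(400, 80))$verdict, "cost-saving")
  expect_equal(icer(base, fake_eval(600, 120))$status, "dominated")
  expect_equal(icer(base, fake_eval(600, 100))$status, "undefined")
  same <- icer(base, fake_eval(500, 100))
  expect_equal(same$status, "indifferent")
  expect_equal(same$delta_cost, 0)
  expect_true(is.na(same$icer))
  # verdict thresholds: ratio 200 vs thresholds at wtp and 3 x wtp
  expect_equal(icer(base, fake_eval(2500, 90), wtp = 250)$verdict,
               "very cost-effective")
  expect_equal(icer(base, fake_eval(2500, 90), wtp = 100)$verdict,
               "cost-effective")
  expect_equal(icer(base, fake_eval(2500, 90), wtp = 50)$verdict,
               "not cost-effective")
})

test_that("the ICER is invariant to uniform cohort scaling", {
  a <- cea_point(fx_params)
  big <- fx_set_param(fx_params, "cohort_size", "shared", "point", mean = 50000)
  b <- cea_point(big)
  expect_equal(a$icer, b$icer, tolerance = 1e-9)
  expect_equal(b$delta_cost, 5 * a$delta_cost, tolerance = 1e-9)
})

test_that("the PSA is reproducible and internally consistent", {
  psa1 <- run_psa(fx_params, n_iter = 400, seed = 11)
  psa2 <- run_psa(fx_params, n_iter = 400, seed = 11)
  expect_identical(as.data.frame(psa1$draws), as.data.frame(psa2$draws))
  expect_error(run_psa(fx_params, n_iter = 1), "at least 2")

  d <- tidy(psa1)
  expect_equal(nrow(d), 400)
  s <- glance(psa1)
  expect_true(s$cri_low <= s$median_icer && s$median_icer <= s$cri_high)

  # net-monetary-benefit ordering agrees with the CEAC membership rule
  for (w in c(30, 100, 500)) {
    nmb_positive <- w * d$dalys_averted - d$delta_cost > 0
    member <- d$status == "cost_saving" | (d$status == "ratio" & d$icer < w)
    expect_equal(member, nmb_positive & d$dalys_averted > 0)
  }
})

test_that("a degenerate all-point parameter set collapses the PSA", {
  psa <- run_psa(fx_point_params, n_iter = 50, seed = 1)
  s <- glance(psa)
  expect_equal(s$cri_high - s$cri_low, 0)
  expect_equal(s$median_icer, cea_point(fx_point_params)$icer, tolerance = 1e-9)
})

test_that("the acceptability curve is monotone with correct limits", {
  psa <- run_psa(fx_params, n_iter = 500, seed = 3,
                 wtp_grid = c(0.01, 1, 50, 200, 1000, 2730, 5000, 1e7))
  cc <- psa$ceac
  expect_true(all(diff(cc$probability) >= 0))
  expect_equal(cc$probability[1], 0)          # below every draw's ratio
  expect_equal(cc$probability[nrow(cc)], 1)   # above every draw's ratio
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("PSA medians agree across independent seeds", {
  m <- vapply(1:2, function(s) glance(run_psa(fx_params, n_iter = 4000,
                                              seed = s))$median_icer, numeric(1))
  expect_lt(abs(m[1] - m[2]) / m[1], 0.05)
})

test_that("one-way sensitivity analysis ranks by swing and respects bounds", {
  tor <- one_way_sa(fx_params,
                    targets = c("p_htd", "above_service_cost", "cost_anc",
                                "eoc_facility.kshi", "discount_rate"))
  expect_s3_class(tor, "kwara_tornado")
  expect_true(all(diff(tor$swing) <= 0)) # sorted decreasing
  # a zero-width parameter produces zero swing
  expect_equal(tor$swing[tor$parameter == "eoc_facility.kshi"], 0)
  # beta bounds: mean +/- 1.96 sd
  row <- tor[tor$parameter == "p_htd", ]
  expect_equal(row$low, 0.085 - 1.96 * 0.04)
  expect_equal(row$high, 0.085 + 1.96 * 0.04)
  expect_error(one_way_sa(fx_params, targets = "no_such_param"), "unknown")
})

test_that("lowering the discount rate lowers the ICER", {
  tor <- one_way_sa(fx_params, targets = "discount_rate")
  expect_lt(tor$icer_low, tor$baseline[1])
  expect_gt(tor$icer_high, tor$baseline[1])
})

test_that("scenario analysis handles alternative base cases and self-comparison", {
  res <- scenario_analysis(fx_params)
  expect_equal(nrow(res), 3)
  expect_equal(res$comparator, c("SoC1", "SoC2", "SoC3"))
  expect_true(all(res$status %in% c("ratio", "cost_saving")))

  clone <- scenario_analysis(fx_params, alternatives = list(kshi_scenario()))
  expect_equal(clone$delta_cost, 0)
  expect_equal(clone$dalys_averted, 0)
  expect_equal(clone$status, "indifferent")
})

test_that("autoplot methods return ggplot objects", {
  psa <- run_psa(fx_params, n_iter = 100, seed = 2)
  expect_s3_class(autoplot(psa, type = "plane"), "ggplot")
  expect_s3_class(autoplot(psa, type = "ceac"), "ggplot")
  tor <- one_way_sa(fx_params, targets = c("p_htd", "cost_anc"))
  expect_s3_class(autoplot(tor), "ggplot")
})
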