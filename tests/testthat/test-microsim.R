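test_that("the record stream is reproducible and respects trivial limits", {
  r1 <- simulate_individuals(2000, fx_point, soc_scenario(), seed = 8)
  r2 <- simulate_individuals(2000, fx_point, soc_scenario(), seed = 8)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- simulate_individuals(2000, fx_point, soc_scenario(), seed = 9)
  expect_false(identical(r1$complication, r3$complication))

  # ANC visit counts: 3-5 for attendees, 0 otherwise
  expect_true(all(r1$n_anc_visits[r1$anc] %in% 3:5))
  expect_true(all(r1$n_anc_visits[!r1$anc] == 0))

  # a record with all complication risks at zero is uncomplicated and alive
  quiet <- fx_point
  for (nm in c("p_pph", "p_ol", "p_htd")) quiet[[nm]] <- 0
  sc <- soc_scenario(); sc$sepsis_home_rate <- 0
  r <- simulate_individuals(1, quiet, sc, seed = 1)
  expect_equal(r$complication, "none")
  expect_false(r$death)
  expect_equal(r$sequela, "none")
  expect_equal(r$daly_incurred, 0)
})

test_that("record invariants hold: sequelae match complications and survival", {
  rec <- simulate_individuals(50000, fx_point, kshi_scenario(), seed = 21)
  expect_true(all(rec$sequela == "none" | !rec$death))
  expect_true(all(rec$complication[rec$sequela == "anaemia"] == "pph"))
  expect_true(all(rec$complication[rec$sequela == "fistula"] == "ol"))
  expect_true(all(!rec$eoc[rec$sequela == "fistula"]))
  expect_true(all(rec$complication[rec$sequela == "infertility"] == "sepsis"))
  expect_true(all(rec$complication[rec$death] != "none"))
  expect_true(all(rec$cost_incurred >= 0) && all(rec$daly_incurred >= 0))
})

test_that("aggregation conserves records and rejects empty input", {
  expect_error(aggregate_records(tibble::tibble()), "non-empty")

  fixture <- tibble::tibble(
    id = 1:4, scenario = "SoC", anc = c(TRUE, TRUE, FALSE, FALSE),
    n_anc_visits = c(3L, 4L, 0L, 0L),
    delivery_location = c("facility", "facility", "home", "home"),
    eoc = c(TRUE, TRUE, FALSE, FALSE),
    complication = c("pph", "sepsis", "htd", "ol"),
    death = c(FALSE, FALSE, FALSE, TRUE),
    sequela = c("anaemia", "infertility", "none", "none"),
    cost_incurred = c(50, 50, 0, 0), daly_incurred = c(0.09, 0.1, 21.3, 23.4)
  )
  agg <- aggregate_records(fixture)
  expect_equal(sum(agg$n_women), 4)
  expect_equal(sum(agg$pph), 1)
  expect_equal(sum(agg$sepsis), 1)
  expect_equal(sum(agg$htd), 1)
  expect_equal(sum(agg$ol), 1)
  expect_equal(sum(agg$deaths), 1)
  expect_equal(sum(agg$cost_total), 100)

  rec <- simulate_individuals(5000, fx_point, soc_scenario(), seed = 4)
  agg2 <- aggregate_records(rec)
  expect_equal(sum(agg2$n_women), 5000)
  expect_equal(sum(agg2$pph + agg2$sepsis + agg2$htd + agg2$ol +
                     agg2$uncomplicated), 5000)
})

test_that("per-record accounting matches aggregate accounting exactly", {
  for (sc in list(soc_scenario(), kshi_scenario())) {
    rec <- simulate_individuals(20000, fx_point, sc, seed = 31)
    agg <- aggregate_records(rec)
    g <- function(nm) kwaracea:::pick_param(fx_point, nm, sc$variant)
    complicated <- agg$pph + agg$sepsis + agg$htd + agg$ol
    rebuilt <- sum(
      ifelse(agg$anc, agg$n_women * g("cost_anc"), 0) +
        ifelse(agg$eoc, complicated * g("cost_delivery_comp"),
               ifelse(agg$facility, complicated * g("cost_delivery_uncomp"), 0)) +
        ifelse(agg$facility, agg$uncomplicated * g("cost_delivery_uncomp"), 0) +
        agg$fistula * g("cost_fistula") +
        agg$anaemia * g("cost_anaemia") +
        if (sc$above_service) agg$n_women * g("above_service_cost") else 0
    )
    expect_equal(sum(rec$cost_incurred), rebuilt, tolerance = 1e-9)
  }
})

test_that("the microsimulation converges to the expectation engine", {
  sizes <- c(1e4, 2e5)
  rel_err <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    rec <- simulate_individuals(n, fx_point, soc_scenario(), seed = 42)
    exp_deaths <- cohort_totals(run_cohort(fx_point, soc_scenario(),
                                           cohort_size = n))$deaths
    rel_err[k] <- abs(sum(rec$death) - exp_deaths) / exp_deaths
    p <- exp_deaths / n
    expect_lt(abs(sum(rec$death) - exp_deaths), 3 * sqrt(n * p * (1 - p)))
  }
  # sampling error shrinks with n (law of large numbers at fixed seed)
  expect_lt(rel_err[2], rel_err[1])
})
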