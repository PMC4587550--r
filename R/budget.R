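#' Adjust a cost for inflation
#'
#' Compounds the Nigerian long-run average inflation rate (12.33% per annum,
#' 1996-2014) between two years. Used to bring historical unit costs onto
#' the US$ 2012 price base of the analysis.
#'
#' @param cost Cost in `from_year` prices.
#' @param from_year,to_year Calendar years (`to_year >= from_year` inflates;
#'   earlier deflates).
#' @param rate Annual inflation rate.
#'
#' @return The adjusted cost.
#'
#' @examples
#' inflate(100, 2010, 2012) # 100 * 1.1233^2
#'
#' @export
inflate <- function(cost, from_year, to_year, rate = 0.1233) {
  cost * (1 + rate)^(to_year - from_year)
}

#' Project the population in need of maternal care
#'
#' Compounds the base-year population of women needing antenatal and
#' obstetric care forward at the rate of natural increase. The packaged
#' default inputs are placeholders documented as synthetic: the actual Kwara
#' State demographic and health-accounts figures behind the published
#' projection are not available in the analysis inputs.
#'
#' @param base_population Women in need of maternal care in the base year.
#' @param base_year First calendar year of the projection.
#' @param years Number of years to project (default 5).
#' @param growth_rate Annual rate of natural increase.
#'
#' @return A tibble with columns `year` and `population`.
#' @export
population_projection <- function(base_population, base_year = 2013,
                                  years = 5, growth_rate = 0.027) {
  stopifnot(base_population > 0, years >= 1)
  yr <- base_year + seq_len(years) - 1
  tibble::tibble(
    year = yr,
    population = base_population * (1 + growth_rate)^(yr - base_year)
  )
}

#' Annual incremental cost of state-wide scale up
#'
#' For each projection year and coverage level, the gross program cost is the
#' population in need times the per-woman expected cost of insured maternal
#' care (ANC, delivery and complication care plus the above-service
#' mark-up, taken from the cohort engine at parameter point estimates) times
#' coverage. The incremental annual cost subtracts the current estimated
#' expenditure on maternal care; only resources above current spending are
#' counted, and cost-sharing revenue is excluded.
#'
#' @param projection A [population_projection()].
#' @param params A parameter set (point estimates are used).
#' @param scenario Scenario defining the scaled-up package (default insured
#'   arm).
#' @param coverage Coverage levels among the population in need.
#' @param current_expenditure Current annual expenditure on maternal care,
#'   US$ 2012.
#'
#' @return A tibble of class `budget_projection`: `year`, `coverage`,
#'   `population`, `per_woman_cost`, `gross_cost`, `incremental_cost`, and
#'   `relative_increase` (share of `current_expenditure`).
#'
#' @examples
#' proj <- population_projection(250000)
#' annual_scaleup_cost(proj, default_parameters(),
#'                     current_expenditure = 3e6)
#'
#' @export
annual_scaleup_cost <- function(projection, params = default_parameters(),
                                scenario = kshi_scenario(),
                                coverage = c(0.6, 0.8, 1.0),
                                current_expenditure) {
  stopifnot(all(coverage >= 0), all(coverage <= 1), current_expenditure >= 0)
  ev <- evaluate_scenario(params, scenario)
  per_woman <- ev$cost_total / ev$n_women
  out <- tidyr::expand_grid(projection, coverage = coverage) |>
    dplyr::mutate(
      per_woman_cost = per_woman,
      gross_cost = .data$population * per_woman * .data$coverage,
      incremental_cost = .data$gross_cost - current_expenditure,
      relative_increase = .data$incremental_cost / current_expenditure
    ) |>
    dplyr::arrange(.data$year, .data$coverage)
  structure(out, class = c("budget_projection", class(tibble::as_tibble(out))))
}

#' @rdname annual_scaleup_cost
#' @param object A `budget_projection`.
#' @param ... Unused.
#' @export
autoplot.budget_projection <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$year, y = .data$incremental_cost,
                 colour = factor(.data$coverage))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Incremental annual cost (US$ 2012)",
                  colour = "Coverage",
                  title = "Budget impact of state-wide scale up") +
    ggplot2::theme_minimal()
}
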