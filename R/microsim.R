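#' Individual-level microsimulation of the care pathway
#'
#' Simulates one record per pregnancy through the same pathway as the
#' expectation engine by sequential Bernoulli/categorical sampling: ANC
#' attendance, number of ANC visits (uniform on 3-5 among attendees),
#' delivery location, EOC access, a single mutually-exclusive complication,
#' survival, and at most one complication-specific sequela. Per-record
#' provider costs and DALYs follow exactly the accounting rules of
#' [compute_cost()] and [compute_health()], so aggregated records converge
#' to the expectation engine's output as `n` grows. Decisions consume the
#' random stream in a fixed documented order (ANC, visits, location, EOC,
#' complication, death, sequela), so a given seed reproduces the record
#' stream exactly.
#'
#' @param n Number of pregnancies to simulate.
#' @param draws A one-row draw tibble (e.g. [point_estimates()]).
#' @param scenario A [scenario_config()].
#' @param seed Integer seed.
#' @param ext_htd_daly,baseline_years Accounting constants, see
#'   [compute_health()].
#'
#' @return A tibble with one row per pregnancy: `id`, `scenario`, `anc`,
#'   `n_anc_visits`, `delivery_location`, `eoc`, `complication`, `death`,
#'   `sequela`, `cost_incurred`, `daly_incurred`.
#'
#' @examples
#' sim <- simulate_individuals(500, point_estimates(default_parameters()),
#'                             soc_scenario(), seed = 1)
#' dplyr::count(sim, complication)
#'
#' @export
simulate_individuals <- function(n, draws, scenario, seed,
                                 ext_htd_daly = pathway_defaults()$ext_htd_daly,
                                 baseline_years = pathway_defaults()$baseline_years) {
  stopifnot(n >= 1)
  draws <- as_draw(draws)
  if (nrow(draws) != 1L) {
    stop("`draws` must be a single parameter draw (one row)", call. = FALSE)
  }
  g <- function(nm) pick_param(draws, nm, scenario$variant)
  set.seed(as.integer(seed))

  # 1. ANC attendance
  anc <- stats::runif(n) < clamp01(g("anc_access"), "anc_access")
  # 2. number of ANC visits (3-5 among attendees)
  n_visits <- ifelse(anc, sample(3:5, n, replace = TRUE), 0L)
  # 3. delivery location
  fac_anc <- if (is.null(scenario$home_share_anc)) {
    g("facility_if_anc") / (g("facility_if_anc") + g("home_if_anc"))
  } else {
    1 - scenario$home_share_anc
  }
  p_fac <- ifelse(anc, fac_anc, scenario$facility_share_no_anc)
  facility <- stats::runif(n) < p_fac
  # 4. EOC access
  eoc_fac <- scenario$eoc_facility_override %||% g("eoc_facility")
  p_eoc <- ifelse(facility, eoc_fac, g("eoc_home"))
  eoc <- stats::runif(n) < p_eoc
  # 5. complication (mutually exclusive)
  rr_proph <- 1 - scenario$prophylaxis_coverage * (1 - g("rr_htd_anc"))
  p_pph <- rep(clamp01(g("p_pph"), "p_pph"), n)
  p_htd <- clamp01(g("p_htd") * ifelse(anc, rr_proph, 1), "p_htd")
  sep_home <- scenario$sepsis_home_rate * g("p_sepsis") / 0.017
  p_sep <- clamp01(ifelse(facility, sep_home * g("rr_sepsis_facility"),
                          sep_home), "sepsis")
  p_ol <- rep(clamp01(g("p_ol"), "p_ol"), n)
  u <- stats::runif(n)
  complication <- dplyr::case_when(
    u < p_pph ~ "pph",
    u < p_pph + p_sep ~ "sepsis",
    u < p_pph + p_sep + p_htd ~ "htd",
    u < p_pph + p_sep + p_htd + p_ol ~ "ol",
    .default = "none"
  )
  # 6. survival
  p_death <- dplyr::case_when(
    complication == "pph" ~ clamp01(g("p_death_pph") *
                                      ifelse(eoc, g("rr_pph_death_eoc"), 1), "pph death"),
    complication == "sepsis" ~ clamp01(g("p_death_sepsis"), "sepsis death"),
    complication == "htd" ~ clamp01(g("p_death_htd"), "htd death"),
    complication == "ol" ~ ifelse(eoc, 0, clamp01(g("p_death_ol"), "ol death")),
    .default = 0
  )
  death <- stats::runif(n) < p_death
  # 7. sequela among survivors
  p_seq <- dplyr::case_when(
    death ~ 0,
    complication == "pph" ~ clamp01(g("p_anaemia_pph") *
                                      ifelse(eoc, g("rr_anaemia_eoc"), 1), "anaemia"),
    complication == "sepsis" ~ clamp01(g("p_infertility_sepsis"), "infertility"),
    complication == "ol" & !eoc ~ clamp01(g("p_fistula_ol"), "fistula"),
    .default = 0
  )
  has_seq <- stats::runif(n) < p_seq
  sequela <- dplyr::case_when(
    !has_seq ~ "none",
    complication == "pph" ~ "anaemia",
    complication == "sepsis" ~ "infertility",
    complication == "ol" ~ "fistula",
    .default = "none"
  )

  mult <- scenario$cost_multiplier
  delivery_cost <- dplyr::case_when(
    complication != "none" & eoc ~ g("cost_delivery_comp") * mult,
    facility ~ g("cost_delivery_uncomp") * mult,
    .default = 0
  )
  cost <- ifelse(anc, g("cost_anc") * mult, 0) + delivery_cost +
    ifelse(sequela == "fistula", g("cost_fistula"), 0) +
    ifelse(sequela == "anaemia", g("cost_anaemia"), 0) +
    ifelse(scenario$above_service, g("above_service_cost"), 0)
  daly <- ifelse(death, g("daly_death"), 0) +
    ifelse(sequela == "anaemia", g("daly_anaemia"), 0) +
    ifelse(sequela == "infertility", g("daly_infertility"), 0) +
    ifelse(sequela == "fistula", g("daly_fistula"), 0) +
    ifelse(complication == "htd" & !death, ext_htd_daly, 0)

  tibble::tibble(
    id = seq_len(n),
    scenario = scenario$name,
    anc = anc,
    n_anc_visits = as.integer(n_visits),
    delivery_location = ifelse(facility, "facility", "home"),
    eoc = eoc,
    complication = complication,
    death = death,
    sequela = sequela,
    cost_incurred = cost,
    daly_incurred = daly
  )
}

#' Aggregate pregnancy records to a cohort table
#'
#' Collapses individual records into the same (ANC, location, EOC) cell
#' layout as [run_cohort()], with complication, death and sequela counts and
#' summed per-record costs and DALYs. Used to validate the expectation
#' engine against the microsimulation and to summarise synthetic claims
#' datasets.
#'
#' @param records Output of [simulate_individuals()] (or a claims-like
#'   tibble with the same columns).
#'
#' @return A tibble with one row per (scenario, anc, facility, eoc) cell:
#'   `n_women`, `pph`, `sepsis`, `htd`, `ol`, `uncomplicated`, `deaths`,
#'   `anaemia`, `fistula`, `infertility`, `cost_total`, `daly_total`.
#' @export
aggregate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty tibble of pregnancy records",
         call. = FALSE)
  }
  records |>
    dplyr::mutate(facility = .data$delivery_location == "facility") |>
    dplyr::group_by(.data$scenario, .data$anc, .data$facility, .data$eoc) |>
    dplyr::summarise(
      n_women = dplyr::n(),
      pph = sum(.data$complication == "pph"),
      sepsis = sum(.data$complication == "sepsis"),
      htd = sum(.data$complication == "htd"),
      ol = sum(.data$complication == "ol"),
      uncomplicated = sum(.data$complication == "none"),
      deaths = sum(.data$death),
      anaemia = sum(.data$sequela == "anaemia"),
      fistula = sum(.data$sequela == "fistula"),
      infertility = sum(.data$sequela == "infertility"),
      cost_total = sum(.data$cost_incurred),
      daly_total = sum(.data$daly_incurred),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$anc), dplyr::desc(.data$facility),
                   dplyr::desc(.data$eoc))
}
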