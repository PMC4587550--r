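# Resolve one parameter column from a draw tibble: scenario-specific rows are
# stored as `name.variant`, shared rows as `name`.
pick_param <- function(draws, name, variant) {
  key <- paste(name, variant, sep = ".")
  if (key %in% names(draws)) {
    draws[[key]]
  } else if (name %in% names(draws)) {
    draws[[name]]
  } else {
    stop("draw is missing parameter '", name, "'", call. = FALSE)
  }
}

clamp01 <- function(x, what) {
  out_of_range <- x < 0 | x > 1
  if (any(out_of_range)) {
    warning(
      sum(out_of_range), " value(s) of ", what,
      " outside [0, 1] were clamped", call. = FALSE
    )
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

# Coerce a parameter set or a draw tibble to the draw layout. A parameter set
# is evaluated at its point estimates, so downstream results are seed-free.
as_draw <- function(x) {
  if (inherits(x, "kwara_params") ||
      (is.data.frame(x) && all(c("name", "family", "scenario") %in% names(x)))) {
    point_estimates(x)
  } else if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    stop("expected a parameter set or a draw tibble", call. = FALSE)
  }
}

#' Stratify the cohort by care pathway
#'
#' Splits the cohort across the eight antenatal-care (ANC) by delivery
#' location by emergency-obstetric-care (EOC) cells of the decision tree.
#' ANC attendees deliver in a facility or at home according to the
#' (renormalised) facility/home split; women without prior ANC deliver in a
#' facility with the scenario's structural share; EOC access then depends on
#' the delivery location. Expected counts are conserved exactly.
#'
#' @param cohort_size Number of pregnant women; `NULL` uses the `cohort_size`
#'   parameter of the draw.
#' @param draws A draw tibble ([point_estimates()] or rows of
#'   [sample_draws()]).
#' @param scenario A [scenario_config()].
#'
#' @return A tibble with columns `draw`, `anc`, `facility`, `eoc`,
#'   `n_women`; eight rows per draw.
#'
#' @examples
#' stratify(10000, point_estimates(default_parameters()), soc_scenario())
#'
#' @export
stratify <- function(cohort_size = NULL, draws, scenario) {
  draws <- as_draw(draws)
  n <- nrow(draws)
  N <- if (is.null(cohort_size)) pick_param(draws, "cohort_size", scenario$variant) else cohort_size
  if (any(N < 0)) stop("cohort size must be non-negative", call. = FALSE)

  p_anc <- clamp01(pick_param(draws, "anc_access", scenario$variant), "anc_access")
  if (is.null(scenario$home_share_anc)) {
    f_anc <- pick_param(draws, "facility_if_anc", scenario$variant)
    h_anc <- pick_param(draws, "home_if_anc", scenario$variant)
    fac_anc <- f_anc / (f_anc + h_anc)
  } else {
    fac_anc <- rep(1 - scenario$home_share_anc, n)
  }
  fac_no <- rep(scenario$facility_share_no_anc, n)
  eoc_fac <- if (is.null(scenario$eoc_facility_override)) {
    clamp01(pick_param(draws, "eoc_facility", scenario$variant), "eoc_facility")
  } else {
    rep(scenario$eoc_facility_override, n)
  }
  eoc_home <- clamp01(pick_param(draws, "eoc_home", scenario$variant), "eoc_home")

  grid <- tidyr::expand_grid(anc = c(TRUE, FALSE), facility = c(TRUE, FALSE),
                             eoc = c(TRUE, FALSE))
  purrr::pmap(grid, function(anc, facility, eoc) {
    w_anc <- if (anc) N * p_anc else N * (1 - p_anc)
    p_fac <- if (anc) fac_anc else fac_no
    w_loc <- if (facility) w_anc * p_fac else w_anc * (1 - p_fac)
    p_eoc <- if (facility) eoc_fac else eoc_home
    w <- if (eoc) w_loc * p_eoc else w_loc * (1 - p_eoc)
    tibble::tibble(draw = seq_len(n), anc = anc, facility = facility,
                   eoc = eoc, n_women = w)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$draw, dplyr::desc(.data$anc),
                   dplyr::desc(.data$facility), dplyr::desc(.data$eoc))
}

#' Expected complication counts per pathway cell
#'
#' Applies the complication incidence model to stratified counts: post-partum
#' haemorrhage and obstructed labour are independent of prior care; sepsis
#' incidence equals the structural home-delivery rate (scaled by the sampled
#' cohort-level sepsis probability relative to its published mean) reduced by
#' the facility relative risk for facility deliveries; hypertensive-disorder
#' incidence is reduced by the prophylaxis relative risk for the covered
#' fraction of ANC attendees. The four complications are mutually exclusive;
#' the remainder of each cell is uncomplicated.
#'
#' @param strata Output of [stratify()].
#' @inheritParams stratify
#'
#' @return `strata` with added columns `pph`, `sepsis`, `htd`, `ol`,
#'   `uncomplicated`.
#' @export
complication_incidence <- function(strata, draws, scenario) {
  draws <- as_draw(draws)
  idx <- strata$draw
  g <- function(nm) pick_param(draws, nm, scenario$variant)[idx]

  p_pph <- clamp01(g("p_pph"), "p_pph")
  p_ol <- clamp01(g("p_ol"), "p_ol")
  rr_htd <- g("rr_htd_anc")
  proph <- ifelse(strata$anc, scenario$prophylaxis_coverage, 0)
  p_htd <- clamp01(g("p_htd") * (1 - proph * (1 - rr_htd)), "p_htd x prophylaxis")
  sep_home <- scenario$sepsis_home_rate * g("p_sepsis") / 0.017
  p_sep <- clamp01(ifelse(strata$facility, sep_home * g("rr_sepsis_facility"),
                          sep_home), "sepsis x facility rr")

  total <- p_pph + p_ol + p_htd + p_sep
  over <- total > 1
  if (any(over)) {
    warning(sum(over), " cell(s) had complication probabilities summing above",
            " 1 and were renormalised", call. = FALSE)
    scl <- ifelse(over, 1 / total, 1)
    p_pph <- p_pph * scl; p_ol <- p_ol * scl
    p_htd <- p_htd * scl; p_sep <- p_sep * scl
    total <- pmin(total, 1)
  }

  strata |>
    dplyr::mutate(
      pph = .data$n_women * p_pph,
      sepsis = .data$n_women * p_sep,
      htd = .data$n_women * p_htd,
      ol = .data$n_women * p_ol,
      uncomplicated = .data$n_women * (1 - total)
    )
}

#' Resolve deaths and sequelae per pathway cell
#'
#' Deaths are the sum over complications of expected cases times the
#' complication's case-fatality probability, with EOC effect modifiers where
#' defined: the haemorrhage death probability is multiplied by its relative
#' risk under EOC, and obstructed-labour death applies only without EOC
#' (case fatality is defined for the no-EOC pathway only). Sequelae accrue
#' among survivors: anaemia after haemorrhage (halved under EOC), fistula
#' after obstructed labour without EOC, secondary infertility after sepsis.
#'
#' @param comp Output of [complication_incidence()].
#' @param draws A draw tibble.
#' @param scenario A [scenario_config()] (used only to resolve parameter
#'   variants).
#'
#' @return `comp` with added columns `deaths`, `anaemia`, `fistula`,
#'   `infertility`.
#' @export
outcome_resolution <- function(comp, draws, scenario = soc_scenario()) {
  draws <- as_draw(draws)
  idx <- comp$draw
  g <- function(nm) pick_param(draws, nm, scenario$variant)[idx]

  d_pph <- clamp01(g("p_death_pph") *
                     ifelse(comp$eoc, g("rr_pph_death_eoc"), 1),
                   "pph death x eoc rr")
  d_sep <- clamp01(g("p_death_sepsis"), "p_death_sepsis")
  d_htd <- clamp01(g("p_death_htd"), "p_death_htd")
  d_ol <- ifelse(comp$eoc, 0, clamp01(g("p_death_ol"), "p_death_ol"))
  p_ana <- clamp01(g("p_anaemia_pph") * ifelse(comp$eoc, g("rr_anaemia_eoc"), 1),
                   "anaemia x eoc rr")

  comp |>
    dplyr::mutate(
      deaths = .data$pph * d_pph + .data$sepsis * d_sep +
        .data$htd * d_htd + .data$ol * d_ol,
      anaemia = .data$pph * (1 - d_pph) * p_ana,
      fistula = ifelse(.data$eoc, 0,
                       .data$ol * (1 - d_ol) * clamp01(g("p_fistula_ol"), "p_fistula_ol")),
      infertility = .data$sepsis * (1 - d_sep) *
        clamp01(g("p_infertility_sepsis"), "p_infertility_sepsis")
    )
}

#' Run the expectation-based cohort engine
#'
#' Propagates the cohort through ANC access, delivery location, EOC access,
#' complication incidence and outcome resolution, returning expected counts
#' per pathway cell. With a parameter set as input the engine runs at the
#' parameters' point estimates (deterministic); with rows of
#' [sample_draws()] it evaluates every draw (the `draw` column indexes
#' iterations).
#'
#' @param params_or_draws A parameter set ([default_parameters()]) or a draw
#'   tibble.
#' @param scenario A [scenario_config()]; default standard of care.
#' @param cohort_size Cohort size override; `NULL` uses the parameter.
#'
#' @return A tibble of class `cohort_table` with one row per (draw, ANC,
#'   location, EOC) cell and columns `n_women`, `pph`, `sepsis`, `htd`, `ol`,
#'   `uncomplicated`, `deaths`, `anaemia`, `fistula`, `infertility`.
#'
#' @examples
#' cohort <- run_cohort(default_parameters(), soc_scenario())
#' cohort_totals(cohort)
#'
#' @export
run_cohort <- function(params_or_draws, scenario = soc_scenario(),
                       cohort_size = NULL) {
  draws <- as_draw(params_or_draws)
  out <- stratify(cohort_size, draws, scenario) |>
    complication_incidence(draws, scenario) |>
    outcome_resolution(draws, scenario) |>
    dplyr::mutate(scenario = scenario$name, .before = 1)
  structure(out,
            class = c("cohort_table", class(tibble::as_tibble(out))),
            scenario = scenario, draws = draws)
}

#' Scenario-level totals of a cohort table
#'
#' Aggregates pathway cells to one row per draw: total women, complication
#' counts, deaths and sequelae. On the default point-estimate engine this is
#' the published cohort-distribution summary.
#'
#' @param cohort A `cohort_table` from [run_cohort()].
#' @param by Optional extra grouping columns (e.g. `c("anc", "eoc")` for the
#'   published sub-stratum layout).
#'
#' @return A tibble with one row per draw (times `by` groups).
#' @export
cohort_totals <- function(cohort, by = NULL) {
  cohort |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("scenario", "draw", by)))) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("n_women", "pph", "sepsis", "htd", "ol",
                      "uncomplicated", "deaths", "anaemia", "fistula",
                      "infertility")), sum), .groups = "drop")
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("<cohort_table> scenario: ", if (!is.null(sc)) sc$name else "?",
      ", ", length(unique(x$draw)), " draw(s)\n", sep = "")
  NextMethod()
}
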