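#' @importFrom rlang .data
NULL

# Canonical registry of model parameters. `scenario` distinguishes rows whose
# value differs between the standard of care ("soc") and the insurance
# program ("kshi"); "shared" rows are common to both arms. The draw column
# name is `name` for shared rows and `name.scenario` otherwise.
parameter_registry <- function() {
  tibble::tribble(
    ~name,                  ~group,        ~scenario, ~family,      ~mean,  ~sd,   ~min,   ~max,
    "anc_access",           "utilization", "soc",     "uniform",    NA,     NA,    0.6,    0.7,
    "anc_access",           "utilization", "kshi",    "uniform",    NA,     NA,    0.8,    0.9,
    "facility_all",         "utilization", "soc",     "uniform",    NA,     NA,    0.4,    0.6,
    "facility_all",         "utilization", "kshi",    "uniform",    NA,     NA,    0.65,   0.7,
    "eoc_facility",         "utilization", "soc",     "uniform",    NA,     NA,    0.9,    0.95,
    "eoc_facility",         "utilization", "kshi",    "point",      1,      NA,    NA,     NA,
    "facility_if_anc",      "utilization", "shared",  "beta",       0.96,   0.03,  NA,     NA,
    "home_if_anc",          "utilization", "shared",  "beta",       0.05,   0.03,  NA,     NA,
    "eoc_home",             "utilization", "shared",  "beta",       0.136,  0.02,  NA,     NA,
    "p_pph",                "outcome",     "shared",  "beta",       0.051,  0.04,  NA,     NA,
    "p_anaemia_pph",        "outcome",     "shared",  "beta",       0.12,   0.01,  NA,     NA,
    "p_death_pph",          "outcome",     "shared",  "uniform",    NA,     NA,    0.028,  0.273,
    "rr_pph_death_eoc",     "outcome",     "shared",  "beta",       0.34,   0.19,  NA,     NA,
    "rr_anaemia_eoc",       "outcome",     "shared",  "beta",       0.5,    0.14,  NA,     NA,
    "p_sepsis",             "outcome",     "shared",  "triangular", 0.017,  NA,    0.01,   0.03,
    "p_infertility_sepsis", "outcome",     "shared",  "uniform",    NA,     NA,    0.05,   0.1,
    "p_death_sepsis",       "outcome",     "shared",  "uniform",    NA,     NA,    0,      0.727,
    "rr_sepsis_facility",   "outcome",     "shared",  "triangular", 0.54,   NA,    0.4,    0.65,
    "p_ol",                 "outcome",     "shared",  "beta",       0.06,   0.02,  NA,     NA,
    "p_fistula_ol",         "outcome",     "shared",  "beta",       0.14,   0.01,  NA,     NA,
    "p_death_ol",           "outcome",     "shared",  "beta",       0.007,  0.01,  NA,     NA,
    "p_htd",                "outcome",     "shared",  "beta",       0.085,  0.04,  NA,     NA,
    "p_death_htd",          "outcome",     "shared",  "beta",       0.083,  0.02,  NA,     NA,
    "rr_htd_anc",           "outcome",     "shared",  "beta",       0.41,   0.08,  NA,     NA,
    "cost_anc",             "cost",        "shared",  "uniform",    NA,     NA,    12.4,   61.5,
    "cost_delivery_uncomp", "cost",        "shared",  "uniform",    NA,     NA,    9.65,   27.2,
    "cost_delivery_comp",   "cost",        "shared",  "uniform",    NA,     NA,    46.7,   53.3,
    "cost_fistula",         "cost",        "shared",  "uniform",    NA,     NA,    190.9,  382.7,
    "cost_anaemia",         "cost",        "shared",  "uniform",    NA,     NA,    9.81,   13.79,
    "daly_death",           "daly",        "shared",  "triangular", 23.43,  NA,    21.09,  25.77,
    "daly_anaemia",         "daly",        "shared",  "triangular", 0.09,   NA,    0.08,   0.09,
    "daly_infertility",     "daly",        "shared",  "triangular", 0.1,    NA,    0.09,   0.11,
    "daly_fistula",         "daly",        "shared",  "triangular", 10.93,  NA,    9.84,   12.02,
    "discount_rate",        "other",       "shared",  "point",      0.03,   NA,    NA,     NA,
    "above_service_cost",   "other",       "shared",  "point",      24.1,   NA,    NA,     NA,
    "cohort_size",          "other",       "shared",  "point",      10000,  NA,    NA,     NA
  )
}

#' Default model parameters
#'
#' Returns the full parameter set of the maternal-care cost-effectiveness
#' model as a tibble with one row per parameter/scenario combination:
#' utilization probabilities (antenatal care access, delivery location,
#' emergency obstetric care access), complication and case-fatality
#' probabilities with their relative-risk effect modifiers, provider unit
#' costs (US$ 2012), per-event DALY weights, the annual discount rate, the
#' above-service (insurer administration) cost per enrolee, and the cohort
#' size.
#'
#' Each row carries a sampling distribution: `point` (no uncertainty),
#' `uniform` by `min`/`max`, `beta` by `mean`/`sd` (method of moments), or
#' `triangular` by `mean`/`min`/`max` (mode derived so the declared mean is
#' preserved).
#'
#' @return A tibble of class `kwara_params` with columns `name`, `group`,
#'   `scenario` (`"shared"`, `"soc"` or `"kshi"`), `family`, `mean`, `sd`,
#'   `min`, `max`.
#'
#' @examples
#' default_parameters()
#'
#' @export
default_parameters <- function() {
  validate_parameters(parameter_registry())
}

new_kwara_params <- function(x) {
  structure(x, class = c("kwara_params", class(tibble::as_tibble(x))))
}

#' Validate a parameter set
#'
#' Checks that every canonical parameter appears exactly once per applicable
#' scenario, that no unknown names are present, that all probability
#' parameters lie in \[0, 1\], costs and DALY weights are non-negative, and
#' that every row's distribution is feasible (see [validate_dist()]).
#'
#' @param params A tibble shaped like [default_parameters()].
#'
#' @return The validated parameter set (invisibly classed `kwara_params`).
#' @export
validate_parameters <- function(params) {
  params <- tibble::as_tibble(params)
  required <- c("name", "scenario", "family", "mean", "sd", "min", "max")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reg <- parameter_registry()
  key <- function(x) paste(x$name, x$scenario, sep = ".")
  unknown <- setdiff(params$name, reg$name)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(key(reg), key(params))
  if (length(absent) > 0) {
    stop("missing mandatory parameter(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(key(params))) {
    stop("duplicated parameter entries: ",
         paste(unique(key(params)[duplicated(key(params))]), collapse = ", "),
         call. = FALSE)
  }
  if (!"group" %in% names(params)) {
    params$group <- reg$group[match(params$name, reg$name)]
  }
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    ok <- tryCatch(
      {
        validate_dist(row$family, row$mean, row$sd, row$min, row$max)
        TRUE
      },
      error = function(e) e
    )
    if (!isTRUE(ok)) {
      stop("invalid distribution for '", key(row), "': ",
           conditionMessage(ok), call. = FALSE)
    }
    pt <- dist_mean(row$family, row$mean, row$sd, row$min, row$max)
    is_prob <- row$group %in% c("utilization", "outcome")
    if (is_prob && (pt < 0 || pt > 1)) {
      stop("parameter '", key(row), "' is a probability but its point ",
           "estimate ", pt, " lies outside [0, 1]", call. = FALSE)
    }
    if (row$group %in% c("cost", "daly") && pt < 0) {
      stop("parameter '", key(row), "' must be non-negative", call. = FALSE)
    }
  }
  invisible(new_kwara_params(params))
}

# Column name used for a parameter row in draw tibbles.
draw_name <- function(name, scenario) {
  ifelse(scenario == "shared", name, paste(name, scenario, sep = "."))
}

#' Point estimates of a parameter set
#'
#' Evaluates every parameter at the analytic mean of its distribution,
#' returning a one-row draw tibble in the layout consumed by the cohort
#' engine (shared parameters by name, scenario-specific ones suffixed, e.g.
#' `anc_access.soc`). Point evaluation involves no randomness and is
#' invariant to any seed.
#'
#' @param params A parameter set, see [default_parameters()].
#'
#' @return A one-row tibble with one column per parameter.
#'
#' @examples
#' point_estimates(default_parameters())$p_pph # 0.051
#'
#' @export
point_estimates <- function(params) {
  params <- validate_parameters(params)
  vals <- purrr::pmap_dbl(
    params[, c("family", "mean", "sd", "min", "max")],
    function(family, mean, sd, min, max) dist_mean(family, mean, sd, min, max)
  )
  out <- tibble::as_tibble(as.list(stats::setNames(vals, draw_name(params$name, params$scenario))))
  out
}

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Draws `n` independent samples of every parameter from its declared
#' distribution. The same draw tibble feeds both scenario arms (common
#' random numbers): shared parameters are sampled once per iteration.
#' Identical seeds give identical draws.
#'
#' @param params A parameter set, see [default_parameters()].
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed for the random stream.
#'
#' @return A tibble with `n` rows and one column per parameter, in the same
#'   layout as [point_estimates()].
#'
#' @examples
#' draws <- sample_draws(default_parameters(), 100, seed = 1)
#'
#' @export
sample_draws <- function(params, n, seed) {
  params <- validate_parameters(params)
  stopifnot(is.numeric(n), n >= 1)
  set.seed(as.integer(seed))
  cols <- purrr::pmap(
    params[, c("family", "mean", "sd", "min", "max")],
    function(family, mean, sd, min, max) dist_sample(n, family, mean, sd, min, max)
  )
  names(cols) <- draw_name(params$name, params$scenario)
  out <- tibble::as_tibble(cols)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Read and write parameter sets as flat CSV
#'
#' The flat form has columns `name, group, scenario, family, mean, sd, min,
#' max` and round-trips losslessly with the in-memory tibble.
#'
#' @param params A parameter set.
#' @param path File path.
#'
#' @return `write_parameters()` returns `params` invisibly;
#'   `read_parameters()` returns a validated parameter set.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  readr::write_csv(params, path)
  invisible(params)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  validate_parameters(readr::read_csv(path, show_col_types = FALSE))
}

#' Load parameters from a nested YAML configuration
#'
#' The configuration dialect mirrors the published input table: a top-level
#' `parameters` map keyed by parameter name, each holding one map per
#' scenario applicability (`shared`, `soc`, `kshi`) with keys `family` and
#' the family's parameters (`mean`, `sd`, `min`, `max`). The packaged default
#' holding all published values is at
#' `system.file("extdata", "params_table1.yaml", package = "kwaracea")`.
#'
#' @param path Path to a YAML file; defaults to the packaged configuration.
#'
#' @return A validated parameter set tibble.
#'
#' @examples
#' load_parameters()
#'
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "params_table1.yaml", package = "kwaracea")
  }
  if (!file.exists(path)) {
    stop("parameter config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters)) {
    stop("config has no top-level `parameters` map: ", path, call. = FALSE)
  }
  reg <- parameter_registry()
  rows <- purrr::imap(cfg$parameters, function(scenarios, nm) {
    purrr::imap(scenarios, function(spec, sc) {
      tibble::tibble(
        name = nm,
        group = if (!is.null(spec$group)) spec$group else
          reg$group[match(nm, reg$name)],
        scenario = sc,
        family = spec$family %||% "point",
        mean = as.numeric(spec$mean %||% NA),
        sd = as.numeric(spec$sd %||% NA),
        min = as.numeric(spec$min %||% NA),
        max = as.numeric(spec$max %||% NA)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  validate_parameters(rows)
}

#' Write a parameter set to the nested YAML configuration dialect
#'
#' @inheritParams write_parameters
#' @return `params`, invisibly.
#' @export
write_parameters_yaml <- function(params, path) {
  params <- validate_parameters(params)
  nested <- split(params, params$name) |>
    purrr::map(function(rows) {
      out <- purrr::map(seq_len(nrow(rows)), function(i) {
        row <- rows[i, ]
        spec <- list(family = row$family)
        for (f in c("mean", "sd", "min", "max")) {
          if (!is.na(row[[f]])) spec[[f]] <- row[[f]]
        }
        spec
      })
      stats::setNames(out, rows$scenario)
    })
  # keep registry ordering for readability
  nested <- nested[intersect(unique(parameter_registry()$name), names(nested))]
  yaml::write_yaml(list(parameters = nested), path)
  invisible(params)
}
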