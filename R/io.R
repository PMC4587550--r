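#' Write analysis results to disk
#'
#' Serialises a result object to an output directory: tabular results as
#' CSV, summaries as JSON, with a run manifest (`manifest.json`: package
#' version, seed, configuration hash, timestamp) written alongside so every
#' output file is traceable to one run. Monetary values are written at two
#' decimals and expected counts at one, matching the reporting precision of
#' the analysis.
#'
#' @param results A result object: `cohort_table`, `cea_result`,
#'   `kwara_psa`, `kwara_tornado`, `budget_projection`, or a plain data
#'   frame.
#' @param out_dir Output directory (created if missing).
#' @param stem File-name stem; defaults to the result class.
#' @param seed Seed recorded in the manifest.
#' @param config Object (e.g. parameter set) whose hash is recorded.
#'
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(results, out_dir, stem = NULL, seed = NULL,
                          config = NULL) {
  UseMethod("write_results")
}

round_cols <- function(df, digits, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

count_cols <- c("n_women", "pph", "sepsis", "htd", "ol", "uncomplicated",
                "deaths", "anaemia", "fistula", "infertility")
money_cols <- c("cost_anc", "cost_uncomplicated", "cost_complicated",
                "cost_fistula", "cost_anaemia", "cost_above_service",
                "cost_total", "delta_cost", "gross_cost", "incremental_cost",
                "per_woman_cost", "cost_incurred")

prepare_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  out_dir
}

write_manifest <- function(out_dir, files, seed = NULL, config = NULL) {
  manifest <- list(
    package = "kwaracea",
    version = as.character(utils::packageVersion("kwaracea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL,
    files = basename(files)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

finish_write <- function(out_dir, files, seed, config) {
  manifest <- write_manifest(out_dir, files, seed, config)
  invisible(c(files, manifest))
}

#' @export
write_results.cohort_table <- function(results, out_dir, stem = "cohort",
                                       seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  readr::write_csv(round_cols(tibble::as_tibble(results), 1, count_cols), csv)
  totals <- cohort_totals(results)
  json <- file.path(out_dir, paste0(stem, "_totals.json"))
  jsonlite::write_json(round_cols(totals, 1, count_cols), json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  finish_write(out_dir, c(csv, json), seed, config)
}

#' @export
write_results.cea_result <- function(results, out_dir, stem = "cea",
                                     seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  json <- file.path(out_dir, paste0(stem, ".json"))
  out <- round_cols(tibble::as_tibble(results), 2,
                    c(money_cols, "dalys_averted", "icer"))
  jsonlite::write_json(out, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  finish_write(out_dir, json, seed, config)
}

#' @export
write_results.kwara_psa <- function(results, out_dir, stem = "psa",
                                    seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  draws_csv <- file.path(out_dir, paste0(stem, "_draws.csv"))
  readr::write_csv(round_cols(tibble::as_tibble(results$draws), 4,
                              c(money_cols, "dalys_averted", "icer")),
                   draws_csv)
  ceac_csv <- file.path(out_dir, paste0(stem, "_ceac.csv"))
  readr::write_csv(results$ceac, ceac_csv)
  json <- file.path(out_dir, paste0(stem, "_summary.json"))
  jsonlite::write_json(results$summary, json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  finish_write(out_dir, c(draws_csv, ceac_csv, json),
               seed %||% results$seed, config)
}

#' @export
write_results.kwara_tornado <- function(results, out_dir, stem = "tornado",
                                        seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  readr::write_csv(tibble::as_tibble(results), csv)
  finish_write(out_dir, csv, seed, config)
}

#' @export
write_results.budget_projection <- function(results, out_dir, stem = "budget",
                                            seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  readr::write_csv(round_cols(tibble::as_tibble(results), 2, money_cols), csv)
  finish_write(out_dir, csv, seed, config)
}

#' @export
write_results.data.frame <- function(results, out_dir, stem = "results",
                                     seed = NULL, config = NULL) {
  prepare_out_dir(out_dir)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  readr::write_csv(tibble::as_tibble(results), csv)
  finish_write(out_dir, csv, seed, config)
}

#' Command-line entry point
#'
#' A thin argument-parsing layer over the package functions, used by the
#' `inst/cli/kwaracea` script. Subcommands: `run` (point-estimate CEA),
#' `psa`, `ceac`, `tornado`, `scenarios`, `bia`, `microsim`. Common flags:
#' `--config` (YAML parameter file; packaged default when omitted),
#' `--seed`, `--n-iter`, `--wtp`, `--out-dir`, plus `--n` and `--scenario`
#' for `microsim`, and `--population`, `--expenditure` for `bia`.
#'
#' @param argv Character vector of command-line tokens.
#'
#' @return Integer exit code: 0 on success, 1 on a usage or validation
#'   failure (with a diagnostic on stderr).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: kwaracea <run|psa|ceac|tornado|scenarios|bia|microsim>",
    "[--config FILE] [--seed N] [--n-iter N] [--wtp X] [--out-dir DIR]",
    "[--n N] [--scenario soc|kshi] [--population N] [--expenditure X]"
  )
  fail <- function(...) {
    message(...)
    message(usage)
    1L
  }
  if (length(argv) < 1) return(fail("no subcommand given"))
  cmd <- argv[1]
  opts <- list(seed = 1L, `n-iter` = 10000L, wtp = pathway_defaults()$wtp_gdp,
               `out-dir` = ".", n = 10000L, scenario = "soc",
               population = 250000, expenditure = 3e6, config = NULL)
  rest <- argv[-1]
  i <- 1
  while (i <= length(rest)) {
    tok <- rest[i]
    if (!startsWith(tok, "--")) return(fail("unexpected argument: ", tok))
    key <- substring(tok, 3)
    if (!key %in% names(opts)) return(fail("unknown flag: --", key))
    if (i + 1 > length(rest)) return(fail("flag --", key, " needs a value"))
    val <- rest[i + 1]
    opts[[key]] <- if (key %in% c("config", "scenario", "out-dir")) val else as.numeric(val)
    i <- i + 2
  }
  out <- tryCatch({
    params <- if (is.null(opts$config)) load_parameters() else load_parameters(opts$config)
    out_dir <- opts$`out-dir`
    message("kwaracea ", cmd, " | seed ", opts$seed,
            " | config hash ", rlang::hash(params))
    switch(cmd,
      run = {
        res <- cea_point(params, wtp = opts$wtp)
        cohort_soc <- run_cohort(params, soc_scenario())
        cohort_kshi <- run_cohort(params, kshi_scenario())
        write_results(cohort_soc, out_dir, stem = "cohort_soc", config = params)
        write_results(cohort_kshi, out_dir, stem = "cohort_kshi", config = params)
        write_results(res, out_dir, seed = opts$seed, config = params)
      },
      psa = ,
      ceac = {
        psa <- run_psa(params, n_iter = as.integer(opts$`n-iter`),
                       seed = as.integer(opts$seed), wtp = opts$wtp)
        write_results(psa, out_dir, config = params)
      },
      tornado = {
        res <- one_way_sa(params, wtp = opts$wtp)
        write_results(res, out_dir, seed = opts$seed, config = params)
      },
      scenarios = {
        res <- scenario_analysis(params, wtp = opts$wtp)
        write_results(res, out_dir, stem = "scenarios", config = params)
      },
      bia = {
        proj <- population_projection(opts$population)
        res <- annual_scaleup_cost(proj, params,
                                   current_expenditure = opts$expenditure)
        write_results(res, out_dir, config = params)
      },
      microsim = {
        sc <- if (opts$scenario == "kshi") kshi_scenario() else soc_scenario()
        rec <- simulate_individuals(as.integer(opts$n),
                                    point_estimates(params), sc,
                                    seed = as.integer(opts$seed))
        write_results(rec, out_dir, stem = "claims",
                      seed = opts$seed, config = params)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (identical(out, 1L)) 1L else 0L
}
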