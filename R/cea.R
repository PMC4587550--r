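#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Classify and summarise incremental results for aligned per-draw rows.
incremental_table <- function(base, intervention, wtp) {
  stopifnot(nrow(base) == nrow(intervention))
  delta_cost <- intervention$cost_total - base$cost_total
  dalys_averted <- base$losses - intervention$losses
  status <- dplyr::case_when(
    dalys_averted > 0 & delta_cost <= 0 ~ "cost_saving",
    dalys_averted > 0 & delta_cost > 0 ~ "ratio",
    dalys_averted < 0 & delta_cost >= 0 ~ "dominated",
    dalys_averted == 0 & delta_cost == 0 ~ "indifferent",
    .default = "undefined"
  )
  icer <- ifelse(status == "ratio", delta_cost / dalys_averted, NA_real_)
  verdict <- dplyr::case_when(
    status == "cost_saving" ~ "cost-saving",
    status == "dominated" ~ "dominated",
    status == "indifferent" ~ "indifferent",
    status == "undefined" ~ "undefined",
    icer <= wtp ~ "very cost-effective",
    icer <= 3 * wtp ~ "cost-effective",
    .default = "not cost-effective"
  )
  tibble::tibble(
    draw = base$draw,
    delta_cost = delta_cost,
    dalys_averted = dalys_averted,
    icer = icer,
    status = status,
    verdict = verdict,
    wtp = wtp
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the incremental cost per DALY averted of an intervention against
#' a base case, with dominance handled explicitly: a cheaper, more effective
#' intervention is flagged `cost-saving` (no ratio); a costlier, less
#' effective one `dominated`; equal effects with unequal costs yield an
#' `undefined` ratio flag rather than an error. Ratios are compared to the
#' willingness-to-pay threshold (default one GDP per capita, US$ 2,730):
#' below it the intervention is labelled very cost-effective, below three
#' times it cost-effective.
#'
#' @param base,intervention Per-draw evaluations from [evaluate_scenario()]
#'   (must share cohort size and accounting mode).
#' @param wtp Willingness-to-pay threshold, US$ per DALY averted.
#'
#' @return A tibble of class `cea_result` with one row per draw:
#'   `delta_cost`, `dalys_averted`, `icer`, `status`, `verdict`.
#'
#' @examples
#' params <- default_parameters()
#' base <- evaluate_scenario(params, soc_scenario())
#' intv <- evaluate_scenario(params, kshi_scenario())
#' icer(base, intv)
#'
#' @export
icer <- function(base, intervention, wtp = pathway_defaults()$wtp_gdp) {
  out <- incremental_table(base, intervention, wtp)
  out$comparator <- base$scenario[1]
  out$intervention <- intervention$scenario[1]
  structure(out, class = c("cea_result", class(tibble::as_tibble(out))))
}

#' Point-estimate cost-effectiveness analysis
#'
#' Runs both scenarios at parameter point estimates and returns the
#' deterministic ICER row.
#'
#' @param params A parameter set.
#' @param base,intervention Scenario configurations.
#' @inheritParams icer
#' @inheritParams evaluate_scenario
#'
#' @return A one-row `cea_result` tibble.
#' @export
cea_point <- function(params = default_parameters(),
                      base = soc_scenario(),
                      intervention = kshi_scenario(),
                      wtp = pathway_defaults()$wtp_gdp,
                      mode = "ledger") {
  icer(
    evaluate_scenario(params, base, mode = mode),
    evaluate_scenario(params, intervention, mode = mode),
    wtp = wtp
  )
}

# Ranking value used for ratio-scale percentiles: cost-saving draws sit below
# every positive ratio, dominated/undefined draws above every ratio.
icer_rank_value <- function(draws) {
  dplyr::case_when(
    draws$status == "cost_saving" ~ -Inf,
    draws$status == "ratio" ~ draws$icer,
    .default = Inf
  )
}

icer_quantile <- function(draws, probs) {
  # type 1 (inverse empirical CDF) so infinite sentinels never interpolate
  stats::quantile(icer_rank_value(draws), probs, type = 1, names = FALSE)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (share of Monte Carlo
#' draws) that the intervention is cost-effective: cost-saving draws count as
#' cost-effective at every threshold; ratio draws when their ICER does not
#' exceed the threshold.
#'
#' @param draws A `cea_result` (per-draw incremental table) or `kwara_psa`.
#' @param wtp_grid Willingness-to-pay grid, US$ per DALY averted.
#'
#' @return A tibble with columns `wtp` and `probability`, non-decreasing in
#'   `wtp`.
#' @export
ceac <- function(draws, wtp_grid = c(1, seq(50, 5000, by = 50))) {
  if (inherits(draws, "kwara_psa")) draws <- draws$draws
  tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(
      wtp_grid,
      function(w) mean(draws$status == "cost_saving" |
                         (draws$status == "ratio" & draws$icer <= w)),
      numeric(1)
    )
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty to the ICER: `n_iter`
#' paired draws (one draw of the shared parameter vector feeds both
#' scenarios — common random numbers), per-draw incremental costs and DALYs
#' averted, the median and 2.5/97.5 percentile credible interval of the
#' per-draw ICER (cost-saving draws ranked below the smallest ratio and
#' reported separately), and the cost-effectiveness acceptability curve.
#'
#' @param params A parameter set.
#' @param base,intervention Scenario configurations.
#' @param n_iter Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param wtp Willingness-to-pay threshold for verdicts.
#' @param wtp_grid Grid for the acceptability curve.
#' @inheritParams evaluate_scenario
#'
#' @return An object of class `kwara_psa`: a list with `draws` (per-draw
#'   tibble), `summary` (median and credible interval), `ceac`, `n_iter`,
#'   `seed`.
#'
#' @examples
#' psa <- run_psa(default_parameters(), n_iter = 200, seed = 1)
#' glance(psa)
#'
#' @export
run_psa <- function(params = default_parameters(),
                    base = soc_scenario(),
                    intervention = kshi_scenario(),
                    n_iter = 10000, seed = 1,
                    wtp = pathway_defaults()$wtp_gdp,
                    wtp_grid = c(1, seq(50, 5000, by = 50)),
                    mode = "ledger") {
  if (n_iter < 2) stop("`n_iter` must be at least 2", call. = FALSE)
  draws <- sample_draws(params, n_iter, seed)
  res <- icer(
    evaluate_scenario(draws, base, mode = mode),
    evaluate_scenario(draws, intervention, mode = mode),
    wtp = wtp
  )
  q <- icer_quantile(res, c(0.025, 0.5, 0.975))
  summary <- tibble::tibble(
    n_iter = n_iter,
    seed = as.integer(seed),
    median_icer = q[2],
    cri_low = q[1],
    cri_high = q[3],
    prop_cost_saving = mean(res$status == "cost_saving"),
    prop_dominated = mean(res$status == "dominated"),
    p_ce_at_wtp = mean(res$status == "cost_saving" |
                         (res$status == "ratio" & res$icer <= wtp))
  )
  structure(
    list(draws = res, summary = summary, ceac = ceac(res, wtp_grid),
         n_iter = n_iter, seed = as.integer(seed), wtp = wtp),
    class = "kwara_psa"
  )
}

#' @export
print.kwara_psa <- function(x, ...) {
  s <- x$summary
  cat("<kwara_psa> ", x$n_iter, " iterations (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  median ICER %.1f US$/DALY averted (95%% CrI %.1f-%.1f)\n",
              s$median_icer, s$cri_low, s$cri_high))
  cat(sprintf("  P(cost-effective at WTP %s): %.3f; cost-saving share %.3f\n",
              format(x$wtp), s$p_ce_at_wtp, s$prop_cost_saving))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `kwara_psa` object.
#' @param ... Unused.
#' @method tidy kwara_psa
#' @export
tidy.kwara_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @method glance kwara_psa
#' @export
glance.kwara_psa <- function(x, ...) x$summary

#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    comparator = x$comparator[1],
    intervention = x$intervention[1],
    delta_cost = mean(x$delta_cost),
    dalys_averted = mean(x$dalys_averted),
    icer = if (nrow(x) == 1) x$icer else stats::median(icer_rank_value(x)),
    verdict = x$verdict[1]
  )
}

# Rescale the lifetime DALY weights of a draw for a different discount rate.
# The per-death weight corresponds to a discounted stream over the remaining
# life expectancy; the lifelong fistula weight is rescaled with the same
# horizon ratio. Short-duration weights (anaemia, infertility) are left
# untouched.
apply_discount_rate <- function(draw, rate, base_rate = 0.03) {
  horizon <- -log(1 - base_rate * draw$daly_death[1]) / base_rate
  f <- discounted_years(horizon, rate) / discounted_years(horizon, base_rate)
  draw$daly_death <- draw$daly_death * f
  draw$daly_fistula <- draw$daly_fistula * f
  attr(draw, "daly_scale") <- f
  draw
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the deterministic ICER with one parameter at a time set to
#' the outer limits of its uncertainty range, all others held at point
#' estimates. Bounds are the distribution support for uniform and triangular
#' parameters and the mean +/- 1.96 standard deviations (truncated to
#' \[0, 1\]) for beta parameters. Two point parameters receive documented
#' ranges: the above-service cost is varied by +/-50% and the discount rate
#' between 0% and 6% (rescaling the lifetime DALY weights). Parameters are
#' ranked by the absolute ICER swing.
#'
#' @param params A parameter set.
#' @param base,intervention Scenario configurations.
#' @param targets Character vector of parameter keys (`name` or
#'   `name.scenario`); `NULL` selects every parameter with a non-degenerate
#'   range plus the two special rows.
#' @param wtp Willingness-to-pay threshold.
#' @inheritParams evaluate_scenario
#'
#' @return A tibble of class `kwara_tornado`, ranked by swing, with columns
#'   `parameter`, `low`, `high`, `icer_low`, `icer_high`, `swing`.
#'
#' @examples
#' one_way_sa(default_parameters(), targets = c("p_htd", "p_death_sepsis"))
#'
#' @export
one_way_sa <- function(params = default_parameters(),
                       base = soc_scenario(),
                       intervention = kshi_scenario(),
                       targets = NULL,
                       wtp = pathway_defaults()$wtp_gdp,
                       mode = "ledger") {
  params <- validate_parameters(params)
  point <- point_estimates(params)
  key <- draw_name(params$name, params$scenario)
  bounds <- purrr::pmap(
    params[, c("family", "mean", "sd", "min", "max")],
    function(family, mean, sd, min, max) dist_bounds(family, mean, sd, min, max)
  )
  names(bounds) <- key
  bounds[["above_service_cost"]] <-
    point$above_service_cost * c(0.5, 1.5)
  bounds[["discount_rate"]] <- c(0, 0.06)
  bounds[["cohort_size"]] <- NULL

  if (is.null(targets)) {
    widths <- vapply(bounds, function(b) diff(b), numeric(1))
    targets <- names(bounds)[widths > 0]
  } else {
    unknown <- setdiff(targets, names(bounds))
    if (length(unknown) > 0) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  eval_icer <- function(draw, ext_scale = 1) {
    res <- icer(
      evaluate_scenario(draw, base, mode = mode,
                        ext_htd_daly = pathway_defaults()$ext_htd_daly * ext_scale),
      evaluate_scenario(draw, intervention, mode = mode,
                        ext_htd_daly = pathway_defaults()$ext_htd_daly * ext_scale),
      wtp = wtp
    )
    if (res$status == "ratio") res$icer else if (res$status == "cost_saving") 0 else NA_real_
  }
  at_value <- function(target, value) {
    draw <- point
    if (target == "discount_rate") {
      draw <- apply_discount_rate(draw, value)
      eval_icer(draw, ext_scale = attr(draw, "daly_scale"))
    } else {
      draw[[target]] <- value
      eval_icer(draw)
    }
  }

  out <- purrr::map(targets, function(tg) {
    b <- bounds[[tg]]
    tibble::tibble(
      parameter = tg, low = b[1], high = b[2],
      icer_low = at_value(tg, b[1]),
      icer_high = at_value(tg, b[2])
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      baseline = eval_icer(point),
      swing = abs(.data$icer_high - .data$icer_low)
    ) |>
    dplyr::arrange(dplyr::desc(.data$swing))
  structure(out, class = c("kwara_tornado", class(tibble::as_tibble(out))))
}

#' Alternative base-case scenario analysis
#'
#' Deterministic ICER of the intervention against each alternative base-case
#' configuration (raised utilization, literature costs with high quality of
#' care, or both), with dominance handled as in [icer()].
#'
#' @param params A parameter set.
#' @param alternatives A named list of comparator [scenario_config()]s.
#' @param intervention The intervention configuration.
#' @inheritParams icer
#' @inheritParams evaluate_scenario
#'
#' @return A tibble with one row per comparator.
#' @export
scenario_analysis <- function(params = default_parameters(),
                              alternatives = list(soc1_scenario(),
                                                  soc2_scenario(),
                                                  soc3_scenario()),
                              intervention = kshi_scenario(),
                              wtp = pathway_defaults()$wtp_gdp,
                              mode = "ledger") {
  intv <- evaluate_scenario(params, intervention, mode = mode)
  purrr::map(alternatives, function(alt) {
    icer(evaluate_scenario(params, alt, mode = mode), intv, wtp = wtp) |>
      tibble::as_tibble()
  }) |>
    purrr::list_rbind()
}

#' Plot methods for analysis results
#'
#' `autoplot.kwara_psa()` draws the incremental cost-effectiveness plane
#' (`type = "plane"`) or the acceptability curve (`type = "ceac"`);
#' `autoplot.kwara_tornado()` the ranked tornado diagram.
#'
#' @param object A result object.
#' @param type For PSA results, `"plane"` or `"ceac"`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.kwara_psa <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    ggplot2::ggplot(object$draws,
                    ggplot2::aes(x = .data$dalys_averted, y = .data$delta_cost)) +
      ggplot2::geom_point(alpha = 0.2, size = 0.6) +
      ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                           linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
      ggplot2::labs(x = "DALYs averted", y = "Incremental cost (US$ 2012)",
                    title = "Incremental cost-effectiveness plane") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$ceac,
                    ggplot2::aes(x = .data$wtp, y = .data$probability)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$wtp, linetype = "dashed") +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(x = "Willingness to pay (US$/DALY averted)",
                    y = "Probability cost-effective",
                    title = "Cost-effectiveness acceptability curve") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.kwara_psa
#' @export
autoplot.kwara_tornado <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$baseline[1]),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (US$/DALY averted)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
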