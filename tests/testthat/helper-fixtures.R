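# Shared fixtures: the default parameter set and its point-estimate draw are
# deterministic, so build them once per test run.
fx_params <- default_parameters()
fx_point <- point_estimates(fx_params)

# A parameter set with every distribution collapsed to its point estimate
# (used for degenerate-PSA checks).
fx_point_params <- local({
  p <- tibble::as_tibble(fx_params)
  pt <- purrr::pmap_dbl(
    p[, c("family", "mean", "sd", "min", "max")],
    function(family, mean, sd, min, max) {
      switch(family,
        point = mean, beta = mean,
        uniform = (min + max) / 2,
        triangular = mean
      )
    }
  )
  p$mean <- pt
  p$family <- "point"
  p$sd <- NA_real_
  p$min <- NA_real_
  p$max <- NA_real_
  validate_parameters(p)
})

# Replace one parameter row's spec in a parameter table.
fx_set_param <- function(params, name, scenario = "shared", family, mean = NA,
                         sd = NA, min = NA, max = NA) {
  p <- tibble::as_tibble(params)
  i <- which(p$name == name & p$scenario == scenario)
  stopifnot(length(i) == 1)
  p$family[i] <- family
  p$mean[i] <- mean
  p$sd[i] <- sd
  p$min[i] <- min
  p$max[i] <- max
  validate_parameters(p)
}
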