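#' Beta shape parameters from a mean and standard deviation
#'
#' Solves the method-of-moments equations for a beta distribution so that the
#' returned shape parameters reproduce the requested mean and standard
#' deviation exactly. This is the standard way to turn a published
#' "mean (sd)" probability into a sampling distribution for probabilistic
#' sensitivity analysis.
#'
#' @param mean Mean of the distribution, strictly inside (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#'
#' @return A named list with elements `shape1` (alpha) and `shape2` (beta),
#'   usable directly with [stats::rbeta()].
#'
#' @examples
#' beta_from_moments(0.051, 0.04)
#'
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || mean >= 1) {
    stop("`mean` must lie strictly inside (0, 1), got ", mean, call. = FALSE)
  }
  if (sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop(
      "infeasible moments: need 0 < sd^2 < mean * (1 - mean); got sd^2 = ",
      signif(sd^2, 4), " against bound ", signif(mean * (1 - mean), 4),
      call. = FALSE
    )
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Triangular mode from a mean and support
#'
#' A triangular distribution on `[min, max]` with mode `c` has mean
#' `(min + c + max) / 3`. Published triangular parameters of the form
#' "average (minimum-maximum)" are therefore converted by solving for the
#' mode: `c = 3 * mean - min - max`.
#'
#' @param mean Published mean of the distribution.
#' @param min,max Support limits, `min <= max`.
#'
#' @return The mode, guaranteed to lie in `[min, max]`.
#'
#' @examples
#' triangular_from_mean(0.017, 0.01, 0.03) # 0.011
#'
#' @export
triangular_from_mean <- function(mean, min, max) {
  stopifnot(min <= max)
  mode <- 3 * mean - min - max
  if (mode < min - 1e-12 || mode > max + 1e-12) {
    stop(
      "infeasible triangular: derived mode ", signif(mode, 4),
      " outside [", min, ", ", max, "]",
      call. = FALSE
    )
  }
  base::min(base::max(mode, min), max)
}

# Inverse CDF of the triangular(min, mode, max) distribution.
qtriangular <- function(p, min, mode, max) {
  if (max <= min) return(rep(min, length(p)))
  fc <- (mode - min) / (max - min)
  ifelse(
    p < fc,
    min + sqrt(p * (max - min) * (mode - min)),
    max - sqrt((1 - p) * (max - min) * (max - mode))
  )
}

rtriangular <- function(n, min, mode, max) {
  qtriangular(stats::runif(n), min, mode, max)
}

# Resolve the triangular mode for a spec row. Rows whose printed mean is
# incompatible with a mean reading (derived mode outside the support, which
# happens when the printed mean is rounded) fall back to treating the printed
# central value as the mode.
triangular_mode <- function(mean, min, max) {
  mode <- 3 * mean - min - max
  if (mode < min || mode > max) {
    base::min(base::max(mean, min), max)
  } else {
    mode
  }
}

#' Validate a distribution specification
#'
#' Checks the feasibility conditions for one parameter's sampling
#' distribution: point needs a mean; uniform needs `min < max`; beta needs
#' `mean` in (0,1) and `sd^2 < mean * (1 - mean)`; triangular needs a mode
#' (derived or fallback) inside `[min, max]`.
#'
#' @param family One of `"point"`, `"uniform"`, `"beta"`, `"triangular"`.
#' @param mean,sd,min,max Distribution parameters; unused slots may be `NA`.
#'
#' @return Invisibly `TRUE`; errors describe the offending condition.
#' @export
validate_dist <- function(family, mean = NA, sd = NA, min = NA, max = NA) {
  family <- match.arg(family, c("point", "uniform", "beta", "triangular"))
  switch(family,
    point = {
      if (is.na(mean)) stop("point distribution requires a mean", call. = FALSE)
    },
    uniform = {
      if (is.na(min) || is.na(max) || !(min < max)) {
        stop("uniform distribution requires min < max", call. = FALSE)
      }
    },
    beta = {
      beta_from_moments(mean, sd)
    },
    triangular = {
      if (is.na(mean) || is.na(min) || is.na(max) || min > max) {
        stop("triangular distribution requires mean, min <= max", call. = FALSE)
      }
      if (mean < min || mean > max) {
        stop("triangular central value outside [min, max]", call. = FALSE)
      }
    }
  )
  invisible(TRUE)
}

# Point estimate (analytic mean) of a spec row. For triangular rows where
# the mean reading is feasible this is the printed mean; under the mode
# fallback it is (min + mode + max) / 3.
dist_mean <- function(family, mean = NA, sd = NA, min = NA, max = NA) {
  switch(family,
    point = mean,
    beta = mean,
    uniform = (min + max) / 2,
    triangular = (min + triangular_mode(mean, min, max) + max) / 3,
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# n samples from one spec row. Sampling is via the family's own support so
# draws never escape it.
dist_sample <- function(n, family, mean = NA, sd = NA, min = NA, max = NA) {
  switch(family,
    point = rep(mean, n),
    uniform = stats::runif(n, min, max),
    beta = {
      sh <- beta_from_moments(mean, sd)
      stats::rbeta(n, sh$shape1, sh$shape2)
    },
    triangular = rtriangular(n, min, triangular_mode(mean, min, max), max),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# Support bounds used by the one-way sensitivity analysis: exact support for
# uniform/triangular; mean +/- 1.96 sd truncated to [0, 1] for beta (the
# nominal 95% normal interval); degenerate for point.
dist_bounds <- function(family, mean = NA, sd = NA, min = NA, max = NA) {
  switch(family,
    point = c(mean, mean),
    uniform = c(min, max),
    triangular = c(min, max),
    beta = c(base::max(0, mean - 1.96 * sd), base::min(1, mean + 1.96 * sd)),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}
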