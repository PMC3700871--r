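#' z-standardize a covariate
#'
#' Centers and scales to mean 0, sd 1 (sample sd, `n - 1` denominator).
#' The returned parameters allow new data to be standardized on the
#' training scale, and fitted optima to be back-transformed to the
#' measurement scale.
#'
#' @param x Numeric vector (length >= 2, not constant) — or, with `params`
#'   supplied, any numeric vector to be standardized on an existing scale.
#' @param params Optional list/row with `mean` and `sd`, as returned by a
#'   previous call; when given, `x` is standardized with these instead of
#'   its own moments.
#' @return A list with `z` (the standardized values) and `params` (a
#'   one-row tibble with `mean` and `sd`).
#' @examples
#' standardize(c(4, 6))$z # -0.7071, +0.7071
#' @export
standardize <- function(x, params = NULL) {
  if (is.null(params)) {
    if (length(x) < 2) stop_validation("need at least 2 values to standardize")
    m <- mean(x)
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop_validation("cannot standardize a constant covariate")
    params <- tibble(mean = m, sd = s)
  } else {
    params <- tibble(mean = params$mean, sd = params$sd)
    if (params$sd <= 0) stop_validation("`params$sd` must be positive")
  }
  list(z = (x - params$mean) / params$sd, params = params)
}

#' @rdname standardize
#' @param z Standardized values to map back to the original scale.
#' @export
unstandardize <- function(z, params) {
  z * params$sd + params$mean
}

#' Standardize the activity and wind columns of a night table
#'
#' Adds `zA` (standardized acoustic activity) and `zW` (standardized wind
#' speed) columns.  With `params = NULL` the standardization parameters
#' are estimated from the table itself (the training data); pass the
#' attached `"std_params"` attribute of a training table to put new data
#' on the same scale.
#'
#' @param nights Night table.
#' @param params Optional standardization parameters (tibble with rows for
#'   `activity` and `wind`).
#' @return The night table with `zA` and `zW` columns; standardization
#'   parameters in `attr(, "std_params")`.
#' @export
standardize_nights <- function(nights, params = NULL) {
  if (is.null(params)) {
    sa <- standardize(nights$activity)
    sw <- standardize(nights$wind)
    params <- bind_rows(
      mutate(sa$params, covariate = "activity", .before = 1),
      mutate(sw$params, covariate = "wind", .before = 1)
    )
  } else {
    sa <- standardize(nights$activity, params[params$covariate == "activity", ])
    sw <- standardize(nights$wind, params[params$covariate == "wind", ])
  }
  out <- mutate(nights, zA = sa$z, zW = sw$z)
  attr(out, "std_params") <- params
  out
}

#' Collision-rate coefficients
#'
#' The nightly number of collisions is Poisson with log link:
#' `log(lambda) = alpha0 + alpha1 * zA + alpha2 * zW + alpha3 * zW^2`,
#' where `zA` and `zW` are standardized acoustic activity and wind speed.
#'
#' @param alpha0,alpha1,alpha2,alpha3 Intercept, activity, wind and
#'   quadratic wind coefficients.
#' @return A named numeric vector of length 4.
#' @export
collision_coefficients <- function(alpha0, alpha1, alpha2, alpha3) {
  coef <- c(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3)
  if (any(!is.finite(coef))) stop_validation("coefficients must be finite")
  coef
}

#' Expected nightly collision rate
#'
#' @param coef Coefficients (see [collision_coefficients()]).
#' @param zA,zW Standardized activity and wind speed (vectors recycle).
#' @return `lambda = exp(alpha0 + alpha1 zA + alpha2 zW + alpha3 zW^2)`.
#' @examples
#' expected_rate(collision_coefficients(-3.5, 0.4, -1.8, -0.8), 0, 0)
#' @export
expected_rate <- function(coef, zA, zW) {
  eta <- coef[["alpha0"]] + coef[["alpha1"]] * zA + coef[["alpha2"]] * zW +
    coef[["alpha3"]] * zW^2
  lambda <- exp(eta)
  if (any(!is.finite(lambda))) stop_validation("rate overflow: linear predictor too large")
  lambda
}

#' Wind speed of maximum collision rate
#'
#' At constant acoustic activity the log collision rate is quadratic in
#' standardized wind; with `alpha3 < 0` its maximum sits at
#' `z* = -alpha2 / (2 alpha3)`, back-transformed to the measurement scale
#' as `wind_mean + wind_sd * z*`.
#'
#' @param coef Coefficients (see [collision_coefficients()]).
#' @param wind_mean,wind_sd Wind standardization parameters (m/s).
#' @param digits When non-`NULL`, round the result half-up to this many
#'   decimals (reported optima conventionally use 1 decimal).
#' @return Wind speed in m/s.
#' @examples
#' wind_at_max_rate(collision_coefficients(-2.7, 0.4, -0.2, -0.2),
#'   wind_mean = 5.2, wind_sd = 1.9, digits = 1
#' ) # 4.3 m/s
#' @export
wind_at_max_rate <- function(coef, wind_mean, wind_sd, digits = NULL) {
  if (coef[["alpha3"]] >= 0) {
    abort_collmix("no interior maximum: alpha3 must be negative",
      class = "collmix_no_maximum_error"
    )
  }
  w <- wind_mean + wind_sd * (-coef[["alpha2"]] / (2 * coef[["alpha3"]]))
  if (!is.null(digits)) w <- round_half_up(w, digits)
  w
}
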