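#' Moment-matched Beta distribution
#'
#' Converts a point estimate and standard error of a probability into the
#' Beta distribution with that mean and variance:
#' `alpha = m (m (1 - m) / v - 1)`, `beta = (1 - m) (m (1 - m) / v - 1)`
#' with `v = se^2`.  Such Beta distributions serve as informative priors
#' for detection parameters whose uncertainty was estimated in the field.
#'
#' A standard error below `se_tol` yields a degenerate specification
#' (`fixed = TRUE`): the parameter is treated as known at its mean rather
#' than represented by an extreme Beta.
#'
#' @param mean Point estimate, strictly between 0 and 1.
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @param se_tol Threshold under which the parameter is treated as fixed.
#' @return A one-row tibble: `alpha`, `beta`, `mean`, `se`, `fixed`.
#' @examples
#' beta_from_moments(0.5, 0.05) # alpha = beta = 49.5
#' @export
beta_from_moments <- function(mean, se, se_tol = 1e-6) {
  if (length(mean) != 1 || !is.finite(mean)) stop_validation("`mean` must be a single finite value")
  if (length(se) != 1 || !is.finite(se) || se < 0) stop_validation("`se` must be a single non-negative value")
  if (mean <= 0 || mean >= 1) {
    abort_collmix(sprintf("`mean` must lie strictly inside (0, 1), got %g", mean),
      class = "collmix_boundary_error"
    )
  }
  if (se < se_tol) {
    return(tibble(alpha = NA_real_, beta = NA_real_, mean = mean, se = se, fixed = TRUE))
  }
  v <- se^2
  if (v >= mean * (1 - mean)) {
    abort_collmix(sprintf(
      "infeasible variance: se^2 = %g is not below mean*(1-mean) = %g",
      v, mean * (1 - mean)
    ), class = "collmix_infeasible_variance_error")
  }
  nu <- mean * (1 - mean) / v - 1
  tibble(alpha = mean * nu, beta = (1 - mean) * nu, mean = mean, se = se, fixed = FALSE)
}

#' Standard error from a confidence interval
#'
#' Normal-approximation conversion: `se = (upper - lower) / (2 z)` with `z`
#' the standard normal quantile for `(1 + level) / 2`.  Asymmetric
#' intervals are thereby symmetrised — only the width is used.
#'
#' @param lower,upper Interval limits.
#' @param level Confidence level of the interval (default 0.95).
#' @return The implied standard error.
#' @examples
#' se_from_ci(0.50, 0.85) # 0.0893
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (any(lower > upper)) stop_validation("`lower` must not exceed `upper`")
  if (level <= 0 || level >= 1) stop_validation("`level` must be in (0, 1)")
  (upper - lower) / (2 * qnorm((1 + level) / 2))
}

#' Beta priors for the detection parameters of each turbine
#'
#' Builds moment-matched Beta priors for the overall detection probability
#' `p`, the daily persistence probability `s` and the searcher efficiency
#' `f` of every turbine in a detection table, converting each 95%
#' confidence interval to a standard error via [se_from_ci()].  The
#' fall-in proportion `a` is treated as known without error and passed
#' through as a constant.
#'
#' Published intervals occasionally exclude the point estimate (a
#' typesetting artefact in the source tables); such rows are accepted
#' because only the interval width enters the prior — the prior mean is
#' always the point estimate.
#'
#' @param detections Detection table (see [read_detection_table()]), or a
#'   single row of one.
#' @return A tibble with one row per turbine and parameter: `turbine`,
#'   `parameter` (`"p"`, `"s"`, `"f"` or `"a"`), `alpha`, `beta`, `mean`,
#'   `se`, `fixed`.
#' @examples
#' detection_priors(example_detection_table()[1, ])
#' @export
detection_priors <- function(detections) {
  purrr::map_dfr(seq_len(nrow(detections)), function(i) {
    row <- detections[i, ]
    one <- function(par) {
      spec <- tryCatch(
        beta_from_moments(
          row[[par]],
          se_from_ci(row[[paste0(par, "_lwr")]], row[[paste0(par, "_upr")]])
        ),
        collmix_infeasible_variance_error = function(e) {
          abort_collmix(sprintf(
            "turbine %s, parameter '%s': %s", row$turbine, par, conditionMessage(e)
          ), class = "collmix_infeasible_variance_error")
        }
      )
      mutate(spec, turbine = row$turbine, parameter = par, .before = 1)
    }
    bind_rows(
      one("p"), one("s"), one("f"),
      tibble(
        turbine = row$turbine, parameter = "a",
        alpha = NA_real_, beta = NA_real_, mean = row$a, se = 0, fixed = TRUE
      )
    )
  })
}

# Draw from a prior specification row: Beta when proper, the fixed mean
# otherwise.
draw_prior <- function(spec, n = 1) {
  if (isTRUE(spec$fixed)) rep(spec$mean, n) else rbeta(n, spec$alpha, spec$beta)
}
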