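#' Posterior of the number of collisions given detection probability
#'
#' With `C` carcasses found, detection probability `p`, and a flat prior
#' on the number of collisions `N`, Bayes' theorem gives
#' `N - C ~ NegBinomial(size = C + 1, prob = p)`, with closed-form
#' posterior mean `(C + 1) / p - 1`.  This is the "corrected count"
#' building block: inverting the binomial search process without any
#' covariate information.
#'
#' @param C Carcasses found (non-negative integer).
#' @param p Detection probability in (0, 1].
#' @param tail_mass Probability mass beyond which the returned table is
#'   truncated.
#' @return A tibble with columns `N` and `prob` (the posterior pmf, from
#'   `N = C` upward until `1 - tail_mass` is covered), with the
#'   closed-form mean in `attr(, "mean")`.
#' @examples
#' posterior_given_p(22, 0.586) |> attr("mean") # 38.25
#' @export
posterior_given_p <- function(C, p, tail_mass = 1e-10) {
  if (!is_count(C) || length(C) != 1) stop_validation("`C` must be one non-negative integer")
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p > 1) {
    stop_validation("`p` must lie in (0, 1]: the posterior is improper at p = 0")
  }
  upper <- if (p == 1) C else C + stats::qnbinom(1 - tail_mass, size = C + 1, prob = p)
  N <- C:upper
  prob <- stats::dnbinom(N - C, size = C + 1, prob = p)
  structure(tibble(N = N, prob = prob), mean = (C + 1) / p - 1)
}

#' Corrected-count estimate with detection uncertainty
#'
#' Propagates the uncertainty of the detection probability into the
#' corrected count by Monte Carlo: detection probabilities are drawn from
#' their Beta prior and the flat-prior negative-binomial posterior is
#' mixed over the draws.
#'
#' @param C Total carcasses found.
#' @param p_prior One-row prior specification for `p` as returned by
#'   [beta_from_moments()] (a degenerate `fixed` spec reduces to
#'   [posterior_given_p()] exactly).
#' @param n_draws Number of Monte-Carlo draws (at least 1000).
#' @return A one-row tibble of class `corrected_count`: `C`, `mean`,
#'   `median`, `lower`, `upper` (95% equal-tail), `mode`.
#' @examples
#' pr <- beta_from_moments(0.586, 0.084)
#' estimate_corrected(22, pr, n_draws = 10000)
#' @export
estimate_corrected <- function(C, p_prior, n_draws = 1e5) {
  if (n_draws < 1000) stop_validation("`n_draws` must be at least 1000")
  if (isTRUE(p_prior$fixed)) {
    post <- posterior_given_p(C, p_prior$mean)
    cum <- cumsum(post$prob)
    qs <- vapply(c(0.025, 0.5, 0.975), function(q) post$N[which(cum >= q)[1]], numeric(1))
    out <- tibble(
      C = C, mean = attr(post, "mean"), median = qs[2],
      lower = qs[1], upper = qs[3], mode = post$N[which.max(post$prob)]
    )
    return(structure(out, class = c("corrected_count", class(out))))
  }
  p <- rbeta(n_draws, p_prior$alpha, p_prior$beta)
  while (any(p == 0)) {
    p[p == 0] <- rbeta(sum(p == 0), p_prior$alpha, p_prior$beta)
  }
  N <- C + rnbinom(n_draws, size = C + 1, prob = p)
  qs <- quantile(N, c(0.025, 0.5, 0.975), names = FALSE, type = 1)
  tab <- tabulate(N + 1L)
  out <- tibble(
    C = C, mean = mean(N), median = qs[2], lower = qs[1], upper = qs[3],
    mode = which.max(tab) - 1L
  )
  structure(out, class = c("corrected_count", class(out)))
}

#' Pooled Beta prior for the detection probability of a set of turbines
#'
#' For totals summed over turbines, the relevant detection probability is
#' the search-effort weighted mean of the per-turbine probabilities.  The
#' prior mean is the `T`-weighted mean of `p`, and the prior standard
#' error is derived from the equally weighted mean of the 95% CI widths.
#'
#' @param detections Detection table rows to pool.
#' @return A one-row prior spec as from [beta_from_moments()].
#' @export
pooled_detection_prior <- function(detections) {
  if (nrow(detections) == 0) stop_validation("empty detection table")
  w <- detections$`T` / sum(detections$`T`)
  mean_p <- sum(w * detections$p)
  width <- sum(w * (detections$p_upr - detections$p_lwr))
  beta_from_moments(mean_p, se_from_ci(0, width))
}

#' Corrected-count estimates for a detection table
#'
#' Either pools the table into a single total (summed carcasses, pooled
#' effort-weighted detection prior) or produces one estimate per turbine
#' from its own `p` interval.
#'
#' @param detections Detection table (filter by year first for per-season
#'   totals).
#' @param mode `"pooled"` or `"per_turbine"`.
#' @param n_draws Monte-Carlo draws per estimate.
#' @return A `corrected_count` tibble: one row (pooled) or one row per
#'   turbine with a leading `turbine` column.
#' @examples
#' det <- dplyr::filter(example_detection_table(), year == 2007)
#' estimate_corrected_per_turbine(det, mode = "pooled", n_draws = 10000)
#' @export
estimate_corrected_per_turbine <- function(detections, mode = c("pooled", "per_turbine"),
                                           n_draws = 1e5) {
  mode <- match.arg(mode)
  if (nrow(detections) == 0) stop_validation("empty detection table")
  if (mode == "pooled") {
    return(estimate_corrected(sum(detections$C), pooled_detection_prior(detections), n_draws))
  }
  out <- purrr::map_dfr(seq_len(nrow(detections)), function(i) {
    row <- detections[i, ]
    prior <- beta_from_moments(row$p, se_from_ci(row$p_lwr, row$p_upr))
    mutate(estimate_corrected(row$C, prior, n_draws), turbine = row$turbine, .before = 1)
  })
  structure(out, class = c("corrected_count", class(tibble())))
}
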