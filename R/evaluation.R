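#' Ratio of estimated to true collision totals
#'
#' The bias of a mortality estimator on simulated data is measured as the
#' ratio between the estimated and the true (simulated) number of
#' collisions per turbine.  Turbines whose true total is zero have an
#' undefined ratio; they are flagged (`NA` ratio) and excluded from
#' summary statistics rather than reported as infinities.
#'
#' @param estimates Per-turbine estimates: a tibble with `turbine` and
#'   `mean` (e.g. from `mortality_summary(fit, "turbine")`) or an
#'   `estimated` column.
#' @param truth Tibble with `turbine` and `true_total` (see
#'   [true_totals()]).
#' @return A tibble `turbine`, `estimated`, `true_total`, `ratio`.
#' @export
bias_ratios <- function(estimates, truth) {
  est_col <- if ("estimated" %in% names(estimates)) "estimated" else "mean"
  if (!setequal(estimates$turbine, truth$turbine)) {
    stop_validation("`estimates` and `truth` must cover the same turbines")
  }
  out <- left_join(
    select(estimates, "turbine", estimated = dplyr::all_of(est_col)),
    select(truth, "turbine", "true_total"),
    by = "turbine"
  )
  mutate(out, ratio = ifelse(.data$true_total > 0,
    .data$estimated / .data$true_total, NA_real_))
}

#' @rdname bias_ratios
#' @param ratios Output of `bias_ratios()` (rows from several replicates
#'   may be concatenated).
#' @return `bias_summary()`: a one-row tibble with the median and
#'   quartiles of the defined ratios and the number of zero-truth
#'   turbines excluded.
#' @export
bias_summary <- function(ratios) {
  ok <- ratios$ratio[!is.na(ratios$ratio)]
  tibble(
    n = length(ok),
    n_zero_truth = sum(is.na(ratios$ratio)),
    median = median(ok),
    q25 = quantile(ok, 0.25, names = FALSE),
    q75 = quantile(ok, 0.75, names = FALSE)
  )
}

#' Posterior predictive check of count frequencies
#'
#' Simulates complete found-carcass data sets from retained posterior
#' draws through the observation chain matching the fitted model, and
#' compares the frequency of searches with `k = 0, 1, 2, ...` carcasses
#' against the observed frequencies.  A well-specified model should place
#' the observed frequencies inside the 95% prediction intervals —
#' in particular the zero-count frequency, which diagnoses the need for
#' zero inflation or overdispersion.
#'
#' @param fit A `collision_fit`.
#' @param thin_draws Use every `thin_draws`-th retained draw (default 10,
#'   bounding the simulation cost).
#' @param max_k Table counts up to this value (frequencies above are
#'   pooled into the last row only if they occur).
#' @return A tibble of class `ppc_table`: `k`, `observed`,
#'   `predicted_median`, `predicted_lower`, `predicted_upper` (95%
#'   equal-tail).  Frequencies in every simulated draw sum to the number
#'   of searched turbine-nights.
#' @export
posterior_predictive_check <- function(fit, thin_draws = 10, max_k = NULL) {
  nights <- arrange(fit$data$nights, .data$turbine, .data$night)
  nights <- standardize_nights(nights, fit$std_params)
  X <- cbind(1, nights$zA, nights$zW, nights$zW^2)
  ids <- fit$turbines
  tindex <- match(nights$turbine, ids)
  searched <- nights$searched
  draws <- fit$draws[seq(1, nrow(fit$draws), by = thin_draws), ]
  n_sims <- nrow(draws)
  obs_counts <- nights$c[searched]
  kmax <- max_k %||% (max(obs_counts) + 3)

  sim_freq <- matrix(0, n_sims, kmax + 1)
  A <- as.matrix(draws[c("alpha0", "alpha1", "alpha2", "alpha3")])
  for (d in seq_len(n_sims)) {
    lambda <- exp(drop(X %*% A[d, ]))
    N <- rpois(length(lambda), lambda)
    if (fit$model == "one_level") {
      p_i <- as.numeric(draws[d, paste0("p_", ids)])
      c_sim <- rbinom(length(N), N, p_i[tindex])
      c_sim <- c_sim[searched]
    } else {
      s_i <- as.numeric(draws[d, paste0("s_", ids)])
      f_i <- as.numeric(draws[d, paste0("f_", ids)])
      a_i <- prior_lookup(fit$priors, ids, "a")$mean
      c_sim <- unlist(lapply(seq_along(ids), function(i) {
        idx <- tindex == i
        path <- simulate_three_level_path(
          N[idx], a_i[i], s_i[i], f_i[i], searched[idx]
        )
        path$found[searched[idx]]
      }))
    }
    c_sim <- pmin(c_sim, kmax)
    sim_freq[d, ] <- tabulate(c_sim + 1L, nbins = kmax + 1)
  }
  obs_freq <- tabulate(pmin(obs_counts, kmax) + 1L, nbins = kmax + 1)
  qs <- apply(sim_freq, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE, type = 1)
  out <- tibble(
    k = 0:kmax,
    observed = obs_freq,
    predicted_median = qs[2, ],
    predicted_lower = qs[1, ],
    predicted_upper = qs[3, ]
  )
  structure(out,
    n_searches = sum(searched), n_sims = n_sims,
    sim_frequencies = sim_freq,
    class = c("ppc_table", class(out))
  )
}
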