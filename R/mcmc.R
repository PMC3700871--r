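#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler.  Latent collision
#' counts and detection probabilities are updated by their exact
#' conditionals (shifted Poisson and conjugate Beta); the four collision
#' coefficients use Gaussian random-walk proposals whose step sizes are
#' adapted towards ~30% acceptance during burn-in only and frozen
#' afterwards, keeping the post-burn-in chain Markovian.
#'
#' @param n_chains Number of chains (default 2; convergence diagnostics
#'   need at least 2).
#' @param n_iterations Iterations per chain (defaults: 20000 for the
#'   one-level model, 100000 for the slower-mixing three-level model).
#' @param burn_in Iterations discarded (defaults 10000 / 90000).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; each chain derives its own sub-seed.
#' @param proposal_scale Initial random-walk sd for the coefficients.
#' @param adapt_interval Burn-in batch length between step-size updates.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 20000, burn_in = 10000,
                        thin = 1, seed = 1L, proposal_scale = 0.1,
                        adapt_interval = 50) {
  if (burn_in >= n_iterations) stop_validation("`burn_in` must be below `n_iterations`")
  if (n_chains < 1) stop_validation("`n_chains` must be positive")
  structure(
    list(
      n_chains = as.integer(n_chains), n_iterations = as.integer(n_iterations),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      seed = as.integer(seed), proposal_scale = proposal_scale,
      adapt_interval = as.integer(adapt_interval)
    ),
    class = "mcmc_config"
  )
}

# Normalize fit input to list(nights, detections).
as_fit_data <- function(data) {
  if (inherits(data, "sim_replicate")) {
    return(list(nights = data$nights, detections = data$detection))
  }
  if (inherits(data, "collision_data") ||
    (is.list(data) && all(c("nights", "detections") %in% names(data)))) {
    return(list(nights = data$nights, detections = data$detections))
  }
  stop_validation("`data` must be a collision_data, sim_replicate, or list(nights, detections)")
}

# Shared pre-processing: sorted nights, design matrix, turbine indexing.
prepare_fit <- function(data, params = NULL) {
  nights <- arrange(data$nights, .data$turbine, .data$night)
  nights <- standardize_nights(nights, params)
  ids <- sort(unique(nights$turbine))
  list(
    nights = nights,
    X = cbind(1, nights$zA, nights$zW, nights$zW^2),
    tindex = match(nights$turbine, ids),
    ids = ids,
    std_params = attr(nights, "std_params")
  )
}

prior_lookup <- function(priors, ids, parameter) {
  rows <- priors[priors$parameter == parameter, ]
  idx <- match(ids, rows$turbine)
  if (any(is.na(idx))) {
    stop_validation(sprintf("missing '%s' prior for turbine(s) %s", parameter,
      paste(ids[is.na(idx)], collapse = ", ")))
  }
  rows[idx, ]
}

# Poisson log-likelihood up to a constant, on the linear-predictor scale.
pois_ll <- function(N, eta, lambda) sum(N * eta) - sum(lambda)

# One coefficient-update sweep (per-coordinate random walk, Normal(0, 100)
# prior).  Returns updated state.
update_coefficients <- function(alpha, eta, lambda, N, X, scales, free) {
  accepted <- logical(4)
  for (k in which(free)) {
    prop <- alpha[k] + rnorm(1, 0, scales[k])
    eta_new <- eta + (prop - alpha[k]) * X[, k]
    lambda_new <- exp(eta_new)
    if (any(!is.finite(lambda_new))) next
    logr <- pois_ll(N, eta_new, lambda_new) - pois_ll(N, eta, lambda) +
      dnorm(prop, 0, 10, log = TRUE) - dnorm(alpha[k], 0, 10, log = TRUE)
    if (log(runif(1)) < logr) {
      alpha[k] <- prop
      eta <- eta_new
      lambda <- lambda_new
      accepted[k] <- TRUE
    }
  }
  list(alpha = alpha, eta = eta, lambda = lambda, accepted = accepted)
}

adapt_scales <- function(scales, acc_count, interval, free) {
  rate <- acc_count / interval
  fac <- exp(pmin(pmax(rate - 0.3, -0.5), 0.5))
  scales[free] <- pmin(pmax(scales[free] * fac[free], 1e-4), 10)
  scales
}

run_chain_one_level <- function(prep, p_prior, cfg, chain, fix_coefficients) {
  set.seed(derive_seed(cfg$seed, chain))
  nights <- prep$nights
  n <- nrow(nights)
  n_turb <- length(prep$ids)
  cc <- nights$c
  searched <- nights$searched
  tindex <- prep$tindex
  X <- prep$X

  free <- rep(TRUE, 4)
  alpha <- numeric(4)
  if (!is.null(fix_coefficients)) {
    fixed_idx <- match(names(fix_coefficients), c("alpha0", "alpha1", "alpha2", "alpha3"))
    free[fixed_idx] <- FALSE
    alpha[fixed_idx] <- fix_coefficients
  }
  p <- p_prior$mean
  p_free <- !p_prior$fixed
  if (free[1]) {
    alpha[1] <- log(max(sum(cc) / max(sum(searched), 1), 1e-3) / max(mean(p), 1e-3))
  }
  eta <- drop(X %*% alpha)
  lambda <- exp(eta)
  N <- ifelse(searched, cc, 0L)

  scales <- rep(cfg$proposal_scale, 4)
  acc_count <- numeric(4)
  n_keep <- (cfg$n_iterations - cfg$burn_in) %/% cfg$thin
  out_alpha <- matrix(NA_real_, n_keep, 4)
  out_p <- matrix(NA_real_, n_keep, n_turb)
  out_Ntot <- matrix(NA_real_, n_keep, n_turb)
  keep <- 0L

  for (iter in seq_len(cfg$n_iterations)) {
    # latent counts: exact conditional N - c ~ Poisson(lambda (1 - p))
    p_night <- p[tindex]
    N <- ifelse(searched,
      cc + rpois(n, lambda * (1 - p_night)),
      rpois(n, lambda)
    )
    # detection probabilities: conjugate Beta update on searched nights
    if (any(p_free)) {
      found_i <- rowsum(cc * searched, tindex)[, 1]
      miss_i <- rowsum((N - cc) * searched, tindex)[, 1]
      upd <- which(p_free)
      p[upd] <- rbeta(length(upd), p_prior$alpha[upd] + found_i[upd],
        p_prior$beta[upd] + miss_i[upd])
    }
    if (any(free)) {
      st <- update_coefficients(alpha, eta, lambda, N, X, scales, free)
      alpha <- st$alpha
      eta <- st$eta
      lambda <- st$lambda
      acc_count <- acc_count + st$accepted
      if (iter <= cfg$burn_in && iter %% cfg$adapt_interval == 0) {
        scales <- adapt_scales(scales, acc_count, cfg$adapt_interval, free)
        acc_count <- numeric(4)
      }
    }
    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0) {
      keep <- keep + 1L
      out_alpha[keep, ] <- alpha
      out_p[keep, ] <- p
      out_Ntot[keep, ] <- rowsum(N, tindex)[, 1]
    }
  }
  list(alpha = out_alpha, detect = list(p = out_p), Ntot = out_Ntot)
}

run_chain_three_level <- function(prep, s_prior, f_prior, a_turb, cfg, chain,
                                  fix_coefficients) {
  set.seed(derive_seed(cfg$seed, chain))
  nights <- prep$nights
  cc <- as.integer(nights$c)
  searched <- nights$searched

  free <- rep(TRUE, 4)
  alpha <- numeric(4)
  if (!is.null(fix_coefficients)) {
    fixed_idx <- match(names(fix_coefficients), c("alpha0", "alpha1", "alpha2", "alpha3"))
    free[fixed_idx] <- FALSE
    alpha[fixed_idx] <- fix_coefficients
  }
  p_eff <- mean(a_turb * s_prior$mean * f_prior$mean)
  if (free[1]) {
    alpha[1] <- log(max(sum(cc) / max(sum(searched), 1), 1e-3) / max(p_eff, 1e-3))
  }

  res <- chain_three_level_cpp(
    cc = cc, searched = searched, tindex = prep$tindex, X = prep$X,
    a_n = a_turb[prep$tindex], night = as.integer(nights$night),
    is_first = !duplicated(nights$turbine),
    is_last = !duplicated(nights$turbine, fromLast = TRUE),
    s_init = s_prior$mean, f_init = f_prior$mean,
    s_alpha = ifelse(s_prior$fixed, 0, s_prior$alpha),
    s_beta = ifelse(s_prior$fixed, 0, s_prior$beta),
    f_alpha = ifelse(f_prior$fixed, 0, f_prior$alpha),
    f_beta = ifelse(f_prior$fixed, 0, f_prior$beta),
    s_free = !s_prior$fixed, f_free = !f_prior$fixed,
    alpha_init = alpha, coef_free = free,
    n_iterations = cfg$n_iterations, burn_in = cfg$burn_in, thin = cfg$thin,
    proposal_scale = cfg$proposal_scale, adapt_interval = cfg$adapt_interval
  )
  list(alpha = res$alpha, detect = list(s = res$s, f = res$f), Ntot = res$Ntot)
}

assemble_fit <- function(chains, prep, model, cfg, priors, data) {
  ids <- prep$ids
  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    res <- chains[[ch]]
    d <- tibble(
      chain = ch, draw = seq_len(nrow(res$alpha)),
      alpha0 = res$alpha[, 1], alpha1 = res$alpha[, 2],
      alpha2 = res$alpha[, 3], alpha3 = res$alpha[, 4]
    )
    for (par in names(res$detect)) {
      m <- res$detect[[par]]
      colnames(m) <- paste0(par, "_", ids)
      d <- dplyr::bind_cols(d, as_tibble(m))
    }
    ntot <- res$Ntot
    colnames(ntot) <- paste0("Ntot_", ids)
    d <- dplyr::bind_cols(d, as_tibble(ntot))
    d$N_total <- rowSums(ntot)
    d
  })
  fit <- structure(
    list(
      draws = draws, model = model, turbines = ids, cfg = cfg,
      priors = priors, std_params = prep$std_params, data = data
    ),
    class = "collision_fit"
  )
  diag_cols <- c(
    "alpha0", "alpha1", "alpha2", "alpha3",
    grep("^(p|s|f)_", names(draws), value = TRUE), "N_total"
  )
  fit$rhat <- tryCatch(gelman_rubin(fit, parameters = diag_cols),
    error = function(e) NULL
  )
  if (!is.null(fit$rhat)) {
    bad <- fit$rhat$parameter[is.finite(fit$rhat$rhat) & fit$rhat$rhat > 1.1]
    fit$converged <- length(bad) == 0
    if (length(bad) > 0) {
      warning(sprintf(
        "possible non-convergence (R-hat > 1.1): %s", paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  fit
}

#' Fit the one-level collision mixture model
#'
#' Samples from the joint posterior of the collision coefficients, the
#' per-turbine detection probabilities `p_i` (informative Beta priors) and
#' the latent nightly collision counts `N_it`, under the one-level
#' observation model `c_it ~ Binomial(N_it, p_i)` and the Poisson
#' collision model `N_it ~ Poisson(lambda_it)` with
#' `log lambda = alpha0 + alpha1 zA + alpha2 zW + alpha3 zW^2`.
#'
#' Latent counts use the exact conditional
#' `N_it - c_it ~ Poisson(lambda_it (1 - p_i))`, detection probabilities
#' the conjugate Beta update, and coefficients adaptive random-walk
#' proposals (see [mcmc_config()]).
#'
#' @param data A `collision_data`, `sim_replicate`, or
#'   `list(nights, detections)`.
#' @param priors Prior table from [detection_priors()]; derived from
#'   `data$detections` when `NULL`.  Rows with `fixed = TRUE` hold the
#'   parameter at its mean.
#' @param cfg An [mcmc_config()].
#' @param fix_coefficients Optional named vector (names among
#'   `alpha0..alpha3`) of coefficients to hold fixed, e.g. for oracle
#'   checks.
#' @param params Optional standardization parameters from a previous fit
#'   (defaults to standardizing over `data`).
#' @return A `collision_fit` object; see [tidy.collision_fit()],
#'   [mortality_summary()], [predict_new()],
#'   [posterior_predictive_check()].
#' @export
fit_one_level <- function(data, priors = NULL, cfg = mcmc_config(),
                          fix_coefficients = NULL, params = NULL) {
  data <- as_fit_data(data)
  if (is.null(priors)) priors <- detection_priors(data$detections)
  prep <- prepare_fit(data, params)
  p_prior <- prior_lookup(priors, prep$ids, "p")
  chains <- purrr::map(
    seq_len(cfg$n_chains),
    ~ run_chain_one_level(prep, p_prior, cfg, .x, fix_coefficients)
  )
  assemble_fit(chains, prep, "one_level", cfg, priors, data)
}

#' Fit the three-level collision mixture model
#'
#' As [fit_one_level()], but with the explicit observation chain:
#' `fallen ~ Binomial(N, a_i)`, availability carry-over
#' `available_t = remaining_{t-1} - found_{t-1} + fallen_t`,
#' `remaining ~ Binomial(available, s_i)` and
#' `found ~ Binomial(remaining, f_i)`.  The fall-in proportion `a_i` is a
#' known constant; `s_i` and `f_i` carry informative Beta priors.  The
#' latent chain is updated by single-site integer random-walk proposals
#' that respect the recursion invariants (any violating proposal has
#' density zero); collision counts use the exact conditional
#' `N - fallen ~ Poisson(lambda (1 - a))`.
#'
#' @inheritParams fit_one_level
#' @param fall_in Optional per-turbine named vector overriding the `a`
#'   values in the priors/detection table.
#' @return A `collision_fit`.
#' @export
fit_three_level <- function(data, priors = NULL, fall_in = NULL,
                            cfg = mcmc_config(n_iterations = 100000, burn_in = 90000),
                            fix_coefficients = NULL, params = NULL) {
  data <- as_fit_data(data)
  if (is.null(priors)) priors <- detection_priors(data$detections)
  prep <- prepare_fit(data, params)
  s_prior <- prior_lookup(priors, prep$ids, "s")
  f_prior <- prior_lookup(priors, prep$ids, "f")
  if (is.null(fall_in)) {
    a_turb <- prior_lookup(priors, prep$ids, "a")$mean
  } else {
    a_turb <- unname(fall_in[as.character(prep$ids)])
    if (any(is.na(a_turb))) stop_validation("`fall_in` must name every turbine")
  }
  chains <- purrr::map(
    seq_len(cfg$n_chains),
    ~ run_chain_three_level(prep, s_prior, f_prior, a_turb, cfg, .x, fix_coefficients)
  )
  assemble_fit(chains, prep, "three_level", cfg, priors, data)
}

#' @export
print.collision_fit <- function(x, ...) {
  cat(sprintf(
    "<collision_fit: %s> %d turbines, %d draws x %d chains\n",
    x$model, length(x$turbines), max(x$draws$draw), max(x$draws$chain)
  ))
  print(tidy(x))
  invisible(x)
}

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Classic potential-scale-reduction statistic computed on the post-burn-in
#' halves of each chain (each retained chain is split in two, doubling the
#' number of sequences).  Values above 1.1 indicate non-convergence.
#'
#' @param fit A `collision_fit`, or a data frame of draws with a `chain`
#'   column.
#' @param parameters Columns to diagnose (default: all numeric parameter
#'   columns).
#' @return A tibble `parameter`, `rhat`, `flagged` (`rhat > 1.1`).
#' @export
gelman_rubin <- function(fit, parameters = NULL) {
  draws <- if (inherits(fit, "collision_fit")) fit$draws else as_tibble(fit)
  if (!"chain" %in% names(draws)) stop_validation("draws need a `chain` column")
  n_chains <- length(unique(draws$chain))
  if (n_chains < 2) stop_validation("at least 2 chains are required for R-hat")
  if (is.null(parameters)) {
    parameters <- setdiff(names(draws)[vapply(draws, is.numeric, logical(1))],
      c("chain", "draw"))
  }
  chains <- split(draws[parameters], draws$chain)
  len <- min(vapply(chains, nrow, integer(1)))
  if (len < 10) stop_validation("need at least 10 post-burn-in draws per chain")
  half <- len %/% 2
  rhat_one <- function(col) {
    seqs <- unlist(lapply(chains, function(ch) {
      x <- ch[[col]][seq_len(2 * half)]
      list(x[seq_len(half)], x[half + seq_len(half)])
    }), recursive = FALSE)
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, var, numeric(1))
    W <- mean(vars)
    B_over_n <- var(means)
    if (!is.finite(W) || W == 0) {
      return(if (!is.finite(B_over_n) || B_over_n == 0) 1 else Inf)
    }
    sqrt((half - 1) / half + B_over_n / W)
  }
  rhat <- unname(vapply(parameters, rhat_one, numeric(1)))
  tibble(parameter = parameters, rhat = rhat, flagged = is.finite(rhat) & rhat > 1.1)
}

#' Posterior mortality summaries
#'
#' Mean, median and 95% equal-tail credible interval of the latent total
#' number of collisions, per turbine or summed over all turbines
#' (draw-wise, so the total is the exact sum of the per-turbine draws).
#'
#' @param fit A `collision_fit`.
#' @param by `"total"` or `"turbine"`.
#' @return A tibble with columns `turbine` (for `by = "turbine"`), `mean`,
#'   `median`, `lower`, `upper`.
#' @export
mortality_summary <- function(fit, by = c("total", "turbine")) {
  by <- match.arg(by)
  summarise_draws <- function(x, label = NULL) {
    qs <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    out <- tibble(mean = mean(x), median = qs[2], lower = qs[1], upper = qs[3])
    if (!is.null(label)) out <- mutate(out, turbine = label, .before = 1)
    out
  }
  if (by == "total") {
    return(summarise_draws(fit$draws$N_total))
  }
  purrr::map_dfr(fit$turbines, function(id) {
    summarise_draws(fit$draws[[paste0("Ntot_", id)]], id)
  })
}

#' Predict collisions for new turbine-nights from covariates alone
#'
#' For every posterior draw of the coefficients, computes the nightly
#' rates for the supplied covariates (standardized on the training
#' scale), draws Poisson collision counts, and summarises the total —
#' the posterior predictive distribution of collisions at a turbine
#' where no carcass searches were made.
#'
#' @param fit A `collision_fit`.
#' @param covariates Night table (only `activity` and `wind` are used).
#' @param params Standardization parameters; defaults to the training
#'   parameters stored in `fit`.
#' @return A one-row tibble `mean`, `median`, `lower`, `upper` (an empty
#'   covariate table yields an exact 0 with zero width).
#' @export
predict_new <- function(fit, covariates, params = NULL) {
  if (nrow(covariates) == 0) {
    return(tibble(mean = 0, median = 0, lower = 0, upper = 0))
  }
  params <- params %||% fit$std_params
  cov <- standardize_nights(covariates, params)
  X <- cbind(1, cov$zA, cov$zW, cov$zW^2)
  A <- as.matrix(fit$draws[c("alpha0", "alpha1", "alpha2", "alpha3")])
  lam <- exp(A %*% t(X)) # draws x nights
  totals <- rpois(nrow(lam), rowSums(lam))
  qs <- quantile(totals, c(0.025, 0.5, 0.975), names = FALSE)
  tibble(mean = mean(totals), median = qs[2], lower = qs[1], upper = qs[3])
}

#' Export posterior draws as CSV
#'
#' One row per retained draw, one column per parameter, with the chain
#' label in the first column.
#'
#' @param fit A `collision_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_draws <- function(fit, path) {
  readr::write_csv(fit$draws, path)
  invisible(path)
}

#' @describeIn fit_one_level Coefficient summaries in broom layout:
#'   `term`, `estimate` (posterior mean), `std.error` (posterior sd),
#'   `conf.low`/`conf.high` (95% credible interval) and `rhat`.
#' @param x,object A `collision_fit`.
#' @param ... Unused.
#' @method tidy collision_fit
#' @export
tidy.collision_fit <- function(x, ...) {
  terms <- c("alpha0", "alpha1", "alpha2", "alpha3")
  out <- purrr::map_dfr(terms, function(tm) {
    v <- x$draws[[tm]]
    tibble(
      term = tm, estimate = mean(v), std.error = sd(v),
      conf.low = quantile(v, 0.025, names = FALSE),
      conf.high = quantile(v, 0.975, names = FALSE)
    )
  })
  if (!is.null(x$rhat)) {
    out <- left_join(out, rename(x$rhat, term = "parameter"), by = "term") %>%
      select(-dplyr::any_of("flagged"))
  }
  out
}

#' @describeIn fit_one_level One-row model overview: model variant,
#'   chains, draws, total-mortality posterior mean and interval, maximum
#'   R-hat.
#' @method glance collision_fit
#' @export
glance.collision_fit <- function(x, ...) {
  tot <- mortality_summary(x, "total")
  tibble(
    model = x$model,
    n_turbines = length(x$turbines),
    n_chains = max(x$draws$chain),
    n_draws = nrow(x$draws),
    mortality = tot$mean,
    mortality_lower = tot$lower,
    mortality_upper = tot$upper,
    max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat$rhat)
  )
}
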