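# One-level data generated from the model itself, small enough for quick
# fits.
make_one_level_data <- function(n_turbines = 3, n_nights = 40, seed = 5,
                                coef = c(-2, 0.4, -0.5, -0.3), p = 0.6) {
  set.seed(seed)
  det <- toy_detection_table(n_turbines)
  det$p <- rep_len(p, n_turbines)
  det$p_lwr <- pmax(det$p - 0.1, 0.01)
  det$p_upr <- pmin(det$p + 0.1, 0.99)
  nights <- toy_night_table(n_turbines, n_nights, seed = seed)
  zn <- standardize_nights(nights)
  lam <- expected_rate(collision_coefficients(coef[1], coef[2], coef[3], coef[4]),
    zn$zA, zn$zW)
  N <- rpois(nrow(nights), lam)
  nights$c <- rbinom(nrow(nights), N, det$p[match(nights$turbine, det$turbine)])
  list(data = list(nights = nights, detections = det), N = N)
}

test_that("sampler settings are validated", {
  expect_error(mcmc_config(burn_in = 100, n_iterations = 100),
    class = "collmix_validation_error"
  )
  expect_error(fit_one_level(list()), class = "collmix_validation_error")
})

test_that("with perfect detection the one-level posterior collapses onto the data", {
  sim <- make_one_level_data(p = 1)
  nights <- sim$data$nights
  nights$c <- sim$N # p = 1: every collision is found
  priors <- fixed_priors(1:3, p = 1)
  fit <- suppressWarnings(fit_one_level(list(nights = nights, detections = sim$data$detections),
    priors = priors,
    cfg = mcmc_config(n_iterations = 1500, burn_in = 500, seed = 2),
    fix_coefficients = c(alpha1 = 0, alpha2 = 0, alpha3 = 0)
  ))
  # latent totals equal observed totals on every draw
  for (id in fit$turbines) {
    expect_true(all(fit$draws[[paste0("Ntot_", id)]] ==
      sum(nights$c[nights$turbine == id])))
  }
  # posterior mean of exp(alpha0) tracks the mean nightly count
  rate <- exp(fit$draws$alpha0)
  expect_lt(abs(mean(rate) - mean(nights$c)), 3 * sd(rate))
})

test_that("posterior totals never fall below observed totals", {
  sim <- make_one_level_data(seed = 9)
  fit <- suppressWarnings(fit_one_level(sim$data,
    cfg = mcmc_config(n_iterations = 1200, burn_in = 400, seed = 3)
  ))
  obs <- tapply(sim$data$nights$c, sim$data$nights$turbine, sum)
  for (id in fit$turbines) {
    expect_true(all(fit$draws[[paste0("Ntot_", id)]] >= obs[[as.character(id)]]))
  }
  # the grand total is the draw-wise sum of the per-turbine totals
  ntot_cols <- paste0("Ntot_", fit$turbines)
  expect_equal(fit$draws$N_total, rowSums(fit$draws[ntot_cols]))
})

test_that("fits are bit-reproducible for a fixed configuration", {
  sim <- make_one_level_data(n_turbines = 2, n_nights = 15)
  cfg <- mcmc_config(n_iterations = 600, burn_in = 200, seed = 77)
  f1 <- suppressWarnings(fit_one_level(sim$data, cfg = cfg))
  f2 <- suppressWarnings(fit_one_level(sim$data, cfg = cfg))
  expect_identical(f1$draws, f2$draws)

  det3 <- toy_detection_table(2)
  nights3 <- sim$data$nights
  cfg3 <- mcmc_config(n_iterations = 600, burn_in = 200, seed = 78)
  g1 <- suppressWarnings(fit_three_level(list(nights = nights3, detections = det3), cfg = cfg3))
  g2 <- suppressWarnings(fit_three_level(list(nights = nights3, detections = det3), cfg = cfg3))
  expect_identical(g1$draws, g2$draws)
})

test_that("a lossless three-level chain pins totals to the observed counts", {
  nights <- toy_night_table(2, 25, seed = 31)
  nights$c <- rpois(nrow(nights), 0.3)
  det <- toy_detection_table(2)
  fit <- suppressWarnings(fit_three_level(list(nights = nights, detections = det),
    priors = fixed_priors(1:2, s = 1, f = 1, a = 1),
    cfg = mcmc_config(n_iterations = 1200, burn_in = 400, seed = 5)
  ))
  for (id in fit$turbines) {
    expect_true(all(fit$draws[[paste0("Ntot_", id)]] ==
      sum(nights$c[nights$turbine == id])))
  }
})

test_that("the classic split-chain R-hat behaves on known chains", {
  set.seed(6)
  base <- tibble::tibble(
    chain = rep(1:2, each = 1e4),
    x = rnorm(2e4),
    const = 1
  )
  rh <- gelman_rubin(base, parameters = c("x", "const"))
  expect_lt(rh$rhat[rh$parameter == "x"], 1.01)
  expect_equal(rh$rhat[rh$parameter == "const"], 1)

  # identical chains
  same <- tibble::tibble(chain = rep(1:2, each = 5000), y = rep(rnorm(5000), 2))
  expect_lt(abs(gelman_rubin(same)$rhat - 1), 1e-3)

  # chains centred 10 sd apart must be flagged
  apart <- tibble::tibble(
    chain = rep(1:2, each = 5000),
    y = rnorm(1e4) + rep(c(0, 10), each = 5000)
  )
  rh2 <- gelman_rubin(apart)
  expect_gt(rh2$rhat, 2)
  expect_true(rh2$flagged)

  expect_error(gelman_rubin(tibble::tibble(chain = 1, x = rnorm(100))),
    class = "collmix_validation_error"
  )

  # against the reference implementation (coda), same split-halves input
  x1 <- rnorm(2000)
  x2 <- rnorm(2000, 0.15)
  ours <- gelman_rubin(
    tibble::tibble(chain = rep(1:2, each = 2000), x = c(x1, x2))
  )$rhat
  halves <- function(x) list(x[1:1000], x[1001:2000])
  ml <- coda::mcmc.list(lapply(c(halves(x1), halves(x2)), coda::mcmc))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]
  expect_equal(ours, ref, tolerance = 0.01)
})

test_that("mortality summaries and broom methods expose the fit", {
  sim <- make_one_level_data(seed = 13)
  fit <- suppressWarnings(fit_one_level(sim$data,
    cfg = mcmc_config(n_iterations = 1000, burn_in = 400, seed = 4)
  ))
  tot <- mortality_summary(fit, "total")
  per <- mortality_summary(fit, "turbine")
  expect_equal(nrow(per), 3)
  expect_true(all(per$lower <= per$median & per$median <= per$upper))
  expect_equal(tot$mean, sum(per$mean), tolerance = 1e-9)

  td <- tidy(fit)
  expect_equal(td$term, c("alpha0", "alpha1", "alpha2", "alpha3"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$model, "one_level")
  expect_equal(gl$n_chains, 2)

  path <- withr::local_tempfile(fileext = ".csv")
  export_draws(fit, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(fit$draws))
  expect_true(all(c("chain", "alpha0", "N_total") %in% names(back)))

  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate posterior summaries are exact", {
  fake <- structure(
    list(
      draws = tibble::tibble(
        chain = 1, draw = 1:50, Ntot_1 = 40, N_total = 40
      ),
      turbines = 1
    ),
    class = "collision_fit"
  )
  ms <- mortality_summary(fake, "total")
  expect_equal(unlist(ms), c(mean = 40, median = 40, lower = 40, upper = 40))
})

test_that("posterior prediction from covariates has the right expectation", {
  sim <- make_one_level_data(n_turbines = 2, n_nights = 10)
  coef <- c(-1.5, 0.3, -0.4, -0.2)
  draws <- tibble::tibble(
    chain = 1, draw = 1:4000,
    alpha0 = coef[1], alpha1 = coef[2], alpha2 = coef[3], alpha3 = coef[4]
  )
  params <- identity_params()
  fake <- structure(list(draws = draws, std_params = params), class = "collision_fit")
  cov <- tibble::tibble(activity = c(0, 1, 2), wind = c(0, 1, -1))
  lam <- exp(coef[1] + coef[2] * cov$activity + coef[3] * cov$wind + coef[4] * cov$wind^2)
  set.seed(3)
  pred <- predict_new(fake, cov)
  mc_se <- sqrt(sum(lam) / nrow(draws))
  expect_lt(abs(pred$mean - sum(lam)), 4 * mc_se)

  expect_equal(
    predict_new(fake, cov[0, ]),
    tibble::tibble(mean = 0, median = 0, lower = 0, upper = 0)
  )
})
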