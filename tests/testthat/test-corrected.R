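# Brute-force oracle: flat prior on N, binomial search likelihood,
# normalized over N in [C, C + horizon].
enumerated_posterior <- function(C, p, horizon = 400) {
  N <- C:(C + horizon)
  w <- dbinom(C, N, p)
  tibble::tibble(N = N, prob = w / sum(w))
}

test_that("the flat-prior inversion matches brute-force enumeration", {
  post <- posterior_given_p(5, 0.5)
  oracle <- enumerated_posterior(5, 0.5)
  expect_equal(attr(post, "mean"), sum(oracle$N * oracle$prob), tolerance = 1e-9)
  expect_equal(attr(post, "mean"), 11) # (C + 1) / p - 1
  m <- min(nrow(post), nrow(oracle))
  expect_equal(post$prob[1:m], oracle$prob[1:m], tolerance = 1e-9)

  # the published 2007 totals: 22 found at pooled detection 0.586
  expect_equal(attr(posterior_given_p(22, 0.586), "mean"), 23 / 0.586 - 1,
    tolerance = 1e-12
  )
  expect_equal(round(attr(posterior_given_p(22, 0.586), "mean"), 2), 38.25)

  # perfect detection pins the posterior at the observed count
  post0 <- posterior_given_p(0, 1)
  expect_equal(post0$N, 0)
  expect_equal(post0$prob, 1)
  expect_equal(attr(post0, "mean"), 0)

  expect_error(posterior_given_p(3, 0), class = "collmix_validation_error")
})

test_that("a point-mass detection prior reduces to the closed form", {
  prior <- beta_from_moments(0.6, 1e-9) # degenerate
  est <- estimate_corrected(10, prior, n_draws = 1000)
  expect_equal(est$mean, 11 / 0.6 - 1, tolerance = 1e-9)
  post <- posterior_given_p(10, 0.6)
  cum <- cumsum(post$prob)
  expect_equal(est$lower, post$N[which(cum >= 0.025)[1]])
  expect_equal(est$upper, post$N[which(cum >= 0.975)[1]])
})

test_that("Monte-Carlo mixtures match numerical integration over the prior", {
  prior <- beta_from_moments(0.5, 0.08)
  set.seed(4)
  est <- estimate_corrected(6, prior, n_draws = 1e5)

  # integrate the negative-binomial posterior over the Beta density
  p_grid <- seq(1e-4, 1 - 1e-4, length.out = 4001)
  dens <- dbeta(p_grid, prior$alpha, prior$beta)
  dens <- dens / sum(dens)
  N <- 6:400
  pmf <- vapply(N, function(nn) {
    sum(dens * dnbinom(nn - 6, size = 7, prob = p_grid))
  }, numeric(1))
  pmf <- pmf / sum(pmf)
  exact_mean <- sum(N * pmf)
  cum <- cumsum(pmf)
  exact_q <- c(N[which(cum >= 0.025)[1]], N[which(cum >= 0.975)[1]])

  expect_lt(abs(est$mean - exact_mean), 0.3)
  expect_lte(abs(est$lower - exact_q[1]), 1)
  expect_lte(abs(est$upper - exact_q[2]), 1)

  # Jensen: averaging over p increases the mean beyond the plug-in value
  expect_gte(est$mean, attr(posterior_given_p(6, 0.5), "mean"))
})

test_that("corrected counts are monotone in effort and detection", {
  prior_hi <- beta_from_moments(0.8, 0.05)
  prior_lo <- beta_from_moments(0.4, 0.05)
  set.seed(1)
  e1 <- estimate_corrected(10, prior_hi, 2e4)
  set.seed(1)
  e2 <- estimate_corrected(10, prior_lo, 2e4)
  expect_lt(e1$mean, e2$mean)
  set.seed(1)
  e3 <- estimate_corrected(20, prior_hi, 2e4)
  expect_lt(e1$mean, e3$mean)
  expect_error(estimate_corrected(10, prior_hi, 500), class = "collmix_validation_error")
})

test_that("pooled estimates reproduce the published season totals", {
  det <- example_detection_table()
  set.seed(2)
  e07 <- estimate_corrected_per_turbine(dplyr::filter(det, year == 2007),
    mode = "pooled", n_draws = 1e5
  )
  expect_equal(e07$C, 22)
  expect_lt(abs(e07$mean - 38), 3)
  e08 <- estimate_corrected_per_turbine(dplyr::filter(det, year == 2008),
    mode = "pooled", n_draws = 1e5
  )
  expect_equal(e08$C, 35)
  expect_lt(abs(e08$mean - 57), 3)
})

test_that("per-turbine mode matches pooling for a single turbine", {
  det <- example_detection_table()[3, ]
  set.seed(7)
  pooled <- estimate_corrected_per_turbine(det, "pooled", n_draws = 1e5)
  set.seed(7)
  per <- estimate_corrected_per_turbine(det, "per_turbine", n_draws = 1e5)
  expect_equal(per$mean, pooled$mean, tolerance = 0.05)
  expect_equal(nrow(per), 1)

  # zero carcasses at poor detection still imply possible unseen kills
  zero <- toy_detection_row(C = 0L, p = 0.19)
  set.seed(8)
  z <- estimate_corrected_per_turbine(zero, "per_turbine", n_draws = 1e4)
  expect_gt(z$mean, 0)

  expect_error(estimate_corrected_per_turbine(det[0, ], "pooled"),
    class = "collmix_validation_error"
  )
})
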