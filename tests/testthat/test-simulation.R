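test_that("parametric covariates match the configured wind climate", {
  cfg <- sim_config(n_turbines = 10, nights_per_turbine = 1000, seed = 1)
  set.seed(5)
  cov <- generate_covariates(cfg)
  # CLT bound: sd 1.8 over 10^4 nights
  expect_lt(abs(mean(cov$wind) - 5.5), 0.06)
  expect_true(all(cov$wind >= 0))
  expect_true(all(cov$activity >= 0))
  # bats fly less in strong wind
  expect_lt(cor(cov$activity, cov$wind, method = "spearman"), 0)
})

test_that("bootstrap covariates resample observed (activity, wind) pairs", {
  one_row <- tibble::tibble(turbine = 1, night = 1, activity = 7L, wind = 3.2)
  cfg <- sim_config(
    n_turbines = 2, nights_per_turbine = 5,
    covariates = one_row, seed = 1
  )
  set.seed(1)
  cov <- generate_covariates(cfg)
  expect_true(all(cov$activity == 7L))
  expect_true(all(cov$wind == 3.2))

  # pairs stay intact: every drawn pair occurs in the source table
  src <- toy_night_table(2, 20)
  cfg2 <- sim_config(n_turbines = 2, nights_per_turbine = 30, covariates = src, seed = 1)
  set.seed(2)
  cov2 <- generate_covariates(cfg2)
  keys <- paste(cov2$activity, cov2$wind)
  expect_true(all(keys %in% paste(src$activity, src$wind)))

  cfg_empty <- sim_config(covariates = src[0, ], seed = 1)
  expect_error(generate_covariates(cfg_empty), class = "collmix_validation_error")
})

test_that("simulated replicates obey the observation-chain invariants", {
  cfg <- sim_config(n_turbines = 6, nights_per_turbine = 40, n_replicates = 10, seed = 3)
  for (r in 1:10) {
    rep <- simulate_replicate(cfg, r)
    tr <- rep$truth
    expect_true(all(tr$fallen <= tr$N))
    expect_true(all(tr$remaining <= tr$available))
    expect_true(all(tr$found <= tr$remaining))
    expect_lte(sum(rep$nights$c), sum(tr$N))
    expect_equal(rep$nights$c, tr$found)
    for (i in unique(tr$turbine)) {
      ti <- tr[tr$turbine == i, ]
      prev_rem <- c(0L, ti$remaining[-nrow(ti)])
      prev_fnd <- c(0L, ti$found[-nrow(ti)])
      expect_equal(ti$available, prev_rem - prev_fnd + ti$fallen)
    }
  }
})

test_that("a lossless observation chain returns every collision", {
  det <- toy_detection_row(a = 1, s = 1, f = 1)
  det$s_lwr <- det$s_upr <- 1
  cfg <- sim_config(
    n_turbines = 3, nights_per_turbine = 50,
    detection = det, seed = 9
  )
  rep <- simulate_replicate(cfg, 1)
  expect_equal(sum(rep$nights$c), sum(rep$truth$N))
})

test_that("the collision process has the configured Poisson rate", {
  cfg <- sim_config(
    n_turbines = 10, nights_per_turbine = 1000,
    coefficients = c(-3, 0, 0, 0), seed = 11
  )
  rep <- simulate_replicate(cfg, 1)
  n <- nrow(rep$truth)
  mc_se <- sqrt(exp(-3) / n)
  expect_lt(abs(mean(rep$truth$N) - exp(-3)), 3 * mc_se)
})

test_that("replicates are deterministic in (config, replicate index)", {
  cfg <- sim_config(n_turbines = 3, nights_per_turbine = 20, seed = 42)
  r1 <- simulate_replicate(cfg, 2)
  r2 <- simulate_replicate(cfg, 2)
  expect_identical(r1$nights, r2$nights)
  expect_identical(r1$truth, r2$truth)
  r3 <- simulate_replicate(cfg, 1)
  expect_false(identical(r1$nights$c, r3$nights$c) &&
    identical(r1$nights$wind, r3$nights$wind))
})

test_that("default study conditions give sparse found counts", {
  cfg <- sim_config(seed = 2)
  rep <- simulate_replicate(cfg, 1)
  expect_lt(mean(rep$nights$c > 0), 0.10)
})

test_that("train/test splits hold out exactly one turbine", {
  cfg <- sim_config(n_turbines = 18, nights_per_turbine = 10, seed = 5)
  rep <- simulate_replicate(cfg, 1)
  set.seed(1)
  sp <- train_test_split(rep)
  expect_length(unique(sp$train$nights$turbine), 17)
  expect_length(unique(sp$test$nights$turbine), 1)
  expect_false(sp$held_out %in% sp$train$nights$turbine)
  # truth travels with the split
  expect_setequal(unique(sp$train$truth$turbine), unique(sp$train$nights$turbine))

  set.seed(1)
  sp2 <- train_test_split(rep)
  expect_identical(sp$held_out, sp2$held_out)

  expect_error(train_test_split(rep, held_out = 99), class = "collmix_validation_error")

  cfg2 <- sim_config(n_turbines = 2, nights_per_turbine = 5, seed = 5)
  rep2 <- simulate_replicate(cfg2, 1)
  sp3 <- train_test_split(rep2, held_out = 2)
  expect_length(unique(sp3$train$nights$turbine), 1)
})
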