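test_that("one-level observation model matches binomial behaviour", {
  expect_equal(simulate_one_level(5L, 1), 5L)
  expect_equal(simulate_one_level(0L, 0.3), 0L)

  set.seed(7)
  reps <- simulate_one_level(rep(10L, 1e5), 0.5)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 5), 3 * se)

  expect_equal(loglik_one_level(1L, 2L, 0.5), log(0.5), tolerance = 1e-12)
  expect_equal(loglik_one_level(0L, 0L, 0.7), 0)
  expect_error(loglik_one_level(3L, 2L, 0.5),
    class = "collmix_impossible_observation_error"
  )
})

test_that("the three-level transition follows the carry-over recursion", {
  # deterministic fall-in: available = remaining - found + new
  set.seed(1)
  st <- step_three_level(3L, 1L, 2L, a = 1, s = 0.5, f = 0.5)
  expect_equal(st$fallen, 2L)
  expect_equal(st$available, 4L)

  # lossless chain: everything is found each night
  st <- step_three_level(5L, 5L, 4L, a = 1, s = 1, f = 1)
  expect_equal(st$found, 4L)
  expect_equal(st$available, 4L)

  # first night with certain fall-in: all collisions are available
  st <- step_three_level(0L, 0L, 7L, a = 1, s = 0.4, f = 0.4)
  expect_equal(st$available, 7L)

  expect_error(step_three_level(1L, 2L, 0L, 1, 1, 1), class = "collmix_state_error")
})

test_that("simulated paths conserve carcasses and respect the chain invariants", {
  set.seed(11)
  for (i in 1:20) {
    N <- rpois(30, 0.8)
    path <- simulate_three_level_path(N, a = 0.9, s = 0.8, f = 0.6)
    expect_true(all(path$fallen <= path$N))
    expect_true(all(path$remaining <= path$available))
    expect_true(all(path$found <= path$remaining))
    prev_rem <- c(0L, path$remaining[-nrow(path)])
    prev_fnd <- c(0L, path$found[-nrow(path)])
    expect_equal(path$available, prev_rem - prev_fnd + path$fallen)
    expect_lte(sum(path$found), sum(path$N))
  }
  # lossless limit: a search every night with a = s = f = 1 finds everything
  N <- rpois(50, 1.5)
  path <- simulate_three_level_path(N, 1, 1, 1)
  expect_equal(sum(path$found), sum(N))
})

test_that("first-night detection has expectation N * a * s * f", {
  set.seed(23)
  a <- 0.9
  s <- 0.7
  f <- 0.6
  N <- 8L
  found <- replicate(1e5, step_three_level(0L, 0L, N, a, s, f)$found)
  se <- sd(found) / sqrt(length(found))
  expect_lt(abs(mean(found) - N * a * s * f), 3 * se)
})

test_that("unsearched nights thin by persistence but are not searched", {
  set.seed(3)
  N <- c(5L, 0L, 0L)
  path <- simulate_three_level_path(N, a = 1, s = 1, f = 1,
    searched = c(FALSE, FALSE, TRUE))
  expect_equal(path$found[1:2], c(0L, 0L))
  # with s = 1 nothing scavenges, so the last search finds all five
  expect_equal(path$found[3], 5L)
})

test_that("three-level path log-likelihood matches hand evaluation", {
  one_night <- tibble::tibble(N = 1L, fallen = 1L, remaining = 1L)
  expect_equal(loglik_three_level_path(one_night, 1L, 1, 1, 1), 0)
  expect_equal(loglik_three_level_path(one_night, 1L, 0.5, 0.5, 0.5),
    3 * log(0.5),
    tolerance = 1e-12
  )
  # found > remaining is impossible
  bad <- tibble::tibble(N = 2L, fallen = 2L, remaining = 1L)
  expect_identical(loglik_three_level_path(bad, 2L, 0.5, 0.5, 0.5), -Inf)
  expect_error(loglik_three_level_path(one_night, c(1L, 0L), 1, 1, 1),
    class = "collmix_validation_error"
  )

  # two-night path with carry-over, against explicit binomial terms
  states <- tibble::tibble(N = c(2L, 0L), fallen = c(2L, 0L), remaining = c(2L, 1L))
  counts <- c(1L, 1L)
  a <- 0.9
  s <- 0.8
  f <- 0.6
  manual <- dbinom(2, 2, a, log = TRUE) + dbinom(2, 2, s, log = TRUE) +
    dbinom(1, 2, f, log = TRUE) +
    dbinom(0, 0, a, log = TRUE) + dbinom(1, 1, s, log = TRUE) +
    dbinom(1, 1, f, log = TRUE)
  expect_equal(loglik_three_level_path(states, counts, a, s, f), manual,
    tolerance = 1e-12
  )
})
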