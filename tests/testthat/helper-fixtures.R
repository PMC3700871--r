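# Small in-code fixtures shared across test files.

# A minimal detection-table row with round numbers.
toy_detection_row <- function(turbine = 1L, year = 2008L, C = 2L, T_ = 10L,
                              a = 0.9, s = 0.8, f = 0.7, p = 0.5) {
  tibble::tibble(
    turbine = turbine, year = year, C = C, `T` = T_, a = a,
    s = s, s_lwr = max(s - 0.1, 0), s_upr = min(s + 0.1, 1),
    f = f, f_lwr = max(f - 0.1, 0), f_upr = min(f + 0.1, 1),
    p = p, p_lwr = max(p - 0.1, 0), p_upr = min(p + 0.1, 1)
  )
}

toy_detection_table <- function(n = 2) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) toy_detection_row(turbine = i)))
}

# A tiny night table: `n_turbines` x `n_nights`, all searched, counts zero
# unless given.
toy_night_table <- function(n_turbines = 2, n_nights = 3, c = 0L, seed = 42) {
  set.seed(seed)
  n <- n_turbines * n_nights
  tibble::tibble(
    turbine = rep(seq_len(n_turbines), each = n_nights),
    night = rep(seq_len(n_nights), times = n_turbines),
    c = rep_len(c, n),
    activity = rpois(n, 10),
    wind = round(runif(n, 2, 9), 2),
    searched = TRUE
  )
}

# Degenerate (fixed-value) prior rows for given parameter means.
fixed_priors <- function(turbines, p = 1, s = 1, f = 1, a = 1) {
  purrr::map_dfr(turbines, function(id) {
    tibble::tibble(
      turbine = id, parameter = c("p", "s", "f", "a"),
      alpha = NA_real_, beta = NA_real_,
      mean = c(p, s, f, a), se = 0, fixed = TRUE
    )
  })
}

# Standardization params that leave chosen covariate values at fixed
# z-scores (z = value - centre with sd 1).
identity_params <- function(activity_centre = 0, wind_centre = 0) {
  tibble::tibble(
    covariate = c("activity", "wind"),
    mean = c(activity_centre, wind_centre), sd = c(1, 1)
  )
}
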