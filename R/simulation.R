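#' Configuration for the collision-data simulator
#'
#' The simulator reproduces the generative process of the model end to
#' end: nightly covariates, a Poisson collision process on the log-linear
#' rate, and the three-level observation chain (fall-in, persistence with
#' carry-over, search) that turns collisions into found carcasses.
#'
#' Covariates come either from a parametric generator (wind from a
#' truncated normal; acoustic activity from a negative binomial whose log
#' mean decreases linearly with standardized wind, reproducing the
#' negative activity-wind correlation of field data) or from a
#' non-parametric bootstrap of an observed night table, resampling
#' (activity, wind) pairs within turbine so their correlation is
#' preserved.
#'
#' @param n_turbines Number of turbines.
#' @param nights_per_turbine Nights simulated per turbine.
#' @param n_replicates Number of replicate data sets for simulation
#'   studies.
#' @param coefficients Either a length-4 vector of collision coefficients
#'   (intercept, activity, wind, wind^2) used for every replicate, or a
#'   data frame of posterior draws with columns `alpha0..alpha3` from
#'   which one row is drawn per replicate.
#' @param detection Detection table supplying per-turbine `a`, `s`, `f`
#'   (rows recycled if fewer than `n_turbines`).  Defaults to the bundled
#'   turbines sampled in 2008.
#' @param covariates `"parametric"`, or a night table to bootstrap from.
#' @param wind_mean,wind_sd Parametric wind moments (m/s).
#' @param activity_log_mean Log mean of nightly activity at average wind.
#' @param activity_wind_slope Change of log mean activity per sd of wind
#'   (negative: bats fly less in strong wind).
#' @param activity_size Negative-binomial dispersion (size) of activity.
#' @param seed Base seed; replicate `r` derives its own sub-seed from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_turbines = 18,
                       nights_per_turbine = 100,
                       n_replicates = 50,
                       coefficients = c(-4.1, 0.5, -2.9, -1.3),
                       detection = NULL,
                       covariates = "parametric",
                       wind_mean = 5.5,
                       wind_sd = 1.8,
                       activity_log_mean = 2.41,
                       activity_wind_slope = -0.6,
                       activity_size = 0.8,
                       seed = 1L) {
  if (is.null(detection)) {
    detection <- filter(example_detection_table(), .data$year == 2008)
  }
  if (n_turbines < 1 || nights_per_turbine < 1 || n_replicates < 1) {
    stop_validation("turbine, night and replicate counts must be positive")
  }
  if (is.numeric(coefficients) && length(coefficients) != 4) {
    stop_validation("`coefficients` must have 4 elements (alpha0..alpha3)")
  }
  structure(
    list(
      n_turbines = as.integer(n_turbines),
      nights_per_turbine = as.integer(nights_per_turbine),
      n_replicates = as.integer(n_replicates),
      coefficients = coefficients,
      detection = detection,
      covariates = covariates,
      wind_mean = wind_mean, wind_sd = wind_sd,
      activity_log_mean = activity_log_mean,
      activity_wind_slope = activity_wind_slope,
      activity_size = activity_size,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate nightly covariates
#'
#' Draws (activity, wind) pairs for every simulated turbine-night, either
#' parametrically or by within-turbine bootstrap from an observed night
#' table (see [sim_config()]).  Uses the current RNG state; seed handling
#' is done by [simulate_replicate()].
#'
#' @param cfg A [sim_config()].
#' @return A tibble with `turbine`, `night`, `activity`, `wind`.
#' @export
generate_covariates <- function(cfg) {
  n <- cfg$n_turbines * cfg$nights_per_turbine
  turbine <- rep(seq_len(cfg$n_turbines), each = cfg$nights_per_turbine)
  night <- rep(seq_len(cfg$nights_per_turbine), times = cfg$n_turbines)
  if (is.data.frame(cfg$covariates)) {
    src <- cfg$covariates
    if (nrow(src) == 0) stop_validation("cannot bootstrap covariates from an empty table")
    ids <- unique(src$turbine)
    by_id <- split(seq_len(nrow(src)), src$turbine)
    rows <- unlist(lapply(seq_len(cfg$n_turbines), function(i) {
      pool <- by_id[[as.character(ids[((i - 1) %% length(ids)) + 1])]]
      pool[sample.int(length(pool), cfg$nights_per_turbine, replace = TRUE)]
    }))
    activity <- src$activity[rows]
    wind <- src$wind[rows]
  } else {
    wind <- rnorm(n, cfg$wind_mean, cfg$wind_sd)
    while (any(wind < 0)) {
      neg <- wind < 0
      wind[neg] <- rnorm(sum(neg), cfg$wind_mean, cfg$wind_sd)
    }
    zw <- (wind - cfg$wind_mean) / cfg$wind_sd
    mu <- exp(cfg$activity_log_mean + cfg$activity_wind_slope * zw)
    activity <- rnbinom(n, size = cfg$activity_size, mu = mu)
  }
  tibble(turbine = turbine, night = night, activity = activity, wind = wind)
}

#' Simulate one replicate data set
#'
#' Runs the full generative chain: covariates, coefficient selection,
#' nightly Poisson collisions on the log-linear rate (covariates
#' standardized over the replicate), and the three-level observation
#' chain per turbine with its `a`, `s`, `f`.  Searches take place every
#' night.
#'
#' @param cfg A [sim_config()].
#' @param replicate Replicate index (1-based); together with `cfg$seed` it
#'   fully determines the output.
#' @return A list of class `sim_replicate` with elements `nights` (night
#'   table including found counts `c`), `truth` (latent `N`, `fallen`,
#'   `available`, `remaining` per turbine-night and the per-turbine totals
#'   attribute), `coefficients`, `detection` and `std_params`.
#' @export
simulate_replicate <- function(cfg, replicate = 1L) {
  if (replicate < 1 || replicate > cfg$n_replicates) {
    stop_validation("`replicate` outside 1..n_replicates")
  }
  set.seed(derive_seed(cfg$seed, replicate))
  cov <- generate_covariates(cfg)
  cov <- standardize_nights(cov)
  if (is.data.frame(cfg$coefficients)) {
    row <- cfg$coefficients[sample.int(nrow(cfg$coefficients), 1), ]
    coef <- collision_coefficients(row$alpha0, row$alpha1, row$alpha2, row$alpha3)
  } else {
    coef <- collision_coefficients(
      cfg$coefficients[1], cfg$coefficients[2], cfg$coefficients[3], cfg$coefficients[4]
    )
  }
  det <- cfg$detection[((seq_len(cfg$n_turbines) - 1) %% nrow(cfg$detection)) + 1, ]
  det$turbine <- seq_len(cfg$n_turbines)
  lambda <- expected_rate(coef, cov$zA, cov$zW)
  N <- rpois(nrow(cov), lambda)
  truth <- purrr::map_dfr(seq_len(cfg$n_turbines), function(i) {
    idx <- cov$turbine == i
    path <- simulate_three_level_path(N[idx], det$a[i], det$s[i], det$f[i])
    mutate(path, turbine = i, .before = 1)
  })
  nights <- cov %>%
    select("turbine", "night", "activity", "wind") %>%
    mutate(c = truth$found, searched = TRUE) %>%
    select("turbine", "night", "c", "activity", "wind", "searched")
  structure(
    list(
      nights = nights,
      truth = truth,
      coefficients = coef,
      detection = det,
      std_params = attr(cov, "std_params")
    ),
    class = "sim_replicate"
  )
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf(
    "<sim_replicate> %d turbines x %d nights: %d collisions, %d carcasses found\n",
    length(unique(x$nights$turbine)), max(x$nights$night),
    sum(x$truth$N), sum(x$nights$c)
  ))
  invisible(x)
}

#' True collision totals of a simulated replicate
#'
#' @param rep A `sim_replicate`.
#' @return Tibble `turbine`, `true_total`.
#' @export
true_totals <- function(rep) {
  rep$truth %>%
    group_by(.data$turbine) %>%
    summarise(true_total = sum(.data$N), .groups = "drop")
}

#' Split a simulated replicate into training and test turbines
#'
#' One turbine is held out to play the role of a new, unsearched turbine
#' whose collisions are predicted from covariates alone; the remainder
#' form the training set.
#'
#' @param rep A `sim_replicate`.
#' @param held_out A turbine id, or `"random"` to select one at random
#'   (uses the current RNG state).
#' @return A list with `train` and `test`, each a `sim_replicate`-shaped
#'   list restricted to its turbines, and `held_out`, the id chosen.
#' @export
train_test_split <- function(rep, held_out = "random") {
  ids <- unique(rep$nights$turbine)
  if (length(ids) < 2) stop_validation("need at least 2 turbines to split")
  if (identical(held_out, "random")) {
    held_out <- ids[sample.int(length(ids), 1)]
  } else if (!held_out %in% ids) {
    stop_validation(sprintf("unknown turbine '%s'", held_out))
  }
  subset_rep <- function(keep) {
    structure(
      list(
        nights = filter(rep$nights, .data$turbine %in% keep),
        truth = filter(rep$truth, .data$turbine %in% keep),
        coefficients = rep$coefficients,
        detection = filter(rep$detection, .data$turbine %in% keep),
        std_params = rep$std_params
      ),
      class = "sim_replicate"
    )
  }
  list(
    train = subset_rep(setdiff(ids, held_out)),
    test = subset_rep(held_out),
    held_out = held_out
  )
}
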