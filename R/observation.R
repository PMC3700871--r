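#' One-level observation model
#'
#' In the one-level model the carcasses found at a search are a binomial
#' thinning of the collisions of that same night:
#' `c ~ Binomial(N, p)` with `p` the composite carcass detection
#' probability.  Carry-over of overlooked carcasses to later searches is
#' not represented.
#'
#' @param N Number of collisions (non-negative integer, vectorized).
#' @param p Detection probability (scalar or vector).
#' @return `simulate_one_level()`: simulated counts; `loglik_one_level()`:
#'   the exact log binomial pmf (`-Inf` for impossible observations raises
#'   an error when `c > N`).
#' @examples
#' simulate_one_level(5, 1) # 5
#' loglik_one_level(1, 2, 0.5) # log(0.5)
#' @export
simulate_one_level <- function(N, p) {
  if (!is_count(N)) stop_validation("`N` must be non-negative integer(s)")
  if (!is_probability(p)) stop_validation("`p` must be probabilities in [0, 1]")
  rbinom(length(N), size = N, prob = p)
}

#' @rdname simulate_one_level
#' @param c Carcasses found (non-negative integer, `c <= N`).
#' @export
loglik_one_level <- function(c, N, p) {
  if (!is_count(c) || !is_count(N)) stop_validation("counts must be non-negative integers")
  if (any(c > N)) {
    abort_collmix("impossible observation: c > N",
      class = "collmix_impossible_observation_error"
    )
  }
  sum(dbinom(c, size = N, prob = p, log = TRUE))
}

#' Three-level observation chain: one night's transition
#'
#' The three-level model decomposes detection into (1) falling into the
#' searched area, (2) persisting on the ground until the search (not being
#' scavenged) and (3) being found by the searcher.  Unfound carcasses
#' remain available and can be found at later searches; found carcasses
#' are removed from the field.  For night `t`:
#'
#' * `fallen ~ Binomial(N_new, a)`
#' * `available = prev_remaining - prev_found + fallen` (night 1:
#'   `available = fallen`, no carcasses present at the start)
#' * `remaining ~ Binomial(available, s)`
#' * `found ~ Binomial(remaining, f)` when the night is searched, else 0.
#'
#' @param prev_remaining,prev_found State after the previous night's
#'   search (both 0 on night 1).
#' @param N_new Collisions during the night.
#' @param a,s,f Fall-in proportion, daily persistence probability and
#'   searcher efficiency.
#' @param searched Whether a search takes place at the end of the night;
#'   unsearched nights undergo the persistence thinning only.
#' @return A list with `fallen`, `available`, `remaining`, `found`.
#' @export
step_three_level <- function(prev_remaining, prev_found, N_new, a, s, f,
                             searched = TRUE) {
  if (any(prev_found > prev_remaining)) {
    abort_collmix("state corruption: prev_found > prev_remaining",
      class = "collmix_state_error"
    )
  }
  n <- length(N_new)
  fallen <- rbinom(n, size = N_new, prob = a)
  available <- prev_remaining - prev_found + fallen
  remaining <- rbinom(n, size = available, prob = s)
  found <- ifelse(rep_len(searched, n), rbinom(n, size = remaining, prob = f), 0L)
  list(fallen = fallen, available = available, remaining = remaining, found = found)
}

#' Simulate a full three-level observation path for one turbine
#'
#' Applies [step_three_level()] across consecutive nights, starting with
#' an empty field.
#'
#' @param N Vector of nightly collision counts.
#' @param a,s,f Detection parameters (scalars, or vectors of
#'   `length(N)` for time-varying parameters).
#' @param searched Logical vector (recycled) of search nights.
#' @return A tibble with columns `night`, `N`, `fallen`, `available`,
#'   `remaining`, `found`.
#' @export
simulate_three_level_path <- function(N, a, s, f, searched = TRUE) {
  T_n <- length(N)
  a <- rep_len(a, T_n)
  s <- rep_len(s, T_n)
  f <- rep_len(f, T_n)
  searched <- rep_len(searched, T_n)
  fallen <- available <- remaining <- found <- integer(T_n)
  prev_rem <- prev_found <- 0L
  for (t in seq_len(T_n)) {
    st <- step_three_level(prev_rem, prev_found, N[t], a[t], s[t], f[t], searched[t])
    fallen[t] <- st$fallen
    available[t] <- st$available
    remaining[t] <- st$remaining
    found[t] <- st$found
    prev_rem <- st$remaining
    prev_found <- st$found
  }
  tibble(
    night = seq_len(T_n), N = N, fallen = fallen, available = available,
    remaining = remaining, found = found
  )
}

#' Log-likelihood of a three-level latent path
#'
#' Sums the three binomial log-pmfs per night for a complete latent state
#' sequence against the observed counts; paths violating the recursion
#' invariants have probability zero (`-Inf`).
#'
#' @param states Tibble/data frame with columns `N`, `fallen`, `remaining`
#'   for consecutive nights of one turbine.
#' @param counts Observed found counts per night (vector or a night-table
#'   slice with columns `c` and `searched`).
#' @param a,s,f Detection parameters (scalar or per-night).
#' @return Total log-likelihood (possibly `-Inf`).
#' @export
loglik_three_level_path <- function(states, counts, a, s, f) {
  if (is.data.frame(counts)) {
    searched <- counts$searched
    counts <- counts$c
  } else {
    searched <- rep(TRUE, length(counts))
  }
  T_n <- length(counts)
  if (nrow(states) != T_n) stop_validation("states and counts differ in length")
  a <- rep_len(a, T_n)
  s <- rep_len(s, T_n)
  f <- rep_len(f, T_n)
  N <- states$N
  fallen <- states$fallen
  remaining <- states$remaining
  prev_rem <- c(0L, remaining[-T_n])
  prev_found <- c(0L, counts[-T_n])
  available <- prev_rem - prev_found + fallen
  if (any(fallen > N) || any(available < 0) || any(remaining > available) ||
    any(counts > remaining)) {
    return(-Inf)
  }
  ll <- sum(dbinom(fallen, N, a, log = TRUE)) +
    sum(dbinom(remaining, available, s, log = TRUE)) +
    sum(dbinom(counts[searched], remaining[searched], f[searched], log = TRUE))
  ll
}
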