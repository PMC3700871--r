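# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals.  base::round() rounds
# half to even, which would turn 4.25 into 4.2; reported wind optima use
# the conventional half-up rule.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Abort with a consistent error class so callers/tests can distinguish
# validation problems from R-level errors.
abort_collmix <- function(message, class) {
  rlang::abort(message, class = c(class, "collmix_error"))
}

stop_validation <- function(message) abort_collmix(message, "collmix_validation_error")
stop_format <- function(message) abort_collmix(message, "collmix_format_error")

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))

is_probability <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

check_scalar_prob <- function(x, name) {
  if (length(x) != 1 || !is_probability(x)) {
    stop_validation(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

# Derive a per-chain / per-replicate seed that stays inside the 32-bit
# integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483629) + 1L
}

`%||%` <- rlang::`%||%`
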