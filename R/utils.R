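#' @importFrom stats rnorm runif
#' @importFrom utils head tail
NULL

# Condition constructors -------------------------------------------------

abort_enose <- function(message, class, ...) {
  stop(rlang::error_cnd(
    class = c(class, "enose_error"),
    message = message, ...
  ))
}

#' Signal a validation error (invariant violation on records or metadata)
#' @noRd
abort_validation <- function(message, ...) {
  abort_enose(message, "enose_validation_error", ...)
}

#' Signal a contract error (caller broke a precondition)
#' @noRd
abort_contract <- function(message, ...) {
  abort_enose(message, "enose_contract_error", ...)
}

# Seed handling ----------------------------------------------------------

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Derive independent child seeds from a master seed
#'
#' Spawns `n` seeds (each in `[1, 2^31 - 2]`) deterministically from a master
#' seed, so that per-experiment randomness is independent and individually
#' reproducible.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Small numeric helpers --------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Short stable hash of an R object (for config provenance stamps)
#' @noRd
config_hash <- function(x) rlang::hash(x)
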