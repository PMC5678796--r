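## Seeding policy: one top-level seed per scenario; per-replicate substreams
## from L'Ecuyer-CMRG so replicate r is reproducible in isolation and a grid
## can be parallelized without changing results. Sample-size-search
## evaluations key their stream on (seed, n) so any two arms evaluating the
## same n see identical cohorts.

#' Derive a child seed from a parent seed and integer keys
#'
#' Deterministic integer mixing (multiplicative-congruential steps modulo
#' 2^31 - 1) used to split one top-level seed into per-scenario,
#' per-evaluation and fresh-validation seeds. The result is always a strictly
#' positive integer below 2^31, valid for [set.seed()].
#'
#' @param seed integer scalar, the parent seed.
#' @param ... one or more integer keys (e.g. a scenario counter, a sample
#'   size).
#' @return a positive integer scalar.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 1, 250) # nested keys give a different child
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed), length(keys) >= 1L,
            all(is.finite(keys)))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- (abs(as.numeric(seed)) %% m)
  for (k in as.numeric(keys)) {
    # two Lehmer-style steps keep successive keys well separated
    x <- (x * 48271 + (abs(k) %% m) + 1) %% m
    x <- (x * 69621 + 1) %% m
  }
  as.integer(x + 1)
}

## Master L'Ecuyer-CMRG state for a seed, without disturbing the caller's RNG.
rng_master_state <- function(seed) {
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  suppressWarnings(set.seed(as.integer(seed %% 2147483647), kind = "L'Ecuyer-CMRG"))
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

rng_restore <- function(snapshot) {
  if (is.null(snapshot)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", snapshot, envir = globalenv())
  }
  invisible(NULL)
}

rng_set_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
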