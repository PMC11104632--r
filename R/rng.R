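#' Seeded pseudorandom generator state
#'
#' Constructs the generator state used to drive stimulus rendering. Two
#' algorithms are supported: the 32-bit Marsaglia xorshift generator with
#' shift triple (13, 17, 5) -- the production generator, free of the lattice
#' artifacts of linear congruential generators -- and a configurable linear
#' congruential generator (LCG), included to demonstrate those artifacts.
#'
#' The xorshift generator never visits state 0; a seed of 0 is remapped to
#' the documented constant `2654435769` (the 32-bit golden-ratio word) so a
#' pipeline seeded with 0 still runs deterministically. LCG seeds are reduced
#' modulo the modulus.
#'
#' @param algorithm `"xorshift32"` or `"lcg"`.
#' @param seed Non-negative integer-valued seed (< 2^32).
#' @param lcg_params Named numeric vector with multiplier `a`, increment `c`
#'   and modulus `m` (only used when `algorithm = "lcg"`). The default is the
#'   classic RANDU-style preset `a = 65539, c = 0, m = 2^31`, a generator
#'   with a notoriously coarse lattice structure.
#' @return An object of class `"rng_state"`: a list with fields `algorithm`,
#'   `state`, and (for LCG) `a`, `c`, `m`.
#' @examples
#' s <- rng_state("xorshift32", seed = 1)
#' next_u32(s)$value   # 270369
#' @export
rng_state <- function(algorithm = c("xorshift32", "lcg"), seed = 1,
                      lcg_params = c(a = 65539, c = 0, m = 2^31)) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed < 0 || seed != floor(seed) || seed >= 2^32)
    nf_config_error("seed must be a single integer in [0, 2^32)")
  st <- list(algorithm = algorithm)
  if (algorithm == "xorshift32") {
    st$state <- if (seed == 0) 2654435769 else seed
  } else {
    p <- as.list(lcg_params)
    if (!all(c("a", "c", "m") %in% names(p)))
      nf_config_error("lcg_params must name a, c and m")
    if (p$m < 2 || p$m > 2^32) nf_config_error("lcg modulus must be in [2, 2^32]")
    st$a <- as.numeric(p$a); st$c <- as.numeric(p$c); st$m <- as.numeric(p$m)
    st$state <- seed %% st$m
  }
  structure(st, class = "rng_state")
}

#' @export
print.rng_state <- function(x, ...) {
  cat("<rng_state>", x$algorithm, "state:", format(x$state, scientific = FALSE), "\n")
  if (x$algorithm == "lcg")
    cat("  lcg a =", x$a, "c =", x$c, "m =", format(x$m, scientific = FALSE), "\n")
  invisible(x)
}

.rng_alg_code <- function(state) match(state$algorithm, c("xorshift32", "lcg")) - 1L

.rng_args <- function(state) {
  if (!inherits(state, "rng_state")) nf_input_error("not an rng_state object")
  if (state$algorithm == "xorshift32" && state$state == 0)
    nf_input_error("xorshift32 state must be nonzero")
  list(alg = .rng_alg_code(state),
       state = state$state,
       a = state[["a"]] %||% 0,
       c = state[["c"]] %||% 0,
       m = state[["m"]] %||% 0)
}

.rng_update <- function(state, new_raw_state) {
  state$state <- new_raw_state
  state
}

#' Advance the generator one step
#'
#' @param state An [rng_state()].
#' @return A list with `value` (the raw 32-bit output as a double) and
#'   `state` (the successor state).
#' @export
next_u32 <- function(state) {
  a <- .rng_args(state)
  r <- cpp_rng_raw(a$alg, a$state, a$a, a$c, a$m, 1L)
  list(value = r$values[[1]], state = .rng_update(state, r$state))
}

#' Draw raw 32-bit outputs in bulk
#'
#' @param state An [rng_state()].
#' @param n Number of values.
#' @return List with numeric `values` (length `n`) and the advanced `state`.
#' @export
draw_u32 <- function(state, n) {
  a <- .rng_args(state)
  r <- cpp_rng_raw(a$alg, a$state, a$a, a$c, a$m, as.integer(n))
  list(values = r$values, state = .rng_update(state, r$state))
}

#' Unbiased uniform index via rejection sampling
#'
#' Maps raw generator output to an index in `[0, k)` without modulo bias:
#' raw values at or above `floor(range / k) * k` are rejected and redrawn
#' (`range` is `2^32` for xorshift, the modulus for an LCG).
#'
#' @param state An [rng_state()].
#' @param k Positive integer number of outcomes.
#' @return List with integer `index` in `[0, k)` and the advanced `state`.
#' @export
uniform_index <- function(state, k) {
  r <- draw_indices(state, 1L, k)
  list(index = r$indices[[1]], state = r$state)
}

#' Draw many uniform indices
#'
#' @inheritParams uniform_index
#' @param n Number of indices to draw.
#' @return List with integer vector `indices` (values in `[0, k)`) and the
#'   advanced `state`.
#' @export
draw_indices <- function(state, n, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k))
    nf_input_error("k must be a positive integer")
  a <- .rng_args(state)
  r <- cpp_rng_indices(a$alg, a$state, a$a, a$c, a$m, as.integer(k), as.integer(n))
  list(indices = r$indices, state = .rng_update(state, r$state))
}
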