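#' Derive a child seed from a master seed
#'
#' All stochastic routines in the package draw their randomness from seeds
#' derived deterministically from a single master seed, so that an entire
#' study is reproducible from one integer. The derivation is a Lehmer-style
#' mixing step kept inside the 32-bit signed range.
#'
#' @param seed Integer master seed.
#' @param salt Integer distinguishing the consumer (fold index, repeat
#'   index, permutation index, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + 7919 * as.numeric(salt)) %% m)
}

# Internal: stop with a consistent error class
nl_abort <- function(msg, class = "neurolens_error") {
  rlang::abort(msg, class = class)
}

# Internal: check a scalar is a positive finite number
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    nl_abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Internal: probability in [0, 1]
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    nl_abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

# Internal: run code with a temporary RNG state seeded from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
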