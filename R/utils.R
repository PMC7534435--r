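# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Test-set sizes are `proportion * pool` rounded half away from zero, so
#' 0.5 rounds up for positive arguments (base `round()` rounds half to even).
#'
#' @param x numeric vector (non-negative in this package's usage).
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a deterministic seed for a cross-validation cell
#'
#' Folds the master seed together with arbitrary cell coordinates (scenario,
#' subpopulation, proportion, replicate, ...) into a single 31-bit integer, so
#' any cell of a factorial design can be re-run in isolation without replaying
#' the whole stream of random draws.
#'
#' @param seed integer master seed.
#' @param ... cell coordinates; coerced to character and folded in order.
#' @return a positive integer below 2^31.
#' @export
cell_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tokens <- paste(vapply(list(...), function(t) paste(format(t), collapse = ","),
                         character(1)), collapse = "|")
  s <- abs(as.double(seed)) %% 2147483647
  for (b in utf8ToInt(tokens)) {
    s <- (s * 31 + b) %% 2147483647
  }
  as.integer(max(s, 1))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Consistent condition constructors: classed errors so callers can distinguish
# validation problems from degenerate inputs.
gs_error <- function(msg, class) {
  stop(structure(class = c(class, "gs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
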