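# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so simulation calls do not perturb user code.
#' `seed = NULL` uses (and advances) the current RNG stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed: must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() is half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Validate a single positive / non-negative numeric, naming the field.
check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s: must be a single finite number", field), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("%s: must be > 0 (got %g)", field, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("%s: must be >= 0 (got %g)", field, x), call. = FALSE)
  }
  if (integerish && x != trunc(x)) {
    stop(sprintf("%s: must be an integer (got %g)", field, x), call. = FALSE)
  }
  invisible(x)
}

# Enforce strictly increasing times after jitter + sort; ties get a
# nanosecond-scale ladder (jitter is continuous so ties are fp corner cases).
make_strictly_increasing <- function(t, eps = 1e-9) {
  t <- sort(t)
  d <- diff(t)
  while (any(d <= 0)) {
    i <- which(d <= 0)[1L] + 1L
    t[i] <- t[i - 1L] + eps
    d <- diff(t)
  }
  t
}

`%||%` <- function(a, b) if (is.null(a)) b else a
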