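# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds are mandatory, explicit inputs throughout the package; this helper
#' runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no function mutates global randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a well-level seed from a plate seed and well index, keeping the
# result inside the 32-bit integer range. Forking per well makes plate
# generation independent of iteration order.
fork_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2039L + as.integer(index) * 7L
}

# preserves dim attributes: x must be the first argument of pmax/pmin
clip01 <- function(x) pmin(pmax(x, 0), 1)

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("need at least two points to integrate", call. = FALSE)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

stop_if_not_finite <- function(value, field) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop(sprintf("field '%s' must be finite numeric", field), call. = FALSE)
  }
  invisible(value)
}

#' Four-parameter logistic curve
#'
#' Standard 4PL on the log10-molar dose axis:
#' `f(x) = bottom + (top - bottom) / (1 + 10^(hill * (log10_ec50 - x)))`.
#' With `hill > 0` the response increases with concentration; at
#' `x = log10_ec50` the curve is exactly halfway between `bottom` and `top`.
#'
#' @param x Log10 molar concentration(s).
#' @param top,bottom Upper/lower asymptotes.
#' @param log10_ec50 Log10 molar inflection point.
#' @param hill Hill slope.
#' @return Numeric vector of responses.
#' @export
fourpl <- function(x, top, bottom, log10_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_ec50 - x)))
}
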