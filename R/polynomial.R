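#' Polynomial generating functions
#'
#' A `polynomial_function` maps the lateral cue position `x` (mm, 0 at the
#' display centre) to a target onset time (ms). Coefficients are stored in
#' ascending degree order, so the degree-`d` term has units ms/mm^d.
#'
#' @param coefficients Numeric vector of coefficients, ascending degree.
#'   The constant term comes first; a degree-`d` polynomial has `d + 1`
#'   entries. The leading coefficient may be zero only for degree 0.
#' @return An object of class `polynomial_function`.
#' @examples
#' f <- polynomial_function(c(1350))       # constant 1350 ms
#' eval_function(f, 37)
#' @export
polynomial_function <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients)) {
    stop("'coefficients' must be a non-empty numeric vector")
  }
  structure(
    list(coefficients = coefficients, degree = length(coefficients) - 1L),
    class = "polynomial_function"
  )
}

#' @export
print.polynomial_function <- function(x, ...) {
  terms <- sprintf("%g*x^%d", x$coefficients, seq_along(x$coefficients) - 1L)
  cat("polynomial_function: f(x) =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Evaluate a polynomial generating function
#'
#' @param f A [polynomial_function()].
#' @param x Numeric vector of lateral positions (mm).
#' @return Onset times (ms), one per element of `x`.
#' @export
eval_function <- function(f, x) {
  stopifnot(inherits(f, "polynomial_function"))
  out <- numeric(length(x))
  # Horner evaluation, highest degree first
  for (coef in rev(f$coefficients)) out <- out * x + coef
  out
}

#' Built-in generating functions
#'
#' The stationary sessions use a linear, a quadratic and a cubic function
#' over a 200 mm span; the switching sessions use a constant, a linear and
#' a quadratic. `exp1_functions()` and `exp2_functions()` return named
#' lists of [polynomial_function()] objects.
#'
#' Stationary-session set: linear `-5x + 1250`, quadratic
#' `-0.1x^2 + 0.5x + 1700`, cubic `a x^3 + a x^2 - 3 a x + 1500` with
#' `a = 1/1500`. Switching-session set: constant `1350`, linear
#' `7x + 1350`, quadratic `-0.15x^2 + 0.1x + 2100`.
#'
#' @return Named list of `polynomial_function` objects.
#' @export
exp1_functions <- function() {
  a <- 1 / 1500
  list(
    linear    = polynomial_function(c(1250, -5)),
    quadratic = polynomial_function(c(1700, 0.5, -0.1)),
    cubic     = polynomial_function(c(1500, -3 * a, a, a))
  )
}

#' @rdname exp1_functions
#' @export
exp2_functions <- function() {
  list(
    constant  = polynomial_function(c(1350)),
    linear    = polynomial_function(c(1350, 7)),
    quadratic = polynomial_function(c(2100, 0.1, -0.15))
  )
}
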