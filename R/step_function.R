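#' Right-continuous step functions
#'
#' Light-weight container for right-continuous piecewise-constant paths such
#' as cumulative transition hazards, survival curves, state occupation
#' probabilities, or the marginal mean number of events. The function takes
#' the value `v0` on `[0, times[1])` and `values[k]` on
#' `[times[k], times[k+1])`.
#'
#' @param times Strictly increasing jump times.
#' @param values Value of the function from each jump time onward (same
#'   length as `times`).
#' @param v0 Value before the first jump (default 0).
#' @return An object of class `step_function`.
#' @examples
#' f <- step_function(c(1, 3), c(1/3, 4/3))
#' eval_step(f, c(0.5, 1, 2.9, 3))
#' @export
step_function <- function(times, values, v0 = 0) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length")
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  structure(list(times = times, values = values, v0 = as.numeric(v0)),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param f A [step_function()].
#' @param t Evaluation times.
#' @param left If `TRUE`, return the left limit `f(t-)` instead of the
#'   right-continuous value `f(t)`.
#' @return Numeric vector of values.
#' @export
eval_step <- function(f, t, left = FALSE) {
  stopifnot(inherits(f, "step_function"))
  idx <- findInterval(t, f$times, left.open = left)
  c(f$v0, f$values)[idx + 1L]
}

#' Exact integral of a step function
#'
#' Computes \eqn{\int_{lower}^{upper} f(u) du} exactly by summing rectangles;
#' used, e.g., for the average length of stay (integral of the hospital
#' occupation probability) and for person-time-alive denominators.
#'
#' @param f A [step_function()].
#' @param upper Upper limit of integration (scalar, >= `lower`).
#' @param lower Lower limit (default 0).
#' @return The integral as a scalar.
#' @export
integrate_step <- function(f, upper, lower = 0) {
  stopifnot(inherits(f, "step_function"), length(upper) == 1L)
  if (upper < lower) stop("`upper` must be >= `lower`")
  if (upper == lower) return(0)
  knots <- c(lower, f$times[f$times > lower & f$times < upper], upper)
  vals <- eval_step(f, knots[-length(knots)])
  sum(vals * diff(knots))
}

#' Jump increments of a step function
#'
#' @param f A [step_function()].
#' @return Data frame with columns `time` and `increment`.
#' @export
step_increments <- function(f) {
  stopifnot(inherits(f, "step_function"))
  data.frame(time = f$times,
             increment = diff(c(f$v0, f$values)))
}

#' @export
print.step_function <- function(x, ...) {
  cat("Right-continuous step function with", length(x$times), "jumps\n")
  if (length(x$times)) {
    cat("  range of jump times: [", min(x$times), ",", max(x$times), "]\n")
    cat("  value:", x$v0, "->", x$values[length(x$values)], "\n")
  } else {
    cat("  constant at", x$v0, "\n")
  }
  invisible(x)
}

#' Export a step function as a tidy table
#'
#' @param x A [step_function()].
#' @param ... Unused.
#' @return Data frame with columns `time` and `estimate`, starting with the
#'   time-zero value.
#' @export
as.data.frame.step_function <- function(x, ...) {
  data.frame(time = c(0, x$times), estimate = c(x$v0, x$values))
}
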