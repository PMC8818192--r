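#' Blood input functions on a dense time grid
#'
#' An `input_function` is a continuous-time, non-negative activity curve
#' (kBq/ml or SUV) defined on `[0, T]`, stored on a dense uniform grid with
#' linear interpolation between samples and value 0 before `t = 0`. All
#' model convolutions run on this grid.
#'
#' @param time_s numeric vector of sample times in seconds, starting at 0.
#' @param value activity at each time; non-negative, `value[1] == 0`
#'   (pre-injection).
#' @param dt_s grid spacing in seconds for the internal dense grid.
#'
#' @return An object of class `input_function`: a list with `time_s`,
#'   `value` (dense grid) and `dt_s`.
#' @examples
#' t <- seq(0, 300, by = 0.5)
#' f <- input_function(t, pmax(0, 10 * exp(-(t - 30)^2 / 200)))
#' eval_input(f, c(0, 30, 300))
#' @export
input_function <- function(time_s, value, dt_s = 0.1) {
  stopifnot(is.numeric(time_s), is.numeric(value), length(time_s) == length(value))
  if (length(time_s) < 2L) stop("an input function needs at least two samples")
  if (time_s[1] != 0) stop("input function must start at t = 0")
  if (is.unsorted(time_s, strictly = TRUE)) stop("`time_s` must be strictly increasing")
  if (any(!is.finite(value))) stop("input function values must be finite")
  if (any(value < 0)) stop("input function values must be non-negative")
  grid <- seq(0, time_s[length(time_s)], by = dt_s)
  dense <- approx(time_s, value, xout = grid, rule = 2)$y
  structure(list(time_s = grid, value = dense, dt_s = dt_s),
            class = "input_function")
}

new_input_function <- function(grid, value, dt_s) {
  structure(list(time_s = grid, value = value, dt_s = dt_s),
            class = "input_function")
}

#' Evaluate an input function at arbitrary times
#'
#' Linear interpolation on the dense grid; times before 0 evaluate to 0,
#' times past the stored span are an error.
#'
#' @param f an [input_function()].
#' @param t numeric vector of times in seconds.
#' @return numeric vector of activities.
#' @export
eval_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  tmax <- f$time_s[length(f$time_s)]
  if (any(t > tmax + 1e-9)) {
    stop(sprintf("time(s) up to %.3f s exceed the input-function span [0, %.3f] s",
                 max(t), tmax))
  }
  out <- approx(f$time_s, f$value, xout = pmin(pmax(t, 0), tmax))$y
  out[t < 0] <- 0
  out
}

#' @export
as_tibble.input_function <- function(x, ...) {
  tibble::tibble(time_s = x$time_s, value = x$value)
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %d samples on [0, %g] s (dt = %g s), peak %.3g at %g s\n",
              length(x$time_s), x$time_s[length(x$time_s)], x$dt_s,
              max(x$value), x$time_s[which.max(x$value)]))
  invisible(x)
}

span_s <- function(f) f$time_s[length(f$time_s)]

# Align two input functions on a common grid; errors if spans differ.
check_common_grid <- function(a, b) {
  if (abs(span_s(a) - span_s(b)) > 1e-9 || abs(a$dt_s - b$dt_s) > 1e-12) {
    stop(sprintf(
      "input functions are on different grids: [0, %g] s (dt %g) vs [0, %g] s (dt %g)",
      span_s(a), a$dt_s, span_s(b), b$dt_s))
  }
  invisible(TRUE)
}
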