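#' Kinetic parameter vectors
#'
#' The five parameters of the dual-input reversible two-tissue-compartment
#' model: `k1` (ml/min/ml, blood to tissue), `k2` (1/min, tissue to blood),
#' `k3` (1/min, phosphorylation), `k4` (1/min, dephosphorylation) and `hpi`,
#' the hepatic arterial perfusion index (dimensionless fraction of hepatic
#' inflow supplied by the artery).
#'
#' @param k1,k2,k3,k4 non-negative rate constants (per minute).
#' @param hpi arterial fraction in `[0, 1]`.
#' @return Named numeric vector of class `kinetic_params`.
#' @examples
#' kinetic_params(0.65, 0.59, 0.14, 0.064, 0.67)
#' @export
kinetic_params <- function(k1, k2, k3, k4, hpi) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, hpi = hpi)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  if (length(p) != 5L || any(!is.finite(p))) {
    stop("kinetic parameters must be 5 finite values (k1, k2, k3, k4, hpi)")
  }
  if (any(p[1:4] < 0)) stop("rate constants k1..k4 must be non-negative")
  if (p[[5]] < 0 || p[[5]] > 1) stop("hpi must lie in [0, 1]")
  invisible(p)
}

as_kinetic_params <- function(p) {
  if (inherits(p, "kinetic_params")) return(p)
  if (is.list(p)) p <- unlist(p)
  if (is.null(names(p))) names(p) <- c("k1", "k2", "k3", "k4", "hpi")
  kinetic_params(p[["k1"]], p[["k2"]], p[["k3"]], p[["k4"]], p[["hpi"]])
}

#' Dual blood input: HPI-weighted arterial/portal mixture
#'
#' The liver receives blood from both the hepatic artery and the portal
#' vein; the effective input is
#' `C_B(t) = hpi * A(t) + (1 - hpi) * P(t)`.
#'
#' @param arterial,portal [input_function()]s on the same grid.
#' @param hpi arterial fraction in `[0, 1]`.
#' @return An [input_function()] for the mixed input.
#' @export
blood_input <- function(arterial, portal, hpi) {
  stopifnot(inherits(arterial, "input_function"), inherits(portal, "input_function"))
  check_common_grid(arterial, portal)
  if (!is.finite(hpi) || hpi < 0 || hpi > 1) stop("hpi must lie in [0, 1]")
  new_input_function(arterial$time_s,
                     hpi * arterial$value + (1 - hpi) * portal$value,
                     arterial$dt_s)
}

#' Macro rate constants of the two-tissue model
#'
#' The impulse response of the reversible two-tissue model is a sum of two
#' exponentials with rates `alpha1 <= alpha2`, the roots of
#' `x^2 - (k2 + k3 + k4) x + k2 k4 = 0`:
#' \deqn{\alpha_{1,2} = \frac{k_2+k_3+k_4 \mp \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}}{2}}
#' The discriminant is non-negative for any non-negative rates, so the
#' roots are always real.
#'
#' @param k2,k3,k4 non-negative rate constants (1/min).
#' @return Named numeric `c(alpha1, alpha2)` with `alpha1 <= alpha2`.
#' @examples
#' macro_rates(0.5, 0.1, 0)     # alpha1 = 0 exactly when k4 = 0
#' @export
macro_rates <- function(k2, k3, k4) {
  if (any(!is.finite(c(k2, k3, k4))) || any(c(k2, k3, k4) < 0)) {
    stop("k2, k3, k4 must be finite and non-negative")
  }
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  disc <- max(disc, 0)
  r <- sqrt(disc)
  c(alpha1 = (s - r) / 2, alpha2 = (s + r) / 2)
}

#' Model tissue curve for one parameter vector
#'
#' Computes the analytic output of the dual-input two-tissue model,
#' \deqn{C_T(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right]
#'   \otimes C_B(t),}
#' by causal trapezoid convolution on the dense grid of the input
#' functions. Rates are per minute; the grid is in seconds and the
#' conversion happens internally. When the two macro rates coincide
#' (repeated root, only possible at `k3 = 0`, `k2 = k4`) the analytic
#' limit `K1 (1 + (k3 + k4 - alpha) t) e^{-alpha t}` is used.
#'
#' @param params a [kinetic_params()] vector (or named vector/list).
#' @param arterial,portal [input_function()]s on a common grid.
#' @return An [input_function()] holding `C_T` on the same grid.
#' @examples
#' grid <- seq(0, 300, by = 0.1)
#' a <- arterial_input()
#' p <- portal_from_arterial(a)
#' ct <- model_tac(kinetic_params(0.65, 0.59, 0.14, 0.064, 0.67), a, p)
#' sample_frames(ct, frame_schedule())
#' @export
model_tac <- function(params, arterial, portal) {
  p <- as_kinetic_params(params)
  stopifnot(inherits(arterial, "input_function"), inherits(portal, "input_function"))
  check_common_grid(arterial, portal)
  ct <- .model_tac_core(arterial$value, portal$value,
                        p[["k1"]], p[["k2"]], p[["k3"]], p[["k4"]], p[["hpi"]],
                        arterial$dt_s)
  new_input_function(arterial$time_s, ct, arterial$dt_s)
}

#' Model frame values in one call
#'
#' Convenience wrapper: [model_tac()] followed by [sample_frames()],
#' returning only the per-frame values. This is the quantity compared
#' against a measured TAC during fitting.
#'
#' @inheritParams model_tac
#' @param schedule a [frame_schedule()].
#' @return Numeric vector, one value per frame.
#' @export
model_frames <- function(params, arterial, portal, schedule = frame_schedule()) {
  p <- as_kinetic_params(params)
  check_common_grid(arterial, portal)
  schedule <- as_frame_schedule(schedule)
  if (max(schedule$end_s) > span_s(arterial) + 1e-9) {
    stop("schedule extends past the input-function span")
  }
  idx <- frame_indices(schedule, arterial$dt_s)
  .model_frames_params(arterial, portal, unclass(p), idx)
}

# internal fast path shared with the fitters
.model_frames_params <- function(arterial, portal, p, idx) {
  ct <- .model_tac_core(arterial$value, portal$value,
                        p[["k1"]], p[["k2"]], p[["k3"]], p[["k4"]], p[["hpi"]],
                        arterial$dt_s)
  .frame_averages(ct, idx$i0, idx$i1)
}
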