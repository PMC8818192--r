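#' Synthetic arterial input function
#'
#' A Feng-type arterial model: a sharp first-pass peak (linear rise times a
#' fast exponential) plus a bi-exponential washout tail,
#' `b(t) = (A1*t - A2 - A3) e^{-l1 t} + A2 e^{-l2 t} + A3 e^{-l3 t}`.
#' The curve is rescaled in time so its maximum lands at `peak_time_s` and
#' in amplitude so the maximum equals `amplitude`; it is 0 at `t = 0` and
#' non-negative throughout.
#'
#' @param peak_time_s time of the bolus peak, seconds.
#' @param amplitude peak activity (SUV units by convention here).
#' @param decay_rates three positive exponential rates (1/min), fastest
#'   first: bolus clearance and the two washout components.
#' @param tail_fractions heights of the two washout components relative to
#'   the rise slope term, as in the classic Feng parameterisation.
#' @param span_s end of the time grid, seconds.
#' @param dt_s grid spacing, seconds.
#' @return An [input_function()].
#' @examples
#' a <- arterial_input()
#' a$time_s[which.max(a$value)]   # ~ 20 s
#' @export
arterial_input <- function(peak_time_s = 20, amplitude = 25,
                           decay_rates = c(4.134, 0.119, 0.0104),
                           tail_fractions = c(21.88, 20.81) / 851.1,
                           span_s = 300, dt_s = 0.1) {
  if (peak_time_s <= 0 || amplitude < 0 || any(decay_rates <= 0) ||
      any(tail_fractions < 0) || span_s <= 0) {
    stop("arterial input shape parameters must be positive (amplitude >= 0)")
  }
  l <- sort(decay_rates, decreasing = TRUE)
  a2 <- tail_fractions[1]; a3 <- tail_fractions[2]
  base <- function(tm) {
    pmax(0, (tm - a2 - a3) * exp(-l[1] * tm) + a2 * exp(-l[2] * tm) +
           a3 * exp(-l[3] * tm))
  }
  # locate the unscaled peak, then stretch time so it falls at peak_time_s
  tprobe <- seq(0, 10, by = 1e-3)
  tstar <- tprobe[which.max(base(tprobe))]
  grid <- seq(0, span_s, by = dt_s)
  v <- base(grid / 60 * (tstar / (peak_time_s / 60)))
  v <- if (max(v) > 0) amplitude * v / max(v) else v
  new_input_function(grid, v, dt_s)
}

#' Portal-vein curve from the arterial curve
#'
#' Models splanchnic transit as convolution of the arterial curve with a
#' normalised single-exponential dispersion kernel
#' `h(t) = beta e^{-beta t}` (unit area), the standard device in dual-input
#' liver models. The portal curve is delayed, broadened and — over an
#' infinite horizon — area-preserving.
#'
#' @param arterial an [input_function()].
#' @param dispersion_rate kernel rate `beta` in 1/min; larger values give
#'   less dispersion (the kernel tends to a delta).
#' @return An [input_function()] on the same grid.
#' @export
portal_from_arterial <- function(arterial, dispersion_rate = 2) {
  stopifnot(inherits(arterial, "input_function"))
  if (!is.finite(dispersion_rate) || dispersion_rate <= 0) {
    stop("dispersion_rate must be positive")
  }
  # exact first-order-hold convolution with the unit-area kernel: for a
  # piecewise-linear input the recursion y_n = e y_{n-1} + c1 x_{n-1} + c2 x_n
  # with z = beta*dt, e = exp(-z), c2 = (z - 1 + e)/z, c1 = (1 - e(z+1))/z
  # is exact, and recovers the identity (delta kernel) as z -> Inf
  z <- dispersion_rate * arterial$dt_s / 60
  e <- exp(-z)
  c2 <- (z - 1 + e) / z
  c1 <- (1 - e * (z + 1)) / z
  x <- arterial$value
  u <- c(0, c1 * x[-length(x)] + c2 * x[-1])
  y <- as.numeric(stats::filter(u, e, method = "recursive"))
  new_input_function(arterial$time_s, pmax(y, 0), arterial$dt_s)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate an HCC-versus-background-liver study: group means
#' follow clinically plausible dual-input FDG values for hepatocellular
#' carcinoma (higher `k1`, `k3` and arterial fraction `hpi`) and background
#' liver (portal-dominated supply, lower phosphorylation), with
#' truncated-normal between-subject spread.
#'
#' @param n_per_group subjects per group (>= 1).
#' @param groups named list: for each group a list with `mean` and `sd`,
#'   each a length-5 vector (k1, k2, k3, k4, hpi).
#' @param noise_level fractional TAC noise; per-frame noise sd is
#'   `noise_level * value / sqrt(duration_s / 5)` so longer frames are
#'   less noisy.
#' @param schedule a [frame_schedule()].
#' @param bounds search-space used to truncate parameter draws; see
#'   [search_space()].
#' @param arterial,portal input functions shared by the cohort; defaults
#'   are [arterial_input()] and [portal_from_arterial()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20,
                        groups = default_group_params(),
                        noise_level = 0.05,
                        schedule = frame_schedule(),
                        bounds = search_space(),
                        arterial = NULL, portal = NULL) {
  stopifnot(n_per_group >= 1, noise_level >= 0, length(groups) >= 1)
  for (g in groups) {
    stopifnot(length(g$mean) == 5L, length(g$sd) == 5L, all(g$sd >= 0))
    if (any(g$mean < bounds$lower) || any(g$mean > bounds$upper)) {
      stop("group means must lie inside the search bounds")
    }
  }
  if (is.null(arterial)) arterial <- arterial_input()
  if (is.null(portal)) portal <- portal_from_arterial(arterial)
  structure(list(n_per_group = n_per_group, groups = groups,
                 noise_level = noise_level,
                 schedule = as_frame_schedule(schedule), bounds = bounds,
                 arterial = arterial, portal = portal),
            class = "cohort_spec")
}

#' Default group kinetic parameters
#'
#' Group means/sds for the synthetic cohort: HCC with arterially dominated
#' supply and high phosphorylation, background liver portal-dominated with
#' low `k3`. Values are on the scale reported for dual-input liver FDG
#' modelling of HCC.
#'
#' @return Named list with `HCC` and `liver` entries (`mean`, `sd`).
#' @export
default_group_params <- function() {
  list(
    HCC = list(mean = c(k1 = 0.651, k2 = 0.592, k3 = 0.137, k4 = 0.064, hpi = 0.667),
               sd = c(0.013, 0.012, 0.024, 0.003, 0.183)),
    liver = list(mean = c(k1 = 0.628, k2 = 0.620, k3 = 0.075, k4 = 0.090, hpi = 0.310),
                 sd = c(0.015, 0.013, 0.024, 0.009, 0.092))
  )
}

# truncated-normal draw by rejection, vectorised over parameters
rtruncnorm_vec <- function(mean, sd, lower, upper) {
  out <- numeric(length(mean))
  for (i in seq_along(mean)) {
    if (sd[i] == 0) { out[i] <- mean[i]; next }
    repeat {
      x <- rnorm(1, mean[i], sd[i])
      if (x >= lower[i] && x <= upper[i]) { out[i] <- x; break }
    }
  }
  out
}

# frame-duration-weighted Gaussian noise; 5 s is the reference duration
frame_noise_sd <- function(values, duration_s, noise_level) {
  noise_level * values / sqrt(duration_s / 5)
}

add_frame_noise <- function(values, duration_s, noise_level) {
  values + rnorm(length(values), 0, frame_noise_sd(values, duration_s, noise_level))
}

#' Generate a synthetic dynamic-PET cohort
#'
#' For each subject, draws a true parameter vector from its group's
#' truncated-normal distribution, computes the noiseless model TAC on the
#' schedule via [model_frames()], and adds zero-mean Gaussian noise with
#' per-frame sd `noise_level * value / sqrt(duration_s / 5)`. Fully
#' reproducible given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A tibble with one row per subject: `subject`, `group`,
#'   true parameters `k1..hpi`, and a `tissue` list-column of
#'   [tissue_curve()] tibbles. The shared input functions are attached as
#'   attributes `arterial` and `portal`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 2), seed = 1)
#' coh$tissue[[1]]
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  idx <- frame_indices(spec$schedule, spec$arterial$dt_s)
  rows <- purrr::imap(spec$groups, function(g, gname) {
    purrr::map(seq_len(spec$n_per_group), function(i) {
      p <- rtruncnorm_vec(g$mean, g$sd, spec$bounds$lower, spec$bounds$upper)
      names(p) <- c("k1", "k2", "k3", "k4", "hpi")
      clean <- .model_frames_params(spec$arterial, spec$portal, p, idx)
      noisy <- add_frame_noise(clean, spec$schedule$duration_s, spec$noise_level)
      tibble::tibble(
        group = gname,
        k1 = p[["k1"]], k2 = p[["k2"]], k3 = p[["k3"]], k4 = p[["k4"]],
        hpi = p[["hpi"]],
        tissue = list(tissue_curve(noisy, spec$schedule, label = gname))
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out <- dplyr::mutate(out, subject = sprintf("S%03d", dplyr::row_number()),
                       .before = 1)
  attr(out, "arterial") <- spec$arterial
  attr(out, "portal") <- spec$portal
  attr(out, "seed") <- seed
  class(out) <- c("kin_cohort", class(out))
  out
}
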