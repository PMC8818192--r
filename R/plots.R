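#' Plot a fitted TAC against its data
#'
#' Observed per-frame values (points at frame mid-times) with the fitted
#' model frame values overlaid.
#'
#' @param object a `kin_fit` from [fit_tac()].
#' @param observed the [tissue_curve()] that was fitted.
#' @param arterial,portal the input functions used for the fit.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.kin_fit <- function(object, observed, arterial, portal, ...) {
  sched <- as_frame_schedule(observed)
  fitted <- model_frames(object$par, arterial, portal, sched)
  d <- tibble::tibble(mid_s = rep(sched$mid_s, 2),
                      value = c(observed$value, fitted),
                      what = rep(c("observed", "fitted"), each = nrow(sched)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid_s, y = .data$value,
                                  colour = .data$what)) +
    ggplot2::geom_point(data = function(x) x[x$what == "observed", ]) +
    ggplot2::geom_line(data = function(x) x[x$what == "fitted", ]) +
    ggplot2::labs(x = "frame mid-time (s)", y = "activity (SUV)",
                  colour = NULL,
                  title = sprintf("%s fit, RSS = %.3g", object$method,
                                  object$fitness)) +
    ggplot2::theme_minimal()
}

#' Convergence traces of one or more fits
#'
#' Best-so-far fitness per iteration on a log scale.
#'
#' @param fits a named list of `kin_fit` objects.
#' @return A ggplot object.
#' @export
plot_traces <- function(fits) {
  d <- purrr::imap(fits, function(f, nm) {
    tibble::tibble(method = nm, iteration = seq_along(f$trace) - 1L,
                   fitness = f$trace)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best-so-far RSS", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of estimated parameters by group and method
#'
#' The study-style consistency view: one panel per parameter, boxes per
#' method split by group.
#'
#' @param fits tibble from [fit_cohort()].
#' @param params parameter columns to show.
#' @return A ggplot object.
#' @export
plot_parameter_boxes <- function(fits, params = c("k1", "k3")) {
  d <- tidyr::pivot_longer(fits, cols = dplyr::all_of(params),
                           names_to = "parameter", values_to = "estimate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$estimate,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate", fill = NULL) +
    ggplot2::theme_minimal()
}
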