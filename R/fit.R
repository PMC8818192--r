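new_kin_fit <- function(par, fitness, trace, method, seed, config = NULL,
                        space = NULL, residuals = NULL, n_frames = NA_integer_,
                        n_params = length(par), extra = list()) {
  structure(
    c(list(par = par, fitness = fitness, trace = trace, method = method,
           seed = seed, config = config, space = space,
           residuals = residuals, n_frames = n_frames, n_params = n_params),
      extra),
    class = "kin_fit")
}

#' Sum-of-squares fitness of a candidate parameter vector
#'
#' The quantity all three fitters minimise: the sum over frames of the
#' squared difference between the observed TAC and the model frame values,
#' `sum_f (C_T'(f) - C_m(f))^2`. Zero iff the model reproduces the data
#' exactly.
#'
#' @param candidate a [kinetic_params()] vector (or named vector/list).
#' @param observed a [tissue_curve()] (or tibble with schedule columns and
#'   `value`).
#' @param arterial,portal [input_function()]s spanning the schedule.
#' @return Non-negative scalar.
#' @export
fitness <- function(candidate, observed, arterial, portal) {
  tac_objective(observed, arterial, portal)(as_kinetic_params(candidate))
}

#' Build the per-TAC objective function
#'
#' Returns a closure mapping a length-5 parameter vector to the
#' sum-of-squared-residuals [fitness()], with the input grids and frame
#' windows pre-resolved so repeated evaluation (25k calls per swarm fit)
#' stays cheap.
#'
#' @inheritParams fitness
#' @return `function(par) -> scalar`.
#' @export
tac_objective <- function(observed, arterial, portal) {
  sched <- as_frame_schedule(observed)
  check_common_grid(arterial, portal)
  if (max(sched$end_s) > span_s(arterial) + 1e-9) {
    stop("observed schedule extends past the input-function span")
  }
  idx <- frame_indices(sched, arterial$dt_s)
  obs <- observed$value
  av <- arterial$value; pv <- portal$value; dt <- arterial$dt_s
  function(par) {
    .model_rss_core(av, pv, par[[1]], par[[2]], par[[3]], par[[4]], par[[5]],
                    dt, idx$i0, idx$i1, obs)
  }
}

#' Bounded nonlinear least-squares fit
#'
#' Levenberg-Marquardt trust-region least squares (via
#' [minpack.lm::nls.lm()]) on the per-frame residual vector, with box
#' bounds and multi-start: `n_starts` starting points drawn uniformly in
#' the bounds (or supplied explicitly), best final RSS wins. A single
#' deliberately chosen start reproduces the well-known sensitivity of NLLS
#' to its initial value.
#'
#' @inheritParams fitness
#' @param space a [search_space()].
#' @param starts optional matrix of starting points (rows = starts); if
#'   `NULL`, `n_starts` uniform draws are used.
#' @param n_starts number of random starts.
#' @param seed seed for the random starts.
#' @return A `kin_fit` object (method `"nlls"`); `trace` is the cumulative
#'   best RSS across starts.
#' @export
nlls_fit <- function(observed, arterial, portal, space = search_space(),
                     starts = NULL, n_starts = 10, seed = 1L) {
  obj <- tac_objective(observed, arterial, portal)
  sched <- as_frame_schedule(observed)
  idx <- frame_indices(sched, arterial$dt_s)
  resid_fn <- function(par) {
    observed$value - .model_frames_params(arterial, portal,
                                          setNames(par, c("k1","k2","k3","k4","hpi")),
                                          idx)
  }
  if (is.null(starts)) {
    set.seed(seed)
    starts <- matrix(runif(n_starts * space$d), n_starts, space$d, byrow = TRUE)
    starts <- sweep(sweep(starts, 2, space$upper - space$lower, "*"),
                    2, space$lower, "+")
  } else {
    starts <- rbind(starts)
    if (ncol(starts) != space$d) stop("start points must have one column per parameter")
  }
  best <- NULL; trace <- numeric(0); diagnostics <- character(0)
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = space$lower,
                         upper = space$upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, sprintf("start %d: %s", s, conditionMessage(res)))
      trace <- c(trace, if (length(trace)) trace[length(trace)] else Inf)
      next
    }
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = res, rss = rss)
    trace <- c(trace, if (length(trace)) min(trace[length(trace)], rss) else rss)
  }
  if (is.null(best)) {
    stop("all NLLS starts failed to converge:\n", paste(diagnostics, collapse = "\n"))
  }
  par <- setNames(pmin(pmax(best$fit$par, space$lower), space$upper),
                  space$names %||% c("k1", "k2", "k3", "k4", "hpi"))
  new_kin_fit(par = par, fitness = best$rss, trace = trace, method = "nlls",
              seed = seed, space = space,
              residuals = resid_fn(par), n_frames = nrow(sched),
              n_params = space$d,
              extra = list(n_starts = nrow(starts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one tissue TAC with a chosen engine
#'
#' Front end tying the model to the fitters: builds the
#' sum-of-squared-residuals objective for the observed TAC and minimises
#' it with bounded NLLS, the classic gravitational search, or the dynamic
#' chaotic variant. All five parameters, including the arterial fraction
#' `hpi`, are estimated jointly.
#'
#' @param observed a [tissue_curve()] (schedule + `value`).
#' @param arterial,portal [input_function()]s on a common grid spanning
#'   the schedule.
#' @param method `"nlls"`, `"gsa"` or `"dcgsa"`.
#' @param space a [search_space()].
#' @param config a [gsa_config()] (swarm methods; the `variant` field is
#'   set from `method`).
#' @param seed integer seed.
#' @param ... passed to [nlls_fit()] for `method = "nlls"`.
#' @return A `kin_fit` object with fields `par` (named estimates),
#'   `fitness` (final RSS), `trace` (best-so-far RSS per iteration),
#'   `residuals`, `n_frames`, `n_params`, `method`, `seed`. Use [tidy()]
#'   and [glance()] for tabular views.
#' @examples
#' a <- arterial_input(); p <- portal_from_arterial(a)
#' truth <- kinetic_params(0.65, 0.59, 0.14, 0.064, 0.67)
#' tc <- tissue_curve(model_frames(truth, a, p), frame_schedule())
#' fit <- fit_tac(tc, a, p, method = "dcgsa",
#'                config = gsa_config(n = 20, t_max = 50), seed = 1)
#' tidy(fit)
#' @export
fit_tac <- function(observed, arterial, portal,
                    method = c("nlls", "gsa", "dcgsa"),
                    space = search_space(), config = gsa_config(),
                    seed = 1L, ...) {
  method <- match.arg(method)
  if (method == "nlls") {
    return(nlls_fit(observed, arterial, portal, space = space, seed = seed, ...))
  }
  config$variant <- method
  obj <- tac_objective(observed, arterial, portal)
  fit <- gsa_minimize(obj, space, config, seed = seed)
  sched <- as_frame_schedule(observed)
  idx <- frame_indices(sched, arterial$dt_s)
  fit$residuals <- observed$value -
    .model_frames_params(arterial, portal, fit$par, idx)
  fit$n_frames <- nrow(sched)
  fit$n_params <- space$d
  fit
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit> method %s, RSS %.4g over %s frames\n",
              x$method, x$fitness,
              ifelse(is.na(x$n_frames), "?", x$n_frames)))
  print(round(x$par, 4))
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x a `kin_fit`.
#' @param ... unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par) %||% paste0("x", seq_along(x$par)),
                 estimate = unname(x$par))
}

#' One-row fit summary
#'
#' @param x a `kin_fit`.
#' @param ... unused.
#' @return Tibble with `method`, `rss`, `aic`, `bic`, `n_frames`,
#'   `n_params`, `iterations`, `seed`.
#' @export
glance.kin_fit <- function(x, ...) {
  fq <- if (!is.na(x$n_frames)) fit_quality(x) else
    tibble::tibble(aic = NA_real_, bic = NA_real_)
  tibble::tibble(method = x$method, rss = x$fitness, aic = fq$aic, bic = fq$bic,
                 n_frames = x$n_frames, n_params = x$n_params,
                 iterations = length(x$trace) - 1L, seed = x$seed)
}
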