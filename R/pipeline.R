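#' Read a run configuration
#'
#' YAML (or JSON) configuration with optional blocks `cohort`
#' (`n_per_group`, `noise_level`), `schedule` (run-length blocks, default
#' `[[12, 5], [4, 60]]`), `gsa` (fields of [gsa_config()]), `bounds`
#' (`lower`/`upper`), `methods` and `seed`. Missing blocks fall back to
#' package defaults; the parsed config is validated before any
#' computation.
#'
#' @param path file path, or `NULL` for an all-defaults config.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sched <- if (!is.null(raw$schedule)) {
    frame_schedule(purrr::map(raw$schedule, unlist))
  } else frame_schedule()
  gsa_args <- raw$gsa %||% list()
  # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
  names(gsa_args)[names(gsa_args) %in% c("FALSE", "no")] <- "n"
  gsa <- do.call(gsa_config, gsa_args)
  bounds <- if (!is.null(raw$bounds)) {
    search_space(lower = unlist(raw$bounds$lower), upper = unlist(raw$bounds$upper))
  } else search_space()
  coh <- raw$cohort %||% list()
  spec <- cohort_spec(
    n_per_group = coh$n_per_group %||% 20,
    noise_level = coh$noise_level %||% 0.05,
    schedule = sched, bounds = bounds)
  structure(list(spec = spec, gsa = gsa, bounds = bounds,
                 methods = raw$methods %||% c("nlls", "gsa", "dcgsa"),
                 seed = raw$seed %||% 1L, raw = raw),
            class = "run_config")
}

config_hash <- function(config) {
  # stable fingerprint of the effective configuration, embedded in outputs
  s <- jsonlite::toJSON(config$raw %||% list(), auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% .Machine$integer.max)
}

#' Write a synthetic cohort to disk
#'
#' One directory per subject with `tissue.csv`
#' (`frame_start_s,frame_duration_s,value`), `arterial.csv` and
#' `portal.csv` (`time_s,value`, written at 1 s resolution), and
#' `truth.json` (true parameters, group, seed); plus a cohort
#' `manifest.csv` listing every subject.
#'
#' @param config a `run_config` (see [read_run_config()]), or `NULL` for
#'   defaults.
#' @param out_dir output directory (created; must be writable).
#' @param seed overrides the config seed.
#' @return Invisibly, the manifest tibble.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  config <- config %||% read_run_config()
  seed <- seed %||% config$seed
  cohort <- generate_cohort(config$spec, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- attr(cohort, "arterial"); p <- attr(cohort, "portal")
  tcoarse <- seq(0, span_s(a), by = 1)
  hash <- config_hash(config)
  rows <- purrr::pmap(cohort, function(subject, group, k1, k2, k3, k4, hpi, tissue) {
    sdir <- file.path(out_dir, subject)
    dir.create(sdir, showWarnings = FALSE)
    utils::write.csv(
      data.frame(frame_start_s = tissue$start_s,
                 frame_duration_s = tissue$duration_s,
                 value = tissue$value),
      file.path(sdir, "tissue.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time_s = tcoarse, value = eval_input(a, tcoarse)),
                     file.path(sdir, "arterial.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time_s = tcoarse, value = eval_input(p, tcoarse)),
                     file.path(sdir, "portal.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(subject = subject, group = group,
           params = list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, hpi = hpi),
           seed = seed, config_hash = hash),
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    tibble::tibble(subject = subject, group = group, dir = sdir,
                   k1 = k1, k2 = k2, k3 = k3, k4 = k4, hpi = hpi,
                   seed = seed, config_hash = hash)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read TAC and input-function CSVs
#'
#' `read_tissue_csv` expects `frame_start_s,frame_duration_s,value`;
#' `read_input_csv` expects `time_s,value`.
#'
#' @param path CSV file path.
#' @param label optional group label for the tissue curve.
#' @return A [tissue_curve()] / [input_function()].
#' @export
read_tissue_csv <- function(path, label = NA_character_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame_start_s", "frame_duration_s", "value") %in% names(d)))
  sched <- as_frame_schedule(data.frame(start_s = d$frame_start_s,
                                        duration_s = d$frame_duration_s))
  tissue_curve(d$value, sched, label = label)
}

#' @rdname read_tissue_csv
#' @param dt_s dense-grid spacing for the interpolated input function.
#' @export
read_input_csv <- function(path, dt_s = 0.1) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  input_function(d$time_s, d$value, dt_s = dt_s)
}

#' Fit every subject of an on-disk cohort
#'
#' Reads each subject directory produced by [run_simulate()] and writes
#' one `<subject>_<method>.json` result per requested method into
#' `out_dir`. A subject whose files are missing or unreadable is recorded
#' as failed and the run continues.
#'
#' @param cohort_dir directory containing `manifest.csv`.
#' @param out_dir output directory for result JSONs.
#' @param methods subset of `c("nlls", "gsa", "dcgsa")`.
#' @param config a `run_config` or `NULL`.
#' @param seed overrides the config seed.
#' @return Invisibly, a tibble of written results with a `status` column.
#' @export
run_fit <- function(cohort_dir, out_dir, methods = c("nlls", "gsa", "dcgsa"),
                    config = NULL, seed = NULL) {
  config <- config %||% read_run_config()
  seed <- seed %||% config$seed
  manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  grid <- tidyr::expand_grid(row = seq_len(nrow(manifest)), method = methods)
  status <- purrr::pmap(grid, function(row, method) {
    sub <- manifest[row, ]
    out_file <- file.path(out_dir, sprintf("%s_%s.json", sub$subject, method))
    res <- tryCatch({
      tc <- read_tissue_csv(file.path(sub$dir, "tissue.csv"), label = sub$group)
      a <- read_input_csv(file.path(sub$dir, "arterial.csv"))
      p <- read_input_csv(file.path(sub$dir, "portal.csv"))
      fit <- fit_tac(tc, a, p, method = method, space = config$bounds,
                     config = config$gsa,
                     seed = (seed * 1009L + row * 31L +
                               match(method, c("nlls", "gsa", "dcgsa"))) %%
                       2147483647L)
      fq <- fit_quality(fit)
      jsonlite::write_json(
        list(subject = sub$subject, group = sub$group, method = method,
             params = as.list(fit$par), rss = fit$fitness,
             aic = fq$aic, bic = fq$bic, trace = fit$trace,
             seed = fit$seed, config_hash = hash,
             gsa_config = unclass(config$gsa)),
        out_file, auto_unbox = TRUE, digits = NA)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    tibble::tibble(subject = sub$subject, method = method,
                   file = out_file, status = res)
  })
  status <- dplyr::bind_rows(status)
  fails <- status[status$status != "ok", ]
  if (nrow(fails) > 0) {
    warning(sprintf("%d fit(s) failed (%s)", nrow(fails),
                    paste(unique(fails$subject), collapse = ", ")))
  }
  invisible(status)
}

#' Summarise a directory of fit results
#'
#' Collects every result JSON written by [run_fit()], rebuilds the fits
#' table, and writes `summary.csv` (the per-method, per-parameter group
#' table) and `comparison.json` (AUCs, t-test and DeLong p values, AIC/BIC
#' means).
#'
#' @param fits_dir directory of `*_<method>.json` files.
#' @param out_dir where to write the two summary artifacts.
#' @param positive_group label of the lesion group (default: first group).
#' @return Invisibly, the [cohort_report()].
#' @export
run_evaluate <- function(fits_dir, out_dir, positive_group = NULL) {
  files <- list.files(fits_dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no result JSONs found in ", fits_dir)
  fits <- purrr::map(files, function(f) {
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    tibble::tibble(subject = j$subject, group = j$group, method = j$method,
                   k1 = j$params$k1, k2 = j$params$k2, k3 = j$params$k3,
                   k4 = j$params$k4, hpi = j$params$hpi,
                   rss = j$rss, aic = j$aic, bic = j$bic)
  }) |> dplyr::bind_rows()
  report <- cohort_report(fits, positive_group = positive_group)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$parameters, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(parameters = report$parameters, fit_quality = report$fit_quality,
         auc_comparisons = report$auc_comparisons,
         positive_group = report$positive_group),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Benchmark the swarm fitters on analytic test functions
#'
#' Runs the classic and dynamic chaotic gravitational search on standard
#' optimisation test functions and reports the final best fitness of each
#' repeat. Used to verify optimizer correctness independently of the
#' kinetic model.
#'
#' @param functions subset of `c("sphere", "rosenbrock", "rastrigin")`.
#' @param methods subset of `c("gsa", "dcgsa")`.
#' @param d dimension for sphere/rastrigin (rosenbrock runs in 2-D).
#' @param repeats seeded repeats per (function, method).
#' @param config a [gsa_config()].
#' @param seed master seed.
#' @return Tibble with one row per (function, method, repeat):
#'   `best_fitness` and the distance of the best point from the known
#'   optimum (`dist_opt`).
#' @export
run_benchmark <- function(functions = c("sphere", "rosenbrock", "rastrigin"),
                          methods = c("gsa", "dcgsa"), d = 5, repeats = 3,
                          config = gsa_config(), seed = 1L) {
  functions <- match.arg(functions, several.ok = TRUE)
  suite <- list(
    sphere = list(fn = function(x) sum(x^2),
                  space = search_space(lower = rep(-5, d), upper = rep(5, d)),
                  opt = rep(0, d)),
    rosenbrock = list(fn = function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 +
                                             (1 - x[-length(x)])^2),
                      space = search_space(lower = rep(-5, 2), upper = rep(5, 2)),
                      opt = rep(1, 2)),
    rastrigin = list(fn = function(x) 10 * length(x) +
                       sum(x^2 - 10 * cos(2 * pi * x)),
                     space = search_space(lower = rep(-5.12, d),
                                          upper = rep(5.12, d)),
                     opt = rep(0, d))
  )
  grid <- tidyr::expand_grid(fun = functions, method = methods,
                             repeat_id = seq_len(repeats))
  out <- purrr::pmap(grid, function(fun, method, repeat_id) {
    cfg <- config; cfg$variant <- method
    s <- suite[[fun]]
    fit <- gsa_minimize(s$fn, s$space, cfg,
                        seed = (seed * 7919L + repeat_id) %% 2147483647L)
    tibble::tibble(fun = fun, method = method, repeat_id = repeat_id,
                   best_fitness = fit$fitness,
                   dist_opt = sqrt(sum((fit$par - s$opt)^2)))
  })
  dplyr::bind_rows(out)
}
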