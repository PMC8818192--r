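#' AIC and BIC of a least-squares TAC fit
#'
#' Gaussian least-squares information criteria computed from the residual
#' sum of squares: `AIC = n ln(RSS/n) + 2p` and `BIC = n ln(RSS/n) +
#' p ln(n)` with `n` frames and `p` free parameters (5 here). Constant
#' additive terms are dropped — only differences between fits of the same
#' data are meaningful. Smaller is better.
#'
#' @param rss residual sum of squares, or a `kin_fit` object.
#' @param n_frames,n_params counts (taken from the fit object if given);
#'   requires `n_frames > n_params`.
#' @return Tibble with `aic`, `bic`, `rss`, `n_frames`, `n_params`.
#' @examples
#' fit_quality(1.6, n_frames = 16, n_params = 5)
#' @export
fit_quality <- function(rss, n_frames = NULL, n_params = 5) {
  if (inherits(rss, "kin_fit")) {
    n_frames <- rss$n_frames; n_params <- rss$n_params; rss <- rss$fitness
  }
  stopifnot(is.numeric(rss), rss >= 0, n_frames > n_params)
  if (rss == 0) {
    warning("RSS is exactly 0; AIC/BIC are -Inf")
    aic <- bic <- -Inf
  } else {
    aic <- n_frames * log(rss / n_frames) + 2 * n_params
    bic <- n_frames * log(rss / n_frames) + n_params * log(n_frames)
  }
  tibble::tibble(aic = aic, bic = bic, rss = rss,
                 n_frames = n_frames, n_params = n_params)
}

#' Two-sample comparison of a kinetic parameter between groups
#'
#' Student's two-sided t-test (pooled variance by default, matching the
#' classical "Student's t-test"; set `var_equal = FALSE` for Welch).
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return Tibble with group means/sds, `statistic`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(tibble::tibble(mean_a = mean(values_a), sd_a = 0,
                          mean_b = mean(values_b), sd_b = 0,
                          statistic = 0, p_value = 1))
  }
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  tibble::tibble(mean_a = mean(values_a), sd_a = sd(values_a),
                 mean_b = mean(values_b), sd_b = sd(values_b),
                 statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' ROC AUC with DeLong confidence interval
#'
#' Area under the ROC curve by the Mann-Whitney construction (ties count
#' one half), with a DeLong-variance confidence interval. Scores are
#' oriented so that the reported AUC is at least 0.5; the direction used
#' is returned so that parameters running lower in the positive class are
#' reported transparently.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second level / `TRUE` / `1` is the positive class).
#' @param conf_level confidence level for the DeLong interval.
#' @return Tibble with `auc`, `ci_lower`, `ci_upper`, `direction`
#'   (`">"` if positives score higher).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "auto", levels = c(0, 1))
  ci <- pROC::ci.auc(r, method = "delong", conf.level = conf_level)
  tibble::tibble(auc = as.numeric(pROC::auc(r)),
                 ci_lower = max(0, ci[1]), ci_upper = min(1, ci[3]),
                 direction = if (r$direction == "<") ">" else "<")
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' (paired design) with the DeLong test. Symmetric in the order of the
#' score vectors; monotone transforms of a score vector leave its ROC
#' curve, and hence the test, unchanged.
#'
#' @param scores_1,scores_2 paired score vectors.
#' @param labels binary labels shared by both.
#' @return Tibble with `auc_1`, `auc_2`, `statistic`, `p_value`.
#' @export
compare_auc <- function(scores_1, scores_2, labels) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  stopifnot(length(scores_1) == length(scores_2))
  r1 <- pROC::roc(labels, scores_1, quiet = TRUE, direction = "auto",
                  levels = c(0, 1))
  r2 <- pROC::roc(labels, scores_2, quiet = TRUE, direction = "auto",
                  levels = c(0, 1))
  if (r2$direction != r1$direction) {
    # orient the second curve by score reversal so both curves share a
    # direction (each AUC keeps its own oriented value)
    r2 <- pROC::roc(labels, -scores_2, quiet = TRUE,
                    direction = r1$direction, levels = c(0, 1))
  }
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(a1, a2))) {
    # identical or rank-equivalent scores: no difference to test
    return(tibble::tibble(auc_1 = a1, auc_2 = a2, statistic = 0, p_value = 1))
  }
  tt <- tryCatch(
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE),
    error = function(e) stop("DeLong comparison failed: ", conditionMessage(e)))
  tibble::tibble(auc_1 = a1, auc_2 = a2,
                 statistic = unname(tt$statistic), p_value = tt$p.value)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly two levels")
    as.integer(as.character(labels) == lv[2])
  } else {
    as.integer(as.logical(labels))
  }
}

#' Fit every subject of a cohort with one or more methods
#'
#' Maps [fit_tac()] over the rows of a cohort tibble (as produced by
#' [generate_cohort()]), one fit per subject per method. Per-subject seeds
#' are derived deterministically from `seed`.
#'
#' @param cohort a `kin_cohort` tibble (needs `subject`, `group`, `tissue`
#'   list-column, and `arterial`/`portal` attributes or arguments).
#' @param methods subset of `c("nlls", "gsa", "dcgsa")`.
#' @param space,config passed to [fit_tac()].
#' @param seed master seed.
#' @param arterial,portal override the cohort's input functions.
#' @param ... passed to [fit_tac()].
#' @return Tibble, one row per subject x method: `subject`, `group`,
#'   `method`, estimates `k1..hpi`, `rss`, `aic`, `bic` plus the true
#'   parameters as `true_k1..true_hpi`.
#' @export
fit_cohort <- function(cohort, methods = c("nlls", "gsa", "dcgsa"),
                       space = search_space(), config = gsa_config(),
                       seed = 1L, arterial = NULL, portal = NULL, ...) {
  arterial <- arterial %||% attr(cohort, "arterial")
  portal <- portal %||% attr(cohort, "portal")
  stopifnot(!is.null(arterial), !is.null(portal))
  methods <- match.arg(methods, c("nlls", "gsa", "dcgsa"), several.ok = TRUE)
  grid <- tidyr::expand_grid(row = seq_len(nrow(cohort)), method = methods)
  res <- purrr::pmap(grid, function(row, method) {
    sub <- cohort[row, ]
    fit <- fit_tac(sub$tissue[[1]], arterial, portal, method = method,
                   space = space, config = config,
                   seed = (seed * 1009L + row * 31L +
                             match(method, c("nlls", "gsa", "dcgsa"))) %%
                     2147483647L,
                   ...)
    fq <- fit_quality(fit)
    tibble::tibble(subject = sub$subject, group = sub$group, method = method,
                   !!!setNames(as.list(unname(fit$par)), names(fit$par)),
                   rss = fit$fitness, aic = fq$aic, bic = fq$bic,
                   true_k1 = sub$k1, true_k2 = sub$k2, true_k3 = sub$k3,
                   true_k4 = sub$k4, true_hpi = sub$hpi)
  })
  dplyr::bind_rows(res)
}

#' Group comparison table for a fitted cohort
#'
#' Builds the study-style summary from per-subject fits: for each method
#' and parameter, group mean +/- sd, the Student t-test between groups,
#' and the (oriented) ROC AUC of the parameter for separating the groups;
#' plus a per-method, per-group AIC/BIC summary. Subjects with missing
#' fits are listed and excluded with a warning.
#'
#' @param fits tibble as returned by [fit_cohort()] (needs `subject`,
#'   `group`, `method`, parameter columns, `aic`, `bic`).
#' @param positive_group label of the positive class for ROC (default the
#'   first group encountered, conventionally the lesion group).
#' @param params parameter columns to summarise.
#' @return List of class `cohort_report`: `parameters` (one row per
#'   method x parameter), `fit_quality` (one row per method x group),
#'   `auc_comparisons` (pairwise DeLong p per parameter across methods,
#'   when >= 2 methods are present).
#' @export
cohort_report <- function(fits, positive_group = NULL,
                          params = c("k1", "k2", "k3", "k4", "hpi")) {
  stopifnot(all(c("subject", "group", "method") %in% names(fits)))
  params <- intersect(params, names(fits))
  bad <- !stats::complete.cases(fits[, c(params, "aic", "bic")])
  if (any(bad)) {
    warning("excluding incomplete fits for subject(s): ",
            paste(unique(fits$subject[bad]), collapse = ", "))
    fits <- fits[!bad, ]
  }
  groups <- unique(fits$group)
  if (length(groups) != 2) stop("cohort_report needs exactly two groups")
  pos <- positive_group %||% groups[1]
  neg <- setdiff(groups, pos)

  parameters <- purrr::map(unique(fits$method), function(m) {
    fm <- fits[fits$method == m, ]
    purrr::map(params, function(p) {
      a <- fm[[p]][fm$group == pos]; b <- fm[[p]][fm$group == neg]
      cg <- compare_groups(a, b)
      av <- roc_auc(fm[[p]], fm$group == pos)
      tibble::tibble(method = m, parameter = p,
                     mean_pos = cg$mean_a, sd_pos = cg$sd_a,
                     mean_neg = cg$mean_b, sd_neg = cg$sd_b,
                     statistic = cg$statistic, p_value = cg$p_value,
                     auc = av$auc, auc_ci_lower = av$ci_lower,
                     auc_ci_upper = av$ci_upper, auc_direction = av$direction)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  quality <- fits |>
    dplyr::group_by(.data$method, .data$group) |>
    dplyr::summarise(mean_aic = mean(.data$aic), sd_aic = sd(.data$aic),
                     mean_bic = mean(.data$bic), sd_bic = sd(.data$bic),
                     n = dplyr::n(), .groups = "drop")

  auc_cmp <- NULL
  methods <- unique(fits$method)
  if (length(methods) >= 2) {
    wide <- fits |>
      dplyr::select(dplyr::all_of(c("subject", "group", "method", params))) |>
      tidyr::pivot_wider(names_from = "method",
                         values_from = dplyr::all_of(params))
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    auc_cmp <- purrr::map(params, function(p) {
      purrr::map(pairs, function(pr) {
        col1 <- if (length(params) > 1) paste(p, pr[1], sep = "_") else pr[1]
        col2 <- if (length(params) > 1) paste(p, pr[2], sep = "_") else pr[2]
        cmp <- compare_auc(wide[[col1]], wide[[col2]], wide$group == pos)
        tibble::tibble(parameter = p, method_1 = pr[1], method_2 = pr[2],
                       auc_1 = cmp$auc_1, auc_2 = cmp$auc_2,
                       p_value = cmp$p_value)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }
  structure(list(parameters = parameters, fit_quality = quality,
                 auc_comparisons = auc_cmp, positive_group = pos),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (positive group:", x$positive_group, ")\n\nParameters:\n")
  print(x$parameters, n = Inf)
  cat("\nFit quality (AIC/BIC):\n")
  print(x$fit_quality, n = Inf)
  if (!is.null(x$auc_comparisons)) {
    cat("\nPairwise AUC comparisons (DeLong):\n")
    print(x$auc_comparisons, n = Inf)
  }
  invisible(x)
}
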