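test_that("information criteria follow the Gaussian least-squares forms", {
  fq <- fit_quality(1.6, n_frames = 16, n_params = 5)
  expect_equal(fq$aic, 16 * log(0.1) + 10)
  expect_equal(fq$bic, 16 * log(0.1) + 5 * log(16))
  # BIC - AIC = p (ln n - 2), independent of RSS
  for (rss in c(0.01, 1, 50)) {
    fq <- fit_quality(rss, n_frames = 16, n_params = 5)
    expect_equal(fq$bic - fq$aic, 5 * (log(16) - 2))
  }
  # monotone in RSS at fixed n, p
  a <- fit_quality(0.5, 16, 5); b <- fit_quality(1.5, 16, 5)
  expect_lt(a$aic, b$aic); expect_lt(a$bic, b$bic)
  expect_warning(z <- fit_quality(0, 16, 5), "-Inf")
  expect_equal(z$aic, -Inf)
  expect_error(fit_quality(1, n_frames = 4, n_params = 5))
})

test_that("group comparison matches Student's t and is symmetric", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  shifted <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 1e-3)

  # textbook case against the pooled-variance closed form
  x <- c(5.1, 4.9, 6.0, 5.5, 5.3); y <- c(4.2, 4.8, 4.1, 4.6)
  cg <- compare_groups(x, y)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(x) + length(y) - 2)
  expect_equal(cg$statistic, t_oracle, tolerance = 1e-6)
  expect_equal(cg$p_value, p_oracle, tolerance = 1e-6)

  # swap changes only the sign of t
  sw <- compare_groups(y, x)
  expect_equal(sw$statistic, -cg$statistic)
  expect_equal(sw$p_value, cg$p_value)
})

test_that("AUC equals the scaled Mann-Whitney U statistic", {
  # worked 6-point example with a tie across classes
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  # U oracle: pairs where case > control count 1, ties count 1/2
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  u <- sum(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(scores, labels)$auc, u / (3 * 3))

  # perfect separation (pROC warns that the CI of a perfect AUC degenerates)
  expect_equal(suppressWarnings(
    roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc), 1)

  # labels independent of scores at large n: AUC near 1/2 (after
  # orientation, slightly above by construction)
  set.seed(31)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.5)
  a <- roc_auc(s, l)
  expect_lt(a$auc, 0.53)
  expect_gte(a$auc, 0.5)

  # invariance under strictly monotone transforms
  s2 <- rnorm(50); l2 <- rep(c(0, 1), 25)
  expect_equal(roc_auc(exp(2 * s2) + 1, l2)$auc, roc_auc(s2, l2)$auc)

  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong machinery matches a hand-coded reference and handles ties", {
  # identical and rank-equivalent scores: identical curves, p = 1
  set.seed(13)
  s <- rnorm(30); l <- rep(c(0, 1), 15)
  expect_equal(compare_auc(s, s, l)$p_value, 1)
  expect_equal(compare_auc(s, 2 * s + 7, l)$p_value, 1)
  expect_equal(compare_auc(s, exp(s), l)$p_value, 1)

  # hand-coded DeLong test (placement values) on a small example
  delong_oracle <- function(s1, s2, labels) {
    psi <- function(x, y) outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    comp <- function(s) {
      x <- s[labels == 1]; y <- s[labels == 0]
      m <- length(x); n <- length(y)
      P <- psi(x, y)
      auc <- mean(P)
      v10 <- rowMeans(P) - auc   # per-case placements
      v01 <- colMeans(P) - auc   # per-control placements
      list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
    }
    c1 <- comp(s1); c2 <- comp(s2)
    s10 <- cov(cbind(c1$v10, c2$v10)); s01 <- cov(cbind(c1$v01, c2$v01))
    S <- s10 / c1$m + s01 / c1$n
    z <- (c1$auc - c2$auc) / sqrt(S[1, 1] + S[2, 2] - 2 * S[1, 2])
    2 * stats::pnorm(-abs(z))
  }
  set.seed(17)
  lab <- rep(c(0, 1), each = 12)
  s1 <- rnorm(24) + lab
  s2 <- rnorm(24) + 0.5 * lab
  got <- compare_auc(s1, s2, lab)
  expect_equal(got$p_value, delong_oracle(s1, s2, lab), tolerance = 1e-6)
  # symmetric in argument order
  expect_equal(compare_auc(s2, s1, lab)$p_value, got$p_value)
  expect_error(compare_auc(s1, s2, rep(1, 24)), "both classes")
})

test_that("cohort report summarises parameters, fit quality and AUCs", {
  # build a fits table directly (no fitting needed to test the reporter)
  set.seed(23)
  n <- 12
  mk <- function(method, shift) {
    tibble::tibble(
      subject = sprintf("S%02d", 1:(2 * n)),
      group = rep(c("HCC", "liver"), each = n),
      method = method,
      k1 = rnorm(2 * n, 0.6, 0.05),
      k2 = rnorm(2 * n, 0.6, 0.05),
      k3 = c(rnorm(n, 0.14 + shift, 0.02), rnorm(n, 0.075, 0.02)),
      k4 = rnorm(2 * n, 0.07, 0.01),
      hpi = c(rnorm(n, 0.67, 0.1), rnorm(n, 0.31, 0.1)),
      rss = runif(2 * n, 0.1, 1),
      aic = rnorm(2 * n, -40, 3), bic = rnorm(2 * n, -37, 3)
    )
  }
  fits <- dplyr::bind_rows(mk("nlls", 0), mk("dcgsa", 0.02))
  rep <- cohort_report(fits, positive_group = "HCC")
  expect_s3_class(rep, "cohort_report")
  expect_equal(nrow(rep$parameters), 10)  # 2 methods x 5 parameters
  k3row <- rep$parameters[rep$parameters$method == "dcgsa" &
                            rep$parameters$parameter == "k3", ]
  expect_lt(k3row$p_value, 0.05)
  expect_gt(k3row$mean_pos, k3row$mean_neg)
  expect_true(all(rep$parameters$auc >= 0.5))
  expect_equal(nrow(rep$fit_quality), 4)  # 2 methods x 2 groups
  expect_equal(nrow(rep$auc_comparisons), 5)  # one method pair x 5 params

  # single-method table renders without the AUC comparison block
  rep1 <- cohort_report(mk("nlls", 0), positive_group = "HCC")
  expect_null(rep1$auc_comparisons)

  # incomplete fits are excluded with a warning
  broken <- fits
  broken$k1[3] <- NA
  expect_warning(cohort_report(broken, positive_group = "HCC"), "S03")
})

test_that("the reporter's t-tests are calibrated under the null", {
  # both groups share one generating distribution: the per-parameter
  # rejection rate at nominal 5% stays near 5% over repeated cohorts
  set.seed(29)
  n <- 20
  rejections <- replicate(200, {
    fits <- tibble::tibble(
      subject = sprintf("S%02d", 1:(2 * n)),
      group = rep(c("HCC", "liver"), each = n),
      method = "nlls",
      k1 = rnorm(2 * n, 0.6, 0.05), k2 = rnorm(2 * n, 0.6, 0.05),
      k3 = rnorm(2 * n, 0.1, 0.02), k4 = rnorm(2 * n, 0.07, 0.01),
      hpi = rnorm(2 * n, 0.5, 0.1),
      rss = runif(2 * n), aic = rnorm(2 * n), bic = rnorm(2 * n))
    cohort_report(fits, positive_group = "HCC")$parameters$p_value < 0.05
  })
  rates <- rowMeans(rejections)
  expect_true(all(rates <= 0.10))   # 5% nominal + binomial slack at 200 reps
  expect_true(all(rates >= 0.005))  # and not degenerately conservative
})
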