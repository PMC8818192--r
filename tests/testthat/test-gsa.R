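test_that("mass update maps fitness to normalised inertial masses", {
  # hand evaluation: fit (2,4,10) -> m = (1, 0.75, 0), M = (4/7, 3/7, 0)
  expect_equal(update_masses(c(2, 4, 10)), c(4, 3, 0) / 7)
  expect_equal(update_masses(rep(3, 5)), rep(0.2, 5))
  set.seed(1)
  for (i in 1:50) {
    m <- update_masses(runif(sample(2:30, 1), 0, 100))
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
  # non-finite fitness carries zero mass
  m <- update_masses(c(1, Inf, 3))
  expect_equal(m[2], 0)
  expect_equal(sum(m), 1)
})

test_that("gravitational constant schedules decay as specified", {
  cfg <- gsa_config(g0 = 100, alpha = 20, t_max = 500)
  expect_equal(gravitational_constant(0, cfg), 100)
  expect_equal(gravitational_constant(500, cfg), 100 * exp(-20))
  expect_equal(gravitational_constant(250, cfg), 100 * exp(-10))
  g <- sapply(0:500, gravitational_constant, cfg = cfg)
  expect_true(all(diff(g) < 0))

  # dynamic schedule: both forms equal G0 at t = 0
  for (form in c("normalized", "unscaled")) {
    cfgd <- gsa_config(g0 = 100, alpha = 20, t_max = 500,
                       variant = "dcgsa", g_dynamic_form = form)
    expect_equal(dynamic_gravitational_constant(0, cfgd, rand_t = 0.3), 100)
    expect_lte(dynamic_gravitational_constant(123, cfgd, rand_t = 0.9), 100)
  }
  # closed form of the unscaled variant at t = T with rand_t = 1
  cfgu <- gsa_config(g0 = 100, alpha = 20, t_max = 500, variant = "dcgsa",
                     g_dynamic_form = "unscaled")
  expect_equal(dynamic_gravitational_constant(500, cfgu, rand_t = 1),
               100 * exp(-2 * 20 / sqrt(500)))
  # and of the normalized default
  cfgn <- gsa_config(g0 = 100, alpha = 20, t_max = 500, variant = "dcgsa")
  expect_equal(dynamic_gravitational_constant(500, cfgn, rand_t = 1),
               100 * exp(-2 * 20))

  # Monte-Carlo expectation over rand_t matches the closed form
  # E[G'] = G0 * e^{-c t/T} * (1 - e^{-c}) / c with c = alpha * (t/T)^1.5
  set.seed(11)
  t <- 200; Tm <- 500
  c_const <- 20 * (t / Tm)^1.5
  mc <- mean(replicate(1e5, dynamic_gravitational_constant(t, cfgn)))
  closed <- 100 * exp(-c_const * t / Tm) * (1 - exp(-c_const)) / c_const
  expect_lt(abs(mc - closed) / closed, 0.005)
})

test_that("pairwise force follows the gravitational law and is attractive", {
  pos <- matrix(c(0, 1), 2, 1)
  m <- c(0.5, 0.5)
  f <- pairwise_force(1, 2, pos, m, g = 1, epsilon = 0)
  expect_equal(abs(f), 0.25)
  expect_gt(f, 0)  # points from particle 1 toward particle 2
  expect_equal(pairwise_force(2, 1, pos, m, g = 1, epsilon = 0), -0.25)

  expect_equal(pairwise_force(1, 2, pos, c(0, 0.5), g = 1), 0)
  same <- matrix(c(1, 1), 2, 1)
  expect_equal(pairwise_force(1, 2, same, m, g = 1), 0)
})

test_that("resultant force matches a brute-force double loop", {
  set.seed(3)
  n <- 3; d <- 4
  pos <- matrix(runif(n * d), n, d)
  fit <- c(5, 1, 9)
  m <- update_masses(fit)
  rw <- matrix(runif(n * n), n, n)
  for (kb in 1:3) {
    for (i in 1:n) {
      f <- resultant_force(i, pos, m, fit, g = 2, kbest = kb, rand_w = rw)
      # oracle: explicit sum over the kb best individuals
      elite <- order(fit)[seq_len(kb)]
      expected <- numeric(d)
      for (j in elite) {
        if (j == i) next
        diffv <- pos[j, ] - pos[i, ]
        r <- sqrt(sum(diffv^2))
        expected <- expected + rw[i, j] * 2 * m[i] * m[j] / (r + 1e-9) * diffv
      }
      expect_equal(f, expected, tolerance = 1e-14)
    }
  }
  # kbest = 1 and i is the best: empty sum
  expect_equal(resultant_force(2, pos, m, fit, g = 2, kbest = 1, rand_w = rw),
               numeric(d))
  # all other masses zero: nothing attracts
  m0 <- c(0, 1, 0)
  expect_equal(resultant_force(2, pos, m0, fit, g = 2, kbest = 3, rand_w = rw),
               numeric(d))
})

test_that("one classic step reproduces the sequenced-equation oracle", {
  cfg <- gsa_config(n = 3, t_max = 10)
  space <- search_space(lower = rep(-5, 2), upper = rep(5, 2))
  pos <- matrix(c(1, -2, 3, 0.5, 2, -1), 3, 2)
  vel <- matrix(0.1, 3, 2)
  obj <- function(x) sum(x^2)
  fit <- apply(pos, 1, obj)
  swarm <- dipetkin:::new_swarm(pos, vel, fit, t = 2L)

  set.seed(77)
  out <- gsa_step(swarm, cfg, space, obj)

  # oracle: replay the documented draw order and apply the update equations
  set.seed(77)
  rw <- matrix(runif(9), 3, 3, byrow = TRUE)
  rv <- runif(3)
  g <- cfg$g0 * exp(-cfg$alpha * 2 / cfg$t_max)
  m <- update_masses(fit)
  kb <- as.integer(ceiling(3 - 2 * 2 / 10))
  acc <- t(sapply(1:3, function(i) {
    elite <- order(fit)[seq_len(kb)]
    f <- numeric(2)
    for (j in setdiff(elite, i)) {
      diffv <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(diffv^2))
      f <- f + rw[i, j] * g * m[j] / (r + cfg$epsilon) * diffv
    }
    f  # a_i: inertial mass cancels against the passive mass
  }))
  vel2 <- rv * vel + acc
  pos2 <- pos + vel2
  hit <- pos2 < -5 | pos2 > 5
  pos2 <- pmin(pmax(pos2, -5), 5); vel2[hit] <- 0

  expect_equal(out$positions, pos2, tolerance = 1e-13)
  expect_equal(out$velocities, vel2, tolerance = 1e-13)
  expect_equal(out$fitness, apply(pos2, 1, obj), tolerance = 1e-13)
  expect_equal(out$t, 3L)

  # zero forces + zero velocities leave positions fixed
  still <- dipetkin:::new_swarm(pos, matrix(0, 3, 2), rep(2, 3), t = 0L)
  cfg0 <- gsa_config(n = 3, t_max = 10, g0 = 1e-300)
  out0 <- gsa_step(still, cfg0, space, obj)
  expect_equal(out0$positions, pos, tolerance = 1e-10)
})

test_that("one chaotic step reproduces the sequenced-equation oracle", {
  cfg <- gsa_config(n = 3, t_max = 10, variant = "dcgsa")
  space <- search_space(lower = rep(-5, 2), upper = rep(5, 2))
  pos <- matrix(c(1, -2, 3, 0.5, 2, -1), 3, 2)
  vel <- matrix(0.2, 3, 2)
  obj <- function(x) sum(x^2)
  fit <- apply(pos, 1, obj)
  swarm <- dipetkin:::new_swarm(pos, vel, fit, t = 5L)
  chaos <- c(0.3, 0.6, 0.11)

  set.seed(123)
  out <- dcgsa_step(swarm, cfg, space, obj, chaos)

  set.seed(123)
  rand_t <- runif(1)
  rw <- matrix(runif(9), 3, 3, byrow = TRUE)
  g <- cfg$g0 * exp(-cfg$alpha * (5 / 10)^1.5 * (rand_t + 5 / 10))
  m <- update_masses(fit)
  kb <- as.integer(ceiling(3 - 2 * 5 / 10))
  acc <- t(sapply(1:3, function(i) {
    elite <- order(fit)[seq_len(kb)]
    f <- numeric(2)
    for (j in setdiff(elite, i)) {
      diffv <- pos[j, ] - pos[i, ]
      r <- sqrt(sum(diffv^2))
      f <- f + rw[i, j] * g * m[j] / (r + cfg$epsilon) * diffv
    }
    f
  }))
  w <- 0.7 - (0.7 - 0.1) * 5 / 10
  expect_equal(w, 0.4)
  vel2 <- w * vel + acc
  chaos2 <- 4 * chaos * (1 - chaos)
  pos2 <- pos + vel2 * chaos2
  hit <- pos2 < -5 | pos2 > 5
  pos2 <- pmin(pmax(pos2, -5), 5); vel2[hit] <- 0

  expect_equal(out$chaos, chaos2)
  expect_equal(out$swarm$positions, pos2, tolerance = 1e-13)
  expect_equal(out$swarm$velocities, vel2, tolerance = 1e-13)
})

test_that("inertia weight interpolates linearly between its endpoints", {
  cfg <- gsa_config(variant = "dcgsa", t_max = 400)
  expect_equal(inertia_weight(0, cfg), 0.7)
  expect_equal(inertia_weight(400, cfg), 0.1)
  expect_equal(inertia_weight(200, cfg), 0.4)
})

test_that("logistic chaotic sequence iterates correctly and fills (0,1)", {
  expect_equal(chaotic_next(0.3), 0.84)
  expect_equal(chaotic_next(0.84), 0.5376)
  # degenerate orbit: 0.5 -> 1 -> 0
  expect_equal(chaotic_next(0.5), 1)
  expect_error(dipetkin:::check_chaotic_seed(0.5), "degenerate")
  expect_error(dipetkin:::check_chaotic_seed(0.25), "degenerate")
  expect_error(dipetkin:::check_chaotic_seed(1.2), "degenerate|\\(0,1\\)")

  # arcsine-like invariant density: mass piles near 0 and 1,
  # far from uniform by the KS statistic
  x <- numeric(1e5); x[1] <- 0.3123
  for (i in 2:1e5) x[i] <- chaotic_next(x[i - 1])
  ks <- suppressWarnings(stats::ks.test(x, "punif"))
  expect_gt(unname(ks$statistic), 0.1)
  expect_gt(mean(x < 0.1 | x > 0.9), 2 * 0.1)  # heavier tails than uniform
})

test_that("gsa_minimize solves standard benchmarks and is reproducible", {
  sp5 <- search_space(lower = rep(-5, 5), upper = rep(5, 5))
  sphere <- function(x) sum(x^2)
  quick <- gsa_config(n = 30, t_max = 150)
  f1 <- gsa_minimize(sphere, sp5, quick, seed = 4)
  f2 <- gsa_minimize(sphere, sp5, quick, seed = 4)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_lt(f1$fitness, 1e-2)
  expect_true(all(diff(f1$trace) <= 0))

  fd <- gsa_minimize(sphere, sp5, gsa_config(n = 30, t_max = 150,
                                             variant = "dcgsa"), seed = 4)
  fd2 <- gsa_minimize(sphere, sp5, gsa_config(n = 30, t_max = 150,
                                              variant = "dcgsa"), seed = 4)
  expect_identical(fd$par, fd2$par)
  expect_true(all(diff(fd$trace) <= 0))

  # non-finite objective values are tolerated
  nasty <- function(x) if (x[1] > 0) NaN else sum(x^2)
  fn <- gsa_minimize(nasty, sp5, gsa_config(n = 10, t_max = 30), seed = 1)
  expect_true(is.finite(fn$fitness))
})

test_that("swarm respects bounds and mass normalisation at every iteration", {
  sp <- search_space(lower = c(-1, 0), upper = c(1, 2))
  cfg <- gsa_config(n = 8, t_max = 40)
  obj <- function(x) (x[1] - 0.3)^2 + (x[2] - 1.1)^2
  set.seed(9)
  pos <- matrix(runif(16), 8, 2)
  pos <- sweep(sweep(pos, 2, sp$upper - sp$lower, "*"), 2, sp$lower, "+")
  swarm <- dipetkin:::new_swarm(pos, matrix(0, 8, 2), apply(pos, 1, obj))
  for (t in 1:40) {
    swarm <- gsa_step(swarm, cfg, sp, obj)
    expect_equal(sum(swarm$masses), 1, tolerance = 1e-12)
    expect_true(all(swarm$positions[, 1] >= -1 & swarm$positions[, 1] <= 1))
    expect_true(all(swarm$positions[, 2] >= 0 & swarm$positions[, 2] <= 2))
  }
})

test_that("config validation rejects degenerate settings", {
  expect_error(gsa_config(n = 1), "at least 2")
  expect_error(gsa_config(t_max = 0), "t_max")
  expect_error(gsa_config(g0 = -1), "g0")
  expect_error(gsa_config(omega_max = 0.1, omega_min = 0.7), "omega")
  expect_error(search_space(lower = c(0, 1), upper = c(1, 1)), "below")
})
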