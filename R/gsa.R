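#' Search space for the five kinetic parameters
#'
#' Box bounds for `(k1, k2, k3, k4, hpi)`. Defaults cover the range of
#' published dual-input liver FDG estimates with margin; the `hpi`
#' dimension is a fraction and is always bounded by `[0, 1]`.
#'
#' @param lower,upper numeric vectors of per-dimension bounds
#'   (`lower < upper` everywhere).
#' @return A list of class `search_space` with `lower`, `upper`, `d`.
#' @export
search_space <- function(lower = c(k1 = 0, k2 = 0, k3 = 0, k4 = 0, hpi = 0),
                         upper = c(k1 = 3, k2 = 3, k3 = 1, k4 = 0.5, hpi = 1)) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)))
  if (any(lower >= upper)) stop("each lower bound must be below its upper bound")
  if ("hpi" %in% names(lower) && (lower[["hpi"]] < 0 || upper[["hpi"]] > 1)) {
    stop("hpi bounds must lie within [0, 1]")
  }
  structure(list(lower = unname(lower), upper = unname(upper),
                 d = length(lower), names = names(lower)),
            class = "search_space")
}

#' Configuration for the gravitational search fitters
#'
#' @param n population size (>= 2).
#' @param t_max maximum number of iterations (>= 1).
#' @param g0 initial gravitational constant.
#' @param alpha decay constant of the gravitational schedule.
#' @param epsilon small constant guarding divisions.
#' @param variant `"gsa"` for the classic algorithm (Eqs with the
#'   exponentially decaying constant and random-velocity update) or
#'   `"dcgsa"` for the dynamic chaotic variant (randomised dynamic
#'   gravitational constant, linear inertia weight, chaotic step on the
#'   position update).
#' @param omega_max,omega_min inertia-weight endpoints of the linear
#'   schedule used by the chaotic variant (defaults 0.7 and 0.1).
#' @param kbest_final value `Kbest` decreases to at the final iteration
#'   (starts at `n`).
#' @param rand_force_per_dim draw the random force weights per dimension
#'   instead of once per particle pair.
#' @param g_dynamic_form exponent convention of the dynamic schedule:
#'   `"normalized"` (default) uses `alpha * (t/T)^1.5 * (rand_t + t/T)`,
#'   whose decay profile is independent of `T` and realises the intended
#'   large-steps-early / small-steps-late behaviour; `"unscaled"` uses
#'   `alpha * (t/T^1.5) * (rand_t + t/T)`, which for typical `T` leaves
#'   the constant within a factor of a few of `G0` throughout the run.
#'   See the methods vignette for the rationale.
#' @return A list of class `gsa_config`.
#' @export
gsa_config <- function(n = 50, t_max = 500, g0 = 100, alpha = 20,
                       epsilon = 1e-9, variant = c("gsa", "dcgsa"),
                       omega_max = 0.7, omega_min = 0.1,
                       kbest_final = 1, rand_force_per_dim = FALSE,
                       g_dynamic_form = c("normalized", "unscaled")) {
  variant <- match.arg(variant)
  g_dynamic_form <- match.arg(g_dynamic_form)
  if (n < 2) stop("population size n must be at least 2")
  if (t_max < 1) stop("t_max must be at least 1")
  if (g0 <= 0) stop("g0 must be positive")
  if (!(omega_max > omega_min && omega_min > 0)) {
    stop("need omega_max > omega_min > 0")
  }
  structure(list(n = n, t_max = t_max, g0 = g0, alpha = alpha,
                 epsilon = epsilon, variant = variant,
                 omega_max = omega_max, omega_min = omega_min,
                 kbest_final = kbest_final,
                 rand_force_per_dim = rand_force_per_dim,
                 g_dynamic_form = g_dynamic_form),
            class = "gsa_config")
}

#' Normalised inertial masses from fitness values
#'
#' For minimisation the best (lowest-fitness) individual gets raw mass 1
#' and the worst gets 0; raw masses are then normalised to sum to 1. When
#' every fitness is equal the mapping is 0/0 and masses are set uniform.
#'
#' @param fitness numeric vector of fitness values (lower is better).
#' @return Numeric vector of masses summing to 1.
#' @examples
#' update_masses(c(2, 4, 10))   # c(4, 3, 0) / 7
#' @export
update_masses <- function(fitness) {
  stopifnot(length(fitness) >= 2)
  fin <- is.finite(fitness)
  if (!any(fin)) return(rep(1 / length(fitness), length(fitness)))
  best <- min(fitness[fin]); worst <- max(fitness[fin])
  if (worst == best && all(fin)) return(rep(1 / length(fitness), length(fitness)))
  m <- (fitness - worst) / (best - worst)
  m[!fin] <- 0
  m / sum(m)
}

#' Gravitational constant schedules
#'
#' The classic schedule decays exponentially,
#' `G(t) = G0 exp(-alpha t / T)`. The dynamic schedule used by the chaotic
#' variant injects a fresh uniform random number each iteration,
#' `G'(t) = G0 exp(-alpha (t/T)^1.5 (rand_t + t / T))` in the default
#' normalized form, so the constant can jump between iterations while
#' decaying on average -- slower than the classic schedule early (longer
#' exploration), faster late (smaller mining steps). At `t = 0` both
#' schedules equal `G0` exactly. The `"unscaled"` form replaces
#' `(t/T)^1.5` by `t/T^1.5`; see [gsa_config()].
#'
#' @param t current iteration (0-based, `0 <= t <= t_max`).
#' @param cfg a [gsa_config()].
#' @param rand_t uniform(0,1) draw for the dynamic schedule; drawn
#'   internally if missing.
#' @return Scalar gravitational constant.
#' @export
gravitational_constant <- function(t, cfg) {
  cfg$g0 * exp(-cfg$alpha * t / cfg$t_max)
}

#' @rdname gravitational_constant
#' @export
dynamic_gravitational_constant <- function(t, cfg, rand_t = runif(1)) {
  frac <- if (identical(cfg$g_dynamic_form, "unscaled")) {
    t / cfg$t_max^1.5
  } else {
    (t / cfg$t_max)^1.5
  }
  cfg$g0 * exp(-cfg$alpha * frac * (rand_t + t / cfg$t_max))
}

#' Pairwise gravitational force between two candidates
#'
#' `F_ij^d = G * M_i M_j / (R_ij + eps) * (x_j^d - x_i^d)` with `R_ij` the
#' Euclidean distance: the force on `i` points toward `j` (attraction
#' toward mass, the convention required for the swarm to condense on good
#' solutions).
#'
#' @param i,j particle indices (`i != j`).
#' @param positions `n x d` matrix of positions.
#' @param masses normalised masses.
#' @param g gravitational constant.
#' @param epsilon small guard added to the distance.
#' @return Length-`d` force vector acting on `i`.
#' @export
pairwise_force <- function(i, j, positions, masses, g, epsilon = 1e-9) {
  stopifnot(i != j)
  diff <- positions[j, ] - positions[i, ]
  r <- sqrt(sum(diff^2))
  g * masses[i] * masses[j] / (r + epsilon) * diff
}

# Kbest: linear decrease from n at t=0 to kbest_final at t=t_max, rounded up
kbest_at <- function(t, cfg) {
  as.integer(ceiling(cfg$n - (cfg$n - cfg$kbest_final) * t / cfg$t_max))
}

#' Resultant stochastic force on one particle
#'
#' Sums the pairwise forces from the `kbest` best-fitness particles
#' (excluding `i` itself), each weighted by a uniform(0,1) random number.
#' The weights are supplied as a full `n x n` matrix (row `i`, column `j`)
#' so the draw order is independent of `kbest`; by default one weight per
#' ordered pair is used for all dimensions.
#'
#' @param i particle index.
#' @param positions `n x d` positions.
#' @param masses normalised masses.
#' @param fitness fitness vector (defines the Kbest elite).
#' @param g gravitational constant.
#' @param kbest number of elite attractors (`1 <= kbest <= n`).
#' @param rand_w `n x n` matrix of uniform weights.
#' @param epsilon distance guard.
#' @return Length-`d` force vector.
#' @export
resultant_force <- function(i, positions, masses, fitness, g, kbest, rand_w,
                            epsilon = 1e-9) {
  elite <- order(fitness)[seq_len(kbest)]
  f <- numeric(ncol(positions))
  for (j in setdiff(elite, i)) {
    f <- f + rand_w[i, j] * pairwise_force(i, j, positions, masses, g, epsilon)
  }
  f
}

# Vectorised forces + accelerations for the whole swarm.
# Random draw order per iteration (fixed contract, relied on by tests):
#   [dcgsa only] rand_t (1 draw) -> rand_w (n x n, byrow) ->
#   [gsa only] rand_v (n draws)
swarm_accelerations <- function(positions, masses, fitness, g, kbest, rand_w,
                                epsilon) {
  n <- nrow(positions); d <- ncol(positions)
  elite <- order(fitness)[seq_len(kbest)]
  acc <- matrix(0, n, d)
  per_dim <- length(dim(rand_w)) == 3L
  for (j in elite) {
    diff <- sweep(positions, 2, positions[j, ], "-") * -1  # x_j - x_i rows
    r <- sqrt(rowSums(diff^2))
    # a_i = F_i / M_i with F_ij ~ M_i M_j: the inertial M_i cancels against
    # the passive M_i in the force, leaving a_i = sum_j rand G M_j d/(R+eps).
    # Zero-mass (worst, possibly tied) particles take M_i = eps on both
    # sides, which preserves the cancellation -- they must keep moving or
    # the swarm sheds particles at the bounds.
    base <- g * masses[j] / (r + epsilon)
    base[j] <- 0  # no self-force
    if (per_dim) {
      acc <- acc + diff * (rand_w[, j, ] * base)
    } else {
      acc <- acc + diff * (rand_w[, j] * base)
    }
  }
  acc
}

draw_force_weights <- function(cfg, d) {
  n <- cfg$n
  if (isTRUE(cfg$rand_force_per_dim)) {
    array(runif(n * n * d), c(n, n, d))
  } else {
    matrix(runif(n * n), n, n, byrow = TRUE)
  }
}

new_swarm <- function(positions, velocities, fitness, t = 0L) {
  list(positions = positions, velocities = velocities, fitness = fitness,
       masses = update_masses(fitness), t = t)
}

# clip to bounds; velocity components that violated are zeroed
clip_positions <- function(positions, velocities, space) {
  lo <- matrix(space$lower, nrow(positions), ncol(positions), byrow = TRUE)
  hi <- matrix(space$upper, nrow(positions), ncol(positions), byrow = TRUE)
  hit <- positions < lo | positions > hi
  positions <- pmin(pmax(positions, lo), hi)
  velocities[hit] <- 0
  list(positions = positions, velocities = velocities)
}

#' One iteration of the classic gravitational search update
#'
#' Computes masses from the current fitness, the decaying gravitational
#' constant, stochastic resultant forces from the shrinking `Kbest` elite,
#' accelerations `a = F / M`, the random-inertia velocity update
#' `v <- rand * v + a` and position update `x <- x + v`, then clips to
#' bounds and re-evaluates fitness.
#'
#' @param swarm swarm state as returned by [gsa_step()]/[dcgsa_step()] or
#'   created internally by [gsa_minimize()].
#' @param cfg a [gsa_config()].
#' @param space a [search_space()].
#' @param objective function mapping a parameter vector to scalar fitness.
#' @return Updated swarm state (iteration counter advanced).
#' @export
gsa_step <- function(swarm, cfg, space, objective) {
  n <- cfg$n
  g <- gravitational_constant(swarm$t, cfg)
  rand_w <- draw_force_weights(cfg, ncol(swarm$positions))
  rand_v <- runif(n)
  kb <- kbest_at(swarm$t, cfg)
  acc <- swarm_accelerations(swarm$positions, swarm$masses, swarm$fitness,
                             g, kb, rand_w, cfg$epsilon)
  vel <- rand_v * swarm$velocities + acc
  pos <- swarm$positions + vel
  cl <- clip_positions(pos, vel, space)
  fit <- apply(cl$positions, 1, safe_objective, objective = objective)
  new_swarm(cl$positions, cl$velocities, fit, swarm$t + 1L)
}

#' One iteration of the dynamic chaotic gravitational search update
#'
#' As [gsa_step()], with three changes: the gravitational constant is the
#' randomised dynamic schedule, the velocity update uses the linear inertia
#' weight `W(t) = omega_max - (omega_max - omega_min) t / T` in place of the
#' random multiplier, and the position step is scaled by the particle's
#' next chaotic-sequence value, `x <- x + v * c(i)`.
#'
#' @inheritParams gsa_step
#' @param chaos numeric vector of per-particle logistic-map states.
#' @return List with `swarm` (updated state) and `chaos` (advanced states).
#' @export
dcgsa_step <- function(swarm, cfg, space, objective, chaos) {
  n <- cfg$n
  g <- dynamic_gravitational_constant(swarm$t, cfg, rand_t = runif(1))
  rand_w <- draw_force_weights(cfg, ncol(swarm$positions))
  kb <- kbest_at(swarm$t, cfg)
  acc <- swarm_accelerations(swarm$positions, swarm$masses, swarm$fitness,
                             g, kb, rand_w, cfg$epsilon)
  w <- inertia_weight(swarm$t, cfg)
  vel <- w * swarm$velocities + acc
  chaos <- vapply(chaos, chaotic_next, numeric(1))
  pos <- swarm$positions + vel * chaos
  cl <- clip_positions(pos, vel, space)
  fit <- apply(cl$positions, 1, safe_objective, objective = objective)
  list(swarm = new_swarm(cl$positions, cl$velocities, fit, swarm$t + 1L),
       chaos = chaos)
}

#' Linear inertia-weight schedule
#'
#' `W(t) = omega_max - (omega_max - omega_min) * t / T`; defaults run from
#' 0.7 at the first iteration to 0.1 at the last, trading early exploration
#' for late exploitation.
#'
#' @inheritParams gravitational_constant
#' @return Scalar weight.
#' @export
inertia_weight <- function(t, cfg) {
  cfg$omega_max - (cfg$omega_max - cfg$omega_min) * t / cfg$t_max
}

#' Logistic chaotic sequence
#'
#' The chaotic driver of the position update: the logistic map
#' `x <- 4 x (1 - x)`, whose iterates fill (0,1) aperiodically for generic
#' seeds (arcsine-distributed, mass piling near 0 and 1). Seeds 0.25, 0.5
#' and 0.75 sit on fixed or short-periodic orbits that collapse to 0 and
#' are rejected.
#'
#' @param state current value in (0, 1).
#' @return Next value.
#' @examples
#' chaotic_next(0.3)   # 0.84
#' @export
chaotic_next <- function(state) 4 * state * (1 - state)

#' @rdname chaotic_next
#' @param n number of seeds to draw.
#' @export
chaotic_seeds <- function(n) {
  s <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- runif(1, 0.01, 0.99)
      if (min(abs(x - c(0.25, 0.5, 0.75))) > 1e-3) { s[i] <- x; break }
    }
  }
  s
}

check_chaotic_seed <- function(state) {
  if (!is.finite(state) || state <= 0 || state >= 1 ||
      min(abs(state - c(0.25, 0.5, 0.75))) < 1e-12) {
    stop("chaotic seed must lie in (0,1) away from the degenerate orbits 0.25, 0.5, 0.75")
  }
  state
}

safe_objective <- function(x, objective) {
  v <- tryCatch(objective(x), error = function(e) Inf)
  if (!is.finite(v)) Inf else v
}

#' Minimise an objective with the gravitational search fitters
#'
#' Runs `t_max` iterations of [gsa_step()] or [dcgsa_step()] according to
#' `cfg$variant`, tracking the best solution ever evaluated. Candidates
#' with non-finite objective values are assigned infinite fitness and the
#' run continues. Fully reproducible under a fixed `seed`.
#'
#' @param objective function of a length-`d` parameter vector.
#' @param space a [search_space()].
#' @param cfg a [gsa_config()].
#' @param seed integer seed for all randomness (initial population, force
#'   weights, chaotic seeds).
#' @return A `kin_fit` object; see [fit_tac()] for the fields.
#' @examples
#' sphere <- function(x) sum(x^2)
#' sp <- search_space(lower = rep(-5, 5), upper = rep(5, 5))
#' fit <- gsa_minimize(sphere, sp, gsa_config(n = 30, t_max = 100), seed = 1)
#' fit$fitness
#' @export
gsa_minimize <- function(objective, space, cfg = gsa_config(), seed = 1L) {
  stopifnot(inherits(space, "search_space"), inherits(cfg, "gsa_config"))
  set.seed(seed)
  n <- cfg$n; d <- space$d
  pos <- matrix(runif(n * d), n, d, byrow = TRUE)
  pos <- sweep(sweep(pos, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  chaos <- if (cfg$variant == "dcgsa") chaotic_seeds(n) else NULL
  fit <- apply(pos, 1, safe_objective, objective = objective)
  swarm <- new_swarm(pos, matrix(0, n, d), fit)

  ib <- which.min(fit)
  best_x <- pos[ib, ]; best_f <- fit[ib]
  trace <- numeric(cfg$t_max + 1L)
  trace[1L] <- best_f
  for (t in seq_len(cfg$t_max)) {
    if (cfg$variant == "dcgsa") {
      st <- dcgsa_step(swarm, cfg, space, objective, chaos)
      swarm <- st$swarm; chaos <- st$chaos
    } else {
      swarm <- gsa_step(swarm, cfg, space, objective)
    }
    ib <- which.min(swarm$fitness)
    if (swarm$fitness[ib] < best_f) {
      best_f <- swarm$fitness[ib]
      best_x <- swarm$positions[ib, ]
    }
    trace[t + 1L] <- best_f
  }
  if (!is.null(space$names)) names(best_x) <- space$names
  new_kin_fit(par = best_x, fitness = best_f, trace = trace,
              method = cfg$variant, seed = seed,
              config = cfg, space = space)
}
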