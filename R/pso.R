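#' Particle swarm optimizer configuration
#'
#' Settings for the inertia-weight PSO used to train the fuzzy model. Both
#' attraction constants default to 2.0; the inertia weight decays linearly
#' from `w_max` to `w_min` over the iteration budget (the inertia weight
#' approach, IWA).
#'
#' @param n_particles Swarm size (default 30).
#' @param max_iters Iteration budget; the run always uses the full budget,
#'   since the inertia schedule is defined relative to it (default 200).
#' @param c1,c2 Personal-best and global-best learning rates (default 2.0).
#' @param w_max,w_min Initial and final inertia weights (defaults 0.9, 0.4).
#' @param seed RNG seed for the run.
#' @param lower,upper Optional per-dimension position bounds (may be
#'   infinite); filled in by [anfis_train()] from the model when absent.
#' @param init_lower,init_upper Optional initialization window; defaults to
#'   the bounds where they are finite.
#' @param v_max_frac Velocity cap as a fraction of the per-dimension bound
#'   width (default 0.2); for unbounded dimensions the initialization
#'   window width is used instead.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(n_particles = 30L, max_iters = 200L,
                       c1 = 2.0, c2 = 2.0, w_max = 0.9, w_min = 0.4,
                       seed = 1L, lower = NULL, upper = NULL,
                       init_lower = NULL, init_upper = NULL,
                       v_max_frac = 0.2) {
  stopifnot(n_particles >= 2L, max_iters >= 1L,
            w_max >= w_min, w_min >= 0, c1 >= 0, c2 >= 0, v_max_frac > 0)
  structure(list(n_particles = as.integer(n_particles),
                 max_iters = as.integer(max_iters),
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 seed = as.integer(seed), lower = lower, upper = upper,
                 init_lower = init_lower, init_upper = init_upper,
                 v_max_frac = v_max_frac),
            class = "pso_config")
}

#' Linearly decaying inertia weight
#'
#' `w(itr) = w_max - (w_max - w_min) * itr / max_iters`: the swarm explores
#' broadly early (high inertia) and settles into local refinement late.
#'
#' @param cfg A [pso_config()].
#' @param itr Current iteration, `0 <= itr <= max_iters`.
#' @return The inertia weight at `itr`.
#' @export
inertia_weight <- function(cfg, itr) {
  if (itr < 0 || itr > cfg$max_iters)
    stop("iteration ", itr, " outside [0, ", cfg$max_iters, "]")
  cfg$w_max - (cfg$w_max - cfg$w_min) * itr / cfg$max_iters
}

#' Velocity update rule
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, element-wise; `r1`
#' and `r2` are uniform random factors drawn per dimension.
#'
#' @param v,x Current velocity and position vectors.
#' @param pbest,gbest Personal-best and global-best positions.
#' @param w Inertia weight.
#' @param c1,c2 Learning rates.
#' @param r1,r2 Random factors in `[0, 1]` (vectors or scalars).
#' @return Updated velocity vector.
#' @export
pso_velocity <- function(v, x, pbest, gbest, w, c1, c2, r1, r2) {
  w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
}

# Resolve initialization window and velocity cap from a config.
pso_resolve <- function(cfg, D) {
  lower <- if (is.null(cfg$lower)) rep(-Inf, D) else rep_len(cfg$lower, D)
  upper <- if (is.null(cfg$upper)) rep(Inf, D) else rep_len(cfg$upper, D)
  init_lo <- if (is.null(cfg$init_lower))
    ifelse(is.finite(lower), lower, -5) else rep_len(cfg$init_lower, D)
  init_hi <- if (is.null(cfg$init_upper))
    ifelse(is.finite(upper), upper, 5) else rep_len(cfg$init_upper, D)
  if (any(init_hi < init_lo)) stop("invalid initialization window")
  width <- ifelse(is.finite(upper - lower), upper - lower, init_hi - init_lo)
  list(lower = lower, upper = upper, init_lower = init_lo,
       init_upper = init_hi, v_max = cfg$v_max_frac * width)
}

# Evaluate fitness defensively: any non-finite value becomes +Inf.
safe_fitness <- function(fitness, x) {
  f <- fitness(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) Inf else f
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly within the initialization window;
#' velocities start at zero. If `init_position` is given, particle 1 is
#' placed there (seeding the swarm with a heuristic solution, e.g. the
#' grid-partition defaults).
#'
#' @param cfg A [pso_config()] with bounds set.
#' @param D Search-space dimension.
#' @param fitness Function mapping a position vector to a scalar.
#' @param init_position Optional D-vector for particle 1.
#' @return A list of class `swarm` with `position` and `velocity`
#'   (`n_particles x D` matrices), `pbest_position`, `pbest_fitness`,
#'   `gbest_position`, `gbest_fitness` and `iteration = 0`.
#' @export
pso_init <- function(cfg, D, fitness, init_position = NULL) {
  bx <- pso_resolve(cfg, D)
  pos <- matrix(0, cfg$n_particles, D)
  for (p in seq_len(cfg$n_particles))
    pos[p, ] <- stats::runif(D, bx$init_lower, bx$init_upper)
  if (!is.null(init_position)) {
    stopifnot(length(init_position) == D)
    pos[1L, ] <- init_position
  }
  fit <- vapply(seq_len(cfg$n_particles),
                function(p) safe_fitness(fitness, pos[p, ]), numeric(1L))
  g <- which.min(fit)
  structure(list(position = pos,
                 velocity = matrix(0, cfg$n_particles, D),
                 pbest_position = pos, pbest_fitness = fit,
                 gbest_position = pos[g, ], gbest_fitness = fit[g],
                 iteration = 0L, bounds = bx),
            class = "swarm")
}

#' Advance the swarm by one iteration
#'
#' Applies the velocity and position update to every particle with
#' per-dimension random factors, caps velocities, clamps positions to the
#' bounds (zeroing the offending velocity component), re-evaluates fitness
#' and updates personal and global bests. The global best is updated
#' asynchronously (as soon as a particle improves on it) and is therefore
#' non-increasing across iterations by construction.
#'
#' @param swarm A `swarm` from [pso_init()] or a previous step.
#' @param cfg The [pso_config()] used to create it.
#' @param fitness Fitness function.
#' @return The updated `swarm`.
#' @export
pso_step <- function(swarm, cfg, fitness) {
  itr <- swarm$iteration + 1L
  w <- inertia_weight(cfg, itr)
  bx <- swarm$bounds
  D <- ncol(swarm$position)
  for (p in seq_len(cfg$n_particles)) {
    r1 <- stats::runif(D); r2 <- stats::runif(D)
    v <- pso_velocity(swarm$velocity[p, ], swarm$position[p, ],
                      swarm$pbest_position[p, ], swarm$gbest_position,
                      w, cfg$c1, cfg$c2, r1, r2)
    v <- pmin(pmax(v, -bx$v_max), bx$v_max)
    x <- swarm$position[p, ] + v
    at_lo <- x < bx$lower; at_hi <- x > bx$upper
    x[at_lo] <- bx$lower[at_lo]; x[at_hi] <- bx$upper[at_hi]
    v[at_lo | at_hi] <- 0
    f <- safe_fitness(fitness, x)
    swarm$position[p, ] <- x
    swarm$velocity[p, ] <- v
    if (f < swarm$pbest_fitness[p]) {
      swarm$pbest_fitness[p] <- f
      swarm$pbest_position[p, ] <- x
      # asynchronous global-best update: later particles in the same
      # iteration are attracted to improvements found in this sweep
      if (f < swarm$gbest_fitness) {
        swarm$gbest_fitness <- f
        swarm$gbest_position <- x
      }
    }
  }
  swarm$iteration <- itr
  swarm
}

#' Run the optimizer to its iteration budget
#'
#' Seeds the RNG from the config, initializes the swarm and performs
#' `max_iters` steps. Identical (fitness, config, seed) give bit-identical
#' trajectories.
#'
#' @param fitness Function mapping a D-vector to a scalar to minimize.
#' @param D Search-space dimension.
#' @param cfg A [pso_config()].
#' @param init_position Optional heuristic start for particle 1.
#' @return List with `par` (best position), `value` (best fitness),
#'   `history` (global-best fitness after initialization and after each
#'   iteration, length `max_iters + 1`) and the final `swarm`.
#' @export
pso_optimize <- function(fitness, D, cfg = pso_config(),
                         init_position = NULL) {
  set.seed(cfg$seed)
  swarm <- pso_init(cfg, D, fitness, init_position)
  history <- numeric(cfg$max_iters + 1L)
  history[1L] <- swarm$gbest_fitness
  for (itr in seq_len(cfg$max_iters)) {
    swarm <- pso_step(swarm, cfg, fitness)
    history[itr + 1L] <- swarm$gbest_fitness
  }
  list(par = swarm$gbest_position, value = swarm$gbest_fitness,
       history = history, swarm = swarm)
}

#' Write a fitness-history table
#'
#' Emits a plain-text two-column table (iteration, gbest_rmse) suitable
#' for plotting a convergence curve.
#'
#' @param history Numeric vector as returned in `$history`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitness_history <- function(history, path) {
  utils::write.table(
    data.frame(iteration = seq_along(history) - 1L, gbest_rmse = history),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
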