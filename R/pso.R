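#' Particle swarm optimizer configuration
#'
#' Settings for both the standard inertia-weight PSO and the improved
#' variant. The improved variant replaces the fixed inertia schedule with a
#' per-particle, fitness-proportional adaptive weight ([adapt_inertia()]) and
#' adds a position-mutation escape mechanism with probability `pm`
#' ([mutate_position()]); both can be disabled independently.
#'
#' @param bounds D x 2 matrix (or length-2 vector recycled) of per-dimension
#'   (low, high) box constraints; mandatory — the search space must be bounded.
#' @param n_particles swarm size (default 50).
#' @param max_iter maximum iterations (default 200).
#' @param c1 cognition learning factor (attraction to the particle's own
#'   best), default 2.
#' @param c2 social learning factor (attraction to the swarm best), default 2.
#' @param w_init inertia weight at iteration 1 for the standard schedule.
#' @param w_min,w_max inertia-weight range, `w_min <= w_max`.
#' @param pm mutation probability in `[0, 1]` (improved variant only).
#' @param vmax per-dimension velocity cap; default 0.2 x (high - low).
#' @param improved use the adaptive-inertia + mutation variant (default TRUE);
#'   FALSE gives the standard PSO with a linearly decreasing inertia weight
#'   from `w_init` to `w_min`.
#' @param fitness_floor stop early once the swarm best reaches this value
#'   (default 0: run all iterations for non-negative objectives... and any
#'   objective bounded below by 0).
#' @param seed integer seed; the full run is reproducible from it.
#' @return object of class `pso_config`.
#' @export
pso_config <- function(bounds, n_particles = 50L, max_iter = 200L,
                       c1 = 2, c2 = 2, w_init = 0.9, w_min = 0.4, w_max = 0.9,
                       pm = 0.05, vmax = NULL, improved = TRUE,
                       fitness_floor = 0, seed = 1L) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, ncol = 2L, byrow = TRUE)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(!is.finite(bounds)))
    stop("bounds must be a finite D x 2 matrix of (low, high)", call. = FALSE)
  if (any(bounds[, 1L] >= bounds[, 2L]))
    stop("each lower bound must be strictly below its upper bound",
         call. = FALSE)
  if (n_particles < 2L) stop("n_particles must be >= 2", call. = FALSE)
  if (max_iter < 0L) stop("max_iter must be >= 0", call. = FALSE)
  if (pm < 0 || pm > 1) stop("pm must lie in [0, 1]", call. = FALSE)
  if (w_min > w_max) stop("w_min must be <= w_max", call. = FALSE)
  if (is.null(vmax)) vmax <- 0.2 * (bounds[, 2L] - bounds[, 1L])
  vmax <- rep_len(vmax, nrow(bounds))
  structure(list(bounds = bounds, dim = nrow(bounds),
                 n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter),
                 c1 = c1, c2 = c2, w_init = w_init, w_min = w_min,
                 w_max = w_max, pm = pm, vmax = vmax,
                 improved = isTRUE(improved), fitness_floor = fitness_floor,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Adaptive inertia weight of the improved PSO
#'
#' Particles at least as fit as the swarm average are considered close to the
#' global optimum and receive a small inertia weight, interpolated linearly
#' between `w_min` (for the swarm's best fitness) and `w_max` (at the
#' average); particles worse than the average need larger position changes
#' and receive `w_max`. When best and average coincide the weight is `w_min`.
#'
#' @param particle_fit this particle's current fitness (smaller = better).
#' @param fit_min the swarm's minimum (best) fitness this iteration.
#' @param fit_avg the swarm's mean fitness this iteration
#'   (`fit_min <= fit_avg`).
#' @param config a [pso_config()] supplying `w_min`, `w_max`.
#' @return inertia weight in `[w_min, w_max]`.
#' @export
adapt_inertia <- function(particle_fit, fit_min, fit_avg, config) {
  w <- ifelse(
    particle_fit <= fit_avg,
    if (fit_avg > fit_min)
      config$w_min + (config$w_max - config$w_min) *
        (particle_fit - fit_min) / (fit_avg - fit_min)
    else config$w_min,
    config$w_max)
  pmin(pmax(w, config$w_min), config$w_max)
}

#' Uniform position mutation
#'
#' With probability `pm` the particle's position is re-drawn uniformly within
#' the bounds (an escape mechanism against premature convergence); otherwise
#' it is returned unchanged. Draws from R's global RNG stream.
#'
#' @param position length-D position within bounds.
#' @param pm mutation probability.
#' @param bounds D x 2 bounds matrix.
#' @return length-D position.
#' @export
mutate_position <- function(position, pm, bounds) {
  if (stats::runif(1L) < pm)
    stats::runif(length(position), bounds[, 1L], bounds[, 2L])
  else position
}

init_swarm <- function(objective, config) {
  D <- config$dim
  N <- config$n_particles
  pos <- matrix(stats::runif(N * D), N, D)
  pos <- sweep(sweep(pos, 2L, config$bounds[, 2L] - config$bounds[, 1L], "*"),
               2L, config$bounds[, 1L], "+")
  fit <- evaluate_swarm(objective, pos)
  g <- which.min(fit)
  structure(list(positions = pos, velocities = matrix(0, N, D),
                 fitness = fit, pbest_pos = pos, pbest_fit = fit,
                 gbest_pos = pos[g, ], gbest_fit = fit[g],
                 iteration = 0L, gbest_history = fit[g]),
            class = "swarm_state")
}

evaluate_swarm <- function(objective, pos) {
  fit <- apply(pos, 1L, function(x) {
    v <- tryCatch(objective(x), error = function(e) NA_real_)
    if (length(v) != 1L || !is.finite(v)) Inf else as.numeric(v)
  })
  if (any(is.infinite(fit)))
    message(sum(is.infinite(fit)),
            " particle(s) returned a non-finite objective; treated as +Inf")
  fit
}

#' One particle-swarm iteration
#'
#' Velocity update \eqn{v \gets w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)}
#' followed by \eqn{x \gets x + v}, with `r1`, `r2` drawn fresh per particle
#' and dimension in `[0, 1]`; velocities are clipped to `+/- vmax`, positions
#' to the bounds. In the improved variant the inertia weight is adapted per
#' particle from the current fitness spread and each particle may then be
#' mutated with probability `pm`. Finally the swarm is re-evaluated and
#' personal/global bests updated by strict improvement (so a non-finite
#' objective can never degrade the bests). Uses R's global RNG stream: seed
#' externally or via [run_pso()].
#'
#' @param state a swarm state as produced by [run_pso()]'s initializer or a
#'   previous `pso_step` call.
#' @param objective function mapping a length-D vector to one real.
#' @param config a [pso_config()].
#' @return the advanced swarm state.
#' @export
pso_step <- function(state, objective, config) {
  stopifnot(inherits(state, "swarm_state"), inherits(config, "pso_config"))
  N <- config$n_particles
  D <- config$dim
  finite_fit <- state$fitness[is.finite(state$fitness)]
  if (config$improved && length(finite_fit)) {
    w <- adapt_inertia(state$fitness, min(finite_fit), mean(finite_fit),
                       config)
    w[!is.finite(w)] <- config$w_max
  } else {
    # standard PSO: inertia decreases linearly from w_init to w_min
    frac <- if (config$max_iter > 1L)
      min(state$iteration, config$max_iter - 1L) / (config$max_iter - 1L)
    else 0
    w <- rep(config$w_init - (config$w_init - config$w_min) * frac, N)
  }
  r1 <- matrix(stats::runif(N * D), N, D)
  r2 <- matrix(stats::runif(N * D), N, D)
  gmat <- matrix(state$gbest_pos, N, D, byrow = TRUE)
  v <- w * state$velocities +
    config$c1 * r1 * (state$pbest_pos - state$positions) +
    config$c2 * r2 * (gmat - state$positions)
  v <- pmin(pmax(v, matrix(-config$vmax, N, D, byrow = TRUE)),
            matrix(config$vmax, N, D, byrow = TRUE))
  x <- state$positions + v
  x <- pmin(pmax(x, matrix(config$bounds[, 1L], N, D, byrow = TRUE)),
            matrix(config$bounds[, 2L], N, D, byrow = TRUE))
  if (config$improved && config$pm > 0) {
    for (i in seq_len(N))
      x[i, ] <- mutate_position(x[i, ], config$pm, config$bounds)
  }
  fit <- evaluate_swarm(objective, x)
  better <- fit < state$pbest_fit
  state$pbest_pos[better, ] <- x[better, , drop = FALSE]
  state$pbest_fit[better] <- fit[better]
  g <- which.min(state$pbest_fit)
  state$positions <- x
  state$velocities <- v
  state$fitness <- fit
  state$gbest_pos <- state$pbest_pos[g, ]
  state$gbest_fit <- state$pbest_fit[g]
  state$iteration <- state$iteration + 1L
  state$gbest_history <- c(state$gbest_history, state$gbest_fit)
  state
}

#' Run a particle swarm optimization
#'
#' Initializes the swarm uniformly within the bounds with zero velocities,
#' evaluates it, then iterates [pso_step()] until `max_iter` iterations or
#' until the swarm best reaches `fitness_floor`. Fully reproducible from
#' `config$seed`. With `max_iter = 0` the best of the initial population is
#' returned.
#'
#' @param objective function mapping a length-D vector to one real (smaller =
#'   better); non-finite values are treated as `+Inf`.
#' @param config a [pso_config()].
#' @return list with `best_position`, `best_fitness`, `gbest_history` (swarm
#'   best after the initial evaluation and after each iteration; always
#'   non-increasing), `iterations`, and the final `state`.
#' @export
run_pso <- function(objective, config) {
  stopifnot(inherits(config, "pso_config"))
  set.seed(config$seed)
  state <- init_swarm(objective, config)
  while (state$iteration < config$max_iter &&
         state$gbest_fit > config$fitness_floor) {
    state <- pso_step(state, objective, config)
  }
  list(best_position = state$gbest_pos, best_fitness = state$gbest_fit,
       gbest_history = state$gbest_history, iterations = state$iteration,
       state = state)
}

#' Tune LSSVM hyper-parameters with (improved) PSO
#'
#' Each particle encodes `(log10 gamma, log10 sigma)`, so decoded parameters
#' are always positive and the search is scale-free. A particle's fitness is
#' the RMSE between predicted and actual values on held-out data within the
#' training block, either the final `holdout` fraction (temporal order
#' respected; the default) or `folds`-fold cross-validation.
#'
#' @param X,y the forecasting training block.
#' @param config a [pso_config()] with `dim = 2`; bounds are
#'   `(log10 gamma, log10 sigma)` boxes.
#' @param holdout fraction of the block held out for fitness evaluation
#'   (default 0.2, the last rows).
#' @param folds if non-NULL, use k-fold CV fitness instead of the holdout.
#' @return list with `gamma`, `sigma`, `fitness` (the winning validation
#'   RMSE), `gbest_history` and `iterations`.
#' @export
tune_lssvm <- function(X, y, config, holdout = 0.2, folds = NULL) {
  stopifnot(inherits(config, "pso_config"))
  if (config$dim != 2L)
    stop("config$dim must be 2: particles encode (log10 gamma, log10 sigma)",
         call. = FALSE)
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (is.null(folds)) {
    n_val <- floor(N * holdout)
    if (n_val < 1L || N - n_val < 2L)
      stop("training block too small for the holdout validation scheme",
           call. = FALSE)
    tr <- seq_len(N - n_val)
    va <- seq.int(N - n_val + 1L, N)
    objective <- function(p) {
      m <- train_lssvm(X[tr, , drop = FALSE], y[tr],
                       gamma = 10^p[1L], sigma = 10^p[2L])
      sqrt(mean((predict(m, X[va, , drop = FALSE]) - y[va])^2))
    }
  } else {
    folds <- as.integer(folds)
    if (N < folds)
      stop("training block too small for ", folds, "-fold validation",
           call. = FALSE)
    fold_id <- rep_len(seq_len(folds), N)  # contiguous-free but deterministic
    objective <- function(p) {
      errs <- vapply(seq_len(folds), function(f) {
        m <- train_lssvm(X[fold_id != f, , drop = FALSE], y[fold_id != f],
                         gamma = 10^p[1L], sigma = 10^p[2L])
        sqrt(mean((predict(m, X[fold_id == f, , drop = FALSE]) -
                     y[fold_id == f])^2))
      }, numeric(1L))
      mean(errs)
    }
  }
  res <- run_pso(objective, config)
  list(gamma = 10^res$best_position[1L], sigma = 10^res$best_position[2L],
       fitness = res$best_fitness, gbest_history = res$gbest_history,
       iterations = res$iterations)
}
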