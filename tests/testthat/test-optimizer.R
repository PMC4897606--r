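test_that("adaptive inertia follows the fitness-proportional rule", {
  cfg <- pso_config(bounds = rbind(c(-1, 1)), w_min = 0.4, w_max = 0.9)
  # best particle gets the smallest weight
  expect_equal(adapt_inertia(1, 1, 3, cfg), 0.4)
  # worse than average gets the largest
  expect_equal(adapt_inertia(5, 1, 3, cfg), 0.9)
  # linear in between
  expect_equal(adapt_inertia(2, 1, 3, cfg), 0.4 + 0.5 * 0.5)
  # degenerate swarm (all equal) collapses to w_min
  expect_equal(adapt_inertia(2, 2, 2, cfg), 0.4)
  # always inside [w_min, w_max]
  for (f in seq(0, 4, by = 0.25))
    expect_true(adapt_inertia(f, 0, 2, cfg) >= 0.4 &&
                  adapt_inertia(f, 0, 2, cfg) <= 0.9)
})

test_that("mutation redraws positions at the configured probability", {
  b <- rbind(c(-2, 2), c(0, 10))
  x <- c(1, 5)
  set.seed(1)
  expect_identical(mutate_position(x, 0, b), x)
  set.seed(2)
  y <- mutate_position(x, 1, b)
  expect_false(identical(y, x))
  expect_true(all(y >= b[, 1] & y <= b[, 2]))

  set.seed(3)
  n <- 10000
  hits <- sum(vapply(seq_len(n), function(i)
    !identical(mutate_position(x, 0.05, b), x), logical(1)))
  expect_lt(abs(hits - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("a swarm initialized at the optimum is a fixed point", {
  cfg <- pso_config(bounds = rbind(c(-5, 5), c(-5, 5)), n_particles = 3,
                    pm = 0, seed = 1)
  opt <- matrix(0, 3, 2)
  state <- structure(list(positions = opt, velocities = matrix(0, 3, 2),
                          fitness = rep(0, 3), pbest_pos = opt,
                          pbest_fit = rep(0, 3), gbest_pos = c(0, 0),
                          gbest_fit = 0, iteration = 0L, gbest_history = 0),
                     class = "swarm_state")
  set.seed(1)
  for (i in 1:5) state <- pso_step(state, function(x) sum(x^2), cfg)
  expect_equal(state$positions, opt)
  expect_equal(state$gbest_fit, 0)
})

test_that("with zero coupling, fixed inertia and zero velocity the swarm is static", {
  cfg <- pso_config(bounds = rbind(c(-5, 5), c(-5, 5)), n_particles = 4,
                    c1 = 0, c2 = 0, w_init = 0.7, w_min = 0.7, w_max = 0.7,
                    pm = 0, max_iter = 10, seed = 2)
  res <- run_pso(function(x) sum(x^2), cfg)
  # initial positions (uniform under the seed) must be untouched
  set.seed(2)
  p0 <- matrix(runif(8), 4, 2)
  p0 <- sweep(p0 * 10, 2, c(-5, -5), "+")
  expect_equal(res$state$positions, p0)
  expect_equal(res$state$velocities, matrix(0, 4, 2))
})

test_that("swarm best is monotone and positions stay within bounds", {
  set.seed(7)
  rough <- function(x) sum(x^2) + sum(10 * cos(3 * x))
  cfg <- pso_config(bounds = rbind(c(-4, 4), c(-4, 4)), n_particles = 12,
                    max_iter = 40, seed = 11)
  res <- run_pso(rough, cfg)
  expect_true(all(diff(res$gbest_history) <= 0))
  expect_true(all(res$state$positions >= -4 & res$state$positions <= 4))
  # both variants
  cfg$improved <- FALSE
  res2 <- run_pso(rough, cfg)
  expect_true(all(diff(res2$gbest_history) <= 0))
})

test_that("run_pso finds an analytic optimum under default settings", {
  f <- function(x) (x[1] - 2)^2 + (x[2] + 1)^2
  res <- run_pso(f, pso_config(bounds = rbind(c(-5, 5), c(-5, 5)),
                               seed = 42))
  expect_lt(max(abs(res$best_position - c(2, -1))), 0.05)
})

test_that("zero iterations returns the best of the initial population", {
  f <- function(x) sum((x - 1)^2)
  cfg <- pso_config(bounds = rbind(c(-3, 3), c(-3, 3)), n_particles = 8,
                    max_iter = 0, seed = 9)
  res <- run_pso(f, cfg)
  expect_equal(res$iterations, 0L)
  set.seed(9)
  p0 <- sweep(matrix(runif(16), 8, 2) * 6, 2, c(-3, -3), "+")
  expect_equal(res$best_fitness, min(apply(p0, 1, f)))
})

test_that("runs are reproducible and non-finite objectives are survived", {
  cfg <- pso_config(bounds = rbind(c(-2, 2), c(-2, 2)), n_particles = 6,
                    max_iter = 15, seed = 4)
  f <- function(x) sum(x^2)
  expect_identical(run_pso(f, cfg), run_pso(f, cfg))

  nasty <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_message(res <- run_pso(nasty, cfg), "non-finite")
  expect_true(is.finite(res$best_fitness))
  expect_lte(res$best_position[1], 0)
})

test_that("configuration invariants are enforced", {
  expect_error(pso_config(bounds = rbind(c(1, -1))), "lower bound")
  expect_error(pso_config(bounds = rbind(c(0, 1)), n_particles = 1),
               "n_particles")
  expect_error(pso_config(bounds = rbind(c(0, 1)), pm = 2), "pm")
  expect_error(pso_config(bounds = rbind(c(0, Inf))), "finite")
  cfg <- pso_config(bounds = rbind(c(0, 10)))
  expect_equal(cfg$vmax, 2)  # 0.2 x range
})

test_that("LSSVM tuning decodes positive parameters and is deterministic", {
  pd <- plant_lssvm_data(seed = 3, n = 40, n_train = 32)
  cfg <- pso_config(bounds = rbind(c(0, 4), c(-1, 1)), n_particles = 10,
                    max_iter = 15, seed = 5)
  t1 <- tune_lssvm(pd$X, pd$y, cfg)
  t2 <- tune_lssvm(pd$X, pd$y, cfg)
  expect_identical(t1[c("gamma", "sigma", "fitness")],
                   t2[c("gamma", "sigma", "fitness")])
  expect_gt(t1$gamma, 0)
  expect_gt(t1$sigma, 0)
  expect_error(tune_lssvm(pd$X, pd$y,
                          pso_config(bounds = rbind(c(0, 1)))), "dim")
  expect_error(tune_lssvm(pd$X[1:2, ], pd$y[1:2], cfg), "too small")
})

test_that("tuning a constant target reaches (near) zero fitness", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(4.2, 30)
  cfg <- pso_config(bounds = rbind(c(0, 4), c(-1, 1)), n_particles = 8,
                    max_iter = 10, seed = 6)
  tu <- tune_lssvm(X, y, cfg)
  expect_lt(tu$fitness, 1e-6)
  m <- train_lssvm(X, y, tu$gamma, tu$sigma)
  expect_equal(predict(m, X), y, tolerance = 1e-6)
})

test_that("k-fold fitness validation is supported", {
  pd <- plant_lssvm_data(seed = 8, n = 30, n_train = 30)
  cfg <- pso_config(bounds = rbind(c(0, 4), c(-1, 1)), n_particles = 6,
                    max_iter = 8, seed = 7)
  tu <- tune_lssvm(pd$X, pd$y, cfg, folds = 5)
  expect_true(is.finite(tu$fitness))
  expect_error(tune_lssvm(pd$X[1:3, ], pd$y[1:3], cfg, folds = 5),
               "too small")
})
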