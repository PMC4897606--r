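# Shared fixture builders. Everything is generated in code at test time.

# A small faulty frame under fixed seed.
small_frame <- function(n = 260, seed = 1, ...) {
  simulate_frame(synthetic_config(n_samples = n, seed = seed, ...))
}

# Data planted from an exactly-known LSSVM model. The targets are built so
# that the KKT system at (gamma, sigma) is satisfied by (alpha0, b0) exactly
# on the training rows (including the ridge term alpha0/gamma), and the
# validation targets are the planted model's own predictions; the planted
# parameters therefore achieve exactly zero validation RMSE.
plant_lssvm_data <- function(seed, n = 60, d = 3, n_train = 48,
                             gamma = 100, sigma = 1, b0 = 0.7) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  tr <- seq_len(n_train)
  va <- if (n_train < n) seq.int(n_train + 1L, n) else integer(0)
  ctr <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  a0 <- stats::rnorm(n_train)
  a0 <- a0 - mean(a0)
  Ks <- rbf_kernel_matrix(Xs[tr, , drop = FALSE], Xs[tr, , drop = FALSE],
                          sigma)
  y <- numeric(n)
  y[tr] <- drop(Ks %*% a0) + b0 + a0 / gamma
  if (length(va))
    y[va] <- drop(rbf_kernel_matrix(Xs[va, , drop = FALSE],
                                    Xs[tr, , drop = FALSE], sigma) %*% a0) +
      b0
  list(X = X, y = y, tr = tr, va = va, gamma = gamma, sigma = sigma)
}

# Independent brute-force KKT oracle: assembles the (N+1) x (N+1) dual
# system with its own scalar kernel arithmetic and inverts it directly.
kkt_oracle <- function(X, y, gamma, sigma) {
  X <- as.matrix(X)
  N <- nrow(X)
  K <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
  A <- rbind(c(0, rep(1, N)), cbind(rep(1, N), K + diag(N) / gamma))
  sol <- solve(A) %*% c(0, y)
  list(b = sol[1], alpha = sol[-1],
       predict = function(x) {
         k <- vapply(seq_len(N), function(i)
           exp(-sum((x - X[i, ])^2) / (2 * sigma^2)), numeric(1))
         sum(sol[-1] * k) + sol[1]
       })
}
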