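test_that("kmeans_centers handles exact, degenerate and error cases", {
  X <- rbind(c(0, 0), c(10, 10))
  km <- kmeans_centers(X, 2, seed = 1)
  expect_equal(km$centers[order(km$centers[, 1]), ], X, ignore_attr = TRUE)

  X2 <- matrix(rnorm(30), 10, 3)
  km1 <- kmeans_centers(X2, 1, seed = 1)
  expect_equal(drop(km1$centers), colMeans(X2), ignore_attr = TRUE)
  expect_true(all(km1$assignments == 1))

  expect_error(kmeans_centers(X2, 11), "K must satisfy")
  X2[1, 1] <- NA
  expect_error(kmeans_centers(X2, 2), "finite")
})

test_that("kmeans_centers solves a two-blob instance optimally", {
  set.seed(42)
  blob1 <- matrix(rnorm(20, 0, 1), 10, 2)
  blob2 <- matrix(rnorm(20, 100, 1), 10, 2)
  X <- rbind(blob1, blob2)
  km <- kmeans_centers(X, 2, seed = 7)
  cents <- km$centers[order(km$centers[, 1]), ]
  expect_lt(sqrt(sum((cents[1, ] - colMeans(blob1))^2)), 3)
  expect_lt(sqrt(sum((cents[2, ] - colMeans(blob2))^2)), 3)
  # oracle: the blob partition minimizes within-cluster SSE on this instance
  sse <- function(groups) sum(vapply(groups, function(idx) {
    sum(sweep(X[idx, , drop = FALSE], 2,
              colMeans(X[idx, , drop = FALSE]))^2)
  }, numeric(1)))
  oracle_sse <- sse(list(1:10, 11:20))
  ours <- sse(split(seq_len(20), km$assignments))
  expect_equal(ours, oracle_sse, tolerance = 1e-10)
  # independent implementation agrees
  ref <- stats::kmeans(X, 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(ours, ref$tot.withinss, tolerance = 1e-8)
})

test_that("hidden activations follow the Gaussian unit formula", {
  m <- rbf_fusion(centers = rbind(c(0, 0)), widths = 1,
                  out_weights = 0, bias = 0)
  expect_equal(drop(hidden_activations(m, rbind(c(1, 0)))), exp(-0.5))
  expect_equal(drop(hidden_activations(m, rbind(c(0, 0)))), 1)

  wide <- rbf_fusion(rbind(c(0, 0)), widths = 1e6, out_weights = 0, bias = 0)
  expect_equal(drop(hidden_activations(wide, rbind(c(3, 4)))), 1,
               tolerance = 1e-9)
  narrow <- rbf_fusion(rbind(c(0, 0)), widths = 1e-4, out_weights = 0,
                       bias = 0)
  expect_equal(drop(hidden_activations(narrow, rbind(c(3, 4)))), 0)

  set.seed(1)
  mm <- rbf_fusion(matrix(rnorm(12), 4, 3), widths = 0.8,
                   out_weights = rep(0, 4), bias = 0)
  phi <- hidden_activations(mm, matrix(rnorm(30), 10, 3))
  expect_true(all(phi > 0 & phi <= 1))
  expect_error(hidden_activations(mm, matrix(0, 2, 2)), "columns")
})

test_that("training solves the linear output layer exactly", {
  set.seed(3)
  X <- matrix(runif(40, 0, 10), 20, 2)
  m <- train_fusion(X, rep(5, 20), K = 4, seed = 1)
  expect_equal(fuse(m, X), rep(5, 20), tolerance = 1e-6)

  # N = K distinct inputs: square augmented system interpolates
  Xi <- matrix(seq_len(12), 6, 2)
  yi <- rnorm(6)
  mi <- train_fusion(Xi, yi, K = 6, seed = 2)
  expect_lt(mi$train_rmse / stats::sd(yi), 1e-6)
  expect_equal(fuse(mi, Xi), yi, tolerance = 1e-6)

  # evaluating at training rows reproduces the fitted values
  y <- X[, 1] + sin(X[, 2])
  mf <- train_fusion(X, y, K = 5, seed = 1)
  expect_equal(sqrt(mean((fuse(mf, X) - y)^2)), mf$train_rmse,
               tolerance = 1e-12)
  expect_error(fuse(structure(list(), class = "list"), X), "not a fitted")
})

test_that("a larger hidden layer reduces the typical training residual", {
  # K-means dictionaries are not nested across K, so a single dataset can
  # show local inversions; the robust claim is about the distribution:
  # the median training RMSE over datasets falls as K doubles.
  ladder <- c(2, 4, 8, 16)
  rmse <- sapply(1:15, function(ds) {
    set.seed(ds)
    X <- matrix(runif(200, 0, 10), 100, 2)
    y <- sin(X[, 1]) + 0.2 * X[, 2]
    vapply(ladder, function(K)
      train_fusion(X, y, K = K, seed = 5)$train_rmse, numeric(1))
  })
  med <- apply(rmse, 1, median)
  expect_true(all(diff(med) < 0))
})

test_that("fusion recovers the reference signal on self-consistent data", {
  fr <- small_frame(n = 400, seed = 4, noise_sd = 0.05, zero_fault_rate = 0,
                    spike_fault_rate = 0, bias_offset = 0)
  model <- fit_fusion(fr, train_rows = 300, K = 10, seed = 1)
  ff <- fuse_frame(model, fr)
  held <- 301:400
  expect_gt(cor(ff$do_fused[held], ff$do_s1[held]), 0.99)
})

test_that("fusion suppresses injected faults on corrupted frames", {
  fr <- small_frame(n = 500, seed = 6, zero_fault_rate = 0.05,
                    spike_fault_rate = 0.02)
  model <- fit_fusion(fr, train_rows = 350, K = 10, seed = 6)
  ff <- fuse_frame(model, fr)
  test_rows <- 351:500
  fused_rmse <- sqrt(mean((ff$do_fused[test_rows] -
                             ff$do_truth[test_rows])^2))
  sensor_rmse <- vapply(1:4, function(s)
    sqrt(mean((ff[[paste0("do_s", s)]][test_rows] -
                 ff$do_truth[test_rows])^2)), numeric(1))
  expect_lt(fused_rmse, min(sensor_rmse))
  # no exact zeros in the fused series where the pond truly holds oxygen
  expect_true(all(abs(ff$do_fused[ff$do_truth > 1]) > 1e-8))
})

test_that("covariate-augmented fusion is available and standardizes inputs", {
  fr <- small_frame(n = 300, seed = 10)
  m <- fit_fusion(fr, train_rows = 200, K = 8, seed = 2,
                  use_covariates = TRUE)
  expect_equal(m$input_cols,
               c(paste0("do_s", 1:4), "water_temp", "solar_rad",
                 "wind_speed", "rainfall", "humidity"))
  expect_length(m$center, 9)
  ff <- fuse_frame(m, fr)
  expect_true(all(is.finite(ff$do_fused)))
})

test_that("zero-target rows are excluded from the fusion fit", {
  fr <- small_frame(n = 200, seed = 12, zero_fault_rate = 0.1)
  df <- as.data.frame(fr)
  keep <- df$do_s1[1:150] != 0
  expect_lt(sum(keep), 150)  # the reference sensor does drop out sometimes
  m <- fit_fusion(fr, train_rows = 150, K = 6, seed = 3)
  m2 <- train_fusion(as.matrix(df[1:150, paste0("do_s", 1:4)])[keep, ],
                     df$do_s1[1:150][keep], K = 6, seed = 3)
  expect_equal(m$centers, m2$centers)
  expect_equal(m$out_weights, m2$out_weights)
})
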