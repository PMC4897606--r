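#' Gaussian (RBF) kernel
#'
#' \eqn{K(x, z) = \exp(-\lVert x - z \rVert^2 / (2\sigma^2))}. The width
#' convention (the `2 sigma^2` denominator) matches the fusion network's
#' hidden units and is fixed package-wide, since tuned `(gamma, sigma)`
#' optima are convention-dependent.
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma kernel width, > 0.
#' @return kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, z, sigma) {
  if (length(x) != length(z))
    stop("x and z must have equal dimension", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  exp(-sum((x - z)^2) / (2 * sigma^2))
}

#' RBF kernel (Gram) matrix between two input sets
#'
#' @param X N x M matrix.
#' @param Z Q x M matrix (defaults to `X` for the training Gram matrix).
#' @inheritParams rbf_kernel
#' @return N x Q kernel matrix.
#' @export
rbf_kernel_matrix <- function(X, Z = X, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z))
    stop("X and Z must have equal dimension", call. = FALSE)
  exp(-cross_dist2(X, Z) / (2 * sigma^2))
}

#' Train a least-squares support vector machine regressor
#'
#' LSSVM regression replaces the SVM's inequality constraints and
#' epsilon-insensitive loss with equality constraints and squared error, so
#' training reduces to one symmetric linear system in the dual variables:
#' \deqn{\begin{bmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & K + I/\gamma
#' \end{bmatrix} \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#' \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' with `K` the RBF Gram matrix. The system is solved densely; the relative
#' residual is checked against 1e-8 and a numerical failure raises a
#' descriptive error rather than returning a bad model.
#'
#' Inputs are z-scored from this training block by default (RBF distances on
#' mixed-unit covariates are meaningless otherwise); the scaling parameters
#' are stored in the model and re-applied at prediction, so no information
#' leaks from evaluation data.
#'
#' @param X N x M training inputs.
#' @param y length-N targets.
#' @param gamma regularization parameter, > 0 (large = less regularized).
#' @param sigma RBF kernel width, > 0 (on the standardized scale when
#'   `standardize = TRUE`).
#' @param standardize z-score inputs from the training block (default TRUE).
#' @return object of class `lssvm`: stored (scaled) training inputs, dual
#'   coefficients `alpha`, bias `b`, `sigma`, `gamma`, scaling parameters.
#' @export
train_lssvm <- function(X, y, gamma, sigma, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  stopifnot(N >= 1L, N == length(y))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ctr <- scl <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  }
  K <- rbf_kernel_matrix(X, X, sigma)
  A <- rbind(c(0, rep(1, N)),
             cbind(1, K + diag(1 / gamma, N)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs),
                  error = function(e)
                    stop("LSSVM KKT system could not be solved numerically: ",
                         conditionMessage(e), call. = FALSE))
  res <- max(abs(A %*% sol - rhs)) / max(1, max(abs(rhs)))
  if (!is.finite(res) || res > 1e-8)
    stop(sprintf(
      "LSSVM KKT solve failed the residual check (relative residual %.3g)",
      res), call. = FALSE)
  structure(list(X_train = X, alpha = sol[-1L], b = sol[1L],
                 sigma = sigma, gamma = gamma, center = ctr, scale = scl),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "<lssvm> N = %d support points, dim %d, gamma = %.6g, sigma = %.6g\n",
    length(x$alpha), ncol(x$X_train), x$gamma, x$sigma))
  invisible(x)
}

#' Predict from a fitted LSSVM
#'
#' Evaluates the dual expansion
#' \eqn{f(x) = \sum_i \alpha_i K(x, x_i) + b} exactly.
#'
#' @param object fitted `lssvm` model.
#' @param newdata Q x M matrix (or length-M vector) of inputs.
#' @param ... unused.
#' @return length-Q predictions.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$X_train)) {
    if (nrow(X) == ncol(object$X_train) && ncol(X) == 1L) X <- t(X)
    else stop("newdata has ", ncol(X), " columns; model expects ",
              ncol(object$X_train), call. = FALSE)
  }
  if (!is.null(object$center)) X <- sweep(X, 2L, object$center, "-")
  if (!is.null(object$scale)) X <- sweep(X, 2L, object$scale, "/")
  drop(rbf_kernel_matrix(X, object$X_train, object$sigma) %*% object$alpha) +
    object$b
}

#' Baseline hyper-parameter selection by k-fold cross-validation
#'
#' Grid search over `(gamma, sigma)` candidates minimizing mean CV RMSE.
#' Fold assignment is a deterministic function of `seed`; ties are broken
#' toward smaller `gamma`, then smaller `sigma`.
#'
#' @param X,y training data.
#' @param folds number of folds (default 5; `folds = N` is leave-one-out).
#' @param gamma_grid,sigma_grid candidate values (> 0).
#' @param seed fold-assignment seed.
#' @return list with `gamma`, `sigma`, `cv_rmse` (the winning score) and the
#'   full score `table`.
#' @export
cv_grid_search <- function(X, y, folds = 5L,
                           gamma_grid = 10^seq(-1, 4),
                           sigma_grid = 10^seq(-1, 1.5, by = 0.5),
                           seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  folds <- as.integer(folds)
  if (N < folds) stop("need at least `folds` rows", call. = FALSE)
  if (!length(gamma_grid) || !length(sigma_grid))
    stop("empty candidate grid", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), N))
  grid <- expand.grid(gamma = sort(gamma_grid), sigma = sort(sigma_grid))
  grid <- grid[order(grid$gamma, grid$sigma), ]
  score <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- train_lssvm(X[tr, , drop = FALSE], y[tr],
                       gamma = grid$gamma[i], sigma = grid$sigma[i])
      sqrt(mean((predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2))
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  best <- which(score == min(score))[1L]  # grid pre-sorted for tie-breaking
  list(gamma = grid$gamma[best], sigma = grid$sigma[best],
       cv_rmse = score[best],
       table = cbind(grid, cv_rmse = score))
}

#' Serialize / restore an LSSVM model as JSON text
#'
#' Round-trips every field needed to reproduce predictions exactly:
#' scaling parameters, `sigma`, `gamma`, dual coefficients, bias and the
#' stored training inputs.
#'
#' @param model fitted `lssvm`.
#' @param path file path for the JSON text file.
#' @return `write_lssvm` returns `path` invisibly; `read_lssvm` the model.
#' @export
write_lssvm <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  payload <- list(
    type = "lssvm", sigma = model$sigma, gamma = model$gamma,
    b = model$b, alpha = model$alpha,
    center = model$center, scale = model$scale,
    # column-major flat storage avoids any ambiguity in nested-array order
    X_train = as.numeric(model$X_train),
    n = nrow(model$X_train), dim = ncol(model$X_train))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_lssvm
#' @export
read_lssvm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "lssvm"))
    stop(path, " does not contain an LSSVM model", call. = FALSE)
  structure(list(X_train = matrix(as.numeric(p$X_train), nrow = p$n,
                                  ncol = p$dim),
                 alpha = as.numeric(p$alpha), b = as.numeric(p$b),
                 sigma = p$sigma, gamma = p$gamma,
                 center = if (length(p$center)) as.numeric(p$center),
                 scale = if (length(p$scale)) as.numeric(p$scale)),
            class = "lssvm")
}
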