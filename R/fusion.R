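#' K-means center selection (Lloyd's algorithm)
#'
#' Deterministic Lloyd iteration used to place the hidden-unit centers of the
#' fusion network. Initial centers are `K` rows sampled under `seed`;
#' iteration alternates nearest-center assignment and center re-estimation
#' until no assignment changes (or `max_iter` sweeps). A cluster left empty is
#' re-seeded to the point farthest from its current center, which keeps all
#' `K` units in play on degenerate data.
#'
#' @param X numeric N x M matrix of finite values.
#' @param K number of centers, `1 <= K <= N`.
#' @param seed integer seed for the initial center draw.
#' @param max_iter maximum Lloyd sweeps (default 300).
#' @return list with `centers` (K x M), `assignments` (length-N labels in
#'   `1..K`) and `iterations` used.
#' @export
kmeans_centers <- function(X, K, seed = 1L, max_iter = 300L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("X must be a finite numeric matrix", call. = FALSE)
  N <- nrow(X)
  K <- as.integer(K)
  if (K < 1L || K > N)
    stop("K must satisfy 1 <= K <= nrow(X)", call. = FALSE)
  set.seed(seed)
  centers <- X[sample.int(N, K), , drop = FALSE]
  assign_old <- rep(0L, N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- cross_dist2(X, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      idx <- which(assign_new == k)
      if (length(idx)) {
        centers[k, ] <- colMeans(X[idx, , drop = FALSE])
      } else {
        # re-seed empty cluster to the globally farthest point
        far <- which.max(apply(d2, 1L, min))
        centers[k, ] <- X[far, ]
        assign_new[far] <- k
      }
    }
    if (identical(assign_new, assign_old) || iter >= max_iter) break
    assign_old <- assign_new
  }
  list(centers = centers, assignments = assign_new, iterations = iter)
}

# squared Euclidean cross-distance matrix: nrow(A) x nrow(B)
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Construct an RBF fusion network
#'
#' Three-layer RBF network container: Gaussian hidden units around `centers`
#' with receiving-field `widths`, and a linear hidden-to-output map
#' (`out_weights` plus `bias`). Optional input standardization parameters
#' (`center`/`scale`) are applied before distance computation when present.
#'
#' @param centers K x M matrix of hidden-unit centers.
#' @param widths length-K positive receiving-field widths.
#' @param out_weights length-K hidden-to-output weights.
#' @param bias output bias.
#' @param center,scale optional length-M input standardization parameters.
#' @return object of class `rbf_fusion`.
#' @export
rbf_fusion <- function(centers, widths, out_weights, bias,
                       center = NULL, scale = NULL) {
  centers <- as.matrix(centers)
  K <- nrow(centers)
  widths <- rep_len(as.numeric(widths), K)
  if (any(widths <= 0)) stop("widths must be > 0", call. = FALSE)
  if (length(out_weights) != K)
    stop("out_weights length must equal number of centers", call. = FALSE)
  structure(list(centers = centers, widths = widths,
                 out_weights = as.numeric(out_weights), bias = as.numeric(bias),
                 K = K, input_dim = ncol(centers),
                 center = center, scale = scale, train_rmse = NA_real_),
            class = "rbf_fusion")
}

#' @export
print.rbf_fusion <- function(x, ...) {
  cat(sprintf("<rbf_fusion> K = %d Gaussian units, input dim %d%s\n",
              x$K, x$input_dim,
              if (is.finite(x$train_rmse))
                sprintf(", training RMSE %.4g", x$train_rmse) else ""))
  invisible(x)
}

scale_inputs <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$center))
    X <- sweep(X, 2L, model$center, "-")
  if (!is.null(model$scale))
    X <- sweep(X, 2L, model$scale, "/")
  X
}

#' Hidden-layer Gaussian activations
#'
#' \eqn{\phi_j(x) = \exp(-\lVert x - c_j \rVert^2 / (2 \sigma_j^2))}; every
#' entry lies in (0, 1], equalling 1 exactly at the center.
#'
#' @param model an [rbf_fusion()] network.
#' @param X N x M input matrix (M = `model$input_dim`).
#' @return N x K activation matrix.
#' @export
hidden_activations <- function(model, X) {
  stopifnot(inherits(model, "rbf_fusion"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop("input has ", ncol(X), " columns; model expects ", model$input_dim,
         call. = FALSE)
  X <- scale_inputs(model, X)
  d2 <- cross_dist2(X, model$centers)
  exp(-sweep(d2, 2L, 2 * model$widths^2, "/"))
}

#' Train the RBF fusion network
#'
#' Centers come from [kmeans_centers()]; all receiving-field widths use the
#' classical heuristic \eqn{\sigma = d_{max} / \sqrt{2K}} with `d_max` the
#' maximum pairwise center distance (falling back to 1 when all centers
#' coincide). Because the hidden-to-output map is linear, the output weights
#' and bias are the least-squares solution of `[Phi 1] w = y`, computed by a
#' minimum-norm SVD solve so rank-deficient designs (e.g. N = K
#' interpolation) are handled without failure.
#'
#' @param X N x M training inputs (typically the S simultaneous DO readings).
#' @param y length-N training target (the reference sensor's reading).
#' @param K number of hidden units (default 10).
#' @param seed seed for K-means initialization.
#' @param standardize z-score the inputs from this training block (stored in
#'   the model and re-applied at prediction). Default FALSE: raw mg/L inputs,
#'   appropriate when all inputs share units.
#' @return fitted [rbf_fusion()] model with `train_rmse` recorded.
#' @export
train_fusion <- function(X, y, K = 10L, seed = 1L, standardize = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  ctr <- scl <- NULL
  Xs <- X
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  }
  km <- kmeans_centers(Xs, K, seed = seed)
  dmax <- if (K > 1L) sqrt(max(cross_dist2(km$centers, km$centers))) else 0
  width <- if (dmax > 0) dmax / sqrt(2 * K) else 1
  model <- rbf_fusion(km$centers, rep(width, K), rep(0, K), 0,
                      center = ctr, scale = scl)
  Phi <- hidden_activations(model, X)
  A <- cbind(Phi, 1)
  coef <- svd_min_norm_solve(A, y)
  model$out_weights <- coef[seq_len(K)]
  model$bias <- coef[K + 1L]
  model$train_rmse <- sqrt(mean((A %*% coef - y)^2))
  model
}

# minimum-norm least squares via SVD pseudo-inverse
svd_min_norm_solve <- function(A, y, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, y)))
}

#' Fuse sensor readings through a fitted network
#'
#' Output is the linear combination of hidden activations plus bias.
#'
#' @param model fitted [rbf_fusion()].
#' @param X N x M inputs.
#' @return length-N fused DO values.
#' @export
fuse <- function(model, X) {
  if (!inherits(model, "rbf_fusion"))
    stop("model is not a fitted rbf_fusion network", call. = FALSE)
  drop(hidden_activations(model, X) %*% model$out_weights) + model$bias
}

#' Fit the fusion stage on a sensor frame
#'
#' Frame-level wrapper implementing the fusion protocol: inputs are the S
#' simultaneous sensor readings (optionally augmented with the environmental
#' covariates), the target is the reference sensor's own reading, and
#' training rows whose reference reading is an exact 0.00 (a dropout fault by
#' construction) are excluded from the fit. Prediction runs on all rows.
#'
#' @param frame a [sensor_frame()] with sensor columns.
#' @param train_rows training block: row indices, or a single count meaning
#'   the first that many rows (default 500).
#' @param K hidden units.
#' @param seed K-means seed.
#' @param reference_sensor index of the sensor treated as the credible target
#'   (default 1).
#' @param use_covariates also feed the five environmental covariates to the
#'   network (default FALSE: sensors only).
#' @return fitted [rbf_fusion()] with the input-column set recorded.
#' @export
fit_fusion <- function(frame, train_rows = 500L, K = 10L, seed = 1L,
                       reference_sensor = 1L, use_covariates = FALSE) {
  stopifnot(inherits(frame, "sensor_frame"))
  S <- attr(frame, "n_sensors")
  if (S < 1L) stop("frame has no sensor columns", call. = FALSE)
  if (length(train_rows) == 1L) train_rows <- seq_len(train_rows)
  cols <- sensor_names(S)
  if (use_covariates) cols <- c(cols, covariate_names())
  tr <- as.data.frame(frame)[train_rows, , drop = FALSE]
  y <- tr[[paste0("do_s", reference_sensor)]]
  keep <- y != 0
  model <- train_fusion(as.matrix(tr[keep, cols, drop = FALSE]), y[keep],
                        K = K, seed = seed, standardize = use_covariates)
  model$input_cols <- cols
  model
}

#' Append the fused DO series to a frame
#'
#' @param model a [fit_fusion()] result.
#' @param frame the frame to fuse (all rows are predicted).
#' @return the frame with a `do_fused` column appended.
#' @export
fuse_frame <- function(model, frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  if (is.null(model$input_cols))
    stop("model was not fitted with fit_fusion()", call. = FALSE)
  df <- as.data.frame(frame)
  df$do_fused <- fuse(model, as.matrix(df[, model$input_cols, drop = FALSE]))
  sensor_frame(df, attr(frame, "interval_minutes"),
               valid_mask = attr(frame, "valid_mask"))
}
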