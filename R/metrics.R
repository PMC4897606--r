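#' Forecast-accuracy metrics
#'
#' Standard statistical criteria for one model on one evaluation set:
#' MAE = mean |o - p|; MSE = mean (o - p)^2; RMSE = sqrt(MSE);
#' MAPE = 100 mean |o - p| / |o| (percent); Nash-Sutcliffe efficiency
#' NSC = 1 - sum (o - p)^2 / sum (o - mean(o))^2; R^2 = squared sample
#' correlation. All values are kept at full precision; rounding belongs to
#' the reporting layer only.
#'
#' Degenerate cases: a constant observed series makes NSC undefined (reported
#' `NA` with a warning); a constant series on either side makes R^2 undefined
#' (`NA` with a warning); observations equal to zero are excluded from the
#' MAPE mean with a warning (`NA` if all are zero).
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return object of class `metrics_report`: list with `mae`, `rmse`, `mse`,
#'   `mape`, `nsc`, `r2`, `n`.
#' @export
compute_metrics <- function(observed, predicted) {
  o <- as.numeric(observed)
  p <- as.numeric(predicted)
  if (!length(o) || length(o) != length(p))
    stop("observed and predicted must have equal nonzero length",
         call. = FALSE)
  if (any(!is.finite(o)) || any(!is.finite(p)))
    stop("metrics require finite values", call. = FALSE)
  err <- o - p
  mae <- mean(abs(err))
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  nz <- o != 0
  if (!all(nz))
    warning("MAPE: ", sum(!nz),
            " zero observation(s) excluded from the percentage mean")
  mape <- if (any(nz)) 100 * mean(abs(err[nz]) / abs(o[nz])) else NA_real_
  ss_tot <- sum((o - mean(o))^2)
  nsc <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else {
    warning("NSC undefined for a constant observed series")
    NA_real_
  }
  r2 <- if (stats::sd(o) > 0 && stats::sd(p) > 0)
    stats::cor(o, p)^2
  else {
    warning("R^2 undefined when either series is constant")
    NA_real_
  }
  structure(list(mae = mae, rmse = rmse, mse = mse, mape = mape,
                 nsc = nsc, r2 = r2, n = length(o)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "<metrics_report> n = %d\n  MAE %s  RMSE %s  MSE %s  MAPE %s%%  NSC %s  R2 %s\n",
    x$n, signif(x$mae, digits), signif(x$rmse, digits),
    signif(x$mse, digits), signif(x$mape, digits),
    signif(x$nsc, digits), signif(x$r2, digits)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(mae = x$mae, rmse = x$rmse, mse = x$mse, mape = x$mape,
             nsc = x$nsc, r2 = x$r2, n = x$n)
}

#' Relative difference between two error metrics, in percent
#'
#' `100 * (reference - candidate) / reference`: the percentage by which the
#' candidate model improves on the reference model's error metric. Values are
#' rounded to 2 decimals when `digits = 2` (the reporting convention);
#' pass `digits = NULL` for full precision.
#'
#' @param reference_metric the reference model's error value, > 0.
#' @param candidate_metric the candidate model's error value.
#' @param digits decimals for reporting (default 2; NULL = no rounding).
#' @return percent relative difference.
#' @export
relative_difference <- function(reference_metric, candidate_metric,
                                digits = 2L) {
  if (!is.finite(reference_metric) || reference_metric <= 0)
    stop("reference metric must be > 0", call. = FALSE)
  out <- 100 * (reference_metric - candidate_metric) / reference_metric
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Published benchmark error statistics for the three DO forecasters
#'
#' The reference comparison table for the hybrid method: error statistics
#' (MAE, RMSE, MSE, NSC and running time T in seconds) reported for the
#' IPSO-tuned LSSVM, the cross-validated LSSVM and a back-propagation neural
#' network baseline on the same pond evaluation period. Used as pure
#' arithmetic input to [relative_difference()] model comparisons; T is
#' hardware-dependent and excluded from comparisons.
#'
#' @return data.frame with columns `model`, `mae`, `rmse`, `mse`, `nsc`, `t`.
#' @export
benchmark_error_stats <- function() {
  data.frame(
    model = c("IPSO-LSSVM", "LSSVM", "BPNN"),
    mae = c(0.2814, 0.4305, 0.5776),
    rmse = c(0.4057, 0.7745, 0.8954),
    mse = c(0.1085, 0.2722, 0.3320),
    nsc = c(0.9531, 0.9187, 0.9002),
    t = c(3.2143, 3.1265, 4.3298),
    stringsAsFactors = FALSE)
}

#' Model-comparison table with relative differences
#'
#' Assembles per-model metric rows and, for every non-candidate model, the
#' percent relative MAE/RMSE/MSE differences of the candidate against it.
#'
#' @param reports named list of `metrics_report` (or single-row data.frames
#'   with mae/rmse/mse columns, e.g. [benchmark_error_stats()] rows).
#' @param candidate name of the candidate model (default: first entry).
#' @return list with `metrics` (one row per model) and `relative` (percent
#'   improvements of the candidate over each reference, 2-decimal rounding).
#' @export
comparison_table <- function(reports, candidate = names(reports)[1L]) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  rows <- lapply(reports, function(r)
    if (inherits(r, "metrics_report")) as.data.frame(r) else as.data.frame(r))
  metrics <- do.call(rbind, lapply(names(rows), function(nm)
    cbind(model = nm, rows[[nm]][, intersect(
      c("mae", "rmse", "mse", "mape", "nsc", "r2", "n"), names(rows[[nm]])),
      drop = FALSE])))
  refs <- setdiff(names(rows), candidate)
  relative <- do.call(rbind, lapply(refs, function(nm) {
    data.frame(reference = nm, candidate = candidate,
               rel_mae = relative_difference(rows[[nm]]$mae,
                                             rows[[candidate]]$mae),
               rel_rmse = relative_difference(rows[[nm]]$rmse,
                                              rows[[candidate]]$rmse),
               rel_mse = relative_difference(rows[[nm]]$mse,
                                             rows[[candidate]]$mse))
  }))
  list(metrics = metrics, relative = relative)
}
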