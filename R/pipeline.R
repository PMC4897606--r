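#' Configuration of the end-to-end forecasting experiment
#'
#' Defines the whole protocol: data source, the temporally ordered contiguous
#' splits (fusion train/test, then forecast train/test carved out of the
#' fused test block), the model roster, and optimizer settings. With the
#' defaults, 500 rows train the fusion network and the next 200 fused rows
#' form the forecasting table; lag-1 supervision consumes one row, leaving
#' 199 usable rows split 120 train / 79 test.
#'
#' @param synthetic a [synthetic_config()], used when `csv` is NULL.
#' @param csv optional path to a frame in the package CSV dialect (overrides
#'   `synthetic`).
#' @param fusion_train,fusion_test fusion split sizes (defaults 500 / 200).
#' @param forecast_train forecasting training rows within the fused test
#'   block (default 120); the remaining supervised rows are the test set.
#' @param models roster subset of `c("ipso_lssvm", "pso_lssvm", "cv_lssvm")`.
#' @param external optional named list of CSV paths with external predictions
#'   (single `prediction` column, one per forecast-test row) to score with the
#'   same metrics — e.g. an off-the-shelf neural-network baseline.
#' @param fusion_k fusion hidden units.
#' @param fusion_covariates feed covariates to the fusion network too.
#' @param pso a [pso_config()] template for the tuners; its `seed` is
#'   overridden from `seed` for reproducibility. Default: bounds
#'   `log10 gamma` in [-2, 6], `log10 sigma` in [-2, 2], 50 particles,
#'   200 iterations.
#' @param cv_folds folds for the cross-validated baseline (default 5).
#' @param seed master seed; every stage derives its stream from it.
#' @param out_dir if non-NULL, artifacts (fused CSV, model JSONs, predictions,
#'   metrics JSON, fitness-history CSVs) are persisted there.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              csv = NULL,
                              fusion_train = 500L, fusion_test = 200L,
                              forecast_train = 120L,
                              models = c("ipso_lssvm", "cv_lssvm"),
                              external = NULL,
                              fusion_k = 10L, fusion_covariates = FALSE,
                              pso = NULL, cv_folds = 5L,
                              seed = 1L, out_dir = NULL) {
  models <- match.arg(models, c("ipso_lssvm", "pso_lssvm", "cv_lssvm"),
                      several.ok = TRUE)
  if (is.null(pso))
    pso <- pso_config(bounds = rbind(c(-2, 6), c(-2, 2)))
  n_supervised <- fusion_test - 1L
  if (forecast_train >= n_supervised)
    stop("forecast_train leaves no test rows: the fused test block of ",
         fusion_test, " rows yields ", n_supervised, " supervised rows",
         call. = FALSE)
  structure(list(synthetic = synthetic, csv = csv,
                 fusion_train = as.integer(fusion_train),
                 fusion_test = as.integer(fusion_test),
                 forecast_train = as.integer(forecast_train),
                 forecast_test = as.integer(n_supervised - forecast_train),
                 models = models, external = external,
                 fusion_k = as.integer(fusion_k),
                 fusion_covariates = fusion_covariates,
                 pso = pso, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Build the one-step-ahead supervised forecasting table
#'
#' Features at row `t`: the five environmental covariates at time `t` plus
#' the previous fused DO value (`do_prev`, the fused value at `t - 1`);
#' target: the fused DO at `t`. The first row has no previous value and is
#' dropped, so `n` fused rows yield `n - 1` supervised rows at the native
#' sampling interval.
#'
#' @param frame a [sensor_frame()] (or data.frame with the covariate columns)
#'   aligned with `fused`.
#' @param fused fused DO series, same length as `frame` rows; taken from the
#'   frame's `do_fused` column when omitted.
#' @return data.frame with columns `water_temp`, `solar_rad`, `wind_speed`,
#'   `rainfall`, `humidity`, `do_prev`, `target`.
#' @export
build_forecast_table <- function(frame, fused = NULL) {
  df <- as.data.frame(frame)
  if (is.null(fused)) {
    if (!"do_fused" %in% names(df))
      stop("no fused series: pass `fused` or a frame with do_fused",
           call. = FALSE)
    fused <- df$do_fused
  }
  if (length(fused) != nrow(df))
    stop("fused series length (", length(fused),
         ") does not match frame rows (", nrow(df), ")", call. = FALSE)
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 rows for lag-1 supervision", call. = FALSE)
  out <- df[2:n, covariate_names(), drop = FALSE]
  out$do_prev <- fused[1:(n - 1L)]
  out$target <- fused[2:n]
  rownames(out) <- NULL
  out
}

#' Run the full fusion-then-forecast experiment
#'
#' Orchestrates every stage under one master seed: simulate (or load) the
#' multi-sensor frame; fit the fusion network on the fusion training block
#' and fuse the following test block; build the lag-1 forecasting table;
#' tune/train each roster model on the forecast training rows; predict the
#' forecast test rows; score all models with [compute_metrics()] and the
#' candidate-vs-reference relative differences. All fitting (input scaling,
#' K-means centers, hyper-parameter tuning) sees training partitions only,
#' and every split is contiguous and temporally ordered.
#'
#' @param config an [experiment_config()].
#' @return object of class `do_experiment`: the fused frame slice, split
#'   sizes, per-model tuned parameters, predictions, `metrics_report`s, the
#'   comparison table, and fitness histories for the swarm-tuned models.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  persist <- function(writer, ..., file) {
    if (!is.null(out_dir)) writer(..., file.path(out_dir, file))
  }

  frame <- stage("load", {
    if (!is.null(config$csv)) read_sensor_frame(config$csv)
    else simulate_frame(config$synthetic)
  })
  need <- config$fusion_train + config$fusion_test
  if (nrow(frame) < need)
    stop("[stage load] frame has ", nrow(frame), " rows; the splits need ",
         need, call. = FALSE)

  fusion <- stage("fusion", {
    model <- fit_fusion(frame, train_rows = config$fusion_train,
                        K = config$fusion_k, seed = config$seed,
                        use_covariates = config$fusion_covariates)
    fused_frame <- fuse_frame(model, frame)
    list(model = model, frame = fused_frame)
  })
  test_rows <- seq.int(config$fusion_train + 1L, need)
  fused_test <- fusion$frame[test_rows, , drop = FALSE]
  persist(function(fr, p) write_sensor_frame(
    sensor_frame(as.data.frame(fr), attr(fusion$frame, "interval_minutes")), p),
    fused_test, file = "fused.csv")

  table <- stage("forecast_table",
                 build_forecast_table(as.data.frame(fused_test),
                                      fused = fused_test$do_fused))
  tr <- seq_len(config$forecast_train)
  te <- seq.int(config$forecast_train + 1L, nrow(table))
  feats <- c(covariate_names(), "do_prev")
  X_tr <- as.matrix(table[tr, feats])
  y_tr <- table$target[tr]
  X_te <- as.matrix(table[te, feats])
  y_te <- table$target[te]

  models <- list()
  reports <- list()
  predictions <- list()
  histories <- list()
  for (m in config$models) {
    fit <- stage(m, switch(
      m,
      ipso_lssvm = ,
      pso_lssvm = {
        pc <- config$pso
        pc$improved <- (m == "ipso_lssvm")
        pc$seed <- config$seed + 1L
        tuned <- tune_lssvm(X_tr, y_tr, pc)
        histories[[m]] <- tuned$gbest_history
        list(model = train_lssvm(X_tr, y_tr, gamma = tuned$gamma,
                                 sigma = tuned$sigma),
             gamma = tuned$gamma, sigma = tuned$sigma)
      },
      cv_lssvm = {
        sel <- cv_grid_search(X_tr, y_tr, folds = config$cv_folds,
                              seed = config$seed + 2L)
        list(model = train_lssvm(X_tr, y_tr, gamma = sel$gamma,
                                 sigma = sel$sigma),
             gamma = sel$gamma, sigma = sel$sigma)
      }))
    models[[m]] <- fit
    predictions[[m]] <- predict(fit$model, X_te)
    reports[[m]] <- compute_metrics(y_te, predictions[[m]])
    persist(write_lssvm, fit$model, file = paste0(m, ".json"))
    if (!is.null(histories[[m]]))
      persist(function(h, p) utils::write.csv(
        data.frame(iteration = seq_along(h) - 1L, gbest_fitness = h), p,
        row.names = FALSE), histories[[m]],
        file = paste0(m, "_fitness_history.csv"))
  }
  for (nm in names(config$external)) {
    ext <- stage(paste0("external_", nm),
                 utils::read.csv(config$external[[nm]]))
    pcol <- intersect(c("prediction", "predicted", names(ext)[1L]),
                      names(ext))[1L]
    pred <- as.numeric(ext[[pcol]])
    if (length(pred) != length(y_te))
      stop("[stage external_", nm, "] expected ", length(y_te),
           " predictions, got ", length(pred), call. = FALSE)
    predictions[[nm]] <- pred
    reports[[nm]] <- compute_metrics(y_te, pred)
  }

  comparison <- if (length(reports) > 1L)
    comparison_table(reports, candidate = names(reports)[1L])
  else list(metrics = comparison_table(reports)$metrics, relative = NULL)

  result <- structure(list(
    config = config,
    frame = fusion$frame, fusion_model = fusion$model,
    table = table,
    splits = list(fusion_train = config$fusion_train,
                  fusion_test = config$fusion_test,
                  forecast_train = length(tr), forecast_test = length(te)),
    tuned = lapply(models, function(f) list(gamma = f$gamma, sigma = f$sigma)),
    models = lapply(models, `[[`, "model"),
    observed = y_te, predictions = predictions,
    reports = reports, comparison = comparison,
    histories = histories), class = "do_experiment")

  if (!is.null(out_dir)) {
    pred_df <- data.frame(observed = y_te)
    for (nm in names(predictions)) pred_df[[nm]] <- predictions[[nm]]
    utils::write.csv(pred_df, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, splits = result$splits, tuned = result$tuned,
           metrics = lapply(reports, function(r) unclass(r)),
           relative = comparison$relative),
      file.path(out_dir, "metrics.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  }
  result
}

#' @export
print.do_experiment <- function(x, ...) {
  cat(sprintf(
    "<do_experiment> seed %d | fusion %d/%d | forecast %d/%d\n",
    x$config$seed, x$splits$fusion_train, x$splits$fusion_test,
    x$splits$forecast_train, x$splits$forecast_test))
  for (nm in names(x$tuned))
    cat(sprintf("  %-10s gamma = %.6g, sigma = %.6g\n",
                nm, x$tuned[[nm]]$gamma, x$tuned[[nm]]$sigma))
  m <- x$comparison$metrics
  num <- vapply(m, is.numeric, logical(1L))
  m[num] <- lapply(m[num], signif, 4L)
  print(m, row.names = FALSE)
  if (!is.null(x$comparison$relative)) {
    cat("relative improvement of", x$comparison$relative$candidate[1L],
        "(% of reference error):\n")
    print(x$comparison$relative, row.names = FALSE)
  }
  invisible(x)
}
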