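#' Configuration for the synthetic pond-data generator
#'
#' Bundles every knob of the simulator: sampling layout, the diel truth model
#' for dissolved oxygen (DO), per-sensor noise, and the three fault patterns
#' seen in real pond deployments — dropouts that read exactly 0.00 mg/L,
#' spikes far above neighbouring values, and one sensor that persistently
#' reads low.
#'
#' The noiseless truth model is the closed form
#' \deqn{DO(t) = m + a \sin(2\pi (h(t) - \phi)/24) + b (T(t) - \bar T)}
#' with `h(t)` the hour of day, plus a stationary AR(1) residual when
#' `ar_sd > 0`. Water temperature follows its own diel sinusoid
#' \eqn{T(t) = \bar T + A_T \sin(2\pi (h(t) - \phi_T)/24)}, so the DO peak is
#' phase-locked to the afternoon following the solar-radiation maximum.
#'
#' @param n_samples number of time steps (default 1008 = 14 days at 20 min).
#' @param interval_minutes sampling interval in minutes.
#' @param n_sensors number of DO sensors `S`.
#' @param noise_sd per-sensor Gaussian measurement noise, mg/L.
#' @param zero_fault_rate per-reading probability of a dropout (reads 0.00).
#' @param spike_fault_rate per-reading probability of a spike fault.
#' @param spike_magnitude mg/L added by a spike fault.
#' @param biased_sensor index of the persistently biased sensor, or `NA` for
#'   none. Default: the last sensor, which reads low in field data.
#' @param bias_offset mg/L added to every reading of the biased sensor
#'   (negative = reads low).
#' @param do_mean baseline mean DO `m`, mg/L.
#' @param diel_amplitude diel DO amplitude `a`, mg/L.
#' @param temp_coupling DO response to temperature anomaly `b`, mg/L per degC.
#' @param do_phase_hour hour of day at which the DO sinusoid peaks.
#' @param temp_mean,temp_amplitude,temp_phase_hour water-temperature diel
#'   model: mean (degC), amplitude, and hour of peak.
#' @param ar_rho,ar_sd AR(1) residual on truth DO: lag-1 correlation and
#'   innovation standard deviation (mg/L).
#' @param start origin timestamp (parsed as UTC).
#' @param seed integer seed; the whole frame is a deterministic function of it.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_samples = 72, seed = 1)
#' frame <- simulate_frame(cfg)
#' head(frame)
synthetic_config <- function(n_samples = 1008L,
                             interval_minutes = 20,
                             n_sensors = 4L,
                             noise_sd = 0.2,
                             zero_fault_rate = 0.02,
                             spike_fault_rate = 0.01,
                             spike_magnitude = 5,
                             biased_sensor = n_sensors,
                             bias_offset = -1.5,
                             do_mean = 6,
                             diel_amplitude = 2,
                             temp_coupling = 0.1,
                             do_phase_hour = 10,
                             temp_mean = 25,
                             temp_amplitude = 3,
                             temp_phase_hour = 9,
                             ar_rho = 0.9,
                             ar_sd = 0.15,
                             start = "2015-06-21 00:00:00",
                             seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), interval_minutes = interval_minutes,
    n_sensors = as.integer(n_sensors), noise_sd = noise_sd,
    zero_fault_rate = zero_fault_rate, spike_fault_rate = spike_fault_rate,
    spike_magnitude = spike_magnitude, biased_sensor = biased_sensor,
    bias_offset = bias_offset, do_mean = do_mean,
    diel_amplitude = diel_amplitude, temp_coupling = temp_coupling,
    do_phase_hour = do_phase_hour, temp_mean = temp_mean,
    temp_amplitude = temp_amplitude, temp_phase_hour = temp_phase_hour,
    ar_rho = ar_rho, ar_sd = ar_sd, start = start, seed = as.integer(seed)
  )
  if (is.na(cfg$n_samples) || cfg$n_samples < 1L)
    stop("invalid config: n_samples must be a positive integer", call. = FALSE)
  if (!is.finite(cfg$interval_minutes) || cfg$interval_minutes <= 0)
    stop("invalid config: interval_minutes must be > 0", call. = FALSE)
  if (cfg$n_sensors < 1L)
    stop("invalid config: n_sensors must be >= 1", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("invalid config: noise_sd must be >= 0", call. = FALSE)
  for (r in c("zero_fault_rate", "spike_fault_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      stop("invalid config: ", r, " must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(cfg$biased_sensor) &&
      (cfg$biased_sensor < 1L || cfg$biased_sensor > cfg$n_sensors))
    stop("invalid config: biased_sensor out of range", call. = FALSE)
  if (abs(cfg$ar_rho) >= 1)
    stop("invalid config: ar_rho must satisfy |rho| < 1", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

covariate_names <- function() {
  c("water_temp", "solar_rad", "wind_speed", "rainfall", "humidity")
}

sensor_names <- function(n_sensors) paste0("do_s", seq_len(n_sensors))

#' Construct a sensor frame
#'
#' The universal I/O object of the package: an aligned multi-sensor DO +
#' covariate time series, stored as a `data.frame` with class `sensor_frame`.
#' Columns are `timestamp`, the five covariates (`water_temp`, `solar_rad`,
#' `wind_speed`, `rainfall`, `humidity`), the sensor columns `do_s1..do_sS`
#' (may be absent before corruption), and optionally `do_truth`. A per-reading
#' logical validity mask lives in the `valid_mask` attribute; it flags
#' injected faults for evaluation only and is never fed to the fusion stage.
#'
#' @param df data.frame with the columns above, timestamps strictly increasing
#'   at a fixed interval.
#' @param interval_minutes sampling interval.
#' @param valid_mask optional n x S logical matrix (TRUE = valid reading).
#' @return `sensor_frame` object.
#' @export
sensor_frame <- function(df, interval_minutes, valid_mask = NULL) {
  stopifnot(is.data.frame(df), "timestamp" %in% names(df))
  missing_cov <- setdiff(covariate_names(), names(df))
  if (length(missing_cov))
    stop("sensor_frame missing covariate columns: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  ts <- df$timestamp
  if (nrow(df) > 1L) {
    d <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "mins"))
    if (any(d <= 0) || max(abs(d - interval_minutes)) > 1e-6)
      stop("timestamps must be strictly increasing at the stated interval",
           call. = FALSE)
  }
  scols <- grep("^do_s[0-9]+$", names(df), value = TRUE)
  for (cn in c(scols, intersect("do_truth", names(df)))) {
    v <- df[[cn]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("DO column ", cn, " must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(valid_mask)) {
    valid_mask <- as.matrix(valid_mask)
    if (nrow(valid_mask) != nrow(df) || ncol(valid_mask) != length(scols))
      stop("valid_mask must be n_samples x n_sensors", call. = FALSE)
  }
  structure(df,
            class = c("sensor_frame", "data.frame"),
            interval_minutes = interval_minutes,
            n_sensors = length(scols),
            valid_mask = valid_mask)
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame> %d rows at %g-min interval, %d DO sensor(s)%s\n",
              nrow(x), attr(x, "interval_minutes"), attr(x, "n_sensors"),
              if ("do_truth" %in% names(x)) ", with truth" else ""))
  mask <- attr(x, "valid_mask")
  if (!is.null(mask))
    cat(sprintf("  %d/%d readings flagged invalid\n", sum(!mask), length(mask)))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Generate the noiseless-truth pond frame
#'
#' Simulates covariates with diel structure (water temperature and solar
#' radiation peaking mid-day) and the true dissolved-oxygen series
#' `do_truth`: baseline mean + diel sinusoid phase-locked behind the solar
#' peak + temperature-coupled anomaly + smooth AR(1) residual. No sensor
#' columns and no faults; see [corrupt_sensors()] for those.
#'
#' @param config a [synthetic_config()].
#' @return A [sensor_frame()] with covariates and `do_truth` (all > 0).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  set.seed(config$seed)
  t0 <- as.POSIXct(config$start, tz = "UTC")
  ts <- t0 + (seq_len(n) - 1L) * config$interval_minutes * 60
  hour <- as.numeric(ts - trunc(ts, "days"), units = "hours")

  water_temp <- config$temp_mean +
    config$temp_amplitude * sin(2 * pi * (hour - config$temp_phase_hour) / 24)
  solar_rad <- pmax(0, 900 * sin(pi * (hour - 6) / 12)) *
    (hour >= 6 & hour <= 18)
  # wind: positive AR(1) around 2 m/s
  wind_innov <- stats::rnorm(n, 0, 0.3)
  wind <- numeric(n)
  wind[1L] <- 2
  for (i in seq_len(n)[-1L]) wind[i] <- 2 + 0.8 * (wind[i - 1L] - 2) + wind_innov[i]
  wind <- pmax(0, wind)
  # rainfall: rare showers, exponential depth
  rain <- ifelse(stats::runif(n) < 0.03, stats::rexp(n, rate = 0.5), 0)
  humidity <- pmin(100, pmax(
    20, 70 + 10 * sin(2 * pi * (hour - 3) / 24) + stats::rnorm(n, 0, 2)))

  # AR(1) residual on DO, started from its stationary distribution
  resid <- numeric(n)
  if (config$ar_sd > 0) {
    stat_sd <- config$ar_sd / sqrt(1 - config$ar_rho^2)
    resid[1L] <- stats::rnorm(1L, 0, stat_sd)
    innov <- stats::rnorm(n, 0, config$ar_sd)
    for (i in seq_len(n)[-1L])
      resid[i] <- config$ar_rho * resid[i - 1L] + innov[i]
  }
  do_truth <- config$do_mean +
    config$diel_amplitude * sin(2 * pi * (hour - config$do_phase_hour) / 24) +
    config$temp_coupling * (water_temp - config$temp_mean) +
    resid
  do_truth <- pmax(do_truth, 0.01)

  df <- data.frame(timestamp = ts, water_temp = water_temp,
                   solar_rad = solar_rad, wind_speed = wind, rainfall = rain,
                   humidity = humidity, do_truth = do_truth)
  sensor_frame(df, config$interval_minutes)
}

#' Corrupt a truth frame into faulty sensor readings
#'
#' Fills the `do_s1..do_sS` columns: each reading is truth plus Gaussian noise
#' (plus the persistent offset for the biased sensor), then with probability
#' `spike_fault_rate` a spike of `spike_magnitude` mg/L is added and with
#' probability `zero_fault_rate` the reading is forced to exactly 0.00;
#' readings are clipped at 0 (physical non-negativity). Both fault kinds are
#' recorded as invalid in the `valid_mask` attribute.
#'
#' @param frame a [sensor_frame()] carrying `do_truth`.
#' @param config the same [synthetic_config()] used to generate it.
#' @return The frame with sensor columns filled and `valid_mask` set.
#' @export
corrupt_sensors <- function(frame, config) {
  stopifnot(inherits(frame, "sensor_frame"), inherits(config, "synthetic_config"))
  if (!"do_truth" %in% names(frame))
    stop("frame has no do_truth column; generate_truth() it first", call. = FALSE)
  n <- nrow(frame)
  S <- config$n_sensors
  # separate stream from generate_truth so truth is unchanged by fault knobs
  set.seed(config$seed + 1L)
  readings <- matrix(frame$do_truth, n, S) +
    matrix(stats::rnorm(n * S, 0, config$noise_sd), n, S)
  if (!is.na(config$biased_sensor))
    readings[, config$biased_sensor] <- readings[, config$biased_sensor] +
      config$bias_offset
  spike <- matrix(stats::runif(n * S) < config$spike_fault_rate, n, S)
  readings[spike] <- readings[spike] + config$spike_magnitude
  zero <- matrix(stats::runif(n * S) < config$zero_fault_rate, n, S)
  readings[zero] <- 0
  readings <- pmax(readings, 0)
  mask <- !(spike | zero)

  df <- as.data.frame(frame)
  for (s in seq_len(S)) df[[paste0("do_s", s)]] <- readings[, s]
  df <- df[, c("timestamp", covariate_names(), sensor_names(S), "do_truth")]
  sensor_frame(df, attr(frame, "interval_minutes"), valid_mask = mask)
}

#' Simulate a complete faulty multi-sensor frame
#'
#' Convenience wrapper: [generate_truth()] then [corrupt_sensors()].
#'
#' @inheritParams generate_truth
#' @return A [sensor_frame()] with covariates, sensor readings, truth and mask.
#' @export
simulate_frame <- function(config) {
  corrupt_sensors(generate_truth(config), config)
}

#' Read / write the package CSV dialect
#'
#' Header `timestamp,water_temp,solar_rad,wind_speed,rainfall,humidity,
#' do_s1..do_sS[,do_truth][,do_fused]`, ISO-8601 UTC timestamps, '.' decimal
#' separator. The validity mask is an in-memory evaluation aid and is not
#' serialized.
#'
#' @param frame a [sensor_frame()].
#' @param path file path.
#' @return `write_sensor_frame` returns `path` invisibly; `read_sensor_frame`
#'   returns a [sensor_frame()].
#' @export
write_sensor_frame <- function(frame, path) {
  stopifnot(inherits(frame, "sensor_frame"))
  df <- as.data.frame(frame)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_frame
#' @param interval_minutes sampling interval of the file; inferred from the
#'   first two timestamps when `NULL`.
#' @export
read_sensor_frame <- function(path, interval_minutes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  if (anyNA(df$timestamp))
    stop("unparseable ISO-8601 timestamps in ", path, call. = FALSE)
  if (is.null(interval_minutes)) {
    if (nrow(df) < 2L)
      stop("cannot infer interval from a single row; pass interval_minutes",
           call. = FALSE)
    interval_minutes <-
      as.numeric(difftime(df$timestamp[2L], df$timestamp[1L], units = "mins"))
  }
  sensor_frame(df, interval_minutes)
}
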