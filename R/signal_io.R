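#' Skin conductance recording
#'
#' A uniformly sampled single-channel skin conductance time series.
#'
#' @param samples conductance values in microsiemens (finite, length >= 2).
#' @param sampling_interval seconds per sample (> 0).
#' @param subject_id text label.
#' @param start_time time of the first sample in seconds (default 0).
#' @param annotations optional data frame with columns `label`, `start`,
#'   `end` (seconds); intervals must lie within the recording.
#' @return Object of class `eda_recording`.
#' @export
eda_recording <- function(samples, sampling_interval, subject_id = "subject",
                          start_time = 0, annotations = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 2,
            all(is.finite(samples)),
            is.numeric(sampling_interval), length(sampling_interval) == 1L,
            sampling_interval > 0, is.finite(start_time))
  duration <- length(samples) * sampling_interval
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("label", "start", "end") %in% names(annotations)))
    if (any(annotations$start < start_time) ||
        any(annotations$end > start_time + duration) ||
        any(annotations$end < annotations$start))
      stop("annotation intervals must lie within the recording")
  }
  structure(list(subject_id = subject_id, samples = as.numeric(samples),
                 sampling_interval = sampling_interval,
                 start_time = start_time, annotations = annotations),
            class = "eda_recording")
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf(
    "EDA recording '%s': %d samples at %.4g s (%.4g Hz), %.1f s total\n",
    x$subject_id, length(x$samples), x$sampling_interval,
    1 / x$sampling_interval, length(x$samples) * x$sampling_interval))
  cat(sprintf("  conductance range [%.3f, %.3f] uS\n",
              min(x$samples), max(x$samples)))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotated intervals\n", nrow(x$annotations)))
  invisible(x)
}

#' @export
as.data.frame.eda_recording <- function(x, ...) {
  data.frame(time = x$start_time + (seq_along(x$samples) - 1L) *
               x$sampling_interval,
             conductance = x$samples)
}

#' Read a skin conductance recording from delimited text
#'
#' Expects a CSV with a strictly increasing, uniformly spaced time column
#' (seconds) and a conductance column (microsiemens). The sampling interval
#' is inferred as the median successive time difference; spacing deviating
#' from it by more than 1% is an error.
#'
#' @param path file path.
#' @param column_spec named character vector mapping roles to column names,
#'   e.g. `c(time = "time", conductance = "conductance")`.
#' @param subject_id label for the recording; defaults to the file name.
#' @return An [eda_recording()].
#' @export
read_recording <- function(path,
                           column_spec = c(time = "time",
                                           conductance = "conductance"),
                           subject_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 2) stop("fewer than 2 rows in ", path)
  for (role in c("time", "conductance")) {
    cn <- column_spec[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop("missing ", role, " column '", cn, "'")
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'")
  }
  tt <- df[[column_spec[["time"]]]]
  if (any(diff(tt) <= 0)) stop("time column must be strictly increasing")
  dt <- stats::median(diff(tt))
  if (max(abs(diff(tt) - dt)) > 0.01 * dt)
    stop("non-uniform sampling: time steps deviate more than 1% from ",
         signif(dt, 6), " s")
  eda_recording(df[[column_spec[["conductance"]]]], dt,
                subject_id = subject_id, start_time = tt[1])
}

#' Write a set of time series as delimited text
#'
#' Writes one CSV with a header row, a `time` column, and one column per
#' series. Values are formatted with 15 significant digits so that a
#' write/read round trip preserves at least 10 significant digits, and the
#' formatting is deterministic.
#'
#' @param path output file path.
#' @param series named list of numeric vectors, all the same length.
#' @param time shared time base in seconds (same length as the series).
#' @return Invisibly, the path.
#' @export
write_series <- function(path, series, time) {
  if (!is.list(series) || length(series) == 0L || is.null(names(series)) ||
      any(names(series) == ""))
    stop("series must be a non-empty named list")
  lens <- vapply(series, length, integer(1))
  if (any(lens != length(time)))
    stop("mismatched series lengths: all series must match the time base")
  cols <- c(list(time = time), series)
  txt <- vapply(cols, function(v) sprintf("%.15g", v), character(length(time)))
  txt <- matrix(txt, ncol = length(cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}

## ---- configuration --------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the pipeline, suitable for
#' writing to / reading from YAML. Any subset can be overridden; unnamed
#' parameters keep their defaults.
#'
#' @return Nested list with sections `input`, `simulation`, `decomposition`,
#'   `deconvolution`, `arousal`.
#' @export
default_config <- function() {
  list(
    input = list(path = NULL,
                 columns = list(time = "time", conductance = "conductance")),
    simulation = NULL,                  # a sim_spec-style list, or NULL
    decomposition = list(smoothness_weight = 0.001, knot_spacing_s = 10,
                         driver_l1 = 8e-4),
    deconvolution = list(p_norm = 0.5, lambda0_frac = 1e-3,
                         lambda_growth = 1.3, lambda_max_frac = 0.003,
                         amplitude_floor = 0.01, n_restarts = 10,
                         cd_tol = 1e-6, cd_max_iter = 20,
                         irls_tol = 1e-6, irls_max_iter = 200,
                         segment_seconds = 180, segment_start = 30,
                         obs_interval = 0.5, grid_interval = 0.25,
                         tau_r_bounds = c(0.1, 1.4),
                         tau_d_bounds = c(1.5, 6)),
    arousal = list(p0 = NULL, tol = 1e-8, max_iter = 5000,
                   z_threshold = "median"))
}

## Deep-merge user overrides into the defaults.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a nested list
#'   of overrides; merged over [default_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be NULL, a path, or a list")
  cfg <- merge_config(default_config(), config)
  dc <- cfg$deconvolution
  if (dc$tau_r_bounds[1] >= dc$tau_r_bounds[2] ||
      dc$tau_d_bounds[1] >= dc$tau_d_bounds[2])
    stop("invalid config: tau bounds must be increasing intervals")
  if (dc$tau_r_bounds[2] >= dc$tau_d_bounds[1])
    stop("invalid config: tau_r bounds must lie below tau_d bounds")
  r <- dc$obs_interval / dc$grid_interval
  if (abs(r - round(r)) > 1e-9)
    stop("invalid config: obs_interval must be a multiple of grid_interval")
  if (is.null(cfg$input$path) && is.null(cfg$simulation))
    stop("config must name an input recording or a simulation spec")
  cfg
}

deconv_config_from <- function(dc) {
  deconv_config(p_norm = dc$p_norm, lambda0_frac = dc$lambda0_frac,
                lambda_growth = dc$lambda_growth,
                lambda_max_frac = dc$lambda_max_frac,
                amplitude_floor = dc$amplitude_floor,
                n_restarts = dc$n_restarts, cd_tol = dc$cd_tol,
                cd_max_iter = dc$cd_max_iter, irls_tol = dc$irls_tol,
                irls_max_iter = dc$irls_max_iter,
                segment_seconds = dc$segment_seconds,
                segment_start = dc$segment_start,
                grid_interval = dc$grid_interval,
                tau_bounds = list(tau_r = dc$tau_r_bounds,
                                  tau_d = dc$tau_d_bounds))
}

## ---- pipeline -------------------------------------------------------------

#' Run the full arousal-decoding pipeline
#'
#' Executes decompose -> deconvolve -> bin -> EM fit -> HAI on a recording
#' named in the configuration (or a simulated one), optionally writing every
#' intermediate and final series as CSV plus a flat JSON parameter summary.
#' Outputs are a pure function of (input, config, seed).
#'
#' @param config see [load_config()].
#' @param seed integer seed used for the simulation (if any) and the
#'   deconvolution restarts.
#' @param out_dir optional output directory; created if missing.
#' @param verbose logical; stage and iteration logging.
#' @return Object of class `eda_pipeline`: `recording`, `decomposition`,
#'   `deconvolution`, `binary`, `arousal`, `hai`, `config`, `seed`,
#'   `summary` (flat list of fitted parameters and diagnostics).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = NULL,
                         verbose = FALSE) {
  cfg <- load_config(config)
  stage <- function(name, expr) {
    if (verbose) message("[pipeline] ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  rec <- stage("input", {
    if (!is.null(cfg$input$path)) {
      read_recording(cfg$input$path,
                     column_spec = unlist(cfg$input$columns))
    } else {
      sp <- cfg$simulation
      sp$seed <- seed
      spec <- do.call(sim_spec, sp)
      sim <- simulate_recording(spec)
      truth <- sim$truth
      sim$recording
    }
  })
  dec <- stage("decompose", decompose_eda(
    rec, smoothness_weight = cfg$decomposition$smoothness_weight,
    knot_spacing = cfg$decomposition$knot_spacing_s,
    driver_l1 = cfg$decomposition$driver_l1))
  dcfg <- stage("deconvolve-config", deconv_config_from(cfg$deconvolution))
  T_y <- rec$sampling_interval
  dc <- stage("deconvolve",
              deconvolve(dec$phasic, obs_interval = T_y, config = dcfg,
                         seed = seed, verbose = verbose))
  duration <- length(rec$samples) * T_y
  bs <- stage("bin", bin_impulses(dc$impulses, dcfg$grid_interval, duration))
  p0 <- cfg$arousal$p0
  if (is.null(p0)) p0 <- mean(bs$s)
  fit <- stage("arousal", em_fit(bs, p0 = p0, tol = cfg$arousal$tol,
                                 max_iter = cfg$arousal$max_iter,
                                 verbose = verbose))
  h <- stage("hai", hai(fit, cfg$arousal$z_threshold))
  summ <- list(subject_id = rec$subject_id, seed = seed,
               tau_r = unname(coef(dc)["tau_r"]),
               tau_d = unname(coef(dc)["tau_d"]),
               n_impulses = dc$n_impulses, r_squared = dc$r_squared,
               lambda_final = dc$lambda_final,
               deconv_iterations = dc$iterations,
               decomposition_weights = dec$weights,
               alpha = fit$params$alpha, p0 = fit$params$p0,
               sigma_eps2 = fit$params$sigma_eps2, z0 = fit$params$z0,
               em_iterations = fit$iterations,
               em_converged = fit$converged,
               z_threshold = h$z_threshold)
  out <- structure(list(recording = rec, decomposition = dec,
                        deconvolution = dc, binary = bs, arousal = fit,
                        hai = h, truth = truth, config = cfg, seed = seed,
                        summary = summ),
                   class = "eda_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

## Write all pipeline series as CSV and the parameter summary as flat JSON.
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- x$recording
  t <- rec$start_time + (seq_along(rec$samples) - 1L) * rec$sampling_interval
  write_series(file.path(out_dir, "decomposition.csv"),
               list(conductance = rec$samples, tonic = x$decomposition$tonic,
                    phasic = x$decomposition$phasic,
                    residual = x$decomposition$residual), t)
  tab <- impulse_times(x$deconvolution$impulses)
  write_series(file.path(out_dir, "impulses.csv"),
               list(amplitude = tab$amplitude), tab$time)
  write_series(file.path(out_dir, "reconstruction.csv"),
               list(phasic = x$deconvolution$phasic,
                    reconstruction = x$deconvolution$reconstruction),
               seq_along(x$deconvolution$phasic) * x$deconvolution$obs_interval)
  sm <- x$arousal$smoothed
  tb <- seq_along(x$binary$s) * x$binary$bin_interval
  write_series(file.path(out_dir, "arousal.csv"),
               list(s = as.numeric(x$binary$s), z_smooth = sm$z_smooth,
                    var_smooth = sm$var_smooth, p_smooth = sm$p_smooth,
                    p_lower = sm$p_lower, p_upper = sm$p_upper,
                    hai = x$hai$hai), tb)
  jsonlite::write_json(x$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.eda_pipeline <- function(x, ...) {
  cat("EDA arousal pipeline\n")
  print(x$recording)
  print(x$deconvolution)
  print(x$arousal)
  invisible(x)
}
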