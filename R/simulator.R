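#' Simulation specification
#'
#' Collects every knob of the ground-truthed synthetic-data generator. The
#' defaults reproduce the study conditions used throughout the package's
#' validation: 6-minute recordings observed at `T_y = 0.5` s with the impulse
#' grid at `T_u = 0.25` s, sparse impulse trains with resolvable responses
#' (minimum separation 4 s, drive amplitudes uniform in [0.05, 1]), additive
#' Gaussian measurement noise at 25 dB SNR, a slow cubic-spline tonic drift,
#' and a latent arousal random walk emitting Bernoulli impulse events.
#'
#' @param duration recording duration in seconds.
#' @param obs_interval observation sampling interval `T_y` (s).
#' @param grid_interval impulse grid interval `T_u` (s).
#' @param scr_params an [scr_params()] object (kernel time constants).
#' @param n_impulses number of impulses to draw.
#' @param amplitude_range length-2 range of uniform drive amplitudes.
#' @param min_separation minimum spacing between impulses (s).
#' @param snr_db signal-to-noise ratio of phasic vs. measurement noise in dB
#'   (power ratio); `Inf` means noiseless.
#' @param tonic_spec list with `knot_spacing` (s), `scale` (microsiemens sd of
#'   knot coefficients) and `level` (baseline microsiemens) for the drift.
#' @param arousal_spec list with `sigma_eps2`, `z0`, `p0`, `J` for the latent
#'   arousal process.
#' @param seed integer seed making every draw reproducible.
#' @return Object of class `sim_spec` (a validated list).
#' @export
sim_spec <- function(duration = 360, obs_interval = 0.5, grid_interval = 0.25,
                     scr_params = edarousal::scr_params(0.7, 3.0),
                     n_impulses = 20, amplitude_range = c(0.05, 1),
                     min_separation = 4, snr_db = 25,
                     tonic_spec = list(knot_spacing = 60, scale = 0.1, level = 1.5),
                     arousal_spec = list(sigma_eps2 = 0.005, z0 = 0,
                                         p0 = 0.05, J = 2400),
                     seed = 1L) {
  stopifnot(duration > 0, obs_interval > 0, grid_interval > 0,
            inherits(scr_params, "scr_params"), n_impulses >= 0,
            length(amplitude_range) == 2L, amplitude_range[1] > 0,
            diff(amplitude_range) >= 0, min_separation >= 0,
            is.numeric(snr_db), length(snr_db) == 1L, !is.na(snr_db))
  r <- obs_interval / grid_interval
  if (abs(r - round(r)) > 1e-9)
    stop("obs_interval must be an integer multiple of grid_interval")
  if (n_impulses > 0 && n_impulses * min_separation > duration)
    stop("infeasible: n_impulses * min_separation exceeds duration")
  structure(list(duration = duration, obs_interval = obs_interval,
                 grid_interval = grid_interval, scr_params = scr_params,
                 n_impulses = n_impulses, amplitude_range = amplitude_range,
                 min_separation = min_separation, snr_db = snr_db,
                 tonic_spec = tonic_spec, arousal_spec = arousal_spec,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Reference SCR parameter configurations
#'
#' Six representative per-subject configurations (rise constant, decay
#' constant, number of impulses in a 6-minute window) spanning the
#' physiological range, as estimated from wrist-worn electrodermal recordings
#' of healthy subjects under cognitive stress. Used as the standard presets
#' for parameter-recovery experiments.
#'
#' @return Data frame with columns `subject`, `tau_r`, `tau_d`, `n_impulses`.
#' @export
subject_presets <- function() {
  data.frame(subject = 1:6,
             tau_r = c(0.681, 1.398, 1.159, 0.965, 0.604, 0.663),
             tau_d = c(2.591, 1.568, 1.505, 1.880, 3.018, 2.617),
             n_impulses = c(20L, 17L, 14L, 8L, 35L, 28L))
}

#' Draw a sparse impulse train
#'
#' Samples `n_impulses` grid-aligned impulse times uniformly without
#' replacement subject to a minimum pairwise separation, with amplitudes
#' uniform in `amplitude_range`. Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return An [impulse_train()] covering `duration / grid_interval` grid
#'   points.
#' @export
gen_impulse_train <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  T_u <- spec$grid_interval
  N <- floor(spec$duration / T_u)
  u <- numeric(N)
  if (spec$n_impulses > 0) {
    set.seed(spec$seed)
    sep <- ceiling(spec$min_separation / T_u)
    feasible <- rep(TRUE, N)
    picked <- integer(0)
    for (m in seq_len(spec$n_impulses)) {
      cand <- which(feasible)
      if (length(cand) == 0L)
        stop("infeasible separation constraint: could not place all impulses")
      i <- cand[sample.int(length(cand), 1L)]
      picked <- c(picked, i)
      feasible[max(1L, i - sep + 1L):min(N, i + sep - 1L)] <- FALSE
    }
    u[picked] <- stats::runif(spec$n_impulses,
                              spec$amplitude_range[1], spec$amplitude_range[2])
  }
  impulse_train(u, T_u, t0 = 0)
}

## Smooth random tonic drift: natural cubic spline through random knot values.
gen_tonic <- function(spec, t) {
  ts <- spec$tonic_spec
  knots <- seq(0, spec$duration, by = ts$knot_spacing)
  vals <- ts$level + stats::rnorm(length(knots), 0, ts$scale)
  f <- stats::splinefun(knots, vals, method = "natural")
  f(t)
}

#' Simulate a ground-truthed skin conductance recording
#'
#' Generates `phasic = A_tau*y0 + B_tau*u` from a random sparse impulse train
#' (with `y0 = 0`), adds Gaussian measurement noise rescaled so the realized
#' phasic-power/noise-power ratio equals `snr_db` exactly, and a smooth random
#' tonic drift. The recording is sampled at `obs_interval`; the impulse train
#' lives on the finer `grid_interval` grid.
#'
#' @param spec a [sim_spec()].
#' @return List with `recording` (an [eda_recording()]), and ground-truth
#'   components `truth`: `impulses`, `phasic`, `noise`, `noisy_phasic`,
#'   `tonic`, `time`, `scr_params`, `snr_db_realized`.
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  train <- gen_impulse_train(spec)       # seeds the RNG with spec$seed
  M <- floor(spec$duration / spec$obs_interval)
  phasic <- simulate_exact(spec$scr_params, train, y0 = 0, M = M,
                           T_y = spec$obs_interval)
  if (all(phasic == 0) && is.finite(spec$snr_db))
    stop("all-zero phasic signal: SNR is undefined; use snr_db = Inf")
  if (is.finite(spec$snr_db)) {
    w <- stats::rnorm(M)
    target_pow <- sum(phasic^2) * 10^(-spec$snr_db / 10)
    noise <- w * sqrt(target_pow / sum(w^2))
  } else {
    noise <- numeric(M)
  }
  t <- seq_len(M) * spec$obs_interval
  tonic <- gen_tonic(spec, t)
  rec <- eda_recording(samples = tonic + phasic + noise,
                       sampling_interval = spec$obs_interval,
                       subject_id = sprintf("sim-seed-%d", spec$seed),
                       start_time = t[1])
  snr_real <- if (is.finite(spec$snr_db))
    10 * log10(sum(phasic^2) / sum(noise^2)) else Inf
  list(recording = rec,
       truth = list(impulses = train, phasic = phasic, noise = noise,
                    noisy_phasic = phasic + noise, tonic = tonic, time = t,
                    scr_params = spec$scr_params,
                    snr_db_realized = snr_real))
}

#' Simulate the latent arousal process
#'
#' Draws a Gaussian random walk `z_j = z_{j-1} + eps_j`,
#' `eps_j ~ N(0, sigma_eps2)` from `z0`, maps it through the sigmoid
#' `p_j = 1 / (1 + exp(-(alpha + z_j)))` with `alpha = log(p0/(1-p0))`, and
#' emits Bernoulli impulse indicators `s_j ~ Bern(p_j)`.
#'
#' @param spec a [sim_spec()]; uses `arousal_spec` and `seed`.
#' @return List with `z` (state path), `p` (probability path), `s` (a
#'   [binary_sequence()] on the `grid_interval` bins), `alpha`.
#' @export
simulate_arousal_process <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  a <- spec$arousal_spec
  stopifnot(a$sigma_eps2 >= 0, a$p0 > 0, a$p0 < 1)
  if (a$J < 2) stop("arousal_spec$J must be at least 2")
  set.seed(spec$seed)
  alpha <- compute_alpha(a$p0)
  z <- a$z0 + cumsum(stats::rnorm(a$J, 0, sqrt(a$sigma_eps2)))
  p <- plogis(alpha + z)
  s <- as.integer(stats::runif(a$J) < p)
  list(z = z, p = p,
       s = binary_sequence(s, bin_interval = spec$grid_interval),
       alpha = alpha)
}
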