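#' SCR kernel parameters
#'
#' Container for the rise and decay time constants of a single skin
#' conductance response (SCR). Sweat diffusion into the stratum corneum and
#' its subsequent evaporation are modelled as a cascade of two first-order
#' systems, so a single sudomotor impulse produces a bi-exponential response
#' with rise constant `tau_r` and decay constant `tau_d`.
#'
#' Physiologically plausible (and identifiable) values are box-constrained to
#' 0.1 <= tau_r <= 1.4 s and 1.5 <= tau_d <= 6 s; the two ranges are disjoint
#' so the kernel never degenerates to a critically damped form.
#'
#' @param tau_r rise time constant in seconds.
#' @param tau_d decay time constant in seconds.
#' @return An object of class `scr_params`.
#' @examples
#' scr_params(0.7, 3.0)
#' @export
scr_params <- function(tau_r, tau_d) {
  stopifnot(is.numeric(tau_r), length(tau_r) == 1L, is.finite(tau_r),
            is.numeric(tau_d), length(tau_d) == 1L, is.finite(tau_d))
  b <- tau_bounds()
  if (tau_r < b$tau_r[1] || tau_r > b$tau_r[2])
    stop("tau_r must lie in [", b$tau_r[1], ", ", b$tau_r[2], "]")
  if (tau_d < b$tau_d[1] || tau_d > b$tau_d[2])
    stop("tau_d must lie in [", b$tau_d[1], ", ", b$tau_d[2], "]")
  structure(list(tau_r = tau_r, tau_d = tau_d), class = "scr_params")
}

#' Box constraints for the SCR time constants
#'
#' @return List with components `tau_r` and `tau_d`, each a length-2 numeric
#'   vector `c(lower, upper)` in seconds.
#' @export
tau_bounds <- function() {
  list(tau_r = c(0.1, 1.4), tau_d = c(1.5, 6))
}

#' @export
print.scr_params <- function(x, ...) {
  cat(sprintf("SCR parameters: tau_r = %.4g s (rise), tau_d = %.4g s (decay)\n",
              x$tau_r, x$tau_d))
  invisible(x)
}

#' Sparse sudomotor impulse train
#'
#' Nonnegative impulse amplitudes on a uniform grid with spacing
#' `grid_interval` seconds. Grid index `i` corresponds to time
#' `t0 + (i - 1) * grid_interval`; amplitude zero means no impulse.
#'
#' @param amplitudes nonnegative numeric vector of drive amplitudes.
#' @param grid_interval grid spacing `T_u` in seconds.
#' @param t0 time of the first grid point in seconds (default 0).
#' @return An object of class `impulse_train`.
#' @export
impulse_train <- function(amplitudes, grid_interval, t0 = 0) {
  stopifnot(is.numeric(amplitudes), all(is.finite(amplitudes)),
            is.numeric(grid_interval), length(grid_interval) == 1L,
            grid_interval > 0, is.numeric(t0), length(t0) == 1L)
  if (any(amplitudes < 0)) stop("impulse amplitudes must be nonnegative")
  structure(list(amplitudes = as.numeric(amplitudes),
                 grid_interval = grid_interval, t0 = t0),
            class = "impulse_train")
}

#' @export
print.impulse_train <- function(x, ...) {
  nnz <- sum(x$amplitudes > 0)
  cat(sprintf("Impulse train: %d grid points at %.3g s spacing, %d impulses\n",
              length(x$amplitudes), x$grid_interval, nnz))
  invisible(x)
}

#' Times and amplitudes of the nonzero impulses in a train
#'
#' @param train an [impulse_train()].
#' @return Data frame with columns `time` (s) and `amplitude`.
#' @export
impulse_times <- function(train) {
  stopifnot(inherits(train, "impulse_train"))
  i <- which(train$amplitudes > 0)
  data.frame(time = train$t0 + (i - 1) * train$grid_interval,
             amplitude = train$amplitudes[i])
}

#' Bi-exponential SCR impulse response
#'
#' Closed-form response of the diffusion/evaporation cascade to a unit
#' impulse: `h(t) = (exp(-t/tau_r) - exp(-t/tau_d)) / (tau_r - tau_d)`.
#' `h(0) = 0`, `h(t) > 0` for `t > 0`, and the kernel integrates to 1
#' (unit DC gain of the cascade).
#'
#' @param params an [scr_params()] object.
#' @param t nonnegative times in seconds (vectorized).
#' @return Numeric vector of kernel values (dimensionless gain).
#' @examples
#' impulse_response(scr_params(0.7, 3.0), c(0, 1, 5))
#' @export
impulse_response <- function(params, t) {
  stopifnot(inherits(params, "scr_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be nonnegative")
  (exp(-t / params$tau_r) - exp(-t / params$tau_d)) /
    (params$tau_r - params$tau_d)
}

## Matrix of observation/impulse lags: L[k, i] = k*T_y - (i-1)*T_u.
## Entries <= 0 are non-causal (h(0) = 0, so "<= 0" and "< 0" coincide).
lag_matrix <- function(M, N, T_y, T_u) {
  outer(seq_len(M) * T_y, (seq_len(N) - 1L) * T_u, "-")
}

#' Discrete observation operator for the phasic SCR model
#'
#' Builds the exact discrete-time solution of the two-compartment SCR model
#' sampled at `T_y` intervals: `y = A_tau * y0 + B_tau * u`, where
#' `A_tau[k] = exp(-k*T_y/tau_d)` carries the initial phasic level `y0`
#' (the duct is assumed empty at time zero, so `y0` decays through the
#' evaporation constant only) and row `k` of `B_tau` holds the kernel
#' evaluated at the lags `k*T_y - (i-1)*T_u` for impulse grid indices `i`,
#' with zeros for non-causal lags. `T_y` must be an integer multiple of
#' `T_u`, so row `k` ends in `N - k*T_y/T_u` zero entries.
#'
#' @param params an [scr_params()] object.
#' @param y0 initial phasic value in microsiemens.
#' @param M number of observations.
#' @param N number of impulse grid points; needs `M*T_y/T_u <= N`.
#' @param T_y observation sampling interval in seconds.
#' @param T_u impulse grid interval in seconds.
#' @return Object of class `scr_system`: list with `A_tau` (length `M`),
#'   `B_tau` (`M x N`), `y0`, `obs_interval`, `grid_interval`, `params`.
#' @export
build_system_matrices <- function(params, y0, M, N, T_y, T_u) {
  stopifnot(inherits(params, "scr_params"),
            is.numeric(y0), length(y0) == 1L, is.finite(y0),
            M >= 1, N >= 1)
  if (T_y <= 0 || T_u <= 0) stop("sampling intervals must be positive")
  r <- T_y / T_u
  if (abs(r - round(r)) > 1e-9)
    stop("T_y must be an integer multiple of T_u")
  r <- round(r)
  if (M * r > N)
    stop("impulse grid too short: need M*T_y/T_u <= N")
  A_tau <- exp(-(seq_len(M) * T_y) / params$tau_d)
  L <- lag_matrix(M, N, T_y, T_u)
  B_tau <- matrix(0, M, N)
  pos <- L > 0
  B_tau[pos] <- impulse_response(params, L[pos])
  structure(list(A_tau = A_tau, B_tau = B_tau, y0 = y0,
                 obs_interval = T_y, grid_interval = T_u, params = params),
            class = "scr_system")
}

#' Noiseless phasic signal from an impulse train
#'
#' Evaluates `A_tau * y0 + B_tau * u`, the exact sampled solution of the SCR
#' state-space model driven by the impulse train, with no measurement noise.
#'
#' @param params an [scr_params()] object.
#' @param u an [impulse_train()]; its `grid_interval` sets `T_u`.
#' @param y0 initial phasic value in microsiemens.
#' @param M number of observations to generate.
#' @param T_y observation interval in seconds (integer multiple of `T_u`).
#' @return Numeric vector of length `M` (microsiemens).
#' @export
simulate_exact <- function(params, u, y0, M, T_y) {
  stopifnot(inherits(u, "impulse_train"))
  N <- length(u$amplitudes)
  r <- T_y / u$grid_interval
  if (abs(r - round(r)) > 1e-9)
    stop("T_y must be an integer multiple of the impulse grid interval")
  if (M * round(r) > N)
    stop("impulse train too short for the requested number of observations")
  ## evaluate without materializing B for the all-zero case
  sys <- build_system_matrices(params, y0, M, N, T_y, u$grid_interval)
  as.numeric(sys$A_tau * y0 + sys$B_tau %*% u$amplitudes)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`, the squared multiple
#' correlation coefficient used as the goodness-of-fit statistic throughout.
#'
#' @param y observed series.
#' @param y_hat fitted series of the same length.
#' @return Scalar; `NA` when `y` is constant (undefined).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(is.numeric(y), is.numeric(y_hat), length(y) == length(y_hat),
            length(y) >= 2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - y_hat)^2) / tss
}
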