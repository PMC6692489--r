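## Independent oracles used across the suite. These deliberately avoid the
## package's own solution paths: ODE integration for the kernel, exhaustive
## subset search for sparse recovery, dense-grid forward-backward for the
## state-space posterior.

## Bi-exponential kernel by 4th-order Runge-Kutta integration of the
## diffusion/evaporation cascade; a unit-area impulse into the first
## compartment is the initial condition x1(0) = 1/tau_r.
rk4_kernel <- function(tau_r, tau_d, times) {
  deriv <- function(t, x, parms) {
    list(c(-x[1] / parms$tau_r,
           (x[1] - x[2]) / parms$tau_d))
  }
  out <- deSolve::ode(y = c(x1 = 1 / tau_r, x2 = 0), times = times,
                      func = deriv, parms = list(tau_r = tau_r, tau_d = tau_d),
                      method = "rk4")
  out[, "x2"]
}

## Best support of a given size by exhaustive enumeration: for every subset,
## fit nonnegative least squares and keep the smallest residual.
exhaustive_support <- function(B, y, k) {
  N <- ncol(B)
  combs <- utils::combn(N, k)
  best <- NULL
  best_sse <- Inf
  for (c_i in seq_len(ncol(combs))) {
    idx <- combs[, c_i]
    cf <- pracma::lsqnonneg(B[, idx, drop = FALSE], y)$x
    sse <- sum((y - B[, idx, drop = FALSE] %*% cf)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- idx
    }
  }
  sort(best)
}

## Exact smoothed posterior means of the discretized latent-walk model by
## dense-grid forward-backward (grid over [-lim, lim], Gaussian transition
## kernel applied by FFT convolution).
grid_smoother <- function(s, alpha, sig2, z0, var0, lim = 6, step = 1e-3) {
  zg <- seq(-lim, lim, by = step)
  n <- length(zg)
  J <- length(s)
  half <- ceiling(6 * sqrt(sig2) / step)
  k <- stats::dnorm(seq(-half, half) * step, 0, sqrt(sig2))
  k <- k / sum(k)
  conv <- function(v)
    stats::convolve(v, rev(k), type = "open")[(half + 1):(half + n)]
  lik <- function(sj) {
    p <- stats::plogis(alpha + zg)
    if (sj == 1) p else 1 - p
  }
  a <- matrix(0, n, J)
  a[, 1] <- stats::dnorm(zg, z0, sqrt(var0 + sig2)) * lik(s[1])
  a[, 1] <- a[, 1] / sum(a[, 1])
  for (j in 2:J) {
    a[, j] <- conv(a[, j - 1]) * lik(s[j])
    a[, j] <- a[, j] / sum(a[, j])
  }
  b <- matrix(0, n, J)
  b[, J] <- 1
  for (j in (J - 1):1) {
    b[, j] <- conv(b[, j + 1] * lik(s[j + 1]))
    b[, j] <- b[, j] / max(b[, j])
  }
  post <- a * b
  colSums(post * zg) / colSums(post)
}

## Mean squared second difference (roughness) of a series.
mssd <- function(x) mean(diff(diff(x))^2)
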