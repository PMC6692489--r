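#' Binary impulse-occurrence sequence
#'
#' Per-bin indicators `s_j` of whether at least one sudomotor impulse occurred
#' in bin `j` (bins of `bin_interval` seconds, closed on the left).
#'
#' @param s integer vector of 0/1 values, length at least 2.
#' @param bin_interval bin width in seconds.
#' @return Object of class `binary_sequence`.
#' @export
binary_sequence <- function(s, bin_interval) {
  s <- as.integer(s)
  stopifnot(length(s) >= 2, all(s %in% c(0L, 1L)), bin_interval > 0)
  structure(list(s = s, bin_interval = bin_interval),
            class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  cat(sprintf("Binary sequence: %d bins of %.3g s, %d events (rate %.4f)\n",
              length(x$s), x$bin_interval, sum(x$s), mean(x$s)))
  invisible(x)
}

#' Bin an impulse train into occurrence indicators
#'
#' Divides `[0, duration)` into bins of `bin_interval` seconds and sets
#' `s_j = 1` if at least one impulse with positive amplitude falls in bin `j`
#' (`[j*T, (j+1)*T)`, 0-based). Multiple impulses in one bin still give a
#' single 1.
#'
#' @param impulses an [impulse_train()].
#' @param bin_interval bin width in seconds.
#' @param duration total duration covered; must contain every impulse.
#' @return A [binary_sequence()] of length `ceiling(duration/bin_interval)`.
#' @export
bin_impulses <- function(impulses, bin_interval, duration) {
  stopifnot(inherits(impulses, "impulse_train"), bin_interval > 0,
            duration > 0)
  J <- ceiling(duration / bin_interval)
  tab <- impulse_times(impulses)
  s <- integer(J)
  if (nrow(tab)) {
    if (any(tab$time >= duration) || any(tab$time < 0))
      stop("impulse beyond duration")
    s[floor(tab$time / bin_interval) + 1L] <- 1L
  }
  binary_sequence(s, bin_interval)
}

#' Baseline log-odds of impulse occurrence
#'
#' `alpha = log(p0 / (1 - p0))`, the inverse of the sigmoid observation link
#' at a zero arousal state; `p0` is the probability that an impulse occurs
#' randomly in a time bin.
#'
#' @param p0 baseline per-bin impulse probability, in (0, 1).
#' @return The log-odds (dimensionless).
#' @examples
#' compute_alpha(0.5)  # 0
#' @export
compute_alpha <- function(p0) {
  stopifnot(is.numeric(p0), length(p0) == 1L)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  log(p0 / (1 - p0))
}

#' Arousal state-space parameters
#'
#' The latent sympathetic arousal state follows a random walk
#' `z_j = z_{j-1} + eps_j`, `eps_j ~ N(0, sigma_eps2)`, starting from `z0`;
#' impulse occurrences are Bernoulli with probability
#' `1/(1 + exp(-(alpha + z_j)))` where `alpha` is fixed from the baseline
#' rate `p0`.
#'
#' @param sigma_eps2 process-noise variance (per bin), positive.
#' @param z0 initial state.
#' @param p0 baseline per-bin impulse probability in (0, 1).
#' @return Object of class `arousal_params` with fields `alpha`,
#'   `sigma_eps2`, `z0`, `p0`.
#' @export
arousal_params <- function(sigma_eps2, z0 = 0, p0 = 0.05) {
  stopifnot(is.numeric(sigma_eps2), length(sigma_eps2) == 1L,
            sigma_eps2 >= 0, is.finite(z0))
  structure(list(alpha = compute_alpha(p0), sigma_eps2 = sigma_eps2,
                 z0 = z0, p0 = p0),
            class = "arousal_params")
}

#' Approximate Gaussian forward filter for binary observations
#'
#' Runs the predict/update recursion for the random-walk state with Bernoulli
#' observations. The prediction step is `z_{j|j-1} = z_{j-1|j-1}`,
#' `var_{j|j-1} = var_{j-1|j-1} + sigma_eps2`; the update solves the implicit
#' posterior-mode equation
#' `z_{j|j} = z_{j|j-1} + var_{j|j-1} * (s_j - p(z_{j|j}))` by Newton's
#' method (tolerance 1e-10, bracketed bisection fallback), and the posterior
#' variance is `1 / (1/var_{j|j-1} + p(1-p))` at the converged mode.
#'
#' @param s a [binary_sequence()].
#' @param params an [arousal_params()].
#' @param var0 initial state variance `var_{0|0}` (default `sigma_eps2`).
#' @return Object of class `filtered_state`: list with `z_pred`, `var_pred`,
#'   `z_filt`, `var_filt` (all length `J`) and `params`.
#' @export
forward_filter <- function(s, params, var0 = params$sigma_eps2) {
  stopifnot(inherits(s, "binary_sequence"), inherits(params, "arousal_params"),
            var0 >= 0)
  out <- cpp_forward_filter(s$s, params$alpha, params$sigma_eps2,
                            params$z0, var0)
  out$params <- params
  out$var0 <- var0
  class(out) <- "filtered_state"
  out
}

#' Fixed-interval smoother for the filtered arousal state
#'
#' Combines the forward-filtered estimates with future observations:
#' `A_j = var_{j|j} / var_{j+1|j}`,
#' `z_{j|J} = z_{j|j} + A_j (z_{j+1|J} - z_{j+1|j})`, and the analogous
#' variance recursion, with terminal values copied from the filter. Smoothed
#' occurrence probabilities `p_{j|J}` are the sigmoid of `alpha + z_{j|J}`,
#' with confidence bounds from transforming `z +/- 1.96 sd` through the
#' sigmoid.
#'
#' @param filt a `filtered_state` from [forward_filter()].
#' @param params an [arousal_params()]; defaults to the filter's.
#' @return Object of class `smoothed_state`: `z_smooth`, `var_smooth`,
#'   `gain`, `p_smooth`, `p_lower`, `p_upper`, `params`.
#' @export
backward_smooth <- function(filt, params = filt$params) {
  stopifnot(inherits(filt, "filtered_state"))
  out <- cpp_backward_smooth(filt$z_pred, filt$var_pred,
                             filt$z_filt, filt$var_filt)
  sdv <- sqrt(out$var_smooth)
  out$p_smooth <- plogis(params$alpha + out$z_smooth)
  out$p_lower <- plogis(params$alpha + out$z_smooth - 1.96 * sdv)
  out$p_upper <- plogis(params$alpha + out$z_smooth + 1.96 * sdv)
  out$params <- params
  class(out) <- "smoothed_state"
  out
}

## Expected complete-data M-step update of sigma_eps2. Derived from the
## random-walk Gaussian likelihood with an extra origin step z0 ~ N(0,
## sigma_eps2) (which also yields the z0 update z_{1|J}/2), using smoothed
## means, variances and lag-one covariances cov(z_j, z_{j-1} | S) =
## A_{j-1} var_{j|J}.
m_step_sigma <- function(sm) {
  z <- sm$z_smooth; v <- sm$var_smooth; A <- sm$gain
  J <- length(z)
  S <- v + z^2
  C <- A[1:(J - 1)] * v[2:J] + z[2:J] * z[1:(J - 1)]
  tot <- 2 * (sum(S[2:J]) - sum(C)) + 2 * v[1] + 1.5 * z[1]^2 - S[J]
  tot / (J + 1)
}

#' Fit the arousal state-space model by Expectation-Maximization
#'
#' Alternates the E-step (forward filter started at `z_{0|0} = z0` with
#' `var_{0|0} = sigma_eps2`, then the fixed-interval smoother) with M-step
#' updates of the process-noise variance (from the expected complete-data
#' likelihood) and of the initial state `z0 = z_{1|J} / 2`, until the largest
#' absolute parameter change does not exceed `tol`.
#'
#' @param s a [binary_sequence()]; must contain at least one 0 and one 1.
#' @param p0 baseline impulse probability fixing `alpha`; default is the
#'   empirical rate `mean(s)`.
#' @param tol convergence tolerance on the parameter changes.
#' @param max_iter maximum EM iterations.
#' @param sigma_eps2_init,z0_init starting values.
#' @param verbose logical; log one line per EM iteration.
#' @return Object of class `arousal_fit`: `params` (an [arousal_params()]),
#'   `smoothed`, `filtered`, `iterations`, `converged`, `flag_floor` (TRUE if
#'   the variance update hit its numerical floor), `trace` (per-iteration
#'   parameter matrix), `s`, `final_delta`.
#' @export
em_fit <- function(s, p0 = mean(s$s), tol = 1e-8, max_iter = 5000,
                   sigma_eps2_init = 0.01, z0_init = 0, verbose = FALSE) {
  stopifnot(inherits(s, "binary_sequence"))
  if (all(s$s == s$s[1]))
    stop("degenerate sequence: needs at least one 0 and one 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  sig <- sigma_eps2_init; z0 <- z0_init
  flag_floor <- FALSE
  trace <- matrix(NA_real_, max_iter, 3,
                  dimnames = list(NULL, c("sigma_eps2", "z0", "delta")))
  converged <- FALSE
  delta <- NA_real_
  it <- 0L
  params <- arousal_params(sig, z0, p0)
  repeat {
    it <- it + 1L
    ## bare compiled recursions in the loop; classed wrappers only at the end
    filt <- cpp_forward_filter(s$s, params$alpha, params$sigma_eps2,
                               params$z0, params$sigma_eps2)
    sm <- cpp_backward_smooth(filt$z_pred, filt$var_pred,
                              filt$z_filt, filt$var_filt)
    sig_new <- m_step_sigma(sm)
    if (sig_new <= 0) { sig_new <- 1e-12; flag_floor <- TRUE }
    z0_new <- sm$z_smooth[1] / 2
    delta <- max(abs(sig_new - params$sigma_eps2), abs(z0_new - params$z0))
    trace[it, ] <- c(sig_new, z0_new, delta)
    if (verbose)
      message(sprintf("EM iter %d: sigma_eps2 = %.6g, z0 = %.6g, delta = %.3g",
                      it, sig_new, z0_new, delta))
    params <- arousal_params(max(sig_new, 1e-12), z0_new, p0)
    if (delta <= tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  ## final E-step at the converged parameters
  filt <- forward_filter(s, params, var0 = params$sigma_eps2)
  sm <- backward_smooth(filt, params)
  out <- list(params = params, smoothed = sm, filtered = filt,
              iterations = it, converged = converged,
              flag_floor = flag_floor, trace = trace[seq_len(it), , drop = FALSE],
              s = s, final_delta = delta)
  class(out) <- "arousal_fit"
  out
}

#' High Arousal Index
#'
#' Probability that the arousal state exceeds a threshold under the smoothed
#' Gaussian posterior: `HAI_j = Pr(z_j > z_T) =
#' 1 - Phi((z_T - z_{j|J}) / sd_{j|J})`. With the default `"median"`
#' threshold, `z_T` is the median smoothed state over the whole recording —
#' an approximation of the subject's normal arousal between the stressed and
#' relaxed extremes.
#'
#' @param smoothed a `smoothed_state` (or an `arousal_fit`, whose smoothed
#'   component is used).
#' @param z_threshold numeric threshold, or `"median"`.
#' @return Object of class `hai_series`: `hai` (probabilities), `z_threshold`.
#' @export
hai <- function(smoothed, z_threshold = "median") {
  if (inherits(smoothed, "arousal_fit")) smoothed <- smoothed$smoothed
  stopifnot(inherits(smoothed, "smoothed_state"))
  z <- smoothed$z_smooth; v <- smoothed$var_smooth
  zT <- if (identical(z_threshold, "median")) stats::median(z)
        else as.numeric(z_threshold)
  h <- ifelse(v > 0,
              1 - stats::pnorm((zT - z) / sqrt(v)),
              as.numeric(z > zT))
  structure(list(hai = h, z_threshold = zT), class = "hai_series")
}

## ---- methods --------------------------------------------------------------

#' @export
print.arousal_fit <- function(x, ...) {
  cat("Arousal state-space model (EM fit)\n")
  cat(sprintf("  bins: %d (%.3g s), events: %d, p0 = %.4f, alpha = %.4f\n",
              length(x$s$s), x$s$bin_interval, sum(x$s$s), x$params$p0,
              x$params$alpha))
  cat(sprintf("  sigma_eps2 = %.6g, z0 = %.4g\n",
              x$params$sigma_eps2, x$params$z0))
  cat(sprintf("  EM iterations: %d (%s, final |delta| = %.3g)\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$final_delta))
  invisible(x)
}

#' @export
summary.arousal_fit <- function(object, ...) {
  h <- hai(object)
  structure(list(fit = object,
                 hai_above_90 = mean(h$hai > 0.9),
                 z_range = range(object$smoothed$z_smooth)),
            class = "summary.arousal_fit")
}

#' @export
print.summary.arousal_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  smoothed state range: [%.3f, %.3f]\n",
              x$z_range[1], x$z_range[2]))
  cat(sprintf("  fraction of bins with HAI > 0.9: %.3f\n", x$hai_above_90))
  invisible(x)
}

#' @export
coef.arousal_fit <- function(object, ...) {
  c(alpha = object$params$alpha, sigma_eps2 = object$params$sigma_eps2,
    z0 = object$params$z0)
}

#' @export
fitted.arousal_fit <- function(object, ...) object$smoothed$p_smooth

#' @export
residuals.arousal_fit <- function(object, ...)
  object$s$s - object$smoothed$p_smooth

#' @export
simulate.arousal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- length(object$s$s)
  p <- object$params
  replicate(nsim, {
    z <- p$z0 + cumsum(stats::rnorm(J, 0, sqrt(p$sigma_eps2)))
    as.integer(stats::runif(J) < plogis(p$alpha + z))
  })
}

#' @export
plot.arousal_fit <- function(x, ...) {
  t <- seq_along(x$s$s) * x$s$bin_interval
  sm <- x$smoothed
  h <- hai(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op))
  sdv <- sqrt(sm$var_smooth)
  plot(t, sm$z_smooth, type = "l", xlab = "", ylab = "z (arousal)",
       main = "Smoothed arousal state", ylim = range(sm$z_smooth + 1.96 * sdv,
                                                     sm$z_smooth - 1.96 * sdv))
  graphics::lines(t, sm$z_smooth + 1.96 * sdv, lty = 3)
  graphics::lines(t, sm$z_smooth - 1.96 * sdv, lty = 3)
  plot(t, sm$p_smooth, type = "l", xlab = "", ylab = "p (impulse prob.)",
       main = "Smoothed impulse probability")
  graphics::rug(t[x$s$s == 1])
  plot(t, h$hai, type = "l", xlab = "time (s)", ylab = "HAI",
       main = sprintf("High Arousal Index (z_T = %.3f)", h$z_threshold),
       ylim = c(0, 1))
  graphics::abline(h = 0.9, col = "red", lty = 2)
  invisible(x)
}
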