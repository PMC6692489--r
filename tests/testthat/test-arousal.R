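test_that("binning marks occupied bins once and validates its domain", {
  empty <- impulse_train(numeric(40), 0.25)
  s <- bin_impulses(empty, 0.25, 10)
  expect_equal(sum(s$s), 0)
  expect_equal(length(s$s), 40)

  one <- impulse_train(c(numeric(4), 0.3, numeric(35)), 0.275)  # t = 1.1 s
  s1 <- bin_impulses(one, 0.25, 11)
  expect_equal(which(s1$s == 1L), 5L)          # 0-based bin 4

  ## two impulses in one bin contribute a single 1
  u <- numeric(40); u[c(5, 6)] <- 1            # 1.0 s and 1.25 s with T_u=.25
  two <- impulse_train(u, 0.25)
  s2 <- bin_impulses(two, 0.5, 10)
  expect_equal(sum(s2$s), 1)

  late <- impulse_train(c(numeric(39), 1), 0.25)  # impulse at 9.75 s
  expect_error(bin_impulses(late, 0.25, 9), "beyond duration")
})

test_that("alpha is the log-odds of the baseline rate", {
  expect_equal(compute_alpha(0.5), 0)
  expect_equal(compute_alpha(exp(1) / (1 + exp(1))), 1)
  ## 24 events in 2400 bins
  expect_equal(compute_alpha(0.01), log(0.01 / 0.99), tolerance = 1e-12)
  expect_equal(compute_alpha(0.01), -4.59512, tolerance = 1e-5)
  expect_error(compute_alpha(0), "\\(0, 1\\)")
  expect_error(compute_alpha(1.2), "\\(0, 1\\)")
})

test_that("the filter update solves the implicit mode equation", {
  ## degenerate case: no process noise, no initial variance -> state frozen
  s <- binary_sequence(c(1, 0, 1, 1, 0), 0.25)
  pf <- forward_filter(s, arousal_params(0, z0 = 0.3, p0 = 0.4), var0 = 0)
  expect_equal(pf$z_filt, rep(0.3, 5))
  expect_equal(pf$var_filt, rep(0, 5))

  ## single step vs a scalar root-finder oracle on z = 1 - sigmoid(z)
  root <- uniroot(function(z) z - (1 - plogis(z)), c(-5, 5), tol = 1e-12)$root
  s1 <- binary_sequence(c(1, 0), 1)
  f1 <- forward_filter(s1, arousal_params(0.5, z0 = 0, p0 = 0.5), var0 = 0.5)
  expect_equal(f1$z_filt[1], root, tolerance = 1e-9)

  ## update moves toward the observation: sign(z_filt - z_pred) =
  ## sign(s - p(z_pred))
  set.seed(31)
  for (i in 1:20) {
    par <- arousal_params(runif(1, 0.01, 0.5), rnorm(1), runif(1, 0.05, 0.9))
    sv <- binary_sequence(rbinom(10, 1, 0.5), 0.25)
    ff <- forward_filter(sv, par)
    drift <- ff$z_filt - ff$z_pred
    expected <- sv$s - plogis(par$alpha + ff$z_pred)
    expect_true(all(sign(drift) == sign(expected)))
  }
})

test_that("smoother terminal condition, variance ordering, and limits hold", {
  set.seed(5)
  s <- binary_sequence(rbinom(40, 1, 0.3), 0.25)
  par <- arousal_params(0.05, z0 = 0, p0 = 0.3)
  f <- forward_filter(s, par)
  sm <- backward_smooth(f)
  J <- 40
  expect_equal(sm$z_smooth[J], f$z_filt[J])
  expect_equal(sm$var_smooth[J], f$var_filt[J])
  expect_true(all(sm$var_smooth <= f$var_filt + 1e-12))
  expect_true(all(sm$var_smooth > 0))
  ## growing process noise: the smoother's correction shrinks relative to
  ## the state scale (each Bernoulli observation carries bounded
  ## information, so gains stay in [0, 1) but do not vanish)
  rel_corr <- vapply(c(0.05, 1, 100), function(sg) {
    fl <- forward_filter(s, arousal_params(sg, 0, 0.3))
    sml <- backward_smooth(fl)
    expect_true(all(sml$gain[1:39] >= 0 & sml$gain[1:39] < 1))
    mean(abs(sml$z_smooth - fl$z_filt)) / sd(fl$z_filt)
  }, numeric(1))
  expect_true(all(diff(rel_corr) < 0))
})

test_that("filter/smoother agree with the dense-grid exact posterior", {
  cases <- list(list(sig2 = 0.005, p0 = 0.1), list(sig2 = 0.02, p0 = 0.3))
  for (cs in cases) {
    for (seed in 1:3) {
      set.seed(seed)
      s <- rbinom(15, 1, 0.4)
      if (all(s == s[1])) s[1] <- 1L - s[1]
      bs <- binary_sequence(s, 0.25)
      par <- arousal_params(cs$sig2, z0 = 0.1, p0 = cs$p0)
      sm <- backward_smooth(forward_filter(bs, par))
      gz <- grid_smoother(s, par$alpha, cs$sig2, 0.1, cs$sig2)
      expect_lt(mean(abs(sm$z_smooth - gz)), 0.02)
    }
  }
})

test_that("the M-step matches a numerical maximizer of the expected likelihood", {
  set.seed(9)
  s <- binary_sequence(rbinom(30, 1, 0.3), 0.25)
  sm <- backward_smooth(forward_filter(s, arousal_params(0.05, 0.1, 0.3)))
  z <- sm$z_smooth; v <- sm$var_smooth; A <- sm$gain
  J <- length(z)
  ## E[(z_j - z_{j-1})^2] from smoothed moments and lag-one covariances
  ed2 <- (z[2:J] - z[1:(J - 1)])^2 + v[2:J] + v[1:(J - 1)] -
    2 * A[1:(J - 1)] * v[2:J]
  z0n <- z[1] / 2
  qfun <- function(sig)
    -(J + 1) / 2 * log(sig) -
      (sum(ed2) + (z[1] - z0n)^2 + v[1] + z0n^2) / (2 * sig)
  num <- optimize(function(x) -qfun(x), c(1e-6, 5), tol = 1e-10)$minimum
  expect_equal(edarousal:::m_step_sigma(sm), num, tolerance = 1e-6)
})

test_that("EM converges to a fixed point and honors its stopping rule", {
  spec <- sim_spec(arousal_spec = list(sigma_eps2 = 0.005, z0 = 0,
                                       p0 = 0.05, J = 1200), seed = 2)
  ap <- simulate_arousal_process(spec)
  fit <- em_fit(ap$s, p0 = 0.05)
  if (fit$converged) expect_lte(fit$final_delta, 1e-8)
  ## restarting EM at the converged parameters stops immediately
  refit <- em_fit(ap$s, p0 = 0.05,
                  sigma_eps2_init = fit$params$sigma_eps2,
                  z0_init = fit$params$z0)
  expect_equal(refit$iterations, 1L)
  expect_lte(refit$final_delta, 1e-8)
  ## degenerate constant sequences are rejected
  expect_error(em_fit(binary_sequence(rep(1L, 10), 0.25)), "degenerate")
})

test_that("HAI is calibrated at the threshold and monotone in the state", {
  set.seed(12)
  s <- binary_sequence(rbinom(60, 1, 0.2), 0.25)
  fit_sm <- backward_smooth(forward_filter(s, arousal_params(0.02, 0, 0.2)))
  ## exactly 0.5 when the threshold sits on the smoothed state
  h_at <- hai(fit_sm, z_threshold = fit_sm$z_smooth[10])
  expect_equal(h_at$hai[10], 0.5)
  ## normal-quantile oracle: z = z_T + 1.6449 sd -> HAI ~ 0.95
  zT <- fit_sm$z_smooth[20] - 1.6449 * sqrt(fit_sm$var_smooth[20])
  h_q <- hai(fit_sm, z_threshold = zT)
  expect_equal(h_q$hai[20], 0.95, tolerance = 1e-4)
  ## median threshold: bins above and below balance up to ties
  h <- hai(fit_sm)
  n_above <- sum(h$hai > 0.5)
  n_below <- sum(h$hai < 0.5)
  n_ties <- sum(h$hai == 0.5)
  expect_lte(abs(n_above - n_below), n_ties + 1)
  ## monotone in z_smooth at fixed variance
  ord <- order(fit_sm$z_smooth)
  same_var <- sqrt(fit_sm$var_smooth)
  expect_true(all(diff((1 - pnorm((h$z_threshold - fit_sm$z_smooth[ord]) /
                                    mean(same_var)))) >= 0))
})

test_that("appending event-filled bins does not decrease the terminal state", {
  set.seed(3)
  for (i in 1:5) {
    s0 <- rbinom(100, 1, 0.2)
    if (all(s0 == s0[1])) s0[1] <- 1L - s0[1]
    par <- arousal_params(0.02, 0, 0.2)
    f0 <- forward_filter(binary_sequence(s0, 0.25), par)
    f1 <- forward_filter(binary_sequence(c(s0, rep(1L, 10)), 0.25), par)
    expect_gte(f1$z_filt[110], f0$z_filt[100])
  }
})
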