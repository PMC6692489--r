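test_that("kernel vanishes at zero, is positive, decays, and has unit gain", {
  set.seed(42)
  for (i in 1:5) {
    p <- scr_params(runif(1, 0.1, 1.4), runif(1, 1.5, 6))
    expect_identical(impulse_response(p, 0), 0)
    tt <- seq(0.1, 30, by = 0.1)
    expect_true(all(impulse_response(p, tt) > 0))
    expect_lt(impulse_response(p, 60), 1e-4)
    gain <- integrate(function(t) impulse_response(p, t), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_lt(abs(gain - 1), 1e-6)
  }
  expect_error(impulse_response(scr_params(0.7, 3), -1), "nonnegative")
  expect_error(scr_params(0.05, 3), "tau_r")
  expect_error(scr_params(0.7, 8), "tau_d")
})

test_that("closed-form kernel matches RK4 integration of the two-compartment ODEs", {
  p <- scr_params(0.681, 2.591)
  times <- seq(0, 20, by = 0.001)
  ode <- rk4_kernel(p$tau_r, p$tau_d, times)
  expect_lt(max(abs(impulse_response(p, times) - ode)), 1e-6)
  ## second, randomly drawn configuration
  set.seed(7)
  p2 <- scr_params(runif(1, 0.1, 1.4), runif(1, 1.5, 6))
  ode2 <- rk4_kernel(p2$tau_r, p2$tau_d, times)
  expect_lt(max(abs(impulse_response(p2, times) - ode2)), 1e-6)
})

test_that("system matrices implement the discrete observation operator", {
  p <- scr_params(0.7, 2.0)
  M <- 20; N <- 40; T_y <- 0.5; T_u <- 0.25
  sys <- build_system_matrices(p, y0 = 1, M, N, T_y, T_u)
  ## decay coefficients: strictly decreasing pure exponential in tau_d
  expect_equal(sys$A_tau, exp(-(1:M) * T_y / 2.0))
  expect_true(all(diff(sys$A_tau) < 0))
  ## row k has exactly N - k*T_y/T_u trailing zeros
  r <- T_y / T_u
  for (k in c(1, 7, 19)) {
    row <- sys$B_tau[k, ]
    expect_true(all(row[seq_len(k * r)] > 0))          # causal lags populated
    expect_true(all(row[(k * r + 1):N] == 0))          # trailing zeros
  }
  ## zero drive: y = A_tau * y0 is pure exponential decay
  u0 <- impulse_train(numeric(N), T_u)
  y <- simulate_exact(p, u0, y0 = 1, M, T_y)
  expect_equal(y, exp(-(1:M) * T_y / 2.0))
  ## ratio of intervals fixes the matrix width
  expect_equal(ncol(sys$B_tau), r * M)
  expect_error(build_system_matrices(p, 0, M, N, 0.5, 0.3), "integer multiple")
})

test_that("a single impulse reproduces the kernel pointwise", {
  p <- scr_params(0.681, 2.591)
  N <- 80; M <- 40; T_u <- 0.25; T_y <- 0.5
  u <- numeric(N); u[1] <- 1      # impulse at time 0 (first grid point)
  y <- simulate_exact(p, impulse_train(u, T_u), y0 = 0, M, T_y)
  expect_equal(y, impulse_response(p, (1:M) * T_y), tolerance = 1e-12)
  ## all-zero drive and initial condition
  expect_equal(simulate_exact(p, impulse_train(numeric(N), T_u), 0, M, T_y),
               numeric(M))
})

test_that("the forward model is linear and causal", {
  set.seed(11)
  p <- scr_params(0.9, 4.0)
  N <- 120; M <- 60; T_u <- 0.25; T_y <- 0.5
  u1 <- numeric(N); u1[sample(N, 4)] <- runif(4)
  u2 <- numeric(N); u2[sample(N, 4)] <- runif(4)
  a <- 1.7; b <- 0.4
  y12 <- simulate_exact(p, impulse_train(a * u1 + b * u2, T_u), 0, M, T_y)
  y1 <- simulate_exact(p, impulse_train(u1, T_u), 0, M, T_y)
  y2 <- simulate_exact(p, impulse_train(u2, T_u), 0, M, T_y)
  expect_equal(y12, a * y1 + b * y2, tolerance = 1e-10)
  ## causality: perturbing an impulse at grid time >= k*T_y leaves y_k alone
  k <- 30
  u_pert <- u1
  late <- which((seq_len(N) - 1) * T_u >= k * T_y)
  u_pert[late] <- u_pert[late] + 1
  y_pert <- simulate_exact(p, impulse_train(u_pert, T_u), 0, M, T_y)
  expect_equal(y_pert[1:k], y1[1:k], tolerance = 1e-12)
  expect_gt(max(abs(y_pert - y1)), 0.01)
})

test_that("well-separated impulses produce one peak each", {
  spec <- sim_spec(duration = 360, scr_params = scr_params(0.681, 2.591),
                   n_impulses = 20, min_separation = 12, snr_db = Inf,
                   seed = 21)
  sim <- simulate_recording(spec)
  y <- sim$truth$phasic
  peaks <- sum(diff(sign(diff(y))) == -2)
  expect_equal(peaks, 20)
})

test_that("r_squared matches its definition and handles the degenerate case", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_true(is.na(r_squared(c(2, 2, 2), c(1, 2, 3))))
})
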