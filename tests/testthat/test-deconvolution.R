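make_system <- function(params = scr_params(0.7, 3.0), M = 120, T_y = 0.5,
                        T_u = 0.25, y0 = 0) {
  build_system_matrices(params, y0, M, M * round(T_y / T_u), T_y, T_u)
}

test_that("FOCUSS+ returns zero on zero data and recovers a lone impulse", {
  sys <- make_system()
  cfg <- deconv_config()
  u0 <- focuss_plus(numeric(120), sys, cfg)
  expect_equal(u0$amplitudes, numeric(240))

  u_true <- numeric(240); u_true[40] <- 0.5
  y <- as.numeric(sys$B_tau %*% u_true)
  uf <- focuss_plus(y, sys, cfg)
  g <- gcv_focuss_plus(y, sys, uf, cfg)
  u <- g$impulses$amplitudes
  expect_equal(which(u > 1e-6 * max(u)), 40L)
  expect_lt(abs(u[40] - 0.5) / 0.5, 0.05)
})

test_that("noiseless sparse recovery matches exhaustive support search", {
  ## small systems, sparsity 2: compare against the best subset over all
  ## C(N, 2) supports
  p <- scr_params(0.7, 3.0)
  cfg <- deconv_config(grid_interval = 1)
  for (seed in 1:4) {
    set.seed(seed)
    N <- sample(10:24, 1)
    sys <- build_system_matrices(p, 0, N, N, 1, 1)
    supp <- sort(sample(N - 1, 2))
    u_true <- numeric(N); u_true[supp] <- runif(2, 0.3, 1)
    y <- as.numeric(sys$B_tau %*% u_true)
    uf <- focuss_plus(y, sys, cfg)
    g <- gcv_focuss_plus(y, sys, uf, cfg)
    u <- g$impulses$amplitudes
    rec <- sort(which(u > 1e-6 * max(u)))
    expect_equal(rec, exhaustive_support(sys$B_tau, y, 2))
  }
})

test_that("GCV selects a small lambda on noiseless data and is a fixed point", {
  sys <- make_system()
  cfg <- deconv_config()
  set.seed(2)
  u_true <- numeric(240); u_true[sample(200, 5)] <- runif(5, 0.2, 1)
  y <- as.numeric(sys$B_tau %*% u_true)
  uf <- focuss_plus(y, sys, cfg)
  g <- gcv_focuss_plus(y, sys, uf, cfg)
  ## lambda heads to the small end of the search grid, non-increasing trend
  expect_lte(rev(g$lambdas)[1], g$lambdas[1] * 1.1)
  expect_lt(g$lambda_final, 1e-6)
  ## re-running from the solution does not move it
  g2 <- gcv_focuss_plus(y, sys, g$impulses, cfg)
  expect_lt(max(abs(g2$impulses$amplitudes - g$impulses$amplitudes)), 1e-6)
})

test_that("GCV residual power tracks the injected noise power at 25 dB", {
  spec <- sim_spec(duration = 180, scr_params = scr_params(0.7, 3.0),
                   n_impulses = 10, snr_db = 25, seed = 3)
  sim <- simulate_recording(spec)
  y <- sim$truth$noisy_phasic
  sys <- make_system(scr_params(0.7, 3.0), M = length(y))
  uf <- focuss_plus(y, sys, deconv_config())
  g <- gcv_focuss_plus(y, sys, uf, deconv_config())
  resid <- y - as.numeric(sys$B_tau %*% g$impulses$amplitudes)
  ratio <- sum(resid^2) / sum(sim$truth$noise^2)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("tau estimation recovers the truth and is stationary at the optimum", {
  spec <- sim_spec(duration = 360, scr_params = scr_params(0.681, 2.591),
                   n_impulses = 20, snr_db = Inf, seed = 5)
  sim <- simulate_recording(spec)
  y <- sim$truth$phasic
  tau <- estimate_tau(y, sim$truth$impulses, scr_params(1.0, 4.0),
                      y0 = 0, T_y = 0.5)
  expect_lt(abs(tau$tau_r - 0.681) / 0.681, 0.01)
  expect_lt(abs(tau$tau_d - 2.591) / 2.591, 0.01)
  ## starting at the truth on noiseless data: gradient vanishes
  tau2 <- estimate_tau(y, sim$truth$impulses, scr_params(0.681, 2.591),
                       y0 = 0, T_y = 0.5)
  expect_lt(sqrt(sum(attr(tau2, "gradient")^2)), 1e-6)
  ## bounds-violating initialization is rejected before optimization
  cfg_narrow <- deconv_config(tau_bounds = list(tau_r = c(0.5, 1.0),
                                                tau_d = c(2, 4)))
  expect_error(estimate_tau(y, sim$truth$impulses, scr_params(0.2, 3),
                            cfg_narrow, y0 = 0, T_y = 0.5),
               "box constraints")
})

test_that("full deconvolution honors the amplitude floor and objective descent", {
  spec <- sim_spec(duration = 240, scr_params = scr_params(0.7, 3.0),
                   n_impulses = 12, seed = 8)
  sim <- simulate_recording(spec)
  d <- suppressWarnings(
    deconvolve(sim$truth$noisy_phasic, 0.5,
               config = deconv_config(n_restarts = 3), seed = 42))
  amp <- d$impulses$amplitudes
  expect_false(any(amp > 0 & amp < d$config$amplitude_floor))
  expect_true(all(diff(d$cd_trace) <= 1e-9))
  expect_equal(length(d$reconstruction), length(sim$truth$noisy_phasic))
  expect_lte(d$r_squared, 1)
  ## restart selection: reported squared error is the minimum across restarts
  expect_equal(min(d$restarts$se), d$restarts$se[which.min(d$restarts$se)])
})

test_that("deconvolving a zero signal yields an empty train with missing R2", {
  d <- deconvolve(numeric(200), 0.5)
  expect_equal(sum(d$impulses$amplitudes), 0)
  expect_true(is.na(d$r_squared))
  expect_equal(d$n_impulses, 0L)
})

test_that("deconvolution is scale-equivariant", {
  spec <- sim_spec(duration = 240, scr_params = scr_params(0.7, 3.0),
                   n_impulses = 10, seed = 13, snr_db = 40)
  sim <- simulate_recording(spec)
  y <- sim$truth$noisy_phasic
  cfg <- deconv_config(n_restarts = 3)
  d1 <- suppressWarnings(deconvolve(y, 0.5, cfg, seed = 7))
  cscale <- 5
  cfg2 <- deconv_config(n_restarts = 3,
                        amplitude_floor = cfg$amplitude_floor * cscale)
  d2 <- suppressWarnings(deconvolve(cscale * y, 0.5, cfg2, seed = 7))
  expect_lt(abs(coef(d2)[["tau_r"]] - coef(d1)[["tau_r"]]) /
              coef(d1)[["tau_r"]], 0.05)
  expect_lt(abs(coef(d2)[["tau_d"]] - coef(d1)[["tau_d"]]) /
              coef(d1)[["tau_d"]], 0.05)
  a1 <- impulse_times(d1$impulses)
  a2 <- impulse_times(d2$impulses)
  shared <- intersect(a1$time, a2$time)
  expect_gt(length(shared), 0.7 * nrow(a1))
  ratio <- a2$amplitude[match(shared, a2$time)] /
    a1$amplitude[match(shared, a1$time)]
  expect_lt(max(abs(ratio - cscale) / cscale), 0.1)
})

test_that("random parameter draws are recovered within 10% at 25 dB (median)", {
  set.seed(77)
  errs <- vapply(1:20, function(i) {
    tau <- scr_params(runif(1, 0.2, 1.3), runif(1, 1.7, 5.5))
    spec <- sim_spec(duration = 300, scr_params = tau,
                     n_impulses = sample(10:25, 1), seed = 500 + i)
    sim <- simulate_recording(spec)
    d <- suppressWarnings(
      deconvolve(sim$truth$noisy_phasic, 0.5,
                 config = deconv_config(n_restarts = 5), seed = 900 + i))
    max(abs(coef(d) - c(tau$tau_r, tau$tau_d)) /
          c(tau$tau_r, tau$tau_d)) * 100
  }, numeric(1))
  expect_lt(median(errs), 10)
})

test_that("recovered impulse counts stay close to the truth across presets", {
  ex <- tau_recovery_experiment()
  med_count_err <- tapply(ex$count_err, ex$config, median)
  expect_true(all(med_count_err <= 3))
})
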