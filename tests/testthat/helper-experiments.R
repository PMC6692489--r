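## Shared parameter-recovery experiment over the six reference SCR
## configurations: 6-minute recordings at 25 dB SNR, full-protocol
## deconvolution, 5 simulation seeds per configuration. Memoised so the
## acceptance checks and the impulse-count check share one computation.
tau_recovery_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pr <- subject_presets()
    rows <- list()
    for (i in seq_len(nrow(pr))) {
      for (rep in 1:5) {
        spec <- sim_spec(duration = 360,
                         scr_params = scr_params(pr$tau_r[i], pr$tau_d[i]),
                         n_impulses = pr$n_impulses[i],
                         seed = 100L * i + rep)
        sim <- simulate_recording(spec)
        d <- suppressWarnings(
          deconvolve(sim$truth$noisy_phasic, 0.5, seed = 17L + rep))
        err <- 100 * abs(coef(d) - c(pr$tau_r[i], pr$tau_d[i])) /
          c(pr$tau_r[i], pr$tau_d[i])
        rows[[length(rows) + 1L]] <- data.frame(
          config = i, rep = rep,
          err_r = err[["tau_r"]], err_d = err[["tau_d"]],
          max_err = max(err), r_squared = d$r_squared,
          count_err = abs(d$n_impulses - pr$n_impulses[i]),
          cd_monotone = all(diff(d$cd_trace) <= 1e-9))
      }
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})
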