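# edarousal

Decoding sympathetic arousal from skin conductance recordings.

Electrodermal activity (EDA) is driven by sympathetic nerve fibers
innervating the sweat glands, which makes the skin conductance signal a
peripheral window onto psychological arousal — relevant wherever a
continuous, wearable-friendly arousal readout is wanted (stress monitoring,
affective computing, and biomarker feedback for neuropsychiatric
applications). `edarousal` implements the full chain from raw conductance to
an arousal index, for researchers working with single-channel recordings
from wrist-worn devices or lab amplifiers.

## The method

**Stage 1 — sparse deconvolution.** The phasic component of skin conductance
is a sum of skin conductance responses (SCRs), each the bi-exponential
response $h(t) = (e^{-t/\tau_r} - e^{-t/\tau_d})/(\tau_r - \tau_d)$ of the
sweat diffusion/evaporation cascade to one burst of sudomotor nerve
activity. With the phasic signal sampled every $T_y$ seconds and the neural
drive $u \ge 0$ on a finer $T_u$ grid, the exact discrete model is
$\mathbf{y} = A_\tau y_0 + B_\tau \mathbf{u} + \nu$. The package estimates
the subject-specific time constants and the sparse drive jointly:

$$\min_{\tau,\,u \ge 0} \tfrac12\lVert y - A_\tau y_0 - B_\tau u\rVert^2
  + \lambda \lVert u \rVert_p^p, \qquad
  0.1 \le \tau_r \le 1.4,\; 1.5 \le \tau_d \le 6,$$

by coordinate descent: iteratively reweighted least squares for the
impulses (FOCUSS+ initialization, then GCV-driven reselection of $\lambda$
at every step) alternated with box-constrained nonlinear least squares for
$\tau$, with multiple random restarts on a 3-minute segment and a final
sparse recovery over the whole signal. A cvxEDA-style convex program
separates tonic and phasic components beforehand.

**Stage 2 — arousal state estimation.** Impulse occurrences are binned into
indicators $s_j$, modelled as Bernoulli emissions of a latent random-walk
arousal state: $z_j = z_{j-1} + \varepsilon_j$,
$\Pr(s_j = 1) = 1/(1 + e^{-(\alpha + z_j)})$. An approximate Gaussian
forward filter (Newton-solved posterior mode) and fixed-interval smoother
form the E-step of an EM algorithm that estimates the process-noise
variance $\sigma_\varepsilon^2$ and initial state $z_0$ per subject. The
**High Arousal Index** summarizes the posterior:
$\mathrm{HAI}_j = \Pr(z_j > z_T)$ with $z_T$ the subject's median smoothed
state.

## Worked example

Simulate a 6-minute recording with 20 impulses at 25 dB SNR, decompose it,
and recover the impulses and time constants (truth:
$\tau_r = 0.681$, $\tau_d = 2.591$):

```r
library(edarousal)
spec <- sim_spec(duration = 360, scr_params = scr_params(0.681, 2.591),
                 n_impulses = 20, snr_db = 25, seed = 42)
sim  <- simulate_recording(spec)
dec  <- decompose_eda(sim$recording)
fit  <- deconvolve(dec$phasic, obs_interval = 0.5, seed = 7)
fit
#> Sparse SCR deconvolution
#>   tau_r = 0.637 s, tau_d = 3.093 s
#>   impulses detected: 20 (floor 0.01)
#>   R^2 = 0.9975, objective = 0.00318, lambda = 2.65e-05
```

All 20 impulses are found and the reconstruction explains 99.8% of the
phasic variance; the time constants land within the recovery tolerances
despite passing through the tonic/phasic split. Then track arousal from
binary impulse events (here simulated directly from the state-space model,
truth $\sigma_\varepsilon^2 = 0.005$):

```r
ap  <- simulate_arousal_process(
  sim_spec(arousal_spec = list(sigma_eps2 = 0.005, z0 = 0, p0 = 0.05,
                               J = 2400), seed = 3))
em  <- em_fit(ap$s, p0 = 0.05)
em
#> Arousal state-space model (EM fit)
#>   bins: 2400 (0.25 s), events: 133, p0 = 0.0500, alpha = -2.9444
#>   sigma_eps2 = 0.00343394, z0 = -0.008009
#>   EM iterations: 2568 (converged, final |delta| = 9.97e-09)
h <- hai(em)
#> z_T = -0.0863; HAI > 0.9 in 31.4% of bins
```

The estimated process noise (0.0034) sits within a factor of two of the
truth, and the HAI flags the stretches where the latent state runs above
the subject's median. `plot(em)` draws the smoothed state with confidence
bands, the impulse probability, and the HAI trace;
`run_pipeline()` chains every stage (decompose → deconvolve → bin → EM →
HAI) from a recording or a simulation config and writes CSV/JSON outputs.
A command-line wrapper lives in `inst/cli/edarousal.R`.

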