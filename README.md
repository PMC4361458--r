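# prcclamp

Phase response curve (PRC) estimation for tonically firing neurons, with an
in-silico closed-loop laboratory for validating every estimator against a
known ground truth.

## The problem

Cerebellar Purkinje cells fire simple action potentials (APs) tonically over
a wide range of rates, and how they respond to a brief input depends on
*when* in the firing cycle it arrives. The phase response curve
Z(φ) quantifies this: the normalised shift of the next AP caused by a short
depolarising current pulse delivered at phase φ = τ/⟨ISI⟩ of the cycle
(positive = advance). A flat positive PRC marks a phase-independent
integrator; a phase-selective or biphasic PRC marks a coincidence detector —
and Purkinje cells move smoothly between these regimes as their firing rate
increases.

Measuring that transition in one cell needs thousands of stimulation trials
at each of several *stationary* firing rates, which real neurons do not
volunteer: they adapt and drift. The protocol implemented here solves this
with a **frequency clamp** — a per-spike PID controller on the holding
current driven by an online rate estimator — plus **reactive, Sobol-scheduled
stimulation** (one pulse every 6 APs at quasi-random phases) and the
**corrected direct estimator**, which joins first- and second-order phase
samples

    Z(φ)   = (⟨ISI⟩ − ISI_perturbed)   / (⟨ISI⟩ · Q)        φ ∈ [0, 1]
    Z₂(φ₂) = (⟨ISI⟩ − ISI_perturbed−1) / (⟨ISI⟩ · Q)        φ₂ ∈ [0, 1]

(Q = pulse charge) so that the sampling bound Z ≤ (1−φ)/Q of the traditional
direct method no longer censors the end of the cycle. Raw samples are
smoothed by Gaussian-kernel regression with a data-driven bandwidth and
bootstrap 68% bands; the curve shape is summarised by the peak-to-baseline
ratio r = |m_l − m_e| / (|m_l| + |m_e|) and by the sigmoid fit
r(F) = (1 + e^{−(F−a)/b})⁻¹ of its rate dependence. A weighted
spike-triggered average (WSTA) driven by Ornstein–Uhlenbeck current noise
provides an independent, indirect estimate of the same curve.

The package is for computational and experimental neurophysiologists who
want tested, reusable implementations of these estimators — and a way to
check them: simulated neurons (a phase oscillator with prescribed PRC and a
conductance-based surrogate with channel-noise diffusion approximation) run
through the *same* closed-loop protocol, so recovering the prescribed curve
validates the whole chain end to end.

## A worked example

Clamp a simulated neuron with known PRC z(φ) = 1 − cos 2πφ (in 1/pC) at
50 Hz, deliver 1400 pulses of 0.05 pC, and estimate the curve:

```r
library(prcclamp)

neuron  <- phase_neuron(z_true = prc_preset("peaked"), cv_isi = 0.07)
session <- run_closed_loop_session(neuron, pid_config(f_target = 50),
                                   sobol_scheduler(), n_pulses = 1400,
                                   seed = 1)
session
#> <clamp_session> 8574 spikes, 1400 pulses, target 50.0 Hz (PID)
#>   achieved 49.99 Hz over the last 80% of the session

curve <- session_prc(session)
curve
#> <smoothed_prc> 201 grid points, bandwidth 0.08992, 1370 samples
#>   firing rate 49.63 Hz

peak_to_baseline(curve)
#> # A tibble: 1 × 6
#>     m_e   m_l phi_e phi_l      r flat
#>   <dbl> <dbl> <dbl> <dbl>  <dbl> <lgl>
#> 1  1.81  1.77 0.445   0.5 0.0112 FALSE

peak_time(curve)
#> # A tibble: 1 × 3
#>   phi_peak tau_peak_s z_peak
#>      <dbl>      <dbl>  <dbl>
#> 1    0.445    -0.0112   1.81
```

Reading the numbers: the clamp held the cell within 0.02% of the 50 Hz
target; 1370 of the 1400 trials survived phase attribution. The smoothed
curve peaks at 1.81 pC⁻¹ near mid-cycle (the kernel attenuates the true peak
of 2 by design — the RMSE against the prescribed curve is 0.20 pC⁻¹, about
10% of the peak, the method's accuracy at this charge and trial count). The
two half-cycle extrema are nearly equal, so the peak-to-baseline ratio is
~0.01: a symmetric, type-I-like curve, as prescribed. `tau_peak_s` places
the peak 11 ms before the next AP at this rate.

A rate sweep over a ground-truth family that morphs from flat to biphasic
recovers a monotone r(F) and its sigmoid parameters:

```r
family <- prc_rate_family()           # flat at 20 Hz -> biphasic at 100 Hz
sweep  <- run_rate_sweep(c(20, 40, 60, 80, 100),
                         function(f) phase_neuron(z_true = family(f)),
                         n_pulses = 400, seed = 1)
glance(sweep)      # fitted a, b of r(F)
autoplot(sweep)
```

The WSTA cross-check on the same neuron:

```r
ou  <- generate_ou_current(s = 25, tau_i = 4e-3, duration = 30,
                           dt = 1/30000, seed = 2)
sim <- simulate_phase_neuron(neuron, 30, i_hold = 250, stimulus = ou,
                             seed = 3)
wsta <- wsta_prc(ou, sim$train)
cor(wsta$z, prc_preset("peaked")(wsta$phi))   # ~0.95
```

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/prcclamp.R simulate --target-rate 50 --n-pulses 1400 \
    --seed 7 --out session_dir
Rscript inst/cli/prcclamp.R sweep --rates 20,50,100 --out sweep_dir
```

## Package tour

| Area | Functions |
|---|---|
| Spike trains | `spike_train()`, `detect_spikes()`, `isi_stats()`, `update_rate_estimate()` |
| Direct method | `perturbations()`, `assign_phase()`, `corrected_direct_prc()` |
| Smoothing | `kernel_bandwidth()`, `prc_smooth()`, `prc_bootstrap_ci()` |
| Indirect method | `generate_ou_current()`, `wsta_prc()` |
| Shape metrics | `peak_to_baseline()`, `fit_sigmoid()`, `peak_time()` |
| Closed loop | `pid_config()`, `sobol_scheduler()`, `run_closed_loop_session()`, `session_prc()`, `check_hold_contract()` |
| Simulators | `phase_neuron()`, `prc_preset()`, `conductance_neuron()`, `replay_prc()` |
| Channel noise | `kinetic_scheme()`, `diffusion_coefficients()`, `exact_markov_simulation()`, `simulate_diffusion_noise()` |
| Pipelines & I/O | `run_rate_sweep()`, `write_session()`, `read_session()`, `write_prc_csv()` |

Result objects are tibbles with `tidy()`/`glance()` methods and
`autoplot()` figures. The methods vignette
(`vignettes/prc-estimation-methods.Rmd`) documents the models, the numerical
choices, and the known accuracy limits of each estimator.
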