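---
title: "Estimating phase response curves under a closed-loop frequency clamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phase response curves under a closed-loop frequency clamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcclamp)
```

## The problem

A tonically firing neuron — the cerebellar Purkinje cell is the motivating
example — can be characterised by its **phase response curve** (PRC): the
function $Z(\varphi)$ giving the normalised shift of the next
action-potential (AP) time caused by a brief depolarising current pulse
delivered at phase $\varphi$ of the firing cycle. The phase is elapsed time
since the last AP divided by the mean inter-spike interval,
$\varphi = \tau / \langle ISI\rangle$; positive $Z$ means the next AP is
advanced. The PRC separates phase-independent *integrators* (flat, positive
curve) from *coincidence detectors* (phase-selective, possibly biphasic
curve), and in Purkinje cells its shape depends on the firing rate. Because
estimating a PRC takes thousands of trials at a *stationary* rate, while real
cells adapt and drift, the experimental protocol of interest couples three
ingredients:

1. a **frequency clamp**: a per-spike PID controller that adjusts the holding
   current so the cell fires at a chosen target rate;
2. **reactive, quasi-random stimulation**: one brief pulse every 6 APs, at a
   delay drawn from a Sobol low-discrepancy sequence, so phases are covered
   uniformly;
3. the **corrected direct estimator**, which joins first- and second-order
   phase samples to remove the sampling bound that censors the traditional
   direct method near the end of the cycle.

`prcclamp` implements the estimators and the closed-loop protocol, and pairs
them with simulated neurons whose PRC is known exactly, so every estimator
can be validated by recovering a ground truth — no experimental data are
required.

## Estimators

### Corrected direct method

After detecting AP peaks $t_k$, the mean $\langle ISI\rangle$ is computed
from *unperturbed* intervals only: every ISI containing a pulse, and the ISI
immediately following it, is excluded (including perturbed intervals would
bias the measured shifts toward zero; `unperturbed_isi_indices()` implements
the rule). Each pulse yields the first-order sample

$$Z(\varphi) = \frac{\langle ISI\rangle - ISI_{perturbed}}
  {\langle ISI\rangle \cdot Q},\qquad Q = I_{pulse} T_{pulse},$$

normalised by the injected charge so that estimates are comparable across
pulse amplitudes. Because the next AP cannot precede the pulse, these samples
obey $Z \le (1-\varphi)/Q$: near $\varphi = 1$ the distribution is censored
from above. The correction refers the same pulse to the *second* AP before
it, $\varphi_2 = (\tau + ISI_{perturbed-1})/\langle ISI\rangle$, with

$$Z_2(\varphi_2) = \frac{\langle ISI\rangle - ISI_{perturbed-1}}
  {\langle ISI\rangle \cdot Q},
  \qquad \frac{1-\varphi_2}{Q} \le Z_2 \le \frac{2-\varphi_2}{Q}.$$

On trials whose preceding AP came early, $\varphi_2$ dips below 1 and the
sample lands *above* the first-order bound — exactly the censored tail. The
joined set $Z(\varphi) \cup Z_2(\varphi_2)$, with both phases restricted to
$[0,1]$, restores an unbiased estimate over the whole cycle
(`corrected_direct_prc()`). Samples whose phase exceeds the theoretical
limit by more than `eps = 0.1` (a tolerance for spike jitter) are discarded
and counted in a per-reason skip log.

### Smoothing and uncertainty

Raw samples are smoothed by Nadaraya–Watson Gaussian-kernel regression on a
201-point phase grid (`prc_smooth()`); at the domain edges the kernel mass is
renormalised rather than reflected. The bandwidth is inferred from the data
by the robust rule of thumb

$$h = \left(\frac{4}{3N}\right)^{1/5}
  \frac{\mathrm{median}\,|\varphi - \varphi_{median}|}{0.6745}.$$

A variant that combines this phase factor with the analogous factor computed
on the $z$ values (geometric mean) is available as
`kernel_bandwidth(..., combine = "geometric")`, but it is not the default:
the kernel acts along the phase axis, so its width must carry phase units;
folding in the $z$ scale inflates the bandwidth whenever the per-sample noise
is large (with 0.05 pC pulses the per-sample noise SD is
$CV/Q \approx 1.4\ \mathrm{pC^{-1}}$) and measurably oversmooths — on the
ground-truth recovery benchmark below it doubles the error. Confidence bands
are pointwise 16th/84th bootstrap percentiles over trial resampling
(`prc_bootstrap_ci()`, 1000 resamples by default); we make no claim that
this matches any particular analytic band, only that it is reproducible
given a seed.

### Indirect method (WSTA)

The weighted spike-triggered average drives the cell with exponentially
filtered white noise (an Ornstein–Uhlenbeck current, `generate_ou_current()`,
exact discretisation so the stationary SD equals `s` at any step), rescales
each ISI's stimulus segment to a common phase axis, weights it by
$\alpha_k = \langle ISI\rangle/ISI_k - 1$, and normalises by the area of the
stimulus autocorrelation, $2 s^2 \tau_I$ (`wsta_prc()`). Segments are
mean-subtracted before weighting so the DC offset used to set the firing
rate does not leak into the estimate; whether to use raw or mean-subtracted
segments is not settled usage, and we document our choice rather than claim
it is canonical.

### Shape summaries

`peak_to_baseline()` contrasts the extrema of largest absolute value in the
two halves of the curve, $r = |m_l - m_e| / (|m_l| + |m_e|)$: 0 for a flat
curve, 1 whenever the extrema have opposite signs; $r$ is invariant to
positive rescaling and hence to the charge normalisation. The point
$\varphi = 0.5$ belongs to both halves; ties resolve to the late half. The
rate dependence $r(F)$ is summarised by the two-parameter logistic
$r(F) = (1+e^{-(F-a)/b})^{-1}$, fitted by unweighted least squares from a
fixed grid of starts (`fit_sigmoid()`; deterministic by construction — the
paper trail for the "best fit" is a multi-start Levenberg–Marquardt).
`peak_time()` converts the peak phase to a time before the next AP,
$\tau_{peak} = (\varphi_{peak} - 1)\langle ISI\rangle$, the transform used to
ask whether a rate-dependent peak reflects a fixed time-to-spike preference.

## The closed loop

After every AP the instantaneous rate estimate is updated as

$$\tilde F_k = ISI_k^{-1}\left(1 - e^{-ISI_k/\tau}\right)
  + \tilde F_{k-1} e^{-ISI_k/\tau}, \qquad \tau = 1\ \mathrm{s},$$

a convex combination of the latest inverse ISI and the previous estimate,
initialised at the target rate to avoid start-up transients. The error
$e_k = F_{target} - \tilde F_k$ feeds a per-spike PID controller

$$I^{holding}_k = g_P e_k + g_I \textstyle\sum_{i \le k} e_i
  + g_D (e_k - e_{k-1}),$$

with the gains used for Purkinje cells ($g_P = 0.001$, $g_I = 0.1$,
$g_D = 0$ pA/Hz) and the output clamped to the experimental holding-current
range ($-200$ to $1000$ pA); the integrator freezes while the output is
saturated (anti-windup) and, by default, during hold windows (exposed as
`integrate_during_hold` since usage varies).

Perturbations are scheduled reactively: every 6th AP triggers a pulse after
a delay equal to the next element of a one-dimensional Gray-code Sobol
sequence (first elements 0.5, 0.75, 0.25, ...; the first 16 points are
discarded — the count is a convention, any small burn-in serves) times the
current mean-ISI estimate $1/\tilde F_k$. The realised phase is always
recomputed afterwards from the actual spike times, so scheduler error only
affects sampling density, never correctness. From the trigger AP to the
second spike after the pulse the controller output is **held constant**, so
no controller transient is locked to the stimulus; the controller reconnects
at the following AP, making the holding current exactly constant at every
spike of the window (`check_hold_contract()` verifies this on the session
log).

Sessions begin with a 5 s warm-up during which the clamp runs but no pulse
is delivered, mirroring the experimental practice of waiting for a steady
rate before stimulating. With the gains above the loop settles with a
roughly 2 s envelope, so a large rate step (say 25 to 100 Hz) still carries
a percent-level residual right at 5 s; post-transient rate checks should
average over a few tens of seconds. `session_prc()` additionally drops
spikes and pulses from the first 5 s before estimating: a 1% bias in
$\langle ISI\rangle$ moves every $z$ sample by
$0.01/Q = 0.2\ \mathrm{pC^{-1}}$ at $Q = 0.05$ pC, so the start-up ramp must
never enter the mean.

## Synthetic neurons (what the generator emulates — and what it does not)

### Phase-oscillator neuron

The core validation model has the PRC built in:

$$\dot\varphi = f(I_{hold}) + z_{true}(\varphi)\, I_{pulse}(t)
  + \sigma \sqrt{f}\, \xi(t),$$

with a spike emitted and $\varphi$ reset at 1. The intrinsic rate is linear
in the holding current, $f(I) = \max(25 + 0.1 I, 0)$ Hz (monotone, spanning
20–150 Hz within the holding-current range — the property the clamp needs),
and the phase-diffusion term is scaled as $\sigma = CV\sqrt{f}$ so the
first-passage ISI distribution has the requested coefficient of variation
(default 0.07, the middle of the 5–10% range typical of tonically firing
Purkinje cells). Shipped ground-truth shapes (`prc_preset()`): `flat`
(phase-independent integrator, the low-rate phenotype), `peaked`
$z_0(1 - \cos 2\pi\varphi)$ (the standard recovery oracle), `late_peaked`,
and `biphasic` $-z_0 \sin 2\pi\varphi$ (type-II-like, $r = 1$);
`prc_rate_family()` blends flat into biphasic across 20–100 Hz to emulate
the smooth integrator-to-resonator transition, and the blend's
peak-to-baseline ratio is provably monotone in the blend weight. The
amplitude default $z_0 = 1\ \mathrm{pC^{-1}}$ makes a 0.05 pC pulse shift
the next spike by up to 10% of a cycle — a strong but physiological effect
size.

What this model does *not* emulate: rate adaptation and slow drifts (the
very phenomena the clamp exists to suppress — the clamp is therefore
validated for stability, not for drift rejection), conductance dynamics
during the AP, and any stimulus nonlinearity beyond the self-advancing
phase. Passing recovery tests on this model shows the estimator chain is
correct, not that real recordings are free of additional biases.

### Finite-charge accuracy

With the self-advancing convention the phase traverses
$w f + z(\varphi) Q \approx 0.125$ during a 0.5 ms, 0.05 pC pulse at the
peak of the default curve, so each direct-method sample reflects $z$
averaged slightly *ahead* of the onset phase — measured curves sit a few
hundredths of a phase unit to the left of $z_{true}$. This is a property of
finite-charge direct estimation itself (the phase attribution cannot be
"corrected" without violating the sampling bound $Z \le (1-\varphi)/Q$), and
it shrinks with $Q$: `replay_prc()` at 0.001 pC recovers $z_{true}$ to a few
percent, and the package's tests verify that the deviation grows
monotonically with charge. At the standard protocol
($Q = 0.05$ pC, $CV = 7\%$, 1400 trials) the end-to-end error budget of the
smoothed estimate is roughly 6% of peak from kernel attenuation at the
rule-of-thumb bandwidth, 5–8% from the finite-charge traversal, and ~4%
sampling noise — about 10% of peak in total, the package's honest accuracy
statement at desk scale.

Similarly, the WSTA is a linear-response estimator: at stimulus SDs toward
the upper end of the experimental range (50–75 pA) the per-ISI phase shifts
of the default phase neuron approach a full cycle and the segment-rescaling
step biases the recovered peak rightward. Validation therefore uses the
weak end of the range (25 pA, two to four 30 s realisations), and peak
locations are compared only after filtering both curves with the same
kernel.

### Conductance-based surrogate

A single-compartment spiking model with transient Na, delayed-rectifier K
and leak currents (Wang–Buzsáki kinetics; type-I excitability, so it fires
arbitrarily slowly and the clamp can target 20 Hz). Currents in pA convert
to densities over a 10⁻⁴ cm² membrane; the RK2 step is 25 µs. It is a
*generic surrogate*, not a reconstruction of any published Purkinje-cell
model: detailed models are exercised through the same protocols but live
outside this package's scope.

Channel noise enters by the diffusion approximation: the conductance's open
fraction gains a sum of $N-1$ Ornstein–Uhlenbeck terms,

$$g(t) = \bar g\, p_o(t) + \sum_{i=1}^{N-1} \eta_i(t), \qquad
  \tau_i \dot\eta_i = -\eta_i + \sigma_i \sqrt{2\tau_i}\, \xi_i(t),$$

whose coefficients come from the eigen-decomposition of the kinetic scheme's
generator matrix: the single-channel open-fraction autocovariance decomposes
as $\sum_i c_i e^{\lambda_i t}$ over the non-zero eigenvalues, giving
$\tau_i = -1/\lambda_i$ and $\sigma_i^2 = c_i / n_{channels}$
(`diffusion_coefficients()`; requires a reversible scheme, for which all
eigenvalues are real and weights non-negative). The rates are evaluated at a
frozen voltage near the limit-cycle mean (−60 mV) — a quasi-static
simplification relative to voltage-tracking treatments, documented as such.
The population size `n_channels` is the variability knob (variance scales as
$1/n$); 300 channels give CV ≈ 3–7% over the working rates. The validation
oracle is `exact_markov_simulation()`, a per-step multinomial population
simulation of the discrete scheme (valid for
$dt \times \max\ \text{total rate} \le 0.1$; comparisons use 0.03 to keep
the first-order transition-probability bias well under the Monte-Carlo
noise). Shipped toy schemes: the two-state channel (closed-form
autocovariance oracle), a gate chain, the surrogate's own K scheme, and
`five_state_scheme()`, a birth–death chain whose slow opening gate carries
~98% of the open-fraction variance so that every relaxation time constant is
measurable from a 10 s trace. Note the slowest-lag comparison at 10³
channels × 10 s has ~5% Monte-Carlo scatter, so a 10% agreement check is a
roughly 2-sigma statement per seed.

The alternative noise source is the delta-correlated noisy current
$I(t) = I_m + I_s\xi(t)$ (`current_noise_pA`; a fresh draw per integration
step). With the two sources calibrated to comparable ISI CV, closed-loop
PRCs of the stochastic-conductance and noisy-current variants are very
similar — the package asserts curve correlation rather than visual
similarity.

### Replay protocol

For models with exact state save/restore (both simulators: states are plain
R lists), `replay_prc()` implements the snapshot protocol used for detailed
compartmental models: locate an unperturbed ISI $[t_0, t_1]$ of the
requested duration, save the state at $t_0 - 5$ ms, and replay $N = 50$
trials with one pulse at $t_p^i = t_0 + i (t_1 - t_0)/N$, simulating to
$t_1 + 10$ ms and recording the perturbed closing AP. On a deterministic
neuron the protocol is bit-for-bit repeatable.

## Statistical notes and known limitations

- **Comparing two estimates via confidence bands.** For two independent,
  equally precise estimates of the same curve, their 68% bands intersect at
  any grid point with probability $\approx 0.84$ *regardless of sample
  size*, and kernel smoothing makes non-overlap come in contiguous
  stretches. `prc_ci_overlap()` reports the band-intersection fraction;
  expect occasional dips even for estimates that agree perfectly, and
  corroborate with the curve correlation.
- **Bootstrap bands** capture trial-resampling noise at fixed
  $\langle ISI\rangle$ and bandwidth; the (small) uncertainty of
  $\langle ISI\rangle$ itself is not propagated.
- **Problem sizes.** The package's own validation runs use 1400-pulse
  sessions for end-to-end recovery (the canonical protocol size), 350-pulse
  sessions for per-sample properties, 10 s / 10³-channel population
  simulations for the diffusion approximation, and 30 s OU stimuli — sizes
  chosen so the full suite completes in well under a minute on one core
  while every check retains its statistical meaning.
- **Units** are seconds, Hz, pA and pC internally; conversion happens only
  at I/O boundaries. Session archives are a directory of CSV tables plus a
  JSON sidecar carrying the config snapshot, seed and package version.

## A worked run

```{r example, eval = FALSE}
library(prcclamp)

neuron <- phase_neuron(z_true = prc_preset("peaked"), cv_isi = 0.07)
session <- run_closed_loop_session(neuron, pid_config(f_target = 50),
                                   sobol_scheduler(), n_pulses = 1400,
                                   seed = 1)
curve <- session_prc(session, ci = "bootstrap", seed = 1)
peak_to_baseline(curve)
peak_time(curve)
autoplot(curve)

family <- prc_rate_family()
sweep <- run_rate_sweep(c(20, 40, 60, 80, 100),
                        function(f) phase_neuron(z_true = family(f)),
                        n_pulses = 400, seed = 1)
glance(sweep)
autoplot(sweep)
```
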