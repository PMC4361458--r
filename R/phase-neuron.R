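# Phase-oscillator neuron with a prescribed (ground-truth) PRC. The phase
# advances at the intrinsic rate set by the holding current; perturbation
# currents act through the PRC, so every estimator can be validated against
# the curve the neuron was built with.

#' Ground-truth PRC presets
#'
#' Named PRC shapes for the phase-oscillator neuron, emulating the shape
#' family observed in tonically firing Purkinje cells:
#' * `"flat"` — constant `z0` (phase-independent integrator, low-rate
#'   phenotype);
#' * `"peaked"` — `z0 * (1 - cos(2 pi phi))`, a smooth bump vanishing at both
#'   ends of the cycle (the standard recovery oracle);
#' * `"late_peaked"` — the same bump with its maximum shifted into the late
#'   half of the cycle;
#' * `"biphasic"` — `-z0 * sin(2 pi phi)`, negative early lobe and positive
#'   late lobe (type-II-like, peak-to-baseline ratio 1).
#'
#' @param name Preset name.
#' @param z0 Amplitude scale, 1/pC.
#' @return A function `phi -> z` (vectorised), 1/pC.
#' @export
prc_preset <- function(name = c("flat", "peaked", "late_peaked", "biphasic"),
                       z0 = 1) {
  name <- match.arg(name)
  switch(name,
    flat = function(phi) rep(z0, length(phi)),
    peaked = function(phi) z0 * (1 - cos(2 * pi * phi)),
    late_peaked = function(phi) z0 * (1 - cos(2 * pi * pmin(pmax(phi, 0), 1)^1.4)),
    biphasic = function(phi) -z0 * sin(2 * pi * phi)
  )
}

#' Rate-dependent ground-truth PRC family
#'
#' A factory emulating the smooth integrator-to-resonator transition: at
#' rates at or below `f_lo` the curve is flat, at or above `f_hi` it is fully
#' biphasic, and in between it is a linear blend. The peak-to-baseline ratio
#' of the blend increases monotonically with the blend weight, so a rate
#' sweep over this family must recover a monotone r(F).
#'
#' @param z0 Amplitude scale, 1/pC.
#' @param f_lo,f_hi Rates (Hz) delimiting the transition.
#' @return A function `rate_hz -> (phi -> z)`.
#' @export
prc_rate_family <- function(z0 = 1, f_lo = 20, f_hi = 100) {
  flat <- prc_preset("flat", z0)
  biph <- prc_preset("biphasic", z0)
  function(rate_hz) {
    w <- min(max((rate_hz - f_lo) / (f_hi - f_lo), 0), 1)
    function(phi) (1 - w) * flat(phi) + w * biph(phi)
  }
}

#' Phase-oscillator neuron with known PRC
#'
#' The simplest tonically firing model whose PRC is exact by construction:
#' \deqn{\dot\varphi = f(I_{hold}) + z_{true}(\varphi) I_{pulse}(t) +
#'   \sigma\sqrt{f}\,\xi(t),}
#' a spike is emitted and the phase reset when \eqn{\varphi} reaches 1. The
#' intrinsic rate is linear in the holding current,
#' `f(I) = max(f0 + f_slope * I, 0)` (monotone, so the frequency clamp can
#' control it), and the jitter scale is parameterised directly by the target
#' ISI coefficient of variation: with \eqn{\sigma = CV\sqrt{f}} the
#' first-passage ISI distribution has CV approximately equal to `cv_isi`.
#'
#' @param z_true Ground-truth PRC, a function `phi -> z` in 1/pC (see
#'   [prc_preset()]).
#' @param f0 Intrinsic rate at zero holding current, Hz.
#' @param f_slope Rate gain, Hz/pA.
#' @param cv_isi Target ISI coefficient of variation (0 = deterministic).
#' @param dt Integration step, seconds.
#' @return A `phase_neuron` object.
#' @export
phase_neuron <- function(z_true = prc_preset("peaked"), f0 = 25,
                         f_slope = 0.1, cv_isi = 0.07, dt = 1 / 30000) {
  stopifnot(is.function(z_true), cv_isi >= 0, dt > 0, f_slope > 0)
  grid <- seq(0, 1, length.out = 1025)
  zg <- z_true(grid)
  if (any(!is.finite(zg))) abort("z_true must be finite on [0, 1]")
  structure(
    list(f0 = f0, f_slope = f_slope, cv_isi = cv_isi, dt = dt,
         z_true = z_true, z_grid = zg),
    class = "phase_neuron"
  )
}

#' @export
print.phase_neuron <- function(x, ...) {
  cat(sprintf("<phase_neuron> f(I) = %.3g + %.3g I Hz, CV target %.3g, dt %.3g s\n",
              x$f0, x$f_slope, x$cv_isi, x$dt))
  invisible(x)
}

#' Initial simulator state
#'
#' States are plain lists, so a snapshot is a copy and restore is passing the
#' saved list back — the basis of the replay protocol.
#'
#' @param neuron A simulator object.
#' @param t0 Start time, seconds.
#' @param ... Passed to methods.
#' @return A state list.
#' @export
neuron_init <- function(neuron, t0 = 0, ...) UseMethod("neuron_init")

#' @export
neuron_init.phase_neuron <- function(neuron, t0 = 0, phi0 = 0, ...) {
  list(t = t0, phi = phi0)
}

#' Advance a simulator until its next spike
#'
#' Integrates until the next spike or `t_stop`, whichever comes first, under
#' a constant holding current plus at most one square perturbation pulse
#' (`pulse = list(t, amplitude_pA, duration_s)`), or a sampled stimulus trace
#' (`stimulus`, for the phase neuron). Returns `list(t_spike, state)`;
#' `t_spike` is `NA` if `t_stop` was reached first.
#'
#' @param neuron A simulator object.
#' @param state Its current state list.
#' @param t_stop Hard stop time, seconds.
#' @param i_hold Holding current, pA.
#' @param pulse Optional square pulse, `list(t, amplitude_pA, duration_s)`.
#' @param ... Passed to methods.
#' @return `list(t_spike = <sec or NA>, state = <new state>)`.
#' @export
advance_to_spike <- function(neuron, state, t_stop, i_hold = 0, pulse = NULL,
                             ...) {
  UseMethod("advance_to_spike")
}

#' @export
advance_to_spike.phase_neuron <- function(neuron, state, t_stop, i_hold = 0,
                                          pulse = NULL, stimulus = NULL, ...) {
  if (!is.null(stimulus)) {
    res <- phase_advance_trace_cpp(
      state$t, state$phi, t_stop, i_hold,
      stimulus$i_pA, stimulus$time_s[1], attr(stimulus, "dt", exact = TRUE),
      neuron$f0, neuron$f_slope, neuron$cv_isi, neuron$z_grid, neuron$dt)
  } else {
    pt <- if (is.null(pulse)) NA_real_ else pulse$t
    pa <- if (is.null(pulse)) 0 else pulse$amplitude_pA
    pd <- if (is.null(pulse)) 0 else pulse$duration_s
    res <- phase_advance_cpp(
      state$t, state$phi, t_stop, i_hold, pt, pa, pd,
      neuron$f0, neuron$f_slope, neuron$cv_isi, neuron$z_grid, neuron$dt)
  }
  list(t_spike = if (is.na(res$t_spike)) NA_real_ else res$t_spike,
       state = list(t = res$t, phi = res$phi))
}

#' Simulate a phase neuron over a fixed window
#'
#' Open-loop simulation under a constant holding current, optionally with a
#' table of square pulses ([perturbations()]) or a sampled stimulus trace
#' ([generate_ou_current()]) acting through the PRC. Returns the exact
#' (ground-truth) spike times and, on request, a rendered voltage trace for
#' the spike-detection path.
#'
#' @param neuron A [phase_neuron()].
#' @param duration Simulated time, seconds.
#' @param i_hold Constant holding current, pA.
#' @param pulses Optional [perturbations()] tibble (pulses must not overlap).
#' @param stimulus Optional stimulus trace driving the PRC.
#' @param seed Optional integer seed.
#' @param render_trace Also return a synthetic voltage trace sampled at
#'   `1/neuron$dt`.
#' @return A list with `train` (a [spike_train()]) and, if requested,
#'   `trace` (tibble `time_s`, `v_mV`).
#' @export
simulate_phase_neuron <- function(neuron, duration, i_hold = 0, pulses = NULL,
                                  stimulus = NULL, seed = NULL,
                                  render_trace = FALSE) {
  stopifnot(inherits(neuron, "phase_neuron"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  f <- neuron$f0 + neuron$f_slope * i_hold
  if (f <= 0 && is.null(stimulus)) {
    abort("intrinsic rate f(I) <= 0: no tonic firing at this holding current",
          class = "prcclamp_error_neuron")
  }
  state <- neuron_init(neuron)
  spikes <- numeric(0)
  pulse_times <- if (!is.null(pulses)) pulses$t_pulse_s else numeric(0)
  next_pulse <- 1L
  repeat {
    pulse <- NULL
    if (is.null(stimulus) && next_pulse <= length(pulse_times)) {
      # pass the next upcoming pulse; the scheduler guarantees at most one
      # pulse per ISI, so a single pending pulse suffices
      while (next_pulse <= length(pulse_times) &&
             pulse_times[next_pulse] + pulses$duration_s[next_pulse] < state$t) {
        next_pulse <- next_pulse + 1L
      }
      if (next_pulse <= length(pulse_times)) {
        pulse <- list(t = pulse_times[next_pulse],
                      amplitude_pA = pulses$amplitude_pA[next_pulse],
                      duration_s = pulses$duration_s[next_pulse])
      }
    }
    res <- advance_to_spike(neuron, state, t_stop = duration, i_hold = i_hold,
                            pulse = pulse, stimulus = stimulus)
    state <- res$state
    if (is.na(res$t_spike)) break
    spikes <- c(spikes, res$t_spike)
  }
  out <- list(train = spike_train(spikes, "phase_neuron"))
  if (render_trace) {
    out$trace <- render_voltage_trace(spikes, duration,
                                      sample_rate = 1 / neuron$dt)
  }
  out
}

#' Render a synthetic voltage trace from spike times
#'
#' Stereotyped action-potential waveforms (1 ms triangular spikes from a -60
#' mV baseline to +20 mV) placed at the given spike times, sampled uniformly.
#' Used to exercise the threshold-crossing spike-detection path against
#' ground-truth spike times.
#'
#' @param spikes Spike times, seconds.
#' @param duration Trace length, seconds.
#' @param sample_rate Samples per second.
#' @param baseline_mV,peak_mV Waveform extremes.
#' @param ap_width_s Total AP width, seconds.
#' @return A tibble with `time_s`, `v_mV`.
#' @export
render_voltage_trace <- function(spikes, duration, sample_rate = 30000,
                                 baseline_mV = -60, peak_mV = 20,
                                 ap_width_s = 1e-3) {
  n <- floor(duration * sample_rate) + 1L
  tt <- (seq_len(n) - 1) / sample_rate
  v <- rep(baseline_mV, n)
  half <- ap_width_s / 2
  for (ts in spikes) {
    i0 <- max(1L, ceiling((ts - half) * sample_rate) + 1L)
    i1 <- min(n, floor((ts + half) * sample_rate) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    shape <- 1 - abs(tt[idx] - ts) / half
    v[idx] <- pmax(v[idx], baseline_mV + (peak_mV - baseline_mV) * shape)
  }
  tibble(time_s = tt, v_mV = v)
}
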