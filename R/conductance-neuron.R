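# Conductance-based surrogate: a single-compartment spiking model with Na/K/
# leak currents (Wang-Buzsaki kinetics), tonic type-I firing whose rate
# increases monotonically with holding current, with optional channel-noise
# conductance fluctuations (diffusion approximation) or an additive noisy
# current.

#' Conductance-based surrogate neuron
#'
#' Single-compartment model with transient sodium, delayed-rectifier
#' potassium and leak currents (Wang-Buzsaki kinetics; type-I excitability,
#' so it fires tonically at arbitrarily low rates and the frequency clamp can
#' target the full 20-150 Hz range). External current in pA is converted to a
#' density over the membrane area. Spiking variability can be introduced
#' either endogenously, by adding a sum of Ornstein-Uhlenbeck fluctuations to
#' the potassium open fraction (`noise`, the channel-noise diffusion
#' approximation of [diffusion_coefficients()]), or exogenously via a
#' delta-correlated Gaussian noisy current `I(t) = i_m + i_s xi(t)`
#' (`current_noise_pA` = the SD `i_s`, drawn freshly at every integration
#' step).
#'
#' @param area_cm2 Membrane area, cm^2 (default 1e-4, i.e. 100 pA -> 1
#'   uA/cm^2).
#' @param i_bias Constant bias current density, uA/cm^2, setting spontaneous
#'   firing.
#' @param noise Optional `diffusion_noise` spec (columns `tau_s`, `sigma`)
#'   for K-conductance fluctuations.
#' @param current_noise_pA Optional SD of an additive Gaussian noisy
#'   current, pA (delta-correlated: an independent draw at each integration
#'   step).
#' @param dt Integration step, seconds (default 25e-6).
#' @param gna,gk,gl Maximal conductance densities, mS/cm^2.
#' @param ena,ek,el Reversal potentials, mV.
#' @param phi_temp Temperature factor on gating kinetics.
#' @return A `conductance_neuron` object.
#' @export
conductance_neuron <- function(area_cm2 = 1e-4, i_bias = 0.3, noise = NULL,
                               current_noise_pA = 0, dt = 25e-6,
                               gna = 35, gk = 9, gl = 0.1,
                               ena = 55, ek = -90, el = -65, phi_temp = 5) {
  stopifnot(area_cm2 > 0, dt > 0, dt <= 5e-5, current_noise_pA >= 0)
  if (!is.null(noise)) {
    stopifnot(is.data.frame(noise), all(c("tau_s", "sigma") %in% names(noise)))
  }
  structure(
    list(params = list(cm = 1, gna = gna, gk = gk, gl = gl, ena = ena,
                       ek = ek, el = el, phi_temp = phi_temp,
                       area_cm2 = area_cm2, i_bias = i_bias),
         noise = noise, current_noise_pA = current_noise_pA, dt = dt),
    class = "conductance_neuron"
  )
}

#' @export
print.conductance_neuron <- function(x, ...) {
  cat(sprintf("<conductance_neuron> area %.3g cm^2, bias %.3g uA/cm^2, dt %.3g s\n",
              x$params$area_cm2, x$params$i_bias, x$dt))
  if (!is.null(x$noise)) {
    cat(sprintf("  channel noise: %d OU terms on the K conductance\n",
                nrow(x$noise)))
  }
  if (x$current_noise_pA > 0) {
    cat(sprintf("  noisy current: SD %.3g pA\n", x$current_noise_pA))
  }
  invisible(x)
}

#' @export
neuron_init.conductance_neuron <- function(neuron, t0 = 0, v0 = -64, ...) {
  m <- if (is.null(neuron$noise)) 0L else nrow(neuron$noise)
  list(t = t0, y = c(v0, 0.78, 0.09, rep(0, m)))
}

noise_taus <- function(neuron) {
  if (is.null(neuron$noise)) numeric(0) else neuron$noise$tau_s
}
noise_sigmas <- function(neuron) {
  if (is.null(neuron$noise)) numeric(0) else neuron$noise$sigma
}

#' @export
advance_to_spike.conductance_neuron <- function(neuron, state, t_stop,
                                                i_hold = 0, pulse = NULL,
                                                ...) {
  pt <- if (is.null(pulse)) NA_real_ else pulse$t
  pa <- if (is.null(pulse)) 0 else pulse$amplitude_pA
  pd <- if (is.null(pulse)) 0 else pulse$duration_s
  res <- cond_advance_cpp(state$y, state$t, t_stop, i_hold, pt, pa, pd,
                          neuron$params, noise_taus(neuron),
                          noise_sigmas(neuron), neuron$dt,
                          i_noise_pA = neuron$current_noise_pA)
  list(t_spike = if (is.na(res$t_spike)) NA_real_ else res$t_spike,
       state = list(t = res$t, y = res$state))
}

#' Simulate a conductance neuron over a fixed window
#'
#' Open-loop simulation under constant holding current, optionally with
#' square pulses, including any configured channel-noise or noisy-current
#' fluctuations.
#'
#' @param neuron A [conductance_neuron()].
#' @param duration Simulated time, seconds.
#' @param i_hold Constant holding current, pA.
#' @param pulses Optional [perturbations()] tibble.
#' @param seed Optional integer seed.
#' @param record Also return the membrane-potential trace.
#' @param warmup Seconds simulated (and discarded) before `t = 0` so the
#'   model starts on its limit cycle.
#' @return A list with `train` and, if `record`, `trace`.
#' @export
simulate_conductance_neuron <- function(neuron, duration, i_hold = 0,
                                        pulses = NULL, seed = NULL,
                                        record = FALSE, warmup = 0.5) {
  stopifnot(inherits(neuron, "conductance_neuron"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  nn <- neuron
  state <- neuron_init(nn, t0 = -warmup)
  while (state$t < 0) {
    res <- advance_to_spike(nn, state, t_stop = 0, i_hold = i_hold)
    state <- res$state
    if (is.na(res$t_spike) && state$t < 0) break
  }
  spikes <- numeric(0)
  traces_t <- list()
  traces_v <- list()
  pulse_times <- if (!is.null(pulses)) pulses$t_pulse_s else numeric(0)
  next_pulse <- 1L
  repeat {
    pulse <- NULL
    while (next_pulse <= length(pulse_times) &&
           pulse_times[next_pulse] + pulses$duration_s[next_pulse] < state$t) {
      next_pulse <- next_pulse + 1L
    }
    if (next_pulse <= length(pulse_times)) {
      pulse <- list(t = pulse_times[next_pulse],
                    amplitude_pA = pulses$amplitude_pA[next_pulse],
                    duration_s = pulses$duration_s[next_pulse])
    }
    pt <- if (is.null(pulse)) NA_real_ else pulse$t
    pa <- if (is.null(pulse)) 0 else pulse$amplitude_pA
    pd <- if (is.null(pulse)) 0 else pulse$duration_s
    res <- cond_advance_cpp(state$y, state$t, duration, i_hold, pt, pa, pd,
                            nn$params, noise_taus(nn), noise_sigmas(nn),
                            nn$dt, i_noise_pA = nn$current_noise_pA,
                            record = record)
    if (record) {
      traces_t[[length(traces_t) + 1L]] <- res$rec_t
      traces_v[[length(traces_v) + 1L]] <- res$rec_v
    }
    state <- list(t = res$t, y = res$state)
    if (is.na(res$t_spike)) break
    spikes <- c(spikes, res$t_spike)
  }
  if (length(spikes) == 0) {
    abort("no spikes: model not tonically firing at this holding current",
          class = "prcclamp_error_neuron")
  }
  out <- list(train = spike_train(spikes, "conductance_neuron"))
  if (record) {
    out$trace <- tibble(time_s = unlist(traces_t), v_mV = unlist(traces_v))
  }
  out
}

#' Steady-state firing rate of a simulator at a holding current
#'
#' Convenience wrapper: simulates for `duration` seconds after a transient
#' and returns the mean rate. Used to verify rate monotonicity and to
#' precompute constant-current controls for the frequency clamp.
#'
#' @param neuron A simulator object.
#' @param i_hold Holding current, pA.
#' @param duration Measurement window, seconds.
#' @param transient Discarded initial window, seconds.
#' @param seed Optional seed.
#' @return Mean firing rate, Hz.
#' @export
firing_rate_at <- function(neuron, i_hold, duration = 5, transient = 1,
                           seed = NULL) {
  sim <- if (inherits(neuron, "phase_neuron")) {
    simulate_phase_neuron(neuron, duration + transient, i_hold = i_hold,
                          seed = seed)
  } else {
    simulate_conductance_neuron(neuron, duration + transient,
                                i_hold = i_hold, seed = seed)
  }
  ts <- sim$train$time_s
  ts <- ts[ts >= transient]
  if (length(ts) < 2) return(0)
  (length(ts) - 1) / diff(range(ts))
}
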