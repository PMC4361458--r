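# Shared fixtures, built in code. The canonical deterministic neuron fires at
# exactly 50 Hz under a 250 pA holding current (f = 25 + 0.1 * I).

det_neuron <- function(z = prc_preset("peaked")) {
  phase_neuron(z_true = z, cv_isi = 0)
}

jitter_neuron <- function(z = prc_preset("peaked"), cv = 0.07) {
  phase_neuron(z_true = z, cv_isi = cv)
}

# a regular spike train plus mid-ISI pulses (nothing simulated)
regular_train_fixture <- function(n = 60, isi = 0.01) {
  ts <- seq(0, by = isi, length.out = n)
  list(train = spike_train(ts),
       pulses = perturbations(ts[seq(5, n - 5, by = 6)] + 0.4 * isi,
                              amplitude_pA = 100, duration_s = 5e-4))
}

# small closed-loop session on the jittered phase neuron, cached per run
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_closed_loop_session(
        jitter_neuron(), pid_config(50), sobol_scheduler(),
        n_pulses = 350, seed = 1)
    }
    cache
  }
})
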