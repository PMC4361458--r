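# State-save replay PRC protocol: locate an unperturbed ISI of the requested
# duration, snapshot the simulator state shortly before it, and replay it N
# times with a pulse stepped across the interval.

#' Replay-protocol PRC estimate
#'
#' For simulators whose state can be saved and restored exactly (both shipped
#' neurons: their states are plain lists):
#' 1. simulate until an unperturbed ISI \[t0, t1\] within `tol` (relative) of
#'    `target_isi_s` is found;
#' 2. save the full state at `t0 - 5 ms`;
#' 3. for trial i = 1..N restore that state, deliver one pulse at
#'    `t_p^i = t0 + i (t1 - t0) / N`, simulate to `t1 + 10 ms`, and record
#'    the perturbed time of the AP that closes the interval.
#' Each trial yields a first-order PRC sample at phase `(t_p^i - t0)/(t1 -
#' t0)` with the reference ISI `t1 - t0` as the firing period. With a
#' deterministic neuron the protocol is exactly reproducible.
#'
#' @param neuron A [phase_neuron()] or [conductance_neuron()].
#' @param target_isi_s Requested ISI duration, seconds.
#' @param n_trials Number of replay trials N (pulse positions).
#' @param pulse_amplitude_pA,pulse_duration_s Pulse template.
#' @param i_hold Holding current during the search and the replays, pA.
#' @param tol Relative tolerance on the located ISI.
#' @param max_search_s Simulation horizon for locating the ISI.
#' @param seed Optional seed (stochastic neurons: the search is stochastic,
#'   each replay then restarts the RNG state implicitly via the saved state
#'   only — exact replay requires a deterministic neuron).
#' @return A `raw_prc` with `n_trials` first-order samples.
#' @export
replay_prc <- function(neuron, target_isi_s, n_trials = 50,
                       pulse_amplitude_pA = 100, pulse_duration_s = 5e-4,
                       i_hold = 0, tol = 0.05, max_search_s = 60,
                       seed = NULL) {
  stopifnot(target_isi_s > 0, n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  lead_s <- 5e-3
  settle_s <- max(1, 10 * target_isi_s)

  # search pass; the snapshot for an interval [t0, t1] must predate
  # t0 - 5 ms, so keep the state saved at the spike *two* back
  state <- neuron_init(neuron)
  snap2 <- NULL                  # state at spike k-2
  snap1 <- NULL                  # state at spike k-1 (interval start)
  t_prev <- NA_real_
  found <- NULL
  while (is.null(found) && state$t < max_search_s) {
    res <- advance_to_spike(neuron, state, t_stop = max_search_s,
                            i_hold = i_hold)
    if (is.na(res$t_spike)) break
    t_k <- res$t_spike
    if (!is.na(t_prev) && !is.null(snap2) && t_prev >= settle_s &&
        snap2$t < t_prev - lead_s) {
      isi <- t_k - t_prev
      if (abs(isi - target_isi_s) / target_isi_s <= tol) {
        found <- list(t0 = t_prev, t1 = t_k, snap = snap2)
      }
    }
    snap2 <- snap1
    snap1 <- res$state
    t_prev <- t_k
    state <- res$state
  }
  if (is.null(found)) {
    abort(sprintf(
      "no unperturbed ISI within %.0f%% of %.3g s found in %.0f s",
      100 * tol, target_isi_s, max_search_s),
      class = "prcclamp_error_replay")
  }
  t0 <- found$t0; t1 <- found$t1
  isi_ref <- t1 - t0

  # re-run from the snapshot at the spike preceding t0 up to t0 - 5 ms and
  # save the full state there
  pre <- advance_to_state(neuron, found$snap, t0 - lead_s, i_hold)

  q <- pulse_amplitude_pA * pulse_duration_s
  phi <- z <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tp <- t0 + i * isi_ref / n_trials
    st <- pre
    t_spk <- NA_real_
    # advance until the first spike after t0 (the AP closing the interval)
    repeat {
      res <- advance_to_spike(neuron, st, t_stop = t1 + 10e-3,
                              i_hold = i_hold,
                              pulse = list(t = tp,
                                           amplitude_pA = pulse_amplitude_pA,
                                           duration_s = pulse_duration_s))
      st <- res$state
      if (is.na(res$t_spike)) break
      # skip the AP that opens the interval (re-emitted within one step
      # of t0 on the replayed trajectory)
      if (res$t_spike > t0 + isi_ref * 0.01) { t_spk <- res$t_spike; break }
    }
    isi_pert <- if (is.na(t_spk)) NA_real_ else t_spk - t0
    phi[i] <- (tp - t0) / isi_ref
    z[i] <- (isi_ref - isi_pert) / (isi_ref * q)
  }
  ok <- is.finite(z)
  new_raw_prc(
    tibble(phi = phi[ok], z = z[ok], order = 1L,
           trial_id = seq_len(n_trials)[ok], charge_pC = q),
    mean_isi_s = isi_ref, charge_pC = q, n_trials = n_trials,
    skip_log = tibble(reason = "no_closing_spike", n = sum(!ok))[sum(!ok) > 0, ]
  )
}

# advance a simulator to an exact time (no spike handling needed: the target
# lies strictly inside an ISI)
advance_to_state <- function(neuron, state, t_target, i_hold) {
  while (state$t < t_target - 1e-12) {
    res <- advance_to_spike(neuron, state, t_stop = t_target, i_hold = i_hold)
    state <- res$state
  }
  state
}
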