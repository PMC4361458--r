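# The closed-loop frequency-clamp session: per-AP rate estimation and PID
# updates of the holding current, hold windows around each perturbation, and
# Sobol-scheduled reactive pulse delivery.

#' Run a closed-loop frequency-clamp session
#'
#' Orchestrates the full protocol on a simulated neuron:
#' 1. after every detected AP the online rate estimate is updated
#'    ([update_rate_estimate()], initialised at the target rate) and the PID
#'    controller ([pid_update()]) adjusts the holding current from the rate
#'    error;
#' 2. every `period_aps`-th AP triggers a perturbation: a delay drawn from
#'    the Gray-code Sobol sequence ([sobol_scheduler()]), expressed as a
#'    fraction of the current mean-ISI estimate, schedules a square pulse
#'    after that AP (reactive clamp);
#' 3. from the AP preceding each pulse until the second spike following it
#'    the controller output is held constant ([enter_hold()]), so no
#'    controller transient is locked to the perturbation.
#'
#' The realised stimulation phases are always recomputed afterwards from the
#' actual spike times (by [corrected_direct_prc()]), so scheduling error only
#' affects sampling density, never correctness.
#'
#' @param neuron A [phase_neuron()] or [conductance_neuron()].
#' @param cfg A [pid_config()] (target rate, gains, output clamp).
#' @param sched A [sobol_scheduler()] (skip, pulses-per-AP period).
#' @param pulse_amplitude_pA,pulse_duration_s Square-pulse template.
#' @param n_pulses Number of perturbations to deliver.
#' @param seed Optional integer seed (governs the neuron's stochasticity).
#' @param pid_enabled Set `FALSE` to keep the holding current constant at
#'   `i_const` (open-loop control condition).
#' @param i_const Holding current when `pid_enabled = FALSE`, pA.
#' @param warmup_s Controller warm-up, seconds: the clamp runs but no pulse
#'   is delivered before this time, so every trial is collected in the
#'   steady state (mirroring the experimental practice of waiting for a
#'   stable rate before starting the stimulation protocol).
#' @param max_duration Abort horizon, seconds; default scales with the
#'   session length.
#' @return A `clamp_session` list: `train` (a [spike_train()]), `pulses`
#'   (a [perturbations()] tibble with the scheduled delays), `log` (per-spike
#'   tibble: `t_s`, `isi_s`, `f_hat_hz`, `e_hz`, `i_holding_pA`, `held`),
#'   and `config` (snapshot).
#' @export
run_closed_loop_session <- function(neuron, cfg, sched = sobol_scheduler(),
                                    pulse_amplitude_pA = 100,
                                    pulse_duration_s = 5e-4,
                                    n_pulses = 1400, seed = NULL,
                                    pid_enabled = TRUE, i_const = 0,
                                    warmup_s = 5, max_duration = NULL) {
  stopifnot(inherits(cfg, "pid_config"), n_pulses >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_duration)) {
    max_duration <- 3 * (n_pulses + 2) * sched$period_aps / cfg$f_target +
      warmup_s + 30
  }

  state <- neuron_init(neuron)
  pid <- pid_state(i_holding = if (pid_enabled) 0 else i_const)
  f_hat <- cfg$f_target
  t_prev <- 0

  n_cap <- ceiling((n_pulses + 4) * sched$period_aps * 1.5) + 200L
  log_t <- log_isi <- log_fhat <- log_e <- log_i <- numeric(n_cap)
  log_held <- logical(n_cap)
  k <- 0L

  pulses_t <- pulses_delay <- numeric(n_pulses)
  n_delivered <- 0L
  pending_pulse <- NULL   # list(t, amplitude_pA, duration_s)
  spikes_after_pulse <- -1L  # -1: no active hold window
  aps_since_trigger <- 0L
  saturated_run <- 0L

  repeat {
    res <- advance_to_spike(neuron, state,
                            t_stop = min(state$t + 10 / cfg$f_target + 1,
                                         max_duration),
                            i_hold = pid$i_holding, pulse = pending_pulse)
    state <- res$state
    if (is.na(res$t_spike)) {
      if (state$t >= max_duration) {
        abort(sprintf(
          paste0("closed-loop session aborted at t = %.1f s: %d/%d pulses ",
                 "delivered, f_hat = %.1f Hz, i_holding = %.1f pA ",
                 "(target %.1f Hz unreachable within the output clamp?)"),
          state$t, n_delivered, n_pulses, f_hat, pid$i_holding, cfg$f_target),
          class = "prcclamp_error_session")
      }
      next
    }
    t_k <- res$t_spike
    isi_k <- t_k - t_prev
    if (k > 0L) f_hat <- update_rate_estimate(f_hat, isi_k, cfg$tau_rate)
    e_k <- cfg$f_target - f_hat

    # hold bookkeeping: count spikes after the pulse, release at the second;
    # the controller reconnects only at the *next* AP, so the holding
    # current is constant at every spike of the window, boundaries included
    released_now <- FALSE
    if (!is.null(pending_pulse) && t_k > pending_pulse$t) {
      spikes_after_pulse <- spikes_after_pulse + 1L
      if (spikes_after_pulse >= 2L) {
        if (pid$held) pid <- release_hold(pid)
        pending_pulse <- NULL
        spikes_after_pulse <- -1L
        released_now <- TRUE
      }
    }

    if (pid_enabled && !pid$held && !released_now) {
      pid <- pid_update(cfg, pid, e_k)
      saturated_run <- if (pid$i_holding >= cfg$i_max - 1e-9 ||
                           pid$i_holding <= cfg$i_min + 1e-9) {
        saturated_run + 1L
      } else 0L
    }

    k <- k + 1L
    if (k > n_cap) {  # grow (rare: very slow convergence)
      n_cap <- n_cap * 2L
      length(log_t) <- length(log_isi) <- length(log_fhat) <- n_cap
      length(log_e) <- length(log_i) <- n_cap
      length(log_held) <- n_cap
    }
    log_t[k] <- t_k; log_isi[k] <- isi_k; log_fhat[k] <- f_hat
    log_e[k] <- e_k; log_i[k] <- pid$i_holding; log_held[k] <- pid$held

    # schedule the next perturbation: this AP is the trigger (and the AP
    # preceding the pulse), so the hold starts here
    aps_since_trigger <- aps_since_trigger + 1L
    if (is.null(pending_pulse) && n_delivered < n_pulses &&
        t_k >= warmup_s && aps_since_trigger >= sched$period_aps) {
      nx <- sobol_next_delay(sched)
      sched <- nx$scheduler
      delay_s <- nx$delay / f_hat
      n_delivered <- n_delivered + 1L
      pulses_t[n_delivered] <- t_k + delay_s
      pulses_delay[n_delivered] <- nx$delay
      pending_pulse <- list(t = t_k + delay_s,
                            amplitude_pA = pulse_amplitude_pA,
                            duration_s = pulse_duration_s)
      if (pid_enabled) pid <- enter_hold(pid)
      spikes_after_pulse <- 0L
      aps_since_trigger <- 0L
    }

    t_prev <- t_k
    if (n_delivered >= n_pulses && is.null(pending_pulse)) break
    if (saturated_run > 2000L && abs(e_k) / cfg$f_target > 0.5) {
      abort(sprintf(
        "target rate %.1f Hz unreachable: output pinned at the clamp (%.0f pA) with persistent error %.1f Hz",
        cfg$f_target, pid$i_holding, e_k),
        class = "prcclamp_error_session")
    }
    if (state$t >= max_duration) {
      abort("closed-loop session exceeded max_duration",
            class = "prcclamp_error_session")
    }
  }

  idx <- seq_len(k)
  achieved <- (sum(log_t[idx] >= warmup_s) - 1) /
    (log_t[k] - max(warmup_s, log_t[idx][log_t[idx] >= warmup_s][1]))
  if (is.finite(achieved) && abs(achieved - cfg$f_target) / cfg$f_target > 0.2) {
    abort(sprintf(
      paste0("target rate %.1f Hz not reached: achieved %.1f Hz with ",
             "i_holding = %.1f pA (output clamp [%.0f, %.0f] pA)"),
      cfg$f_target, achieved, pid$i_holding, cfg$i_min, cfg$i_max),
      class = "prcclamp_error_session")
  }
  pulses <- perturbations(pulses_t[seq_len(n_delivered)],
                          pulse_amplitude_pA, pulse_duration_s)
  pulses$scheduled_delay <- pulses_delay[seq_len(n_delivered)]
  structure(
    list(
      train = spike_train(log_t[idx], source_id = class(neuron)[1]),
      pulses = pulses,
      log = tibble(t_s = log_t[idx], isi_s = log_isi[idx],
                   f_hat_hz = log_fhat[idx], e_hz = log_e[idx],
                   i_holding_pA = log_i[idx], held = log_held[idx]),
      config = list(f_target = cfg$f_target, g_p = cfg$g_p, g_i = cfg$g_i,
                    g_d = cfg$g_d, i_min = cfg$i_min, i_max = cfg$i_max,
                    tau_rate = cfg$tau_rate, skip = sched$skip,
                    period_aps = sched$period_aps,
                    pulse_amplitude_pA = pulse_amplitude_pA,
                    pulse_duration_s = pulse_duration_s,
                    n_pulses = n_pulses, seed = seed, warmup_s = warmup_s,
                    pid_enabled = pid_enabled, i_const = i_const,
                    neuron_class = class(neuron)[1])
    ),
    class = "clamp_session"
  )
}

#' @export
print.clamp_session <- function(x, ...) {
  cat(sprintf("<clamp_session> %d spikes, %d pulses, target %.1f Hz (%s)\n",
              nrow(x$train), nrow(x$pulses), x$config$f_target,
              if (x$config$pid_enabled) "PID" else "constant current"))
  cat(sprintf("  achieved %.2f Hz over the last 80%% of the session\n",
              session_rate(x)))
  invisible(x)
}

#' Mean firing rate of a session
#'
#' Average rate either over the tail of the session (default: the last 80%
#' by time) or after a fixed transient (`after_s`), e.g. the controller
#' convergence window.
#'
#' @param session A `clamp_session`.
#' @param tail_fraction Fraction of the session (by time, from the end) over
#'   which to average.
#' @param after_s If given, average over spikes at `t >= after_s` instead.
#' @return Mean rate, Hz.
#' @export
session_rate <- function(session, tail_fraction = 0.8, after_s = NULL) {
  ts <- session$train$time_s
  t_cut <- if (is.null(after_s)) max(ts) * (1 - tail_fraction) else after_s
  ts <- ts[ts >= t_cut]
  (length(ts) - 1) / diff(range(ts))
}

#' Pointwise confidence-band overlap of two smoothed PRCs
#'
#' Fraction of grid points at which the two 68% confidence bands intersect.
#' Used to compare estimates that should agree (e.g. closed-loop vs
#' constant-current control sessions). Note that for two independent,
#' equally precise estimates of the same curve the bands intersect at a
#' given point with probability about 0.84 regardless of sample size, so
#' even perfect agreement leaves occasional non-overlapping stretches where
#' the two sampling-noise wiggles happen to oppose.
#'
#' @param a,b `smoothed_prc` objects with `ci_lo`/`ci_hi` columns, on the
#'   same grid.
#' @return Fraction in \[0, 1\].
#' @export
prc_ci_overlap <- function(a, b) {
  stopifnot(all(c("ci_lo", "ci_hi") %in% names(a)),
            all(c("ci_lo", "ci_hi") %in% names(b)),
            nrow(a) == nrow(b))
  mean(pmin(a$ci_hi, b$ci_hi) >= pmax(a$ci_lo, b$ci_lo))
}

#' @export
glance.clamp_session <- function(x, ...) {
  st <- isi_stats(x$train,
                  exclude = setdiff(seq_len(nrow(x$train) - 1L),
                                    unperturbed_isi_indices(x$train,
                                                            x$pulses$t_pulse_s)))
  tibble(
    n_spikes = nrow(x$train),
    n_pulses = nrow(x$pulses),
    f_target_hz = x$config$f_target,
    rate_hz = session_rate(x),
    cv_unperturbed = st$cv,
    duration_s = max(x$train$time_s),
    pid_enabled = x$config$pid_enabled
  )
}

#' Verify the hold contract on a session log
#'
#' Scans a session for controller activity inside perturbation windows: for
#' every pulse, the holding current recorded at each spike from the trigger
#' AP to the second spike after the pulse must be exactly constant. Returns
#' one row per pulse with the window's current range.
#'
#' @param session A `clamp_session`.
#' @return A tibble: `pulse`, `t_pulse_s`, `n_spikes_in_window`,
#'   `i_range_pA` (max - min holding current in the window; 0 under the
#'   contract).
#' @export
check_hold_contract <- function(session) {
  ts <- session$log$t_s
  ih <- session$log$i_holding_pA
  purrr::map_dfr(seq_len(nrow(session$pulses)), function(i) {
    tp <- session$pulses$t_pulse_s[i]
    trigger <- max(which(ts <= tp))
    after <- which(ts > tp)
    last <- if (length(after) >= 2) after[2] else max(after, trigger)
    win <- trigger:last
    tibble(pulse = i, t_pulse_s = tp,
           n_spikes_in_window = length(win),
           i_range_pA = max(ih[win]) - min(ih[win]))
  })
}

#' ISI statistics of a session after the control transient
#'
#' [isi_stats()] over the unperturbed ISIs of a session, discarding an
#' initial window during which the controller is still converging on the
#' target rate.
#'
#' @param session A `clamp_session`.
#' @param transient_s Discarded initial window, seconds.
#' @return A one-row tibble as from [isi_stats()].
#' @export
session_isi_stats <- function(session, transient_s = 5) {
  ts <- session$train$time_s
  n_isi <- length(ts) - 1L
  keep <- unperturbed_isi_indices(ts, session$pulses$t_pulse_s)
  keep <- keep[ts[keep] >= transient_s]
  isi_stats(session$train, exclude = setdiff(seq_len(n_isi), keep))
}

#' PRC estimate from a closed-loop session
#'
#' Convenience pipeline: corrected direct PRC from the session's spikes and
#' pulses, then kernel smoothing.
#'
#' @param session A `clamp_session`.
#' @param transient_s Initial window discarded before estimation, seconds (the controller convergence transient).
#' @param ... Passed to [prc_smooth()].
#' @return A `smoothed_prc`.
#' @export
session_prc <- function(session, transient_s = 5, ...) {
  # trim spikes as well as pulses: ISIs from the convergence transient are
  # systematically long and would bias the mean-ISI (and hence every z)
  ts <- session$train$time_s
  train <- spike_train(ts[ts >= transient_s],
                       session$train$source_id[ts >= transient_s])
  keep <- session$pulses$t_pulse_s >= transient_s + 0.1
  raw <- corrected_direct_prc(train, session$pulses[keep, ])
  prc_smooth(raw, ...)
}
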