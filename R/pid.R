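# PID controller for the frequency clamp: per-AP updates of the holding
# current from the online rate-estimate error, with a hold contract around
# each perturbation.

#' PID configuration for the frequency clamp
#'
#' Gains follow the convention of a per-spike discrete PID acting on the rate
#' error \eqn{e_k = F_{target} - \tilde F_k}:
#' \deqn{I_k^{holding} = g_P e_k + g_I \sum_{i \le k} e_i + g_D (e_k - e_{k-1}),}
#' clamped to `[i_min, i_max]`. Defaults are the gains used for cerebellar
#' Purkinje cells (g_P = 0.001, g_I = 0.1, g_D = 0 pA/Hz) and an output range
#' matching the -0.2 to 1 nA holding currents used experimentally.
#'
#' @param f_target Target firing rate, Hz (> 0).
#' @param g_p,g_i,g_d Proportional, integral, derivative gains, pA/Hz.
#' @param i_min,i_max Output clamp, pA.
#' @param tau_rate Timescale of the online rate estimator, seconds.
#' @param integrate_during_hold Accumulate the integral term while the
#'   controller output is held (default FALSE: the integrator is frozen
#'   together with the output).
#' @return A `pid_config` list.
#' @export
pid_config <- function(f_target, g_p = 0.001, g_i = 0.1, g_d = 0,
                       i_min = -200, i_max = 1000, tau_rate = 1,
                       integrate_during_hold = FALSE) {
  stopifnot(f_target > 0, i_min < i_max, tau_rate > 0)
  structure(
    list(f_target = f_target, g_p = g_p, g_i = g_i, g_d = g_d,
         i_min = i_min, i_max = i_max, tau_rate = tau_rate,
         integrate_during_hold = integrate_during_hold),
    class = "pid_config"
  )
}

#' Initial PID state
#'
#' @param i_holding Initial holding current, pA.
#' @return A `pid_state` list with fields `err_sum`, `err_prev`, `i_holding`,
#'   `held`.
#' @export
pid_state <- function(i_holding = 0) {
  structure(
    list(err_sum = 0, err_prev = 0, i_holding = i_holding, held = FALSE),
    class = "pid_state"
  )
}

#' One PID update
#'
#' Updates the holding current from the rate error `e_k`. While the
#' controller is held (see [enter_hold()]) the call is a no-op with a
#' warning: the output keeps its most recent value and, by default, the
#' integrator does not accumulate. Anti-windup: when the output saturates at
#' the clamp, the integral term is not accumulated either.
#'
#' @param cfg A [pid_config()].
#' @param state A [pid_state()].
#' @param e_k Rate error `f_target - f_hat`, Hz.
#' @return The updated `pid_state`.
#' @export
pid_update <- function(cfg, state, e_k) {
  if (state$held) {
    if (cfg$integrate_during_hold) state$err_sum <- state$err_sum + e_k
    warn("pid_update called while held; output unchanged")
    return(state)
  }
  err_sum_new <- state$err_sum + e_k
  u <- cfg$g_p * e_k + cfg$g_i * err_sum_new + cfg$g_d * (e_k - state$err_prev)
  if (u > cfg$i_max) {
    state$i_holding <- cfg$i_max        # saturated: freeze integrator
  } else if (u < cfg$i_min) {
    state$i_holding <- cfg$i_min
  } else {
    state$i_holding <- u
    state$err_sum <- err_sum_new
  }
  state$err_prev <- e_k
  state
}

#' Enter / release the hold window around a perturbation
#'
#' The controller output is frozen from the AP preceding a scheduled pulse
#' until the second spike following it, so that no controller transient is
#' locked to the perturbation. `enter_hold()` freezes the output;
#' `release_hold()` reconnects the controller. Releasing a state that is not
#' held is an error.
#'
#' @param state A [pid_state()].
#' @return The updated `pid_state`.
#' @export
enter_hold <- function(state) {
  state$held <- TRUE
  state
}

#' @rdname enter_hold
#' @export
release_hold <- function(state) {
  if (!state$held) abort("release_hold() on a state that is not held",
                         class = "prcclamp_error_hold")
  state$held <- FALSE
  state
}
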