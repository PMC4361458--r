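# Indirect PRC estimation: Ornstein-Uhlenbeck stimulus synthesis and the
# weighted spike-triggered average (WSTA).

#' Generate an Ornstein-Uhlenbeck current stimulus
#'
#' Exponentially filtered white noise
#' \deqn{\tau_I \dot I(t) = -I(t) + s\sqrt{2\tau_I}\,\xi(t)}
#' discretised exactly:
#' \eqn{I_{n+1} = I_n e^{-dt/\tau_I} + s\sqrt{1 - e^{-2dt/\tau_I}}\,
#' \mathcal N(0,1)}, so the stationary SD equals `s` at any step size. A
#' constant `offset` (used to set the neuron's mean firing rate) is added on
#' top of the zero-mean fluctuation. The process is initialised at its
#' stationary distribution.
#'
#' @param s Stationary SD of the fluctuating part, pA.
#' @param tau_i Autocorrelation time, seconds.
#' @param duration Stimulus length, seconds.
#' @param dt Time step, seconds; must satisfy `dt <= tau_i / 10`.
#' @param offset Constant current added to the fluctuation, pA.
#' @param seed Optional integer seed.
#' @return An `ou_stimulus` object: tibble with columns `time_s` and `i_pA`;
#'   attributes `dt`, `s`, `tau_i`, `offset`, `seed`.
#' @export
generate_ou_current <- function(s, tau_i, duration, dt, offset = 0,
                                seed = NULL) {
  stopifnot(s >= 0, tau_i > 0, duration > 0, dt > 0)
  if (dt > tau_i / 10) {
    abort("dt must be <= tau_i / 10 for a well-resolved OU stimulus",
          class = "prcclamp_error_ou")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt) + 1L
  rho <- exp(-dt / tau_i)
  if (s == 0) {
    x <- rep(0, n)
  } else {
    innov <- rnorm(n, sd = s * sqrt(1 - rho^2))
    innov[1] <- rnorm(1, sd = s)  # stationary start
    x <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  }
  structure(
    tibble(time_s = (seq_len(n) - 1) * dt, i_pA = x + offset),
    class = c("ou_stimulus", class(tibble())),
    dt = dt, s = s, tau_i = tau_i, offset = offset, seed = seed
  )
}

#' Weighted spike-triggered average PRC estimate
#'
#' Indirect PRC estimator from the response to a weak fluctuating current.
#' Each ISI's stimulus segment is rescaled to a common phase axis and
#' weighted by how much that ISI deviates from the mean,
#' \eqn{\alpha_k = \langle ISI\rangle / ISI_k - 1}; the weighted sum is
#' normalised by the area of the stimulus autocorrelation function,
#' \eqn{2 s^2 \tau_I}:
#' \deqn{Z(\varphi) \simeq \frac{\sum_k \alpha_k I_k(\varphi)}{2 s^2 \tau_I}.}
#' Only the fluctuating part of the stimulus enters: each segment is
#' mean-subtracted before weighting, so the DC offset used to set the firing
#' rate does not leak into the estimate.
#'
#' @param stimulus An [generate_ou_current()] stimulus (or data frame with
#'   `time_s`, `i_pA` plus attributes `s`, `tau_i`).
#' @param train A [spike_train()] with at least 2 spikes inside the stimulus
#'   window.
#' @param grid_size Number of phase grid points for segment resampling.
#' @return A `wsta_prc` object: tibble with columns `phi`, `z` (1/pC);
#'   attributes `n_isi_used`, `mean_isi_s`, `rate_hz`.
#' @export
wsta_prc <- function(stimulus, train, grid_size = 100) {
  s <- attr(stimulus, "s", exact = TRUE)
  tau_i <- attr(stimulus, "tau_i", exact = TRUE)
  if (is.null(s) || is.null(tau_i)) {
    abort("stimulus must carry `s` and `tau_i` attributes",
          class = "prcclamp_error_ou")
  }
  if (s <= 0) abort("stimulus SD must be > 0 for the WSTA")
  ts <- spike_times(train)
  ts <- ts[ts >= min(stimulus$time_s) & ts <= max(stimulus$time_s)]
  if (length(ts) < 2) {
    abort("need at least one complete ISI inside the stimulus window",
          class = "prcclamp_error_spikes")
  }
  isi <- diff(ts)
  mean_isi <- mean(isi)
  alpha <- mean_isi / isi - 1
  grid <- seq(0, 1, length.out = grid_size)
  # direct index interpolation on the uniform stimulus grid
  i_vals <- stimulus$i_pA
  t0 <- stimulus$time_s[1]
  dt <- attr(stimulus, "dt", exact = TRUE) %||%
    (stimulus$time_s[2] - stimulus$time_s[1])
  nmax <- length(i_vals)
  acc <- numeric(grid_size)
  for (k in seq_along(isi)) {
    x <- (ts[k] + grid * isi[k] - t0) / dt
    x <- pmin(pmax(x, 0), nmax - 1)
    i0 <- floor(x)
    fr <- x - i0
    seg <- i_vals[i0 + 1] * (1 - fr) + i_vals[pmin(i0 + 2, nmax)] * fr
    seg <- seg - mean(seg)
    acc <- acc + alpha[k] * seg
  }
  z <- acc / (2 * s^2 * tau_i)
  structure(
    tibble(phi = grid, z = z),
    class = c("wsta_prc", class(tibble())),
    n_isi_used = length(isi),
    mean_isi_s = mean_isi,
    rate_hz = 1 / mean_isi,
    s = s, tau_i = tau_i
  )
}

#' @export
print.wsta_prc <- function(x, ...) {
  cat(sprintf("<wsta_prc> %d grid points, %d ISIs, rate %.2f Hz\n",
              nrow(x), attr(x, "n_isi_used"), attr(x, "rate_hz")))
  invisible(x)
}

#' @export
glance.wsta_prc <- function(x, ...) {
  tibble(
    n_isi_used = attr(x, "n_isi_used"),
    mean_isi_s = attr(x, "mean_isi_s"),
    rate_hz = attr(x, "rate_hz"),
    grid_size = nrow(x)
  )
}
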