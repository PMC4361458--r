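# Channel-noise diffusion approximation: kinetic schemes, the OU-sum
# coefficients matched to the open-fraction autocovariance, the exact Markov
# population oracle, and the OU-sum simulator.

#' Define a channel kinetic scheme
#'
#' An N-state continuous-time Markov scheme for a population of identical,
#' independent ion channels. `rates[i, j]` is the transition rate from state
#' i to state j (1/s, off-diagonal; the diagonal is ignored). The channel
#' conducts when in any of the `open_states`.
#'
#' @param rates N x N matrix of transition rates, 1/s.
#' @param open_states Integer indices of the conducting states.
#' @param n_channels Number of channels in the population.
#' @return A `kinetic_scheme` object.
#' @export
kinetic_scheme <- function(rates, open_states, n_channels = 1000) {
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == ncol(rates), n_channels >= 1)
  diag(rates) <- 0
  if (any(rates < 0)) abort("transition rates must be >= 0")
  open_states <- as.integer(open_states)
  stopifnot(length(open_states) >= 1,
            all(open_states >= 1), all(open_states <= nrow(rates)))
  structure(
    list(rates = rates, open_states = open_states,
         n_channels = as.integer(n_channels), n_states = nrow(rates)),
    class = "kinetic_scheme"
  )
}

#' Two-state channel scheme
#'
#' Closed <-> open with opening rate `alpha` and closing rate `beta`. Its
#' open-fraction autocovariance is the closed form
#' `p (1 - p) exp(-(alpha + beta) t) / n_channels` with
#' `p = alpha / (alpha + beta)` — the analytic oracle for the diffusion
#' coefficients.
#'
#' @param alpha Opening rate, 1/s.
#' @param beta Closing rate, 1/s.
#' @param n_channels Population size.
#' @return A [kinetic_scheme()].
#' @export
two_state_scheme <- function(alpha, beta, n_channels = 1000) {
  kinetic_scheme(matrix(c(0, alpha, beta, 0), 2, 2, byrow = TRUE),
                 open_states = 2L, n_channels = n_channels)
}

#' Chain scheme of identical gates
#'
#' The (k+1)-state linear chain equivalent to a channel with k identical
#' independent two-state gates (e.g. k = 4 for a delayed-rectifier
#' potassium channel): state i has i - 1 open gates, and the channel
#' conducts in the last state only. Forward rate from state i is
#' `(k - i + 1) alpha`, backward rate `(i - 1) beta`.
#'
#' @param k Number of gates.
#' @param alpha,beta Per-gate opening / closing rates, 1/s.
#' @param n_channels Population size.
#' @return A [kinetic_scheme()].
#' @export
gate_chain_scheme <- function(k, alpha, beta, n_channels = 1000) {
  n <- k + 1L
  r <- matrix(0, n, n)
  for (i in seq_len(k)) {
    r[i, i + 1] <- (k - i + 1) * alpha
    r[i + 1, i] <- i * beta
  }
  kinetic_scheme(r, open_states = n, n_channels = n_channels)
}

#' Five-state toy scheme with a slow opening gate
#'
#' Birth-death chain of five states in which the final transition into the
#' single open state is an order of magnitude slower than the three closed
#' interconversions. The slow mode then carries ~98% of the open-fraction
#' variance, so every relaxation time constant of the scheme is measurable
#' from a short population simulation — the shipped validation case for the
#' diffusion approximation beyond two states.
#'
#' @param rate_fast Rate of the closed-state interconversions, 1/s (both
#'   directions).
#' @param rate_slow Rate of the closed <-> open transition, 1/s (both
#'   directions).
#' @param n_channels Population size.
#' @return A [kinetic_scheme()].
#' @export
five_state_scheme <- function(rate_fast = 5000, rate_slow = 500,
                              n_channels = 1000) {
  r <- matrix(0, 5, 5)
  for (i in 1:3) {
    r[i, i + 1] <- rate_fast
    r[i + 1, i] <- rate_fast
  }
  r[4, 5] <- rate_slow
  r[5, 4] <- rate_slow
  kinetic_scheme(r, open_states = 5L, n_channels = n_channels)
}

#' Delayed-rectifier K scheme of the conductance surrogate
#'
#' The 5-state gate chain of the surrogate's potassium channel (four
#' identical n-gates), with per-gate rates evaluated at a frozen membrane
#' voltage — the quasi-static approximation used to size the channel-noise
#' diffusion terms. Rates use the surrogate's kinetics (1/ms at `phi_temp`)
#' converted to 1/s.
#'
#' @param v_mV Evaluation voltage, mV (default -60, near the limit-cycle
#'   mean).
#' @param n_channels Population size (the CV knob of the noisy surrogate:
#'   fewer channels, larger fluctuations).
#' @param phi_temp Temperature factor (match the neuron's).
#' @return A [kinetic_scheme()].
#' @export
wb_k_scheme <- function(v_mV = -60, n_channels = 1000, phi_temp = 5) {
  x <- v_mV + 34
  an <- if (abs(x) < 1e-9) 0.1 else 0.01 * x / (1 - exp(-x / 10))
  bn <- 0.125 * exp(-(v_mV + 44) / 80)
  gate_chain_scheme(4, alpha = 1e3 * phi_temp * an,
                    beta = 1e3 * phi_temp * bn, n_channels = n_channels)
}

scheme_generator <- function(scheme) {
  a <- scheme$rates
  diag(a) <- -rowSums(a)
  a
}

#' Stationary state distribution of a kinetic scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @return Numeric vector of stationary occupancies (sums to 1).
#' @export
stationary_distribution <- function(scheme) {
  a <- scheme_generator(scheme)
  e <- eigen(t(a))
  k <- which.min(abs(e$values))
  if (abs(e$values[k]) > 1e-8 * max(abs(e$values))) {
    abort("scheme has no stationary distribution",
          class = "prcclamp_error_scheme")
  }
  p <- Re(e$vectors[, k])
  p <- p / sum(p)
  if (any(p < -1e-10)) {
    abort("scheme is not irreducible (negative stationary occupancy)",
          class = "prcclamp_error_scheme")
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Diffusion-approximation coefficients for channel noise
#'
#' Matches a sum of N - 1 Ornstein-Uhlenbeck processes to the stationary
#' autocovariance of the open fraction of `n_channels` independent channels:
#' the single-channel autocovariance decomposes over the non-zero eigenvalues
#' \eqn{\lambda_i} of the scheme's generator as
#' \eqn{C(t) = \sum_i c_i e^{\lambda_i t}}, giving time constants
#' \eqn{\tau_i = -1/\lambda_i} and variances
#' \eqn{\sigma_i^2 = c_i / n_{channels}}. Adding
#' \eqn{\sum_i \eta_i(t)} (each \eqn{\eta_i} an OU process with these
#' coefficients) to the deterministic open fraction reproduces the
#' population's conductance fluctuations. Requires a reversible
#' (detailed-balance) scheme, for which all eigenvalues are real and all
#' weights non-negative.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A `diffusion_noise` tibble with columns `tau_s`, `sigma`
#'   (open-fraction units) and attributes `p_open` (stationary open
#'   fraction) and `var_total` (summed variance).
#' @export
diffusion_coefficients <- function(scheme) {
  a <- scheme_generator(scheme)
  n <- nrow(a)
  p <- stationary_distribution(scheme)
  u <- as.numeric(seq_len(n) %in% scheme$open_states)
  e <- eigen(a)
  if (max(abs(Im(e$values))) > 1e-8 * max(abs(e$values))) {
    abort("complex generator eigenvalues: scheme must satisfy detailed balance",
          class = "prcclamp_error_scheme")
  }
  vals <- Re(e$values)
  w <- Re(e$vectors)
  winv <- solve(w)
  # single-channel autocovariance C(t) = (p*u)' expm(A t) u - p_o^2
  #                                    = sum_k c_k exp(lambda_k t), k != 0
  cvec <- as.vector((p * u) %*% w) * as.vector(winv %*% u)
  k0 <- which.min(abs(vals))
  keep <- setdiff(seq_len(n), k0)
  taus <- -1 / vals[keep]
  cs <- cvec[keep]
  if (any(taus <= 0)) abort("non-negative relaxation eigenvalue: scheme not irreducible",
                            class = "prcclamp_error_scheme")
  if (any(cs < -1e-10 * sum(abs(cs)))) {
    abort("negative autocovariance weight: scheme must satisfy detailed balance",
          class = "prcclamp_error_scheme")
  }
  cs <- pmax(cs, 0)
  ord <- order(taus)
  out <- tibble(tau_s = taus[ord],
                sigma = sqrt(cs[ord] / scheme$n_channels))
  structure(out,
            class = c("diffusion_noise", class(tibble())),
            p_open = sum(p * u),
            var_total = sum(cs) / scheme$n_channels)
}

#' Analytic autocovariance of the summed OU approximation
#'
#' \eqn{C(t) = \sum_i \sigma_i^2 e^{-|t|/\tau_i}} for a `diffusion_noise`
#' spec.
#'
#' @param spec A `diffusion_noise` tibble (columns `tau_s`, `sigma`).
#' @param lags_s Lags at which to evaluate, seconds.
#' @return Numeric vector of autocovariances.
#' @export
ou_sum_autocovariance <- function(spec, lags_s) {
  vapply(lags_s, function(l) sum(spec$sigma^2 * exp(-abs(l) / spec$tau_s)),
         numeric(1))
}

#' Simulate the summed-OU channel-noise approximation
#'
#' Exact-discretisation simulation of \eqn{\sum_i \eta_i(t)} for a
#' `diffusion_noise` spec, each term initialised at its stationary
#' distribution.
#'
#' @param spec A `diffusion_noise` tibble.
#' @param duration Seconds.
#' @param dt Step, seconds.
#' @param seed Optional seed.
#' @return A tibble with `time_s`, `eta`.
#' @export
simulate_diffusion_noise <- function(spec, duration, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt) + 1L
  eta <- numeric(n)
  for (i in seq_len(nrow(spec))) {
    rho <- exp(-dt / spec$tau_s[i])
    s <- spec$sigma[i]
    if (s == 0) next
    innov <- rnorm(n, sd = s * sqrt(1 - rho^2))
    innov[1] <- rnorm(1, sd = s)
    eta <- eta + as.numeric(stats::filter(innov, rho, method = "recursive"))
  }
  tibble(time_s = (seq_len(n) - 1) * dt, eta = eta)
}

#' Exact Markov simulation of a channel population
#'
#' Validation oracle for the diffusion approximation: simulates the
#' population state counts of `n_channels` independent channels by per-step
#' multinomial transitions (first-order transition probabilities
#' `rate * dt`, valid for `dt * max total rate <= 0.1`), and records the
#' open fraction. The population is initialised from the stationary
#' distribution.
#'
#' @param scheme A [kinetic_scheme()] with `n_channels <= 1e4`.
#' @param duration Seconds.
#' @param dt Step, seconds.
#' @param keep_every Record every this many steps.
#' @param seed Optional seed.
#' @return A tibble with `time_s`, `p_open` (population open fraction).
#' @export
exact_markov_simulation <- function(scheme, duration, dt, keep_every = 1,
                                    seed = NULL) {
  stopifnot(scheme$n_channels <= 1e4, duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- stationary_distribution(scheme)
  counts0 <- as.vector(stats::rmultinom(1, scheme$n_channels, p))
  n_steps <- floor(duration / dt)
  open <- as.integer(seq_len(scheme$n_states) %in% scheme$open_states)
  po <- markov_population_cpp(scheme$rates, open, counts0, n_steps, dt,
                              as.integer(keep_every))
  tibble(time_s = seq_along(po) * dt * keep_every, p_open = po)
}

#' Empirical autocovariance at chosen lags
#'
#' Plain biased-normalisation autocovariance
#' \eqn{\hat C(k) = \frac1n \sum_t (x_t - \bar x)(x_{t+k} - \bar x)},
#' evaluated only at the requested lags.
#'
#' @param x Numeric series.
#' @param lag_steps Integer lags, in samples.
#' @return Numeric vector of autocovariances.
#' @export
autocovariance_at <- function(x, lag_steps) {
  x <- x - mean(x)
  n <- length(x)
  vapply(as.integer(lag_steps), function(k) {
    if (k >= n) return(NA_real_)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
}

#' Fitted autocorrelation time of a stationary series
#'
#' Log-linear fit of the empirical autocorrelation over the lags where it
#' stays above `floor`, returning the fitted exponential decay time. Used to
#' verify OU stimulus statistics.
#'
#' @param x Numeric series (e.g. an OU stimulus `i_pA`).
#' @param dt Sampling step, seconds.
#' @param max_lag_s Largest lag to use, seconds.
#' @param rho_floor Smallest autocorrelation included in the fit.
#' @return Fitted autocorrelation time, seconds.
#' @export
fit_autocorrelation_time <- function(x, dt, max_lag_s = NULL,
                                     rho_floor = 0.05) {
  n <- length(x)
  if (is.null(max_lag_s)) max_lag_s <- min(0.05, n * dt / 10)
  max_lag <- max(2L, min(floor(max_lag_s / dt), n - 1L))
  # at most ~200 lag points: enough for a log-linear fit, cheap on long traces
  lags <- unique(pmax(1L, round(seq(1L, max_lag, length.out = min(200L, max_lag)))))
  ac <- autocovariance_at(x, c(0L, lags))
  rho <- ac[-1] / ac[1]
  use <- rho > rho_floor
  if (sum(use) < 2) abort("autocorrelation decays too fast to fit at this dt")
  fit <- stats::lm(log(rho[use]) ~ 0 + I(lags[use] * dt))
  -1 / unname(coef(fit)[1])
}
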