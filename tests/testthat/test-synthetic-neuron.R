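test_that("the deterministic phase neuron fires with exact ISIs", {
  sim <- simulate_phase_neuron(det_neuron(), duration = 1, i_hold = 250)
  isis <- diff(sim$train$time_s)
  expect_equal(isis, rep(0.02, length(isis)), tolerance = 1e-6)
  expect_error(simulate_phase_neuron(det_neuron(), 1, i_hold = -1000),
               class = "prcclamp_error_neuron")
})

test_that("a single pulse shifts the next AP by z_true(phi) * Q to first order", {
  nrn <- det_neuron()
  base <- simulate_phase_neuron(nrn, 1, i_hold = 250)
  t0 <- base$train$time_s[20]
  isi0 <- 0.02
  for (phi0 in c(0.2, 0.5, 0.8)) {
    q <- 0.005  # small charge and brief pulse: 50 pA x 0.1 ms
    p <- perturbations(t0 + phi0 * isi0, amplitude_pA = 50, duration_s = 1e-4)
    sim <- simulate_phase_neuron(nrn, 1, i_hold = 250, pulses = p)
    t_next <- sim$train$time_s[sim$train$time_s > t0][1]
    advance <- isi0 - (t_next - t0)
    expected <- prc_preset("peaked")(phi0) * q * isi0
    expect_equal(advance, expected, tolerance = 0.05)
  }
})

test_that("simulators are reproducible bit-for-bit given a seed", {
  a <- simulate_phase_neuron(jitter_neuron(), 5, i_hold = 250, seed = 42)
  b <- simulate_phase_neuron(jitter_neuron(), 5, i_hold = 250, seed = 42)
  expect_identical(a$train$time_s, b$train$time_s)

  nz <- diffusion_coefficients(wb_k_scheme(n_channels = 300))
  nc <- conductance_neuron(noise = nz)
  ca <- simulate_conductance_neuron(nc, 2, i_hold = 55, seed = 42)
  cb <- simulate_conductance_neuron(nc, 2, i_hold = 55, seed = 42)
  expect_identical(ca$train$time_s, cb$train$time_s)
})

test_that("the noiseless conductance surrogate is a clean limit cycle", {
  nc <- conductance_neuron()
  sim <- simulate_conductance_neuron(nc, 3, i_hold = 55, seed = 1)
  st <- isi_stats(sim$train)
  expect_lt(st$cv, 0.001)
  # rate is strictly increasing with holding current (clamp prerequisite)
  rates <- vapply(c(0, 100, 300, 800),
                  function(i) firing_rate_at(nc, i, duration = 1.5,
                                             transient = 0.5),
                  numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("channel noise lowers ISI variability at higher rates", {
  nz <- diffusion_coefficients(wb_k_scheme(n_channels = 300))
  nc <- conductance_neuron(noise = nz)
  lo <- simulate_conductance_neuron(nc, 6, i_hold = 10, seed = 3)
  hi <- simulate_conductance_neuron(nc, 6, i_hold = 400, seed = 3)
  expect_gt(isi_stats(lo$train)$cv, isi_stats(hi$train)$cv)
})

test_that("endogenous channel noise and an equivalent noisy current yield similar PRCs", {
  nz <- diffusion_coefficients(wb_k_scheme(n_channels = 300))
  n_chan <- conductance_neuron(noise = nz)
  n_curr <- conductance_neuron(current_noise_pA = 100)
  s1 <- run_closed_loop_session(n_chan, pid_config(50), sobol_scheduler(),
                                n_pulses = 450, seed = 4,
                                pulse_amplitude_pA = 150)
  s2 <- run_closed_loop_session(n_curr, pid_config(50), sobol_scheduler(),
                                n_pulses = 450, seed = 4,
                                pulse_amplitude_pA = 150)
  # comparable spiking variability by construction
  expect_lt(abs(session_isi_stats(s1)$cv - session_isi_stats(s2)$cv), 0.03)
  a <- session_prc(s1)
  b <- session_prc(s2)
  expect_gt(cor(a$z, b$z), 0.8)
})

test_that("exact Markov population matches binomial stationary statistics", {
  sch <- two_state_scheme(200, 200, n_channels = 2000)
  mk <- exact_markov_simulation(sch, duration = 5, dt = 1e-4, seed = 7)
  x <- mk$p_open
  # symmetric rates: stationary open fraction 1/2
  n_eff <- 5 / (2 / 400)  # duration / correlation time
  se_mean <- sqrt(0.25 / 2000) / sqrt(n_eff)
  expect_lt(abs(mean(x) - 0.5), 3 * se_mean * 3)  # generous: correlated samples
  # variance of the open fraction: p(1-p)/n
  expect_lt(abs(var(x) - 0.25 / 2000) / (0.25 / 2000), 0.1)
  # autocovariance decay time ~ 1/(alpha+beta)
  tau_hat <- fit_autocorrelation_time(x, 1e-4)
  expect_lt(abs(tau_hat - 1 / 400) / (1 / 400), 0.15)
  # step-size guard
  expect_error(exact_markov_simulation(sch, 0.1, dt = 1e-3), "decrease dt")
})

test_that("diffusion coefficients reproduce the two-state closed form", {
  a <- 100; b <- 300; n <- 1000
  dc <- diffusion_coefficients(two_state_scheme(a, b, n))
  p <- a / (a + b)
  expect_equal(nrow(dc), 1)
  expect_equal(dc$tau_s, 1 / (a + b), tolerance = 1e-12)
  expect_equal(dc$sigma^2, p * (1 - p) / n, tolerance = 1e-12)
  expect_equal(attr(dc, "p_open"), p, tolerance = 1e-12)

  # population scaling: quadrupling the channel count halves every sigma
  dc4 <- diffusion_coefficients(two_state_scheme(a, b, 4 * n))
  expect_equal(dc4$sigma, dc$sigma / 2, tolerance = 1e-12)
})

test_that("summed OU processes reproduce their analytic autocovariance", {
  spec <- diffusion_coefficients(five_state_scheme())
  tr <- simulate_diffusion_noise(spec, duration = 20, dt = 2e-5, seed = 8)
  lags <- c(0, spec$tau_s)
  emp <- autocovariance_at(tr$eta, round(lags / 2e-5))
  ana <- ou_sum_autocovariance(spec, lags)
  expect_true(all(abs(emp / ana - 1) < 0.1))
})

test_that("non-reversible or reducible schemes are rejected", {
  # unidirectional cycle: no detailed balance (complex eigenvalues)
  r <- matrix(0, 3, 3)
  r[1, 2] <- 100; r[2, 3] <- 100; r[3, 1] <- 100
  expect_error(diffusion_coefficients(kinetic_scheme(r, 3)),
               class = "prcclamp_error_scheme")
})

test_that("replay protocol recovers the PRC and is exactly repeatable", {
  nrn <- det_neuron()
  rp <- replay_prc(nrn, target_isi_s = 0.02, n_trials = 50, i_hold = 250,
                   pulse_amplitude_pA = 10, pulse_duration_s = 1e-4)
  zt <- prc_preset("peaked")(rp$phi)
  # small charge: linear-response regime, curve recovered within a few %
  expect_lt(max(abs(rp$z - zt)) / max(zt), 0.05)
  rp2 <- replay_prc(nrn, target_isi_s = 0.02, n_trials = 50, i_hold = 250,
                    pulse_amplitude_pA = 10, pulse_duration_s = 1e-4)
  expect_identical(rp$z, rp2$z)

  # vanishing amplitude: vanishing phase shifts
  rp0 <- replay_prc(nrn, target_isi_s = 0.02, n_trials = 10, i_hold = 250,
                    pulse_amplitude_pA = 1e-9, pulse_duration_s = 1e-4)
  expect_true(all(abs(rp0$z * rp0$charge_pC) < 1e-6))

  expect_error(replay_prc(nrn, target_isi_s = 0.5, n_trials = 5,
                          i_hold = 250, max_search_s = 5),
               class = "prcclamp_error_replay")
})

test_that("replay linear-response error grows with the pulse charge", {
  nrn <- det_neuron()
  errs <- vapply(c(10, 50, 200), function(amp) {
    rp <- replay_prc(nrn, target_isi_s = 0.02, n_trials = 30, i_hold = 250,
                     pulse_amplitude_pA = amp, pulse_duration_s = 5e-4)
    zt <- prc_preset("peaked")(rp$phi)
    sqrt(mean((rp$z - zt)^2)) / max(zt)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("replay works on the conductance surrogate", {
  nc <- conductance_neuron()
  rate <- firing_rate_at(nc, 55, duration = 1.5, transient = 0.5)
  rp <- replay_prc(nc, target_isi_s = 1 / rate, n_trials = 15, i_hold = 55,
                   pulse_amplitude_pA = 100, pulse_duration_s = 5e-4,
                   tol = 0.1)
  expect_gte(nrow(rp), 14)
  expect_true(all(is.finite(rp$z)))
  # a depolarising pulse advances (or at worst leaves) the closing AP
  expect_gt(mean(rp$z > -1e-9), 0.8)
})
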