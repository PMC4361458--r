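test_that("PID output follows the gain equation and the output clamp", {
  cfg <- pid_config(f_target = 50, g_p = 1, g_i = 0, g_d = 0)
  st <- pid_update(cfg, pid_state(), 5)
  expect_equal(st$i_holding, 5)

  # integral only: k identical errors telescope to g_i * k * e
  cfg_i <- pid_config(50, g_p = 0, g_i = 0.1, g_d = 0)
  st <- pid_state()
  for (k in 1:25) st <- pid_update(cfg_i, st, 4)
  expect_equal(st$i_holding, 0.1 * 25 * 4)

  # zero error history: zero output
  st0 <- pid_update(pid_config(50), pid_state(), 0)
  expect_equal(st0$i_holding, 0)

  # derivative term
  cfg_d <- pid_config(50, g_p = 0, g_i = 0, g_d = 2)
  st <- pid_update(cfg_d, pid_state(), 3)
  expect_equal(st$i_holding, 6)
  st <- pid_update(cfg_d, st, 3)
  expect_equal(st$i_holding, 0)
})

test_that("anti-windup freezes the integrator at the output clamp", {
  cfg <- pid_config(50, g_p = 0, g_i = 1, g_d = 0, i_min = -10, i_max = 10)
  st <- pid_state()
  for (k in 1:50) st <- pid_update(cfg, st, 5)
  expect_equal(st$i_holding, 10)
  expect_lte(st$err_sum, 10)  # frozen once saturated, no windup
  # recovery is immediate once the error reverses
  st <- pid_update(cfg, st, -3)
  expect_equal(st$i_holding, cfg$g_i * st$err_sum)
  expect_lt(st$i_holding, 10)
})

test_that("hold contract: no updates while held, release requires a hold", {
  cfg <- pid_config(50)
  st <- pid_update(cfg, pid_state(), 2)
  i0 <- st$i_holding
  st <- enter_hold(st)
  expect_warning(st2 <- pid_update(cfg, st, 50), "held")
  expect_equal(st2$i_holding, i0)
  st3 <- release_hold(st2)
  expect_false(st3$held)
  expect_error(release_hold(st3), class = "prcclamp_error_hold")
})

test_that("holding current is exactly constant inside perturbation windows", {
  s <- small_session()
  hc <- check_hold_contract(s)
  expect_equal(nrow(hc), nrow(s$pulses))
  expect_true(all(hc$i_range_pA == 0))
  expect_true(all(hc$n_spikes_in_window >= 3))
})

test_that("sessions deliver the requested schedule", {
  s <- small_session()
  expect_equal(nrow(s$pulses), 350)
  # one pulse per 6 APs: the session must span at least that many APs
  expect_gte(nrow(s$train), 6 * 350)
  # scheduled delays are the Sobol stream
  expect_equal(s$pulses$scheduled_delay, sobol_sequence(350, skip = 16))
  # every pulse strictly after its trigger AP
  expect_true(all(s$pulses$t_pulse_s > s$config$warmup_s))
})

test_that("the clamp reaches its target rate on both surrogates", {
  # the controller settles with a ~2 s envelope from the paper's gains, so
  # the post-transient mean is taken over a few tens of seconds
  for (ft in c(20, 50, 100)) {
    sp <- run_closed_loop_session(jitter_neuron(), pid_config(ft),
                                  sobol_scheduler(), n_pulses = 400, seed = 2)
    expect_lt(abs(session_rate(sp, after_s = 5) - ft) / ft, 0.02)
  }
  nz <- diffusion_coefficients(wb_k_scheme(n_channels = 300))
  ncn <- conductance_neuron(noise = nz)
  sc <- run_closed_loop_session(ncn, pid_config(50), sobol_scheduler(),
                                n_pulses = 400, seed = 2)
  expect_lt(abs(session_rate(sc, after_s = 5) - 50) / 50, 0.02)
})

test_that("an unreachable target aborts with a diagnostic", {
  # the phase neuron's rate tops out at 25 + 0.1 * i_max = 125 Hz
  expect_error(
    run_closed_loop_session(jitter_neuron(), pid_config(400),
                            sobol_scheduler(), n_pulses = 50, seed = 1,
                            max_duration = 20),
    class = "prcclamp_error_session")
})

test_that("the PID leaves the unperturbed ISI variability unchanged", {
  nrn <- jitter_neuron()
  s_on <- run_closed_loop_session(nrn, pid_config(50), sobol_scheduler(),
                                  n_pulses = 250, seed = 6)
  s_off <- run_closed_loop_session(nrn, pid_config(50), sobol_scheduler(),
                                   n_pulses = 250, seed = 6,
                                   pid_enabled = FALSE, i_const = 250)
  cv_on <- session_isi_stats(s_on)$cv
  cv_off <- session_isi_stats(s_off)$cv
  expect_lt(abs(cv_on - cv_off), 0.01)
})
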