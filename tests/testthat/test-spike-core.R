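test_that("spike trains validate ordering and finiteness", {
  expect_s3_class(spike_train(c(0.01, 0.02)), "spike_train")
  expect_error(spike_train(c(0.02, 0.01)), class = "prcclamp_error_spikes")
  expect_error(spike_train(c(0.01, 0.01)), class = "prcclamp_error_spikes")
  expect_error(spike_train(c(0, NA)), class = "prcclamp_error_spikes")
})

test_that("detect_spikes finds AP peaks at threshold crossings", {
  # flat trace: no crossing, empty train (not an error)
  flat <- tibble::tibble(time_s = seq(0, 0.1, by = 1 / 30000), v_mV = -60)
  expect_equal(nrow(detect_spikes(flat, threshold = -20)), 0)

  # three triangular spikes with peaks at 10/20/30 ms
  tr <- render_voltage_trace(c(0.010, 0.020, 0.030), duration = 0.05)
  det <- detect_spikes(tr, threshold = -20)
  expect_equal(det$time_s, c(0.010, 0.020, 0.030), tolerance = 1e-9)

  # refractory suppresses double counting of a noisy peak
  tr2 <- tr
  peak_i <- which.max(tr2$v_mV)
  tr2$v_mV[peak_i + 2] <- -30  # notch inside the first AP
  det2 <- detect_spikes(tr2, threshold = -20, refractory = 1e-3)
  expect_equal(nrow(det2), 3)

  expect_error(detect_spikes(flat[0, ], -20), class = "prcclamp_error_trace")
})

test_that("detection on simulator output recovers ground-truth spikes", {
  sim <- simulate_phase_neuron(jitter_neuron(), duration = 10, i_hold = 250,
                               seed = 4, render_trace = TRUE)
  det <- detect_spikes(sim$trace, threshold = -20)
  truth <- sim$train$time_s
  expect_equal(nrow(det), length(truth))
  # every detected peak within one sample (1/30 ms) of the true time
  expect_lt(max(abs(det$time_s - truth)), 1 / 30000 + 1e-12)
})

test_that("isi_stats computes mean, CV and rate over usable ISIs", {
  reg <- spike_train(seq(0, 0.1, by = 0.01))
  st <- isi_stats(reg)
  expect_equal(st$mean_isi_s, 0.01)
  expect_equal(st$cv, 0)
  expect_equal(st$rate_hz, 100)

  st2 <- isi_stats(spike_train(c(0, 0.008, 0.020)))
  expect_equal(st2$mean_isi_s, 0.01)
  expect_equal(st2$cv, 0.2, tolerance = 1e-12)

  expect_error(isi_stats(spike_train(0.01)), class = "prcclamp_error_spikes")
  # exclusion removes chosen intervals
  st3 <- isi_stats(spike_train(c(0, 0.01, 0.05, 0.06)), exclude = 2L)
  expect_equal(st3$mean_isi_s, 0.01)
})

test_that("unperturbed ISI selection drops pulse-bearing and following ISIs", {
  ts <- seq(0, 0.09, by = 0.01)  # 9 ISIs
  idx <- unperturbed_isi_indices(ts, pulse_times = 0.034)  # inside ISI 4
  expect_false(4 %in% idx)
  expect_false(5 %in% idx)
  expect_true(all(c(1, 2, 3, 6, 7, 8, 9) %in% idx))
})

test_that("phase-neuron jitter calibration yields the requested ISI CV", {
  sim <- simulate_phase_neuron(jitter_neuron(cv = 0.07), duration = 210,
                               i_hold = 250, seed = 9)
  st <- isi_stats(sim$train)
  expect_gt(st$n_isi, 9999)
  expect_lt(abs(st$cv - 0.07), 0.005)
})

test_that("online rate estimator has the right fixed point and bounds", {
  # constant ISI: monotone convergence to 1/T from any start
  f <- 0
  vals <- numeric(800)
  for (k in 1:800) {
    f <- update_rate_estimate(f, 0.02)
    vals[k] <- f
  }
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(f, 50, tolerance = 1e-6)

  # closed-form single step: isi = tau * ln 2 from 0 gives (1/isi)/2
  isi <- log(2)
  expect_equal(update_rate_estimate(0, isi, tau = 1), (1 / isi) / 2,
               tolerance = 1e-12)

  # convex combination: estimate stays between previous value and 1/isi
  set.seed(42)
  for (i in 1:50) {
    f0 <- runif(1, 0, 200)
    isi_k <- runif(1, 0.005, 0.2)
    f1 <- update_rate_estimate(f0, isi_k)
    expect_gte(f1, min(f0, 1 / isi_k) - 1e-12)
    expect_lte(f1, max(f0, 1 / isi_k) + 1e-12)
  }

  expect_error(update_rate_estimate(50, 0), class = "prcclamp_error_rate")
  expect_error(update_rate_estimate(50, -0.01), class = "prcclamp_error_rate")
})

test_that("rate estimator matches an independent step-by-step replay", {
  isis <- rep(c(0.008, 0.012), 250)
  # iterative path
  f <- 50
  for (x in isis) f <- update_rate_estimate(f, x, tau = 1)
  # independent recomputation from the closed-form unrolled recursion:
  # F_n = sum_k (1/isi_k)(1 - w_k) prod_{j>k} w_j + F_0 prod_j w_j
  w <- exp(-isis / 1)
  tail_prod <- rev(cumprod(rev(c(w[-1], 1))))
  f_direct <- sum((1 / isis) * (1 - w) * tail_prod) + 50 * prod(w)
  expect_equal(f, f_direct, tolerance = 1e-10)
})
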