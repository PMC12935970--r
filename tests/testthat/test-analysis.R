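# Trace and spike-train analysis.

test_that("spike detection: upward crossings with refractory hysteresis", {
  tr <- trace(0:6, c(-70, -70, 10, -70, -70, 20, -70))
  expect_equal(detect_spikes(tr, refractory = 2)$times, c(2, 5))
  expect_equal(length(detect_spikes(trace(0:9, rep(-70, 10)))$times), 0L)
  # plateau above threshold: one spike, no re-trigger without re-crossing
  plateau <- trace(seq(0, 14, 1), c(-70, rep(0, 10), -70, -70, 0, -70))
  expect_equal(detect_spikes(plateau, refractory = 2)$times, c(1, 13))
  expect_error(detect_spikes(trace(numeric(0), numeric(0))), "empty|length")
  expect_error(trace(c(0, 1, 1.5), c(1, 2, 3)), "uniform")
})

test_that("spike counting respects half-open windows", {
  st <- spike_train(c(10, 250, 499))
  expect_equal(count_spikes(st, c(0, 500)), 3L)
  expect_equal(count_spikes(st, c(0, 499)), 2L)
  expect_equal(count_spikes(st, c(500, 500)), 0L)
  expect_equal(count_spikes(spike_train(numeric(0)), c(0, 500)), 0L)
})

test_that("offset series pairs nearest spikes and drops unmatched ones", {
  A <- spike_train(c(10, 30, 50))
  B <- spike_train(c(15, 34, 52))
  ser <- spike_offset_series(A, B)
  expect_equal(ser$offset_ms, c(5, 4, 2))
  expect_equal(attr(ser, "dropped"), 0L)

  ident <- spike_offset_series(A, A)
  expect_true(all(ident$offset_ms == 0))

  expect_warning(empty <- spike_offset_series(A, spike_train(numeric(0))),
                 "no spikes")
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "dropped"), 3L)

  # antisymmetry on matched pairs
  serBA <- spike_offset_series(B, A)
  expect_equal(serBA$offset_ms, -ser$offset_ms)
})

test_that("synchronization time: hold count and no later excursions", {
  ser <- data.frame(t = 1:5 * 1000, offset_ms = c(5, 2, 0.4, 0.3, 0.2))
  expect_equal(synchronization_time(ser, tol = 0.5, hold = 3)$t_ms, 3000)
  all_low <- data.frame(t = 1:4 * 1000, offset_ms = rep(0.1, 4))
  expect_equal(synchronization_time(all_low, tol = 0.5)$t_ms, 1000)
  relapse <- data.frame(t = 1:5 * 1000, offset_ms = c(0.1, 0.1, 0.1, 0.1, 2))
  expect_false(synchronization_time(relapse, tol = 0.5)$reached)
  short <- data.frame(t = 1:2 * 1000, offset_ms = c(0.1, 0.1))
  expect_false(synchronization_time(short, tol = 0.5, hold = 3)$reached)
})

test_that("oscillation amplitude: sinusoids, constants, detrending", {
  t <- seq(0, 100, 0.1)
  pure <- trace(t, 3.7 * sin(2 * pi * t / 20))
  expect_equal(oscillation_amplitude(pure, period_ms = 20), 3.7,
               tolerance = 1e-9)
  flat <- trace(t, rep(2, length(t)))
  expect_equal(oscillation_amplitude(flat, period_ms = 20), 0,
               tolerance = 1e-12)
  drift <- trace(t, 2 * sin(2 * pi * t / 20) + 0.1 * t)
  expect_equal(oscillation_amplitude(drift, period_ms = 20), 2,
               tolerance = 0.01 * 2)
  expect_error(oscillation_amplitude(pure, window = c(0, 5), period_ms = 20),
               "shorter")
})

test_that("spike counts agree with a brute-force local-maxima oracle", {
  tr <- ode_trajectory(hh_model(), Is = -20, T_ms = 150, dt_ms = 0.01,
                       stride = 5L)
  n_detect <- count_spikes(detect_spikes(trace(tr$t, tr$v)))
  v <- tr$v
  maxima <- which(v[-c(1, length(v))] > v[-((length(v) - 1):length(v))] &
                    v[-c(1, length(v))] >= v[-(1:2)]) + 1L
  n_oracle <- sum(v[maxima] > -20)
  expect_equal(n_detect, n_oracle)
  expect_gt(n_detect, 5)
})
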