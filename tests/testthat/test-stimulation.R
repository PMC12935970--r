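# Stimulation protocols: somatic current density and electrode boundary flux.

test_that("somatic stimulus targets its region, cell and time window", {
  s <- somatic_stimulus(0.5, region = "SOMA", cell = 1L, window_ms = c(10, 20))
  expect_equal(somatic_current_density(s, 15, "SOMA", 1), 0.5)
  expect_equal(somatic_current_density(s, 15, "AIS", 1), 0)
  expect_equal(somatic_current_density(s, 15, "SOMA", 2), 0)
  expect_equal(somatic_current_density(s, 25, "SOMA", 1), 0)
  expect_equal(somatic_current_density(s, 5, "SOMA", 1), 0)
  # default window is always-on
  s2 <- somatic_stimulus(-27)
  expect_equal(somatic_current_density(s2, 1e6, "SOMA", 1), -27)
})

test_that("electrode boundary flux follows the protocol formulas", {
  # constant: -Ie/Ae with the measured sphere area
  s <- electrode_stimulus(0.1, "constant", Ae_cm2 = 3.1416e-6)
  expect_equal(electrode_boundary_flux(s, 0), -3.183e4, tolerance = 1e-3)

  # sinusoidal: +Ie/Ae sin(2 pi f t), t converted from ms to seconds
  s5 <- electrode_stimulus(0.1, "sinusoidal", f_Hz = 5, Ae_cm2 = 3.1416e-6)
  expect_equal(electrode_boundary_flux(s5, 0), 0)
  expect_equal(electrode_boundary_flux(s5, 50), 0.1 / 3.1416e-6,
               tolerance = 1e-10)   # sin(pi/2) = 1 at t = 50 ms
  s30 <- electrode_stimulus(0.1, "sinusoidal", f_Hz = 30, Ae_cm2 = 1e-6)
  expect_equal(electrode_boundary_flux(s30, 1000 / 30 / 4), 0.1 / 1e-6,
               tolerance = 1e-9)    # quarter period of a 30 Hz drive

  # explicit sign convention switch flips both protocols
  sf <- electrode_stimulus(0.1, "constant", Ae_cm2 = 1e-6,
                           sign_convention = -1)
  expect_equal(electrode_boundary_flux(sf, 0), +0.1 / 1e-6)

  expect_error(electrode_boundary_flux(electrode_stimulus(0.1, "constant"), 0),
               "Ae")
  expect_error(electrode_stimulus(0.1, "sinusoidal"), "f_Hz")
})

test_that("positive somatic current suppresses firing, negative promotes it", {
  # space-clamped three-point grid on the excitable fixture model: spike
  # count is non-increasing in Is
  counts <- vapply(c(-30, 0, 10), function(Is) {
    tr <- ode_trajectory(hh_model(), region = "SOMA", Is = Is, T_ms = 120,
                         dt_ms = 0.01, stride = 5L)
    count_spikes(detect_spikes(trace(tr$t, tr$v)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
  expect_equal(counts[3], 0L)
})
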