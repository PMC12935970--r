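# Ionic models, Rush-Larsen integration and the membrane ODE sub-system.

test_that("ionic current density evaluates channels, leaks and regions", {
  expect_equal(evaluate_iion(passive_model(), -60), 1.0)
  zero <- passive_model(g_mS_per_cm2 = 0)
  expect_equal(evaluate_iion(zero, -60), 0)
  expect_error(evaluate_iion(hh_model(), -60, region = "MYELIN"), "MYELIN")

  # region-dependent densities select the right table entries
  m <- fixture_ais_model()
  st <- membrane_state(m, "AIS", v = 0)
  i_ais <- evaluate_iion(m, 0, st$s, "AIS")
  i_soma <- evaluate_iion(m, 0, st$s, "SOMA")
  expect_gt(abs(i_ais), abs(i_soma))
})

test_that("ionic current vanishes at the relaxed resting state", {
  ss <- hh_rest()
  expect_true(ss$converged)
  st <- membrane_state(hh_model(), "SOMA", v = ss$v, s = ss$s)
  expect_lt(abs(evaluate_iion(hh_model(), ss$v, st$s, "SOMA")), 1e-6)
})

test_that("Rush-Larsen update equals the frozen-voltage closed form", {
  g <- gate_spec("x", inf = "1", tau = "1")
  expect_equal(rush_larsen_gate_update(g, 0, 0, 1), 1 - exp(-1),
               tolerance = 1e-12)

  # fixed point: s0 at steady state stays put for any dt
  gm <- hh_model()$channels[[1]]$gates[[1]]
  it <- gate_inf_tau(gm, -50)
  for (dt in c(0.001, 0.1, 10)) {
    expect_equal(rush_larsen_gate_update(gm, it$inf, -50, dt), it$inf,
                 tolerance = 1e-14)
  }

  # exactness: matches s_inf + (s0 - s_inf) exp(-dt/tau) to machine precision
  s0 <- 0.2; v <- -40; dt <- 0.37
  it <- gate_inf_tau(gm, v)
  expect_equal(rush_larsen_gate_update(gm, s0, v, dt),
               it$inf + (s0 - it$inf) * exp(-dt / it$tau), tolerance = 1e-15)

  # dt -> 0 limit reproduces the explicit derivative
  dt <- 1e-4
  s1 <- rush_larsen_gate_update(gm, s0, v, dt)
  expect_equal((s1 - s0) / dt, (it$inf - s0) / it$tau, tolerance = 1e-3)
})

test_that("passive membrane follows the RC closed form", {
  st <- membrane_state(passive_model(), "SOMA", v = -60)
  out <- membrane_ode_step(passive_model(), st, Is = 0, dt_global = 10,
                           dt_sub = 0.001)
  # tau = Cm/gL = 10 ms, so v(10 ms) = EL + 10 exp(-1)
  expect_equal(out$v, -70 + 10 * exp(-1), tolerance = 1e-3)
})

test_that("balanced stimulus holds the membrane potential constant", {
  m <- passive_model()
  st <- membrane_state(m, "SOMA", v = -60)
  i0 <- evaluate_iion(m, -60)
  out <- membrane_ode_step(m, st, Is = -i0, dt_global = 5, dt_sub = 0.01)
  expect_equal(out$v, -60, tolerance = 1e-12)
})

test_that("quiescent HH stays at rest; independent reference agrees", {
  ss <- hh_rest()
  st <- membrane_state(hh_model(), "SOMA", v = ss$v, s = ss$s)
  out <- membrane_ode_step(hh_model(), st, Is = 0, dt_global = 50,
                           dt_sub = 0.01)
  expect_lt(abs(out$v - ss$v), 0.5)
  ref <- hh_reference(50, v0 = ss$v, gates0 = c(m = ss$s[1, "Na.m"],
                                                h = ss$s[1, "Na.h"],
                                                n = ss$s[1, "K.n"]))
  expect_lt(abs(out$v - ref$v[nrow(ref)]), 0.1)
})

test_that("membrane ODE step is first-order accurate in the substep", {
  ss <- hh_rest()
  run <- function(dt) {
    st <- membrane_state(hh_model(), "SOMA", v = ss$v, s = ss$s)
    membrane_ode_step(hh_model(), st, Is = -20, dt_global = 5, dt_sub = dt)$v
  }
  ref <- run(0.001)
  e1 <- abs(run(0.02) - ref)
  e2 <- abs(run(0.01) - ref)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("gates stay in [0, 1] along arbitrary bounded voltage trajectories", {
  set.seed(42)
  m <- hh_model()
  st <- membrane_state(m, rep("SOMA", 5), v = runif(5, -120, 60))
  S <- st$s
  for (k in 1:200) {
    v <- runif(5, -120, 60)
    for (cn in colnames(S)) {
      S[, cn] <- rush_larsen_gate_update(st$runtime$gates[[cn]], S[, cn], v,
                                         dt = 0.5)
    }
    expect_true(all(S >= 0 & S <= 1))
  }
})

test_that("excitability threshold: strong brief pulse fires, weak does not", {
  ss <- hh_rest()
  run_pulse <- function(amp) {
    st <- membrane_state(hh_model(), "SOMA", v = ss$v, s = ss$s)
    tr_v <- numeric(0)
    for (k in 1:2000) {  # 20 ms at dt 0.01
      t <- (k - 1) * 0.01
      st <- membrane_ode_step(hh_model(), st, Is = if (t < 1) amp else 0,
                              dt_global = 0.01)
      tr_v <- c(tr_v, st$v)
    }
    count_spikes(detect_spikes(trace(seq_along(tr_v) * 0.01, tr_v)))
  }
  expect_equal(run_pulse(-200), 1L)
  expect_equal(run_pulse(-5), 0L)
  # independent reference integration agrees on both counts
  for (amp in c(-200, -5)) {
    ref <- hh_reference(20, v0 = ss$v,
                        Is = function(t) ifelse(t < 1, amp, 0),
                        gates0 = c(m = ss$s[1, "Na.m"], h = ss$s[1, "Na.h"],
                                   n = ss$s[1, "K.n"]))
    n_ref <- count_spikes(detect_spikes(trace(ref$t, ref$v)))
    expect_equal(n_ref, if (amp == -200) 1L else 0L)
  }
})

test_that("steady_state contracts: passive exact, HH near -65, pacemaker flagged", {
  ssp <- steady_state(passive_model(), horizon_ms = 200, dt_ms = 0.01)
  expect_equal(ssp$v, -70, tolerance = 1e-6)
  expect_true(ssp$converged)

  ss <- hh_rest()
  expect_lt(abs(ss$v - (-65)), 0.5)

  pace <- steady_state(fixture_pacemaker_model(), region = "AIS",
                       horizon_ms = 300, dt_ms = 0.02)
  expect_false(pace$converged)
})

test_that("model files load, validate and round trip", {
  path <- system.file("models", "hh.yaml", package = "emisim")
  m <- load_model_spec(path)
  ref <- hh_model()
  v <- seq(-100, 40, by = 7)
  st <- membrane_state(ref, rep("SOMA", length(v)), v = v)
  expect_equal(evaluate_iion(m, v, st$s, "SOMA"),
               evaluate_iion(ref, v, st$s, "SOMA"), tolerance = 1e-12)

  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(m, f)
  m2 <- load_model_spec(f)
  expect_equal(evaluate_iion(m2, v, st$s, "AIS"),
               evaluate_iion(m, v, st$s, "AIS"), tolerance = 1e-12)
})

test_that("malformed model files are rejected with informative errors", {
  good <- yaml::read_yaml(system.file("models", "hh.yaml", package = "emisim"))
  f <- withr::local_tempfile(fileext = ".yaml")

  bad <- good
  bad$channels[[1]]$conductance_mS_per_cm2 <- list(SOMA2 = 120)
  yaml::write_yaml(bad, f)
  expect_error(load_model_spec(f), "SOMA2")

  bad <- good
  bad$channels[[1]]$gates[[1]]$alpha <- "0.1 * system('rm')"
  yaml::write_yaml(bad, f)
  expect_error(load_model_spec(f), "grammar")

  bad <- good
  bad$channels[[1]]$gates[[1]]$alpha <- "0.1 * (v +"
  yaml::write_yaml(bad, f)
  expect_error(load_model_spec(f), "unparsable")

  bad <- good
  bad$unknown_field <- 1
  yaml::write_yaml(bad, f)
  expect_error(load_model_spec(f), "unknown key")

  # tau <= 0 on the validation grid
  expect_error(gate_spec("bad", inf = "0.5", tau = "v"), "tau")
  # MYELIN must stay passive
  expect_error(channel_spec("Na", 50, c(MYELIN = 10)), "MYELIN")
})
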