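# Shared fixtures, memoized so expensive meshes/runs are built once per
# test session.

.fix <- new.env(parent = emptyenv())
memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

tiny_cell_params <- function(h = 10) {
  cell_geometry(soma_um = c(10, 10, 10), axon_segments = NULL,
                margin_um = 30, h_um = h)
}

tiny_cell_mesh <- function() memo("tiny_cell", build_single_cell_mesh(tiny_cell_params()))

small_cell_mesh <- function() {
  memo("small_cell", build_single_cell_mesh(
    cell_geometry(margin_um = 50, h_um = 10)))
}

small_electrode_mesh <- function() {
  memo("small_electrode", build_single_cell_mesh(
    cell_geometry(margin_um = 50, h_um = 10),
    electrode = list(center_um = c(70, 0, 0), radius_um = 5)))
}

hh_rest <- function() {
  memo("hh_rest", steady_state(hh_model(), horizon_ms = 1000, dt_ms = 0.02))
}

# Independent reference integration of the standard Hodgkin-Huxley point
# model, written directly from the textbook rate equations and solved with
# deSolve's stiff integrator (not the package's Rush-Larsen path).
hh_reference <- function(T_ms, v0 = -65, Is = function(t) 0, gates0 = NULL) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-7, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  am <- function(v) 0.1 * vtrap(-(v + 40), 10)
  bm <- function(v) 4 * exp(-(v + 65) / 18)
  ah <- function(v) 0.07 * exp(-(v + 65) / 20)
  bh <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  an <- function(v) 0.01 * vtrap(-(v + 55), 10)
  bn <- function(v) 0.125 * exp(-(v + 65) / 80)
  deriv <- function(t, y, p) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    iion <- 120 * m^3 * h * (v - 50) + 36 * n^4 * (v + 77) + 0.3 * (v + 54.387)
    list(c(-(iion + Is(t)),
           am(v) * (1 - m) - bm(v) * m,
           ah(v) * (1 - h) - bh(v) * h,
           an(v) * (1 - n) - bn(v) * n))
  }
  g0 <- if (is.null(gates0)) {
    c(m = am(v0) / (am(v0) + bm(v0)), h = ah(v0) / (ah(v0) + bh(v0)),
      n = an(v0) / (an(v0) + bn(v0)))
  } else gates0
  out <- deSolve::lsoda(c(v = v0, g0), seq(0, T_ms, by = 0.05), deriv,
                        NULL, rtol = 1e-10, atol = 1e-10)
  data.frame(t = out[, 1], v = out[, 2], m = out[, 3], h = out[, 4],
             n = out[, 5])
}

# Peak absolute deviation from zero of a trace column after an initial
# settling window.
peak_abs <- function(res, col, after_ms = 1) {
  max(abs(res$traces[[col]][res$traces$t_ms > after_ms]))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
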