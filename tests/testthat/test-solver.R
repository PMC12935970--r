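# Assembly and the coupled elliptic/splitting solver.

cube_mesh <- function() {
  memo("cube", build_box_mesh(seq(0, 50, 10), seq(0, 50, 10), seq(0, 50, 10)))
}

tiny_cache <- function(model = passive_model(), dt = 0.01, stimuli = list()) {
  assemble_operators(emi_problem(tiny_cell_mesh(), model = model,
                                 stimuli = stimuli, dt_ms = dt, T_end_ms = 1))
}

test_that("extracellular stiffness is a Laplacian: zero row sums, linear in sigma", {
  p1 <- emi_problem(cube_mesh(), sigma = conductivities(5, 1), T_end_ms = 0)
  p2 <- emi_problem(cube_mesh(), sigma = conductivities(5, 2), T_end_ms = 0)
  c1 <- assemble_operators(p1)
  A1 <- c1$A
  A2 <- assemble_operators(p2)$A
  # rows of vertices not touching the Dirichlet boundary see the complete
  # Laplacian stencil, whose row sum vanishes
  V <- cm_to_um(cube_mesh()$vertices)
  deep <- which(c1$e_map > 0 &
                  apply(V >= 20 - 1e-9 & V <= 30 + 1e-9, 1, all))
  rs <- as.numeric(A1 %*% rep(1, nrow(A1)))[c1$e_map[deep]]
  expect_lt(max(abs(rs)), 1e-12 * max(abs(A1)))
  expect_equal(as.numeric(2 * A1), as.numeric(A2), tolerance = 1e-14)
})

test_that("lumped membrane mass recovers the total membrane area per cell", {
  cache <- tiny_cache()
  fg <- facet_geometry(tiny_cell_mesh())
  expect_rel_equal(sum(cache$mem[[1]]$area), sum(fg$membrane$area), 1e-12)
})

test_that("homogeneous problem has the trivial solution", {
  cache <- tiny_cache()
  st <- emi_initial_state(cache)
  st$mem[[1]]$v[] <- 0
  st$x[] <- 0
  st <- pde_step(cache, st, t = 0)
  expect_lt(max(abs(st$x)), 1e-12)
  expect_lt(max(abs(st$Im[[1]])), 1e-12)
})

test_that("membrane current conserves charge over each closed cell", {
  # soma-driven cell with a distinct AIS: the region-dependent densities
  # and targeted drive create genuine transmembrane current loops (a
  # uniform cell is space-clamped and carries none)
  cache <- memo("active_cache", assemble_operators(
    emi_problem(small_cell_mesh(), model = fixture_ais_model(),
                stimuli = list(somatic_stimulus(-30)), dt_ms = 0.01,
                T_end_ms = 1)))
  st <- emi_initial_state(cache)
  worst <- 0; biggest <- 0
  for (k in 1:500) {   # 5 ms: through the first action potential
    st <- advance(cache, st)
    mc <- cache$mem[[1]]
    tot <- abs(sum(st$Im[[1]] * mc$area))
    scale <- sum(abs(st$Im[[1]]) * mc$area)
    biggest <- max(biggest, scale)
    # below ~1e-6 uA the currents are pure roundoff and the relative
    # measure is meaningless
    if (scale > 1e-6) worst <- max(worst, tot / scale)
  }
  expect_gt(biggest, 1e-6)   # the cell actually fired
  expect_lt(worst, 1e-8)
})

test_that("resting passive cell is a fixed point and perturbations decay", {
  cache <- tiny_cache()
  st <- emi_initial_state(cache)
  st1 <- advance(cache, st)
  expect_lt(max(abs(st1$mem[[1]]$v - st$mem[[1]]$v)), 1e-10)

  # dissipativity: deviation from EL never grows
  st$mem[[1]]$v <- st$mem[[1]]$v + 5
  dev <- max(abs(st$mem[[1]]$v + 70))
  for (k in 1:20) {
    st <- advance(cache, st)
    dev_new <- max(abs(st$mem[[1]]$v + 70))
    expect_lte(dev_new, dev + 1e-12)
    dev <- dev_new
  }
})

test_that("v = ui - ue holds at membrane vertices after the elliptic solve", {
  cache <- tiny_cache(model = hh_model(),
                      stimuli = list(somatic_stimulus(-30)))
  st <- emi_initial_state(cache)
  for (k in 1:5) st <- advance(cache, st)
  mc <- cache$mem[[1]]
  gap <- st$x[mc$i_idx] - st$x[mc$e_idx] - st$mem[[1]]$v
  expect_lt(max(abs(gap)), 1e-9)
})

test_that("closure-form and direct P1 fluxes converge to each other under refinement", {
  # The closure form (Cm/dt)(v - v*) is the variationally consistent,
  # exactly conservative discrete flux; the elementwise gradient flux is a
  # different discretization of the same conormal derivative. On a smooth
  # resolved field they agree to O(h): check the deviation halves when h
  # does, and that both conserve total current over the closed cell.
  run_at <- function(h) {
    mesh <- build_single_cell_mesh(cell_geometry(soma_um = c(10, 10, 10),
                                                 axon_segments = NULL,
                                                 margin_um = 10, h_um = h))
    cache <- assemble_operators(emi_problem(mesh, model = passive_model(),
                                            dt_ms = 0.01, T_end_ms = 1))
    st <- emi_initial_state(cache)
    st$mem[[1]]$v <- -70 + 2 * cm_to_um(cache$mem[[1]]$pos[, 1])
    st <- pde_step(cache, st, t = 0)
    f <- membrane_current_from_solution(st, cache)$facets
    direct <- facet_flux_direct(st, cache)
    list(median_dev = stats::median(abs(f$Im_uA_per_cm2 - direct)) /
           max(abs(f$Im_uA_per_cm2)),
         closure_total = sum(f$Im_uA_per_cm2 * f$area_cm2),
         direct_total = sum(direct * f$area_cm2),
         scale = sum(abs(f$Im_uA_per_cm2) * f$area_cm2))
  }
  coarse <- run_at(2.5)
  fine <- run_at(1.25)
  expect_gt(coarse$median_dev / fine$median_dev, 1.4)
  expect_lt(fine$median_dev, 0.25)
  for (r in list(coarse, fine)) {
    expect_lt(abs(r$closure_total), 1e-10 * r$scale)
    expect_lt(abs(r$direct_total), 1e-8 * r$scale)
  }
})

test_that("membrane current accessor requires a completed elliptic solve", {
  cache <- tiny_cache()
  st <- emi_initial_state(cache)
  expect_error(membrane_current_from_solution(st, cache), "pde_step")
})

test_that("electrode Neumann data injects exactly the requested current", {
  mesh <- small_electrode_mesh()
  stim <- electrode_stimulus(0.1, "constant", Ae_cm2 = mesh$electrode$area_cm2)
  fg <- facet_geometry(mesh)
  el <- mesh$boundary$label == "ELECTRODE"
  total <- electrode_boundary_flux(stim, t = 5) * sum(fg$boundary$area[el])
  expect_rel_equal(total, -0.1, 1e-12)
})

test_that("point-source potential follows the analytic formula", {
  expect_equal(analytic_point_source(0.1, 3, 2e-3), -1.3263, tolerance = 1e-4)
  expect_equal(analytic_point_source(0, 3, 1e-3), 0)
  expect_equal(analytic_point_source(0.2, 3, 2e-3),
               2 * analytic_point_source(0.2, 3, 4e-3), tolerance = 1e-14)
  expect_error(analytic_point_source(0.1, 3, 0), "positive")
})

test_that("mirrored membrane data produce mirrored fields on the two-cell mesh", {
  mesh <- memo("mirror_mesh",
               build_two_cell_mesh(tiny_cell_params(), gap_um = 10))
  prob <- emi_problem(mesh, model = passive_model(), T_end_ms = 1)
  cache <- assemble_operators(prob)
  st <- emi_initial_state(cache)
  # asymmetric membrane state: depolarize cell 1 only, then swap cells
  st$mem[[1]]$v[] <- -50
  st$mem[[2]]$v[] <- -70
  stA <- pde_step(cache, st, t = 0)
  st$mem[[1]]$v[] <- -70
  st$mem[[2]]$v[] <- -50
  stB <- pde_step(cache, st, t = 0)
  # ue fields are mirror images: compare via mirrored extracellular probes
  for (dx in c(15, 35)) {
    pA <- locate_point(mesh, um_to_cm(c(dx, 0, 0)))
    pB <- locate_point(mesh, c(2 * mesh$mirror_plane_cm - um_to_cm(dx), 0, 0))
    uA <- sum(pA$weights * stA$x[cache$e_map[mesh$tets[pA$tet, ]]])
    uB <- sum(pB$weights * stB$x[cache$e_map[mesh$tets[pB$tet, ]]])
    expect_equal(uA, uB, tolerance = 1e-8)
  }
  # and the membrane potentials swap exactly
  expect_equal(sort(stA$mem[[1]]$v), sort(stB$mem[[2]]$v), tolerance = 1e-8)
})

test_that("simulations are deterministic and respect T_end and strides", {
  prob <- emi_problem(tiny_cell_mesh(), model = hh_model(),
                      stimuli = list(somatic_stimulus(-30)),
                      T_end_ms = 2,
                      probes = list(probe("v", "v", cell = 1, region = "SOMA")))
  r1 <- run_simulation(prob)
  r2 <- run_simulation(prob)
  expect_identical(r1$traces, r2$traces)

  p0 <- emi_problem(tiny_cell_mesh(), model = passive_model(), T_end_ms = 0,
                    probes = list(probe("v", "v", cell = 1, region = "SOMA")))
  r0 <- run_simulation(p0)
  expect_equal(nrow(r0$traces), 1L)       # initial state echo only
  expect_equal(r0$traces$v[1], -70)
  expect_error(emi_problem(tiny_cell_mesh(), T_end_ms = 0.015, dt_ms = 0.01),
               "multiple")
})

test_that("quiescent coupled cell stays within 1 mV of the ODE resting state", {
  prob <- emi_problem(tiny_cell_mesh(), model = hh_model(), T_end_ms = 10,
                      probes = list(probe("v", "v", cell = 1, region = "SOMA")))
  res <- run_simulation(prob)
  expect_lt(max(abs(res$traces$v - hh_rest()$v)), 1)
})

test_that("open-loop point-source reconstruction matches its closed form", {
  # single facet of area-current -0.1 uA at the origin, probe at 20 um
  tr <- mie_extracellular_potential(matrix(-1e5, 1, 1),           # uA/cm^2
                                    matrix(0, 1, 3), 1e-6, 3,
                                    matrix(c(2e-3, 0, 0), 1))
  expect_equal(tr[[1]]$value, -1.3263, tolerance = 1e-4)

  # equal and opposite sources symmetric about the probe cancel
  tr2 <- mie_extracellular_potential(matrix(c(1e5, -1e5), 1, 2),
                                     rbind(c(-1e-3, 0, 0), c(1e-3, 0, 0)),
                                     c(1e-6, 1e-6), 3, matrix(0, 1, 3))
  expect_equal(tr2[[1]]$value, 0, tolerance = 1e-12)

  expect_equal(mie_extracellular_potential(matrix(0, 1, 1), matrix(0, 1, 3),
                                           1e-6, 3, matrix(c(1e-3, 0, 0), 1))[[1]]$value, 0)
  expect_error(mie_extracellular_potential(matrix(1, 1, 1), matrix(0, 1, 3),
                                           1e-6, 3, matrix(0, 1, 3)),
               "coincides")
})

test_that("a quiescent closed cell produces a negligible reconstructed potential", {
  cache <- tiny_cache(model = hh_model())
  st <- emi_initial_state(cache)
  for (k in 1:10) st <- advance(cache, st)
  imc <- membrane_current_from_solution(st, cache)
  tr <- mie_extracellular_potential(
    matrix(imc$facets$Im_uA_per_cm2, 1), as.matrix(imc$facets[, c("x_cm", "y_cm", "z_cm")]),
    imc$facets$area_cm2, 3, matrix(um_to_cm(c(25, 0, 0)), 1))
  expect_lt(abs(tr[[1]]$value), 1e-3)
})
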