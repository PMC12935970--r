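# Mesh construction, tagging and validation.

test_that("discrete membrane area matches the closed-form box-union area", {
  # soma 20^3 with a 40x2x2 AIS axon: union surface area in cm^2
  analytic <- (6 * 20^2 - 2 * 2 + 4 * 40 * 2 + 2 * 2) * 1e-8
  for (h in c(5, 2.5)) {
    p <- cell_geometry(soma_um = c(20, 20, 20), axon_cross_um = c(2, 2),
                       axon_segments = data.frame(region = "AIS", length_um = 40),
                       margin_um = 20, h_um = h)
    m <- build_single_cell_mesh(p)
    area <- sum(facet_geometry(m)$membrane$area)
    # grid planes are snapped to the box faces, so the discrete surface is
    # exact (well inside the O(h * perimeter) tolerance)
    expect_rel_equal(area, analytic, 1e-10)
  }
})

test_that("a 10 um cubic cell has 6e-6 cm^2 of membrane", {
  fg <- facet_geometry(tiny_cell_mesh())
  expect_rel_equal(sum(fg$membrane$area), 6e-6, 1e-10)
})

test_that("generated meshes satisfy all structural invariants", {
  for (mesh in list(tiny_cell_mesh(), small_electrode_mesh())) {
    expect_true(validate_tagged_mesh(mesh))
    expect_true(all(tet_signed_volumes(mesh$vertices, mesh$tets) > 0))
  }
})

test_that("area-weighted membrane normals sum to zero over each closed cell", {
  mesh <- small_electrode_mesh()
  fg <- facet_geometry(mesh)
  for (cell in unique(mesh$membrane$cell)) {
    sel <- mesh$membrane$cell == cell
    s <- colSums(fg$membrane$area[sel] * fg$membrane$normal[sel, ])
    expect_lt(sqrt(sum(s^2)), 1e-12 * sum(fg$membrane$area[sel]))
  }
})

test_that("membrane normals point from the intracellular to the extracellular side", {
  mesh <- tiny_cell_mesh()
  fg <- facet_geometry(mesh)
  d <- tet_centroids(mesh, mesh$membrane$extra_tet) -
    tet_centroids(mesh, mesh$membrane$intra_tet)
  expect_true(all(rowSums(fg$membrane$normal * d) > 0))
})

test_that("electrode handling: cavity tagging, measured area, absence", {
  mesh <- small_electrode_mesh()
  expect_gt(sum(mesh$boundary$label == "ELECTRODE"), 0)
  el <- mesh$boundary$label == "ELECTRODE"
  expect_rel_equal(mesh$electrode$area_cm2,
                   sum(facet_geometry(mesh)$boundary$area[el]), 1e-12)
  expect_equal(sum(small_cell_mesh()$boundary$label == "ELECTRODE"), 0)
})

test_that("impossible geometries are rejected", {
  # margin smaller than two element layers
  expect_error(build_single_cell_mesh(cell_geometry(margin_um = 5, h_um = 5)),
               "margin")
  # electrode overlapping the cell volume
  expect_error(build_single_cell_mesh(
    cell_geometry(margin_um = 50, h_um = 10),
    electrode = list(center_um = c(30, 0, 0), radius_um = 5)), "overlap")
  # electrode outside the domain
  expect_error(build_single_cell_mesh(
    cell_geometry(margin_um = 30, h_um = 10),
    electrode = list(center_um = c(75, 0, 0), radius_um = 5)),
    "fit strictly inside")
  # touching cells
  expect_error(build_two_cell_mesh(tiny_cell_params(), gap_um = 0), "touch")
})

test_that("two-cell meshes are mirror symmetric with the requested gap", {
  p <- cell_geometry(margin_um = 30, h_um = 10)
  mesh <- build_two_cell_mesh(p, gap_um = 10)
  expect_true(validate_tagged_mesh(mesh))
  V <- mesh$vertices
  Vr <- cbind(2 * mesh$mirror_plane_cm - V[, 1], V[, 2], V[, 3])
  o1 <- order(round(V[, 1], 12), round(V[, 2], 12), round(V[, 3], 12))
  o2 <- order(round(Vr[, 1], 12), round(Vr[, 2], 12), round(Vr[, 3], 12))
  expect_lt(max(abs(V[o1, ] - Vr[o2, ])), 1e-12)

  # minimum AIS-to-AIS distance equals the gap
  a1 <- membrane_vertices(mesh, cell = 1, region = "AIS")
  a2 <- membrane_vertices(mesh, cell = 2, region = "AIS")
  d <- min(outer(V[a1, 1], V[a2, 1], function(a, b) abs(a - b)))
  expect_rel_equal(cm_to_um(d), 10, 1e-9)

  # a 1 um gap with a finer local layer still yields extracellular space
  # between the cells
  m2 <- build_two_cell_mesh(p, gap_um = 1, gap_h_um = 0.5)
  probe_tet <- locate_point(m2, c(m2$mirror_plane_cm, 0, 0))$tet
  expect_equal(m2$tet_sub[probe_tet], 0L)
})

test_that("MSH round trip preserves geometry and tags", {
  p <- cell_geometry(soma_um = c(10, 10, 10),
                     axon_segments = data.frame(region = c("AIS", "MYELIN", "RANVIER"),
                                                length_um = c(10, 10, 5)),
                     axon_cross_um = c(2, 2), margin_um = 25, h_um = 5)
  mesh <- build_single_cell_mesh(p, electrode = list(center_um = c(40, 0, 0),
                                                     radius_um = 3))
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, f)
  back <- read_msh(f)
  expect_equal(nrow(back$tets), nrow(mesh$tets))
  expect_equal(sort(as.vector(back$vertices)), sort(as.vector(mesh$vertices)),
               tolerance = 1e-12)
  expect_equal(as.list(table(back$membrane$region)),
               as.list(table(mesh$membrane$region)))
  expect_equal(as.list(table(back$boundary$label)),
               as.list(table(mesh$boundary$label)))
  expect_rel_equal(back$electrode$area_cm2, mesh$electrode$area_cm2, 1e-12)
})

test_that("MSH validation rejects missing groups and open membranes", {
  mesh <- tiny_cell_mesh()
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, f)
  txt <- readLines(f)
  # drop the "outer" physical name
  bad1 <- withr::local_tempfile(fileext = ".msh")
  i <- grep('"outer"', txt)
  n <- grep("^\\$PhysicalNames$", txt) + 1L
  txt1 <- txt[-i]
  txt1[n] <- as.character(as.integer(txt1[n]) - 1L)
  writeLines(txt1, bad1)
  expect_error(read_msh(bad1), "outer")

  # remove one membrane facet -> open membrane edge
  broken <- mesh
  broken$membrane$verts <- broken$membrane$verts[-1, , drop = FALSE]
  for (fld in c("cell", "region", "intra_tet", "extra_tet")) {
    broken$membrane[[fld]] <- broken$membrane[[fld]][-1]
  }
  bad2 <- withr::local_tempfile(fileext = ".msh")
  write_msh(broken, bad2)
  expect_error(read_msh(bad2), "not closed")
})

test_that("VTU export writes named arrays and validates lengths", {
  mesh <- tiny_cell_mesh()
  f <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, list(ue = seq_len(nrow(mesh$vertices)) * 0.1), f)
  txt <- readLines(f)
  expect_true(any(grepl('Name="ue"', txt)))
  expect_true(any(grepl('Name="subdomain"', txt)))
  f2 <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, list(), f2)           # geometry-only file
  expect_true(any(grepl("UnstructuredGrid", readLines(f2))))
  expect_error(write_vtu(mesh, list(bad = 1:7), f2), "length")
})
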