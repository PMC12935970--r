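# Structured mesh generation for idealized box neurons.
#
# The builder voxelizes a rectilinear grid whose planes are snapped to every
# geometric feature (cell part boundaries, electrode extent, two-cell gap
# planes), then splits each hexahedral cell into 6 tetrahedra with the Kuhn
# template, which is face-conforming across neighboring voxels. Because grid
# planes coincide with box faces, the discrete membrane surface (and hence
# its area) is exact for box-union cells; thin features such as a 2 um axon
# or a 1 um inter-cell gap always receive at least one element layer
# regardless of the nominal target size h.

#' Idealized cell geometry parameters
#'
#' Describes a box-union neuron: a cuboid soma, an optional dendrite stub
#' extending in the -x direction, and an axon of constant rectangular
#' cross-section extending in +x, partitioned into contiguous labelled
#' segments (e.g. AIS, PARA_AIS, MYELIN, RANVIER).
#'
#' @param soma_um Soma box dimensions, length-3 (x, y, z) in micrometres.
#' @param dendrite_um Dendrite stub dimensions c(length, width, height) in
#'   micrometres, or `NULL` for no dendrite.
#' @param dendrite_region Region label for the dendrite stub.
#' @param axon_cross_um Axon cross-section c(width_y, height_z) in
#'   micrometres.
#' @param axon_segments `data.frame` with columns `region` and `length_um`
#'   describing the contiguous axon partition from the soma outward, or
#'   `NULL` for a soma-only cell.
#' @param margin_um Extracellular margin added around the cell bounding box
#'   in every direction. Must be at least `2 * h_um` so that at least two
#'   extracellular element layers separate the cell from the outer boundary.
#' @param h_um Target mesh size. Feature boundaries are always resolved
#'   exactly; `h_um` controls the subdivision between them.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(soma_um = c(20, 20, 20),
                          dendrite_um = NULL,
                          dendrite_region = "DENDRITE",
                          axon_cross_um = c(2, 2),
                          axon_segments = data.frame(region = "AIS",
                                                     length_um = 40),
                          margin_um = 100,
                          h_um = 5) {
  stopifnot(length(soma_um) == 3L, all(soma_um > 0),
            margin_um > 0, h_um > 0)
  if (!is.null(dendrite_um)) {
    stopifnot(length(dendrite_um) == 3L, all(dendrite_um > 0))
    assert_region(dendrite_region)
  }
  if (!is.null(axon_segments)) {
    stopifnot(is.data.frame(axon_segments),
              all(c("region", "length_um") %in% names(axon_segments)),
              nrow(axon_segments) >= 1L)
    if (any(axon_segments$length_um <= 0)) {
      stop("axon segment lengths must be positive (contiguous, non-overlapping partition)")
    }
    assert_region(axon_segments$region)
    stopifnot(length(axon_cross_um) == 2L, all(axon_cross_um > 0))
  }
  structure(list(soma_um = as.numeric(soma_um),
                 dendrite_um = if (is.null(dendrite_um)) NULL else as.numeric(dendrite_um),
                 dendrite_region = dendrite_region,
                 axon_cross_um = as.numeric(axon_cross_um),
                 axon_segments = axon_segments,
                 margin_um = margin_um,
                 h_um = h_um),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell_geometry:\n")
  cat(sprintf("  soma %s um", paste(x$soma_um, collapse = "x")))
  if (!is.null(x$dendrite_um))
    cat(sprintf(", dendrite %s um (%s)", paste(x$dendrite_um, collapse = "x"),
                x$dendrite_region))
  cat("\n")
  if (!is.null(x$axon_segments)) {
    cat(sprintf("  axon %sx%s um cross-section: %s\n",
                x$axon_cross_um[1], x$axon_cross_um[2],
                paste(sprintf("%s(%g)", x$axon_segments$region,
                              x$axon_segments$length_um), collapse = " | ")))
  }
  cat(sprintf("  margin %g um, target h %g um\n", x$margin_um, x$h_um))
  invisible(x)
}

# Box decomposition of one cell. Returns a data.frame of axis-aligned boxes
# (coordinates in um, cell local frame: soma centred at the origin, axon
# toward +x) with columns cell, region, x0..z1.
cell_parts <- function(params, cell_id = 1L, shift_um = c(0, 0, 0)) {
  s <- params$soma_um
  parts <- data.frame(cell = cell_id, region = "SOMA",
                      x0 = -s[1] / 2, x1 = s[1] / 2,
                      y0 = -s[2] / 2, y1 = s[2] / 2,
                      z0 = -s[3] / 2, z1 = s[3] / 2,
                      stringsAsFactors = FALSE)
  if (!is.null(params$dendrite_um)) {
    d <- params$dendrite_um
    parts <- rbind(parts, data.frame(
      cell = cell_id, region = params$dendrite_region,
      x0 = -s[1] / 2 - d[1], x1 = -s[1] / 2,
      y0 = -d[2] / 2, y1 = d[2] / 2,
      z0 = -d[3] / 2, z1 = d[3] / 2, stringsAsFactors = FALSE))
  }
  if (!is.null(params$axon_segments)) {
    cx <- params$axon_cross_um
    x <- s[1] / 2
    for (k in seq_len(nrow(params$axon_segments))) {
      len <- params$axon_segments$length_um[k]
      parts <- rbind(parts, data.frame(
        cell = cell_id, region = params$axon_segments$region[k],
        x0 = x, x1 = x + len,
        y0 = -cx[1] / 2, y1 = cx[1] / 2,
        z0 = -cx[2] / 2, z1 = cx[2] / 2, stringsAsFactors = FALSE))
      x <- x + len
    }
  }
  for (col in c("x0", "x1")) parts[[col]] <- parts[[col]] + shift_um[1]
  for (col in c("y0", "y1")) parts[[col]] <- parts[[col]] + shift_um[2]
  for (col in c("z0", "z1")) parts[[col]] <- parts[[col]] + shift_um[3]
  parts
}

mirror_parts_x <- function(parts, x_plane) {
  x0 <- 2 * x_plane - parts$x1
  x1 <- 2 * x_plane - parts$x0
  parts$x0 <- x0
  parts$x1 <- x1
  parts
}

# Subdivide [a, b] so that every feature point becomes a grid plane and no
# interval exceeds h. With grade_ends = TRUE the outermost intervals (from
# the first/last feature out to the domain boundary) are subdivided
# geometrically, spacing h at the feature growing by `ratio` outward, so a
# large far-field margin costs only logarithmically many planes.
axis_breaks <- function(a, b, features = numeric(), h, grade_ends = FALSE,
                        ratio = 1.4) {
  stopifnot(b > a, h > 0)
  pts <- sort(c(a, b, features[features > a + 1e-9 & features < b - 1e-9]))
  pts <- pts[c(TRUE, diff(pts) > 1e-9)]
  np <- length(pts)
  geom_fill <- function(from, len) {
    # increasing spacing h, h*ratio, ... covering len, rescaled to fit
    sp <- h
    steps <- sp
    while (sum(steps) < len) {
      sp <- sp * ratio
      steps <- c(steps, sp)
    }
    steps <- steps * (len / sum(steps))
    from + cumsum(steps[-length(steps)])
  }
  out <- numeric(0)
  for (k in seq_len(np - 1L)) {
    len <- pts[k + 1L] - pts[k]
    if (grade_ends && np > 2L && k == 1L && len > 2 * h) {
      inner <- rev(2 * pts[2] - geom_fill(pts[2], len))  # mirrored: fine near feature
      out <- c(out, pts[1], inner)
    } else if (grade_ends && np > 2L && k == np - 1L && len > 2 * h) {
      out <- c(out, pts[k], geom_fill(pts[k], len))
    } else {
      n <- max(1L, ceiling(len / h - 1e-9))
      out <- c(out, pts[k] + len * (seq_len(n) - 1L) / n)
    }
  }
  c(out, pts[np])
}

# Symmetric graded axis around `center`: spacing h_core within +/-core_half,
# h_mid out to +/-mid, then geometric growth by `ratio` until +/-max_um.
#' Graded axis breakpoints
#'
#' Builds a symmetric, geometrically graded set of grid planes around a
#' focus point: uniform fine spacing in a core region, an intermediate
#' uniform band, then geometric coarsening out to a far boundary. Used for
#' large "open-boundary" boxes where the outer Dirichlet condition must be
#' pushed far from the region of interest (e.g. point-source validation).
#'
#' @param center_um Focus coordinate.
#' @param core_half_um,h_core_um Half-width and spacing of the fine core.
#' @param mid_um,h_mid_um Outer edge and spacing of the intermediate band.
#' @param ratio Geometric growth factor (> 1) beyond the band.
#' @param max_um Minimum half-width of the final axis extent.
#' @return Numeric vector of grid plane coordinates in micrometres.
#' @export
graded_breaks <- function(center_um = 0, core_half_um, h_core_um,
                          mid_um, h_mid_um, ratio = 1.5, max_um) {
  stopifnot(core_half_um > 0, h_core_um > 0, mid_um >= core_half_um,
            ratio > 1, max_um >= mid_um)
  pos <- seq(0, core_half_um, by = h_core_um)
  if (mid_um > core_half_um + 1e-9) {
    n <- max(1L, ceiling((mid_um - core_half_um) / h_mid_um))
    pos <- c(pos, core_half_um + (mid_um - core_half_um) * seq_len(n) / n)
  }
  h <- h_mid_um
  while (pos[length(pos)] < max_um) {
    h <- h * ratio
    pos <- c(pos, pos[length(pos)] + h)
  }
  center_um + c(-rev(pos[-1]), pos)
}

# Core voxelizer shared by every builder. Breaks in um; parts may be NULL
# (cell-free box). Returns a tagged_mesh.
voxelize <- function(xb, yb, zb, parts = NULL, electrode = NULL) {
  nx <- length(xb) - 1L; ny <- length(yb) - 1L; nz <- length(zb) - 1L
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L)
  cx <- (xb[-1] + xb[-length(xb)]) / 2
  cy <- (yb[-1] + yb[-length(yb)]) / 2
  cz <- (zb[-1] + zb[-length(zb)]) / 2
  nv <- nx * ny * nz
  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  vx <- cx[ix]; vy <- cy[iy]; vz <- cz[iz]

  sub <- integer(nv)
  region <- rep(NA_character_, nv)
  if (!is.null(parts)) {
    for (k in seq_len(nrow(parts))) {
      p <- parts[k, ]
      inside <- vx > p$x0 & vx < p$x1 & vy > p$y0 & vy < p$y1 &
        vz > p$z0 & vz < p$z1
      clash <- inside & sub != 0L
      if (any(clash)) {
        stop(sprintf("overlapping cell parts near (%.3g, %.3g, %.3g) um",
                     vx[which(clash)[1]], vy[which(clash)[1]],
                     vz[which(clash)[1]]))
      }
      sub[inside] <- p$cell
      region[inside] <- p$region
    }
  }

  removed <- rep(FALSE, nv)
  if (!is.null(electrode)) {
    ec <- electrode$center_um; er <- electrode$radius_um
    removed <- (vx - ec[1])^2 + (vy - ec[2])^2 + (vz - ec[3])^2 < er^2
    if (any(removed & sub != 0L)) {
      stop("electrode sphere overlaps the cell volume")
    }
    if (!any(removed)) {
      stop("electrode sphere does not enclose any voxel center; refine the mesh near the electrode")
    }
  }

  keep <- which(!removed)
  nk <- length(keep)
  gx <- nx + 1L; gxy <- gx * (ny + 1L)
  corner <- function(dx, dy, dz) {
    (ix[keep] + dx) + gx * (iy[keep] + dy - 1L) + gxy * (iz[keep] + dz - 1L)
  }
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  # Kuhn subdivision: the six tetrahedra share the main diagonal c000-c111.
  tpl <- list(cbind(c000, c100, c110, c111),
              cbind(c000, c100, c101, c111),
              cbind(c000, c010, c110, c111),
              cbind(c000, c010, c011, c111),
              cbind(c000, c001, c101, c111),
              cbind(c000, c001, c011, c111))
  tets <- matrix(0L, nrow = 6L * nk, ncol = 4L)
  for (j in 1:6) tets[seq.int(j, by = 6L, length.out = nk), ] <- tpl[[j]]
  tet_vox <- rep(keep, each = 6L)
  tet_sub <- sub[tet_vox]
  tet_region <- region[tet_vox]

  used <- sort(unique(as.vector(tets)))
  remap <- integer(gxy * (nz + 1L))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)

  g <- used - 1L
  gix <- g %% gx
  giy <- (g %/% gx) %% (ny + 1L)
  giz <- g %/% gxy
  vertices <- cbind(um_to_cm(xb[gix + 1L]), um_to_cm(yb[giy + 1L]),
                    um_to_cm(zb[giz + 1L]))

  # orient all tets positively
  vol6 <- tet_signed_volumes(vertices, tets) * 6
  neg <- vol6 < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]

  faces <- extract_faces(tets, tet_sub)

  voxel_tet_start <- integer(nv)
  voxel_tet_start[keep] <- seq.int(1L, by = 6L, length.out = nk)

  mesh <- structure(list(
    vertices = vertices,
    tets = tets,
    tet_sub = tet_sub,
    tet_region = tet_region,
    membrane = faces$membrane,
    boundary = faces$boundary,
    grid = list(xb_cm = um_to_cm(xb), yb_cm = um_to_cm(yb),
                zb_cm = um_to_cm(zb), nx = nx, ny = ny, nz = nz,
                voxel_tet_start = voxel_tet_start),
    electrode = NULL,
    h_um = NA_real_), class = "tagged_mesh")

  if (!is.null(electrode)) {
    mesh$electrode <- list(center_cm = um_to_cm(electrode$center_um),
                           radius_um = electrode$radius_um,
                           area_cm2 = NA_real_)  # measured in finalize_tags
  }
  mesh
}

tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c_ <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

triangle_areas <- function(vertices, tris) {
  a <- vertices[tris[, 1], , drop = FALSE]
  u <- vertices[tris[, 2], , drop = FALSE] - a
  w <- vertices[tris[, 3], , drop = FALSE] - a
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

# Classify every tet face as interior, membrane (intra/extra subdomain
# change) or domain boundary. Boundary label assignment (OUTER vs ELECTRODE)
# is done by the caller context: a single-tet face whose three vertices lie
# on one bounding-box plane is OUTER, anything else is an electrode cavity
# facet.
extract_faces <- function(tets, tet_sub) {
  m <- nrow(tets)
  f1 <- tets[, c(2, 3, 4)]; f2 <- tets[, c(1, 3, 4)]
  f3 <- tets[, c(1, 2, 4)]; f4 <- tets[, c(1, 2, 3)]
  F <- rbind(f1, f2, f3, f4)
  ft <- rep.int(seq_len(m), 4L)
  a <- pmin(F[, 1], F[, 2], F[, 3])
  cc <- pmax(F[, 1], F[, 2], F[, 3])
  b <- F[, 1] + F[, 2] + F[, 3] - a - cc
  o <- order(a, b, cc)
  a <- a[o]; b <- b[o]; cc <- cc[o]; ft <- ft[o]
  n <- length(a)
  same_next <- c(a[-n] == a[-1] & b[-n] == b[-1] & cc[-n] == cc[-1], FALSE)
  same_prev <- c(FALSE, same_next[-n])
  if (any(same_next & c(same_next[-1], FALSE))) {
    stop("non-manifold mesh: a facet is shared by more than two tetrahedra")
  }
  first <- which(same_next)          # first of each pair
  single <- which(!same_next & !same_prev)

  t1 <- ft[first]; t2 <- ft[first + 1L]
  s1 <- tet_sub[t1]; s2 <- tet_sub[t2]
  is_mem <- s1 != s2
  both_cells <- is_mem & s1 != 0L & s2 != 0L
  if (any(both_cells)) {
    stop("two intracellular subdomains share a facet; cells must be separated by extracellular space")
  }
  mi <- which(is_mem)
  intra_first <- s1[mi] != 0L
  intra_tet <- ifelse(intra_first, t1[mi], t2[mi])
  extra_tet <- ifelse(intra_first, t2[mi], t1[mi])
  membrane <- list(verts = cbind(a[first][mi], b[first][mi], cc[first][mi]),
                   cell = tet_sub[intra_tet],
                   region = character(0),   # filled by caller from tet_region
                   intra_tet = intra_tet,
                   extra_tet = extra_tet)

  boundary <- list(verts = cbind(a[single], b[single], cc[single]),
                   label = character(length(single)),
                   tet = ft[single])
  list(membrane = membrane, boundary = boundary)
}

# Fill membrane region labels and boundary labels; shared by builders.
finalize_tags <- function(mesh) {
  mesh$membrane$region <- mesh$tet_region[mesh$membrane$intra_tet]
  V <- mesh$vertices
  g <- mesh$grid
  lims <- rbind(range(g$xb_cm), range(g$yb_cm), range(g$zb_cm))
  tol <- 1e-12
  bl <- character(nrow(mesh$boundary$verts))
  for (axis in 1:3) {
    for (side in 1:2) {
      plane <- lims[axis, side]
      on_plane <- abs(V[, axis] - plane) < tol + 1e-9 * max(abs(lims))
      hit <- on_plane[mesh$boundary$verts[, 1]] &
        on_plane[mesh$boundary$verts[, 2]] &
        on_plane[mesh$boundary$verts[, 3]]
      bl[hit] <- "OUTER"
    }
  }
  bl[bl == ""] <- "ELECTRODE"
  bad <- bl == "ELECTRODE" & mesh$tet_sub[mesh$boundary$tet] != 0L
  if (any(bad)) stop("internal error: electrode facet adjacent to an intracellular tet")
  mesh$boundary$label <- bl
  if (!is.null(mesh$electrode)) {
    el_idx <- which(bl == "ELECTRODE")
    if (length(el_idx) == 0L) stop("electrode cavity produced no boundary facets")
    mesh$electrode$area_cm2 <-
      sum(triangle_areas(mesh$vertices, mesh$boundary$verts[el_idx, , drop = FALSE]))
  }
  mesh
}

validate_electrode_spec <- function(electrode) {
  stopifnot(is.list(electrode), length(electrode$center_um) == 3L,
            is.numeric(electrode$radius_um), electrode$radius_um > 0)
  electrode
}

#' Build a tagged mesh for a single idealized neuron
#'
#' Meshes one box-union cell (see [cell_geometry()]) surrounded by
#' `margin_um` of extracellular space, optionally with a spherical electrode
#' cavity cut out of the extracellular domain. The electrode surface is the
#' staircase set of facets bounding the removed voxels; its measured
#' discrete area is stored so that boundary fluxes scaled by it inject the
#' requested total current exactly.
#'
#' @param params A [cell_geometry()] object.
#' @param electrode `NULL`, or `list(center_um =, radius_um =)` placing a
#'   spherical electrode cavity in the extracellular space.
#' @param graded_margin If `TRUE`, the extracellular margin is meshed with
#'   geometrically growing element sizes away from the cell/electrode
#'   instead of uniformly at `h`, so large far-field margins (hundreds of
#'   micrometres) stay affordable.
#' @return A `tagged_mesh`.
#' @export
build_single_cell_mesh <- function(params, electrode = NULL,
                                   graded_margin = FALSE) {
  stopifnot(inherits(params, "cell_geometry"))
  if (params$margin_um < 2 * params$h_um) {
    stop(sprintf(paste0("margin (%g um) too small: at least two extracellular",
                        " element layers (2*h = %g um) are required"),
                 params$margin_um, 2 * params$h_um))
  }
  parts <- cell_parts(params)
  bb <- c(min(parts$x0), max(parts$x1), min(parts$y0), max(parts$y1),
          min(parts$z0), max(parts$z1))
  dom <- bb + params$margin_um * c(-1, 1, -1, 1, -1, 1)
  fx <- c(parts$x0, parts$x1); fy <- c(parts$y0, parts$y1)
  fz <- c(parts$z0, parts$z1)
  if (!is.null(electrode)) {
    electrode <- validate_electrode_spec(electrode)
    ec <- electrode$center_um; er <- electrode$radius_um
    if (any(ec - er < dom[c(1, 3, 5)] + 2 * params$h_um) ||
        any(ec + er > dom[c(2, 4, 6)] - 2 * params$h_um)) {
      stop("electrode does not fit strictly inside the extracellular domain; increase margin_um")
    }
    gap <- box_sphere_gap(parts, ec, er)
    if (gap <= 0) stop("electrode sphere overlaps the cell volume")
    fx <- c(fx, ec[1] - er, ec[1], ec[1] + er)
    fy <- c(fy, ec[2] - er, ec[2], ec[2] + er)
    fz <- c(fz, ec[3] - er, ec[3], ec[3] + er)
  }
  xb <- axis_breaks(dom[1], dom[2], fx, params$h_um, grade_ends = graded_margin)
  yb <- axis_breaks(dom[3], dom[4], fy, params$h_um, grade_ends = graded_margin)
  zb <- axis_breaks(dom[5], dom[6], fz, params$h_um, grade_ends = graded_margin)
  mesh <- voxelize(xb, yb, zb, parts, electrode)
  mesh$h_um <- params$h_um
  finalize_tags(mesh)
}

box_sphere_gap <- function(parts, center, radius) {
  d2 <- rep(Inf, nrow(parts))
  for (k in seq_len(nrow(parts))) {
    p <- parts[k, ]
    dx <- pmax(p$x0 - center[1], 0, center[1] - p$x1)
    dy <- pmax(p$y0 - center[2], 0, center[2] - p$y1)
    dz <- pmax(p$z0 - center[3], 0, center[3] - p$z1)
    d2[k] <- dx^2 + dy^2 + dz^2
  }
  sqrt(min(d2)) - radius
}

#' Build a mirror-symmetric two-cell mesh
#'
#' Places two copies of the same idealized cell with their axon tips facing
#' each other across a gap of extracellular space; cell 2 is the mirror
#' image of cell 1 about the mid-plane of the gap. The gap always receives
#' at least two element layers (one per side of the mid-plane).
#'
#' @param params A [cell_geometry()] object describing each cell.
#' @param gap_um Minimum axon-tip to axon-tip distance in micrometres
#'   (> 0).
#' @param gap_h_um Optional local target mesh size inside the gap; defaults
#'   to filling the gap with two layers.
#' @param electrode Optional electrode specification as in
#'   [build_single_cell_mesh()].
#' @return A `tagged_mesh` with intracellular subdomains 1 and 2.
#' @export
build_two_cell_mesh <- function(params, gap_um, gap_h_um = NULL,
                                electrode = NULL) {
  stopifnot(inherits(params, "cell_geometry"))
  if (!is.numeric(gap_um) || gap_um <= 0) {
    stop("gap_um must be positive: the two cells may not touch")
  }
  if (params$margin_um < 2 * params$h_um) {
    stop(sprintf("margin (%g um) too small: at least 2*h = %g um required",
                 params$margin_um, 2 * params$h_um))
  }
  p1 <- cell_parts(params, cell_id = 1L)
  tip <- max(p1$x1)
  x_mid <- tip + gap_um / 2
  p2 <- mirror_parts_x(cell_parts(params, cell_id = 2L), x_mid)
  parts <- rbind(p1, p2)

  a <- min(p1$x0) - params$margin_um
  # exact mirror symmetry: build the left half of the x-axis, then reflect
  feats_left <- c(p1$x0, p1$x1)
  if (!is.null(gap_h_um)) {
    stopifnot(gap_h_um > 0)
    feats_left <- c(feats_left, seq(tip, x_mid, by = gap_h_um))
  }
  lb <- axis_breaks(a, x_mid, feats_left,
                    if (is.null(gap_h_um)) params$h_um else params$h_um)
  xb <- c(lb, 2 * x_mid - rev(lb[-length(lb)]))

  fy <- c(parts$y0, parts$y1); fz <- c(parts$z0, parts$z1)
  dom_y <- c(min(parts$y0), max(parts$y1)) + params$margin_um * c(-1, 1)
  dom_z <- c(min(parts$z0), max(parts$z1)) + params$margin_um * c(-1, 1)
  yb <- axis_breaks(dom_y[1], dom_y[2], fy, params$h_um)
  zb <- axis_breaks(dom_z[1], dom_z[2], fz, params$h_um)

  if (!is.null(electrode)) {
    electrode <- validate_electrode_spec(electrode)
    if (box_sphere_gap(parts, electrode$center_um, electrode$radius_um) <= 0) {
      stop("electrode sphere overlaps a cell volume")
    }
  }
  mesh <- voxelize(xb, yb, zb, parts, electrode)
  mesh$h_um <- params$h_um
  mesh$mirror_plane_cm <- um_to_cm(x_mid)
  finalize_tags(mesh)
}

#' Build a cell-free box mesh from explicit grid planes
#'
#' Meshes a rectilinear box given per-axis grid plane coordinates (e.g. from
#' [graded_breaks()]), optionally cutting out a spherical electrode cavity.
#' Used for open-field validation problems such as checking the 1/r decay of
#' the potential from a current source.
#'
#' @param xb_um,yb_um,zb_um Strictly increasing grid plane coordinates per
#'   axis, in micrometres.
#' @param electrode Optional electrode as in [build_single_cell_mesh()].
#' @return A `tagged_mesh` with no intracellular subdomain.
#' @export
build_box_mesh <- function(xb_um, yb_um, zb_um, electrode = NULL) {
  stopifnot(all(diff(xb_um) > 0), all(diff(yb_um) > 0), all(diff(zb_um) > 0))
  if (!is.null(electrode)) electrode <- validate_electrode_spec(electrode)
  mesh <- voxelize(xb_um, yb_um, zb_um, NULL, electrode)
  mesh$h_um <- min(diff(xb_um), diff(yb_um), diff(zb_um))
  finalize_tags(mesh)
}
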