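# tagged_mesh queries and validation.

#' @export
print.tagged_mesh <- function(x, ...) {
  ncell <- max(0L, x$tet_sub)
  cat("tagged_mesh:\n")
  cat(sprintf("  %d vertices, %d tetrahedra (%d extracellular, %d intracellular in %d cell%s)\n",
              nrow(x$vertices), nrow(x$tets), sum(x$tet_sub == 0L),
              sum(x$tet_sub != 0L), ncell, if (ncell == 1L) "" else "s"))
  regs <- table(x$membrane$region)
  cat(sprintf("  %d membrane facets (%s)\n", nrow(x$membrane$verts),
              paste(sprintf("%s:%d", names(regs), as.integer(regs)),
                    collapse = ", ")))
  cat(sprintf("  %d boundary facets (OUTER: %d, ELECTRODE: %d)\n",
              nrow(x$boundary$verts), sum(x$boundary$label == "OUTER"),
              sum(x$boundary$label == "ELECTRODE")))
  if (!is.null(x$electrode)) {
    cat(sprintf("  electrode: nominal radius %g um, measured area %.4g cm^2\n",
                x$electrode$radius_um, x$electrode$area_cm2))
  }
  invisible(x)
}

tet_centroids <- function(mesh, idx = seq_len(nrow(mesh$tets))) {
  (mesh$vertices[mesh$tets[idx, 1], , drop = FALSE] +
     mesh$vertices[mesh$tets[idx, 2], , drop = FALSE] +
     mesh$vertices[mesh$tets[idx, 3], , drop = FALSE] +
     mesh$vertices[mesh$tets[idx, 4], , drop = FALSE]) / 4
}

facet_centroids <- function(mesh, verts = mesh$membrane$verts) {
  (mesh$vertices[verts[, 1], , drop = FALSE] +
     mesh$vertices[verts[, 2], , drop = FALSE] +
     mesh$vertices[verts[, 3], , drop = FALSE]) / 3
}

#' Facet areas and oriented normals
#'
#' Computes per-facet areas (cm^2) and unit normals for the membrane and
#' boundary facets of a mesh. Membrane normals are oriented outward from the
#' intracellular side (the EMI convention for \eqn{n_i}); electrode normals
#' are oriented toward the cavity (the outward normal \eqn{n_e} of the
#' extracellular domain, pointing toward the sphere center); outer-boundary
#' normals point out of the domain.
#'
#' @param mesh A `tagged_mesh`.
#' @return A list with components `membrane` and `boundary`, each holding
#'   `area` (vector, cm^2) and `normal` (matrix, unit vectors).
#' @export
facet_geometry <- function(mesh) {
  orient <- function(verts, ref_inside) {
    a <- mesh$vertices[verts[, 1], , drop = FALSE]
    u <- mesh$vertices[verts[, 2], , drop = FALSE] - a
    w <- mesh$vertices[verts[, 3], , drop = FALSE] - a
    n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
    nrm <- sqrt(rowSums(n^2))
    if (any(nrm <= 0)) stop("degenerate (zero-area) facet")
    n <- n / nrm
    centr <- (a + mesh$vertices[verts[, 2], , drop = FALSE] +
                mesh$vertices[verts[, 3], , drop = FALSE]) / 3
    # flip so the normal points away from the reference interior point
    flip <- rowSums(n * (centr - ref_inside)) < 0
    n[flip, ] <- -n[flip, ]
    list(area = nrm / 2, normal = n)
  }
  mem <- orient(mesh$membrane$verts, tet_centroids(mesh, mesh$membrane$intra_tet))
  bnd <- if (nrow(mesh$boundary$verts) > 0L) {
    orient(mesh$boundary$verts, tet_centroids(mesh, mesh$boundary$tet))
  } else {
    list(area = numeric(0), normal = matrix(0, 0, 3))
  }
  list(membrane = mem, boundary = bnd)
}

#' Validate a tagged mesh against its structural invariants
#'
#' Checks: positive tet volumes; every membrane facet separates exactly one
#' intracellular and one extracellular tet; each cell's membrane surface is
#' closed (every facet edge shared by exactly two facets of that cell);
#' boundary facets border exactly one extracellular tet; every membrane
#' facet carries a valid region label; membrane vertices are shared by both
#' subdomains (conforming interface).
#'
#' @param mesh A `tagged_mesh`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_tagged_mesh <- function(mesh) {
  vols <- tet_signed_volumes(mesh$vertices, mesh$tets)
  if (any(vols <= 0)) {
    stop(sprintf("%d tetrahedra with non-positive volume", sum(vols <= 0)))
  }
  mb <- mesh$membrane
  if (nrow(mb$verts) > 0L) {
    if (any(mesh$tet_sub[mb$intra_tet] == 0L) ||
        any(mesh$tet_sub[mb$extra_tet] != 0L)) {
      stop("membrane facet not between one intracellular and one extracellular tet")
    }
    if (any(is.na(mb$region))) stop("membrane facet without a region label")
    assert_region(unique(mb$region), "membrane region label")
    for (cell in sort(unique(mb$cell))) {
      sel <- mb$cell == cell
      tri <- mb$verts[sel, , drop = FALSE]
      e <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      key <- paste(e[, 1], e[, 2])
      cnt <- table(key)
      open <- names(cnt)[cnt != 2L]
      if (length(open) > 0L) {
        stop(sprintf("membrane of cell %d is not closed: %d edge(s) not shared by two facets (e.g. vertices %s)",
                     cell, length(open), open[1]))
      }
    }
    # conformity: membrane vertices belong to tets on both sides
    vin <- unique(as.vector(mesh$tets[mesh$tet_sub != 0L, ]))
    vex <- unique(as.vector(mesh$tets[mesh$tet_sub == 0L, ]))
    mv <- unique(as.vector(mb$verts))
    if (!all(mv %in% vin) || !all(mv %in% vex)) {
      stop("non-conforming interface: membrane vertex not shared by both subdomains")
    }
  }
  if (nrow(mesh$boundary$verts) > 0L) {
    if (any(!mesh$boundary$label %in% c("OUTER", "ELECTRODE"))) {
      stop("boundary facet with label outside {OUTER, ELECTRODE}")
    }
    if (any(mesh$tet_sub[mesh$boundary$tet] != 0L)) {
      stop("OUTER/ELECTRODE facet bordering an intracellular tet")
    }
  }
  invisible(TRUE)
}

# --- point location ----------------------------------------------------------

# Barycentric coordinates of point p (cm) in tet i; returns NULL if outside.
tet_barycentric <- function(mesh, i, p, tol = 1e-10) {
  v <- mesh$vertices[mesh$tets[i, ], , drop = FALSE]
  A <- t(v[2:4, , drop = FALSE]) - v[1, ]
  rhs <- p - v[1, ]
  lam <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(lam)) return(NULL)
  l <- c(1 - sum(lam), lam)
  if (all(l >= -tol)) l else NULL
}

# Find the tet containing point p_cm, preferring grid lookup. Returns
# list(tet, weights) with P1 interpolation weights on its 4 vertices.
locate_point <- function(mesh, p_cm) {
  g <- mesh$grid
  cand <- integer(0)
  if (!is.null(g)) {
    ix <- findInterval(p_cm[1], g$xb_cm, rightmost.closed = TRUE)
    iy <- findInterval(p_cm[2], g$yb_cm, rightmost.closed = TRUE)
    iz <- findInterval(p_cm[3], g$zb_cm, rightmost.closed = TRUE)
    if (ix >= 1L && ix <= g$nx && iy >= 1L && iy <= g$ny &&
        iz >= 1L && iz <= g$nz) {
      vox <- ix + g$nx * (iy - 1L) + g$nx * g$ny * (iz - 1L)
      st <- g$voxel_tet_start[vox]
      if (st > 0L) cand <- st:(st + 5L)
    }
  }
  if (length(cand) == 0L) {
    ctr <- tet_centroids(mesh)
    cand <- order((ctr[, 1] - p_cm[1])^2 + (ctr[, 2] - p_cm[2])^2 +
                    (ctr[, 3] - p_cm[3])^2)[1:min(60L, nrow(mesh$tets))]
  }
  for (i in cand) {
    l <- tet_barycentric(mesh, i, p_cm)
    if (!is.null(l)) return(list(tet = i, weights = l))
  }
  stop(sprintf("point (%.4g, %.4g, %.4g) um is not inside the mesh (or lies in a removed cavity)",
               cm_to_um(p_cm[1]), cm_to_um(p_cm[2]), cm_to_um(p_cm[3])))
}

# Vertices on active (non-myelin) membrane facets of one cell, optionally
# restricted to a region.
membrane_vertices <- function(mesh, cell = NULL, region = NULL,
                              include_myelin = FALSE) {
  mb <- mesh$membrane
  sel <- rep(TRUE, length(mb$cell))
  if (!is.null(cell)) sel <- sel & mb$cell == cell
  if (!is.null(region)) sel <- sel & mb$region %in% region
  if (!include_myelin) sel <- sel & mb$region != "MYELIN"
  sort(unique(as.vector(mb$verts[sel, , drop = FALSE])))
}

# Nearest membrane vertex (active) to a point, for v-probes.
nearest_membrane_vertex <- function(mesh, point_cm, cell = NULL,
                                    region = NULL) {
  vv <- membrane_vertices(mesh, cell = cell, region = region)
  if (length(vv) == 0L) stop("no active membrane vertices match the probe specification")
  d2 <- rowSums((mesh$vertices[vv, , drop = FALSE] -
                   matrix(point_cm, length(vv), 3, byrow = TRUE))^2)
  vv[which.min(d2)]
}
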