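# The coupled EMI solver.
#
# Each global step applies first-order (Godunov) operator splitting: the
# membrane ODE system (gates + ionic/stimulus currents) advances first,
# then the backward-Euler-coupled elliptic interface problem is solved
# monolithically for (ui, ue):
#
#   div(sigma_i grad ui) = 0   in each cell,
#   div(sigma_e grad ue) = 0   in the extracellular space,
#   flux continuity and the membrane closure
#       (ui - ue)|Gamma = v* + (dt/Cm) Im,   Im = -n_i . sigma_i grad ui
#   on active membrane, zero flux on both sides of MYELIN facets,
#   ue = 0 on the outer boundary, and the electrode Neumann flux.
#
# Discretization: P1 elements on the shared tetrahedral mesh; membrane
# vertices carry both an intracellular and an extracellular dof, so
# v = ui - ue holds exactly at dofs. Membrane terms use lumped (vertex)
# quadrature. Eliminating v leaves one symmetric positive definite sparse
# system whose matrix is time-independent; its Cholesky factorization
# (CHOLMOD) is computed once and reused every step.

#' Conductivities of the two media
#'
#' @param sigma_i_mS_per_cm Intracellular conductivity (mS/cm), scalar or
#'   one value per cell. The default of 5 mS/cm is a configuration default;
#'   quantitative reproduction of specific cell types requires a user-set
#'   value.
#' @param sigma_e_mS_per_cm Extracellular conductivity (mS/cm), spatially
#'   uniform. Default 3 mS/cm, the standard bulk value for neural tissue.
#' @return A `conductivities` object.
#' @export
conductivities <- function(sigma_i_mS_per_cm = 5, sigma_e_mS_per_cm = 3) {
  stopifnot(all(sigma_i_mS_per_cm > 0), sigma_e_mS_per_cm > 0)
  structure(list(sigma_i = sigma_i_mS_per_cm, sigma_e = sigma_e_mS_per_cm),
            class = "conductivities")
}

#' Simulation probe
#'
#' @param name Column name in the recorded traces.
#' @param kind `"v"` (membrane potential at a membrane vertex), `"ue"`
#'   (extracellular potential) or `"ui"` (intracellular potential).
#' @param point_um Probe location in micrometres. For `"v"`, the nearest
#'   active membrane vertex is used; for `"ue"`/`"ui"` with `cell`/`region`
#'   given, the extracellular/intracellular trace is taken at the membrane
#'   vertex itself (a "membrane point"), otherwise the field is
#'   P1-interpolated at `point_um`.
#' @param cell,region Optional membrane attachment (e.g. `cell = 1`,
#'   `region = "AIS"`): the probe snaps to the nearest active membrane
#'   vertex of that cell/region (to `point_um` if given, else to the region
#'   centroid).
#' @return A `probe` specification.
#' @export
probe <- function(name, kind = c("v", "ue", "ui"), point_um = NULL,
                  cell = NULL, region = NULL) {
  kind <- match.arg(kind)
  if (!is.null(region)) assert_region(region)
  if (kind == "v" && is.null(cell)) cell <- 1L
  structure(list(name = name, kind = kind, point_um = point_um,
                 cell = cell, region = region), class = "emi_probe")
}

#' EMI problem definition
#'
#' @param mesh A `tagged_mesh`.
#' @param model A [membrane_model()] (or bundled name / file path), or a
#'   list of one per cell.
#' @param sigma A [conductivities()] object.
#' @param stimuli List of [somatic_stimulus()] / [electrode_stimulus()]
#'   objects.
#' @param dt_ms Global time step (default 0.01 ms).
#' @param dt_sub_ms Membrane ODE substep (default `dt_ms`); must divide it.
#' @param T_end_ms Simulation horizon (multiple of `dt_ms`).
#' @param probes List of [probe()] specifications.
#' @param init `NULL` for resting initial conditions (per-cell
#'   [steady_state()]), or a list with one `list(v =, s =)` entry per cell
#'   (e.g. from a limit-cycle checkpoint, to stagger spike phases).
#' @param output_stride Record probes every this many steps.
#' @param solver List of solver settings; `tol` (default 1e-10) is the
#'   residual tolerance verified on the first factorized solve.
#' @return An `emi_problem`.
#' @export
emi_problem <- function(mesh, model = hh_model(), sigma = conductivities(),
                        stimuli = list(), dt_ms = 0.01, dt_sub_ms = NULL,
                        T_end_ms = 1, probes = list(), init = NULL,
                        output_stride = 1L, solver = list(tol = 1e-10)) {
  stopifnot(inherits(mesh, "tagged_mesh"), inherits(sigma, "conductivities"))
  stopifnot(dt_ms > 0, T_end_ms >= 0)
  nstep <- T_end_ms / dt_ms
  if (abs(nstep - round(nstep)) > 1e-9 * max(1, nstep)) {
    stop("T_end_ms must be a multiple of dt_ms")
  }
  if (is.null(dt_sub_ms)) dt_sub_ms <- dt_ms
  nsub <- dt_ms / dt_sub_ms
  if (abs(nsub - round(nsub)) > 1e-12 * nsub) stop("dt_sub_ms must divide dt_ms")
  ncell <- max(0L, mesh$tet_sub)
  if (!is.list(model) || inherits(model, "membrane_model")) {
    model <- rep(list(resolve_model(model)), max(1L, ncell))
  } else {
    model <- lapply(model, resolve_model)
    if (length(model) != ncell) stop("need one membrane model per cell")
  }
  if (inherits(stimuli, c("somatic_stimulus", "electrode_stimulus"))) {
    stimuli <- list(stimuli)
  }
  has_elec <- any(vapply(stimuli, inherits, TRUE, "electrode_stimulus"))
  if (has_elec && is.null(mesh$electrode)) {
    stop("electrode stimulus given but the mesh has no electrode cavity")
  }
  structure(list(mesh = mesh, model = model, sigma = sigma, stimuli = stimuli,
                 dt = dt_ms, dt_sub = dt_sub_ms, T_end = T_end_ms,
                 probes = probes, init = init,
                 output_stride = as.integer(output_stride), solver = solver),
            class = "emi_problem")
}

#' Potential of an ideal point current source
#'
#' Analytic far-field solution of the extracellular electrostatic problem:
#' \eqn{u_e(r) = -I_e / (4 \pi \sigma_e r)}. For positive `Ie` (the
#' constant electrode protocol) a negative potential emanates from the
#' source, decaying as 1/r.
#'
#' @param Ie_uA Source strength (uA).
#' @param sigma_e_mS_per_cm Extracellular conductivity (mS/cm).
#' @param r_cm Distance from the source (cm), > 0.
#' @return Potential in mV.
#' @export
analytic_point_source <- function(Ie_uA, sigma_e_mS_per_cm, r_cm) {
  if (any(r_cm <= 0)) stop("r must be positive")
  -Ie_uA / (4 * pi * sigma_e_mS_per_cm * r_cm)
}

# --- assembly ---------------------------------------------------------------

# P1 stiffness triplets for a set of tets under a per-tet conductivity,
# mapped through per-vertex dof ids (0 = eliminated Dirichlet dof).
stiffness_triplets <- function(vertices, tets, sigma_tet, dof) {
  a <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - a
  e2 <- vertices[tets[, 3], , drop = FALSE] - a
  e3 <- vertices[tets[, 4], , drop = FALSE] - a
  # cofactors of J = [e1; e2; e3]
  c11 <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  c12 <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  c13 <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * c11 + e1[, 2] * c12 + e1[, 3] * c13
  c21 <- e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2]
  c22 <- e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3]
  c23 <- e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]
  c31 <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  c32 <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  c33 <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  # gradient of barycentric function k+1 is row k of the cofactor matrix
  # of J = [e1; e2; e3] divided by det; grad1 = -sum of the others
  g2 <- cbind(c11, c12, c13) / det
  g3 <- cbind(c21, c22, c23) / det
  g4 <- cbind(c31, c32, c33) / det
  g1 <- -(g2 + g3 + g4)
  vol <- abs(det) / 6
  G <- list(g1, g2, g3, g4)
  m <- nrow(tets)
  I <- integer(16 * m); J <- integer(16 * m); X <- numeric(16 * m)
  k <- 0L
  for (A in 1:4) for (B in 1:4) {
    idx <- k * m + seq_len(m)
    I[idx] <- dof[tets[, A]]
    J[idx] <- dof[tets[, B]]
    X[idx] <- sigma_tet * vol * rowSums(G[[A]] * G[[B]])
    k <- k + 1L
  }
  keep <- I > 0L & J > 0L
  list(i = I[keep], j = J[keep], x = X[keep])
}

#' Assemble the time-independent operators of an EMI problem
#'
#' Builds the dof maps (extracellular dofs with the outer Dirichlet
#' condition eliminated; one intracellular dof block per cell), the P1
#' stiffness blocks, the lumped membrane coupling (vertex areas times
#' Cm/dt), the electrode lumped load vector, resolves probes, and computes
#' the sparse Cholesky factorization reused by every [pde_step()].
#'
#' @param problem An [emi_problem()].
#' @return An `emi_cache` operator cache.
#' @export
assemble_operators <- function(problem) {
  mesh <- problem$mesh
  nv <- nrow(mesh$vertices)
  ncell <- max(0L, mesh$tet_sub)
  dt <- problem$dt

  # extracellular dofs: vertices of extracellular tets, minus OUTER vertices
  e_verts <- unique(as.vector(mesh$tets[mesh$tet_sub == 0L, , drop = FALSE]))
  outer_v <- unique(as.vector(mesh$boundary$verts[mesh$boundary$label == "OUTER", ,
                                                  drop = FALSE]))
  e_free <- setdiff(e_verts, outer_v)
  e_map <- integer(nv)
  e_map[e_free] <- seq_along(e_free)
  ndof <- length(e_free)

  i_map <- vector("list", ncell)
  mem <- vector("list", ncell)
  fg <- facet_geometry(mesh)

  trip <- stiffness_triplets(mesh$vertices,
                             mesh$tets[mesh$tet_sub == 0L, , drop = FALSE],
                             problem$sigma$sigma_e, e_map)
  I <- trip$i; J <- trip$j; X <- trip$x

  sigma_i <- rep_len(problem$sigma$sigma_i, max(1L, ncell))
  for (c_ in seq_len(ncell)) {
    verts_c <- unique(as.vector(mesh$tets[mesh$tet_sub == c_, , drop = FALSE]))
    imap <- integer(nv)
    imap[verts_c] <- ndof + seq_along(verts_c)
    i_map[[c_]] <- imap
    trip <- stiffness_triplets(mesh$vertices,
                               mesh$tets[mesh$tet_sub == c_, , drop = FALSE],
                               sigma_i[c_], imap)
    I <- c(I, trip$i); J <- c(J, trip$j); X <- c(X, trip$x)
    ndof <- ndof + length(verts_c)

    # active membrane vertices of this cell with area-weighted region mix
    sel <- mesh$membrane$cell == c_ & mesh$membrane$region != "MYELIN"
    if (!any(sel)) stop(sprintf("cell %d has no active (non-myelin) membrane", c_))
    tri <- mesh$membrane$verts[sel, , drop = FALSE]
    reg <- mesh$membrane$region[sel]
    ar3 <- fg$membrane$area[sel] / 3
    vids <- sort(unique(as.vector(tri)))
    loc <- match(as.vector(tri), vids)
    regs <- sort(unique(reg))
    W <- matrix(0, length(vids), length(regs), dimnames = list(NULL, regs))
    Av <- numeric(length(vids))
    for (k in 1:3) {
      idx <- loc[(k - 1) * nrow(tri) + seq_len(nrow(tri))]
      Av <- Av + tapply_add(ar3, idx, length(vids))
      for (r in regs) {
        W[, r] <- W[, r] + tapply_add(ar3 * (reg == r), idx, length(vids))
      }
    }
    W <- W / Av
    model <- problem$model[[c_]]
    rt <- membrane_runtime(model, W)
    if (any(rt$cm <= 0)) {
      stop("active membrane vertex with Cm <= 0; check the model's capacitance table")
    }
    beta <- Av * rt$cm / dt
    i_idx <- imap[vids]
    e_idx <- e_map[vids]
    if (any(e_idx == 0L)) {
      stop("membrane vertex on the outer Dirichlet boundary; increase the margin")
    }
    I <- c(I, i_idx, e_idx, i_idx, e_idx)
    J <- c(J, i_idx, e_idx, e_idx, i_idx)
    X <- c(X, beta, beta, -beta, -beta)

    mem[[c_]] <- list(vids = vids, area = Av, W = W, beta = beta,
                      cm = rt$cm, i_idx = i_idx, e_idx = e_idx,
                      rt = rt, model = model,
                      pos = mesh$vertices[vids, , drop = FALSE])
  }

  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndof, ndof))
  A <- Matrix::forceSymmetric(A, uplo = "L")
  chol <- Matrix::Cholesky(A, LDL = FALSE)

  elec <- NULL
  el_sel <- mesh$boundary$label == "ELECTRODE"
  if (any(el_sel)) {
    tri <- mesh$boundary$verts[el_sel, , drop = FALSE]
    ar3 <- fg$boundary$area[el_sel] / 3
    vids <- sort(unique(as.vector(tri)))
    loc <- match(as.vector(tri), vids)
    lump <- numeric(length(vids))
    for (k in 1:3) {
      idx <- loc[(k - 1) * nrow(tri) + seq_len(nrow(tri))]
      lump <- lump + tapply_add(ar3, idx, length(vids))
    }
    dofs <- e_map[vids]
    if (any(dofs == 0L)) stop("electrode facet vertex on the outer boundary")
    elec <- list(dofs = dofs, lump = lump, Ae = sum(fg$boundary$area[el_sel]),
                 center_cm = mesh$electrode$center_cm)
  }

  # attach measured Ae to electrode stimuli
  stimuli <- lapply(problem$stimuli, function(s) {
    if (inherits(s, "electrode_stimulus") && is.null(s$Ae)) {
      if (is.null(elec)) stop("electrode stimulus but no electrode facets in the mesh")
      s$Ae <- elec$Ae
    }
    s
  })

  cache <- structure(list(problem = problem, mesh = mesh, ndof = ndof,
                          e_map = e_map, i_map = i_map, mem = mem,
                          ncell = ncell, A = A, chol = chol, elec = elec,
                          stimuli = stimuli, dt = dt, fg = fg,
                          sigma = problem$sigma),
                     class = "emi_cache")
  cache$probes <- lapply(problem$probes, resolve_probe, cache = cache)
  cache
}

# scatter-add helper: sum w into n bins by index
tapply_add <- function(w, idx, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

resolve_probe <- function(pr, cache) {
  stopifnot(inherits(pr, "emi_probe"))
  mesh <- cache$mesh
  if (!is.null(pr$cell) && (pr$kind == "v" || !is.null(pr$region))) {
    # membrane-attached probe
    target <- if (!is.null(pr$point_um)) {
      um_to_cm(pr$point_um)
    } else {
      vv <- membrane_vertices(mesh, cell = pr$cell, region = pr$region)
      colMeans(mesh$vertices[vv, , drop = FALSE])
    }
    vid <- nearest_membrane_vertex(mesh, target, cell = pr$cell,
                                   region = pr$region)
    mc <- cache$mem[[pr$cell]]
    li <- match(vid, mc$vids)
    return(list(name = pr$name, kind = pr$kind, cell = pr$cell, vertex = vid,
                local = li, pos_cm = mesh$vertices[vid, ],
                mdof = switch(pr$kind, v = NA_integer_,
                              ue = cache$e_map[vid], ui = mc$i_idx[li])))
  }
  if (is.null(pr$point_um)) stop("probe '", pr$name, "' needs point_um or cell/region")
  p_cm <- um_to_cm(pr$point_um)
  loc <- locate_point(mesh, p_cm)
  sub <- mesh$tet_sub[loc$tet]
  if (pr$kind == "ue" && sub != 0L) {
    stop("probe '", pr$name, "' lies inside a cell; ue is extracellular")
  }
  if (pr$kind == "ui" && sub == 0L) {
    stop("probe '", pr$name, "' lies outside every cell; ui is intracellular")
  }
  dofs <- if (pr$kind == "ue") {
    cache$e_map[mesh$tets[loc$tet, ]]
  } else {
    cache$i_map[[sub]][mesh$tets[loc$tet, ]]
  }
  if (any(dofs == 0L) && pr$kind == "ue") {
    # vertex on the outer boundary contributes ue = 0
  }
  h_cm <- um_to_cm(mesh$h_um)
  g <- mesh$grid
  lim <- c(range(g$xb_cm), range(g$yb_cm), range(g$zb_cm))
  dmin <- min(abs(p_cm - lim[c(1, 3, 5)]), abs(lim[c(2, 4, 6)] - p_cm))
  if (is.finite(h_cm) && dmin < 5 * h_cm) {
    warning(sprintf("probe '%s' is within 5h of the outer boundary; values may be biased by the truncated domain",
                    pr$name))
  }
  list(name = pr$name, kind = pr$kind, cell = sub, tet = loc$tet,
       weights = loc$weights, dofs = dofs, pos_cm = p_cm)
}

# --- time stepping ----------------------------------------------------------

#' Initial coupled state of an EMI problem
#'
#' Membrane potentials and gates start from the per-cell resting state (or
#' from user-supplied per-cell checkpoints), the intracellular potentials
#' uniformly at v0, the extracellular potential at zero.
#'
#' @param cache An `emi_cache` from [assemble_operators()].
#' @return An `emi_state` with fields `x` (stacked ue/ui dofs), `mem`
#'   (per-cell `v`, `s`), `t`, `Im`.
#' @export
emi_initial_state <- function(cache) {
  problem <- cache$problem
  x <- numeric(cache$ndof)
  memst <- vector("list", cache$ncell)
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    init <- if (!is.null(problem$init)) problem$init[[c_]] else NULL
    if (is.null(init)) {
      ss <- steady_state(mc$model, region = colnames(mc$W)[1],
                         horizon_ms = 1000, dt_ms = 0.02)
      v0 <- ss$v
      S <- rt_gate_init(mc$rt, rep(v0, length(mc$vids)))
    } else {
      v0 <- init$v
      S <- matrix(rep(as.numeric(init$s), each = length(mc$vids)),
                  nrow = length(mc$vids),
                  dimnames = list(NULL, colnames(init$s) %||% cache$mem[[c_]]$rt$gate_cols))
      S <- S[, mc$rt$gate_cols, drop = FALSE]
    }
    memst[[c_]] <- list(v = rep(v0, length(mc$vids)), s = S)
    x[cache$i_map[[c_]][cache$i_map[[c_]] > 0]] <- v0
  }
  structure(list(x = x, mem = memst, t = 0, Im = NULL), class = "emi_state")
}

electrode_flux_at <- function(cache, t) {
  g <- 0
  for (s in cache$stimuli) {
    if (inherits(s, "electrode_stimulus")) g <- g + electrode_boundary_flux(s, t)
  }
  g
}

somatic_Is_at <- function(cache, c_, t) {
  mc <- cache$mem[[c_]]
  Is <- numeric(length(mc$vids))
  for (s in cache$stimuli) {
    if (inherits(s, "somatic_stimulus") && s$cell == c_ &&
        t >= s$window[1] && t < s$window[2]) {
      if (s$region %in% colnames(mc$W)) {
        Is <- Is + s$Is * mc$W[, s$region]
      }
    }
  }
  Is
}

#' One elliptic (PDE) half-step of the splitting
#'
#' Given the post-ODE membrane potential v*, solves the backward-Euler
#' coupled interface problem for (ui, ue) and updates v = ui - ue and the
#' transmembrane current density Im = (Cm/dt)(v - v*) at every active
#' membrane vertex.
#'
#' @param cache An `emi_cache`.
#' @param state An `emi_state` whose `mem` holds v*.
#' @param t Time at the end of the step (ms), at which boundary data are
#'   evaluated.
#' @return The updated `emi_state`.
#' @export
pde_step <- function(cache, state, t = state$t) {
  b <- numeric(cache$ndof)
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    bv <- mc$beta * state$mem[[c_]]$v
    b[mc$i_idx] <- b[mc$i_idx] + bv
    b[mc$e_idx] <- b[mc$e_idx] - bv
  }
  if (!is.null(cache$elec)) {
    g <- electrode_flux_at(cache, t)
    if (g != 0) b[cache$elec$dofs] <- b[cache$elec$dofs] + g * cache$elec$lump
  }
  x <- as.numeric(Matrix::solve(cache$chol, b, system = "A"))
  if (is.null(state$residual_checked)) {
    tol <- cache$problem$solver$tol %||% 1e-10
    res <- sqrt(sum((as.numeric(cache$A %*% x) - b)^2))
    nb <- sqrt(sum(b^2))
    if (nb > 0 && res > max(tol, 1e-8) * nb) {
      stop(sprintf("linear solve residual %.3g exceeds tolerance (|b| = %.3g)",
                   res, nb))
    }
    state$residual_checked <- TRUE
  }
  state$x <- x
  state$Im <- vector("list", cache$ncell)
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    v_new <- x[mc$i_idx] - x[mc$e_idx]
    state$Im[[c_]] <- mc$cm / cache$dt * (v_new - state$mem[[c_]]$v)
    state$mem[[c_]]$v <- v_new
  }
  state
}

#' One full operator-splitting step
#'
#' Membrane ODE substeps (Rush-Larsen gates, forward-Euler voltage with
#' ionic and stimulus currents) over `dt`, followed by the coupled elliptic
#' solve ([pde_step()]).
#'
#' @param cache An `emi_cache`.
#' @param state An `emi_state`.
#' @return The state advanced by one global step.
#' @export
advance <- function(cache, state) {
  dt <- cache$dt
  n_sub <- as.integer(round(dt / cache$problem$dt_sub))
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    Is <- somatic_Is_at(cache, c_, state$t)
    out <- rt_ode_substeps(mc$rt, state$mem[[c_]]$v, state$mem[[c_]]$s, Is,
                           dt / n_sub, n_sub, t0 = state$t)
    state$mem[[c_]]$v <- out$v
    state$mem[[c_]]$s <- out$S
  }
  state <- pde_step(cache, state, t = state$t + dt)
  state$t <- state$t + dt
  state
}

probe_values <- function(cache, state) {
  vapply(cache$probes, function(pp) {
    if (pp$kind == "v") {
      state$mem[[pp$cell]]$v[pp$local]
    } else if (!is.null(pp[["mdof"]])) {
      if (is.na(pp$mdof) || pp$mdof == 0L) 0 else state$x[pp$mdof]
    } else {
      vals <- ifelse(pp$dofs == 0L, 0, state$x[pmax(pp$dofs, 1L)])
      sum(pp$weights * vals)
    }
  }, 0)
}

#' Run a full EMI (or open-loop MI+E) simulation
#'
#' Advances the problem from its initial state to `T_end_ms`, recording all
#' probes every `output_stride` steps. Fully deterministic: identical
#' problems produce identical traces.
#'
#' In `mode = "mie"` the bidirectional coupling is switched off: the
#' extracellular potential seen by the membrane is the analytic far field
#' of the electrode source alone (no membrane feedback), and only the
#' intracellular problems are solved. This is the classical open-loop
#' workflow against which the fully coupled model is compared.
#'
#' @param problem An [emi_problem()] (or a prebuilt `emi_cache`).
#' @param mode `"emi"` (fully coupled) or `"mie"` (open loop).
#' @return A `simulation_result` with `traces` (data.frame, `t_ms` plus one
#'   column per probe), the final `state`, and run metadata.
#' @export
run_simulation <- function(problem, mode = c("emi", "mie")) {
  mode <- match.arg(mode)
  cache <- if (inherits(problem, "emi_cache")) problem else assemble_operators(problem)
  if (mode == "mie") cache <- mie_prepare(cache)
  state <- emi_initial_state(cache)
  nstep <- as.integer(round(cache$problem$T_end / cache$dt))
  stride <- max(1L, cache$problem$output_stride)
  rec_at <- seq(0L, nstep, by = stride)
  traces <- matrix(NA_real_, length(rec_at), length(cache$probes),
                   dimnames = list(NULL, vapply(cache$probes, `[[`, "", "name")))
  if (length(cache$probes)) traces[1, ] <- probe_values(cache, state)
  ri <- 2L
  for (k in seq_len(nstep)) {
    state <- if (mode == "emi") advance(cache, state) else mie_advance(cache, state)
    if (!all(is.finite(state$mem[[1]]$v %||% 0)) || !all(is.finite(state$x))) {
      stop(sprintf("non-finite field at t = %.6g ms", state$t))
    }
    if (ri <= length(rec_at) && k == rec_at[ri]) {
      if (length(cache$probes)) traces[ri, ] <- probe_values(cache, state)
      ri <- ri + 1L
    }
  }
  structure(list(traces = data.frame(t_ms = rec_at * cache$dt, traces,
                                     check.names = FALSE),
                 state = state, mode = mode,
                 dt_ms = cache$dt, T_end_ms = cache$problem$T_end),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result (%s): %g ms at dt = %g ms, %d probe(s), %d sample(s)\n",
              x$mode, x$T_end_ms, x$dt_ms, ncol(x$traces) - 1L, nrow(x$traces)))
  invisible(x)
}

#' Transmembrane current density from the last elliptic solve
#'
#' Returns the algebraically exact discrete membrane current
#' \eqn{I_m = (C_m/\Delta t)(v - v^*)} per active membrane vertex, and its
#' facet-averaged form (with areas and centroids) for point-source
#' summation in the open-loop workflow.
#'
#' @param state An `emi_state` after at least one [pde_step()].
#' @param cache The `emi_cache` that produced it.
#' @return `list(vertex = <per-cell list of vertex current densities>,
#'   facets = <data.frame with cell, region, area_cm2, centroid, Im>)`.
#' @export
membrane_current_from_solution <- function(state, cache) {
  if (is.null(state$Im)) {
    stop("no membrane current available: call pde_step()/advance() first")
  }
  mesh <- cache$mesh
  sel <- which(mesh$membrane$region != "MYELIN")
  tri <- mesh$membrane$verts[sel, , drop = FALSE]
  cellf <- mesh$membrane$cell[sel]
  Imf <- numeric(length(sel))
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    iv <- numeric(nrow(mesh$vertices))
    iv[mc$vids] <- state$Im[[c_]]
    rows <- cellf == c_
    Imf[rows] <- (iv[tri[rows, 1]] + iv[tri[rows, 2]] + iv[tri[rows, 3]]) / 3
  }
  ctr <- facet_centroids(mesh, tri)
  list(vertex = state$Im,
       facets = data.frame(cell = cellf, region = mesh$membrane$region[sel],
                           area_cm2 = cache$fg$membrane$area[sel],
                           x_cm = ctr[, 1], y_cm = ctr[, 2], z_cm = ctr[, 3],
                           Im_uA_per_cm2 = Imf))
}

# Direct P1 conormal flux -n_i . sigma_i grad(ui) per active membrane facet,
# for cross-checking the closure form of Im.
facet_flux_direct <- function(state, cache) {
  mesh <- cache$mesh
  sel <- which(mesh$membrane$region != "MYELIN")
  out <- numeric(length(sel))
  sigma_i <- rep_len(cache$sigma$sigma_i, max(1L, cache$ncell))
  fgn <- cache$fg$membrane$normal
  for (k in seq_along(sel)) {
    f <- sel[k]
    tet <- mesh$membrane$intra_tet[f]
    c_ <- mesh$tet_sub[tet]
    vids <- mesh$tets[tet, ]
    vv <- mesh$vertices[vids, , drop = FALSE]
    Jm <- rbind(vv[2, ] - vv[1, ], vv[3, ] - vv[1, ], vv[4, ] - vv[1, ])
    Ginv <- solve(Jm)
    G <- cbind(-rowSums(Ginv), Ginv)   # gradients as columns per vertex
    ui <- state$x[cache$i_map[[c_]][vids]]
    grad <- as.numeric(G %*% ui)
    out[k] <- -sigma_i[c_] * sum(fgn[f, ] * grad)
  }
  out
}

# --- open-loop (MI+E) variant ----------------------------------------------

mie_prepare <- function(cache) {
  els <- Filter(function(s) inherits(s, "electrode_stimulus"), cache$stimuli)
  cache$mie <- list(stimuli = els, chol = vector("list", cache$ncell),
                    r_cm = vector("list", cache$ncell))
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    imap <- cache$i_map[[c_]]
    verts_c <- which(imap > 0L)
    lmap <- integer(length(imap))
    lmap[verts_c] <- seq_along(verts_c)
    trip <- stiffness_triplets(cache$mesh$vertices,
                               cache$mesh$tets[cache$mesh$tet_sub == c_, , drop = FALSE],
                               rep_len(cache$sigma$sigma_i, cache$ncell)[c_], lmap)
    li <- lmap[mc$vids]
    Ai <- Matrix::sparseMatrix(i = c(trip$i, li), j = c(trip$j, li),
                               x = c(trip$x, mc$beta),
                               dims = rep(length(verts_c), 2))
    cache$mie$chol[[c_]] <- Matrix::Cholesky(Matrix::forceSymmetric(Ai, "L"),
                                             LDL = FALSE)
    cache$mie$lmap[[c_]] <- lmap
    if (length(els) && !is.null(cache$elec)) {
      d <- sqrt(rowSums((mc$pos - matrix(cache$elec$center_cm,
                                         nrow(mc$pos), 3, byrow = TRUE))^2))
      cache$mie$r_cm[[c_]] <- d
    }
  }
  cache
}

mie_ue_at <- function(cache, c_, t) {
  ue <- numeric(length(cache$mem[[c_]]$vids))
  for (s in cache$mie$stimuli) {
    ue <- ue + electrode_farfield(s, cache$sigma$sigma_e,
                                  cache$mie$r_cm[[c_]], t)
  }
  ue
}

mie_advance <- function(cache, state) {
  dt <- cache$dt
  n_sub <- as.integer(round(dt / cache$problem$dt_sub))
  t_new <- state$t + dt
  for (c_ in seq_len(cache$ncell)) {
    mc <- cache$mem[[c_]]
    Is <- somatic_Is_at(cache, c_, state$t)
    out <- rt_ode_substeps(mc$rt, state$mem[[c_]]$v, state$mem[[c_]]$s, Is,
                           dt / n_sub, n_sub, t0 = state$t)
    ue_a <- mie_ue_at(cache, c_, t_new)
    lmap <- cache$mie$lmap[[c_]]
    nloc <- sum(lmap > 0L)
    b <- numeric(nloc)
    li <- lmap[mc$vids]
    b[li] <- mc$beta * (out$v + ue_a)
    ui <- as.numeric(Matrix::solve(cache$mie$chol[[c_]], b, system = "A"))
    v_new <- ui[li] - ue_a
    state$Im[[c_]] <- mc$cm / dt * (v_new - out$v)
    state$mem[[c_]]$v <- v_new
    state$mem[[c_]]$s <- out$S
    state$x[cache$i_map[[c_]][cache$i_map[[c_]] > 0]] <- ui
  }
  state$t <- t_new
  state
}
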