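# Region-dependent ionic membrane models and their ODE integration.
#
# A membrane model is a list of channels; each channel has a reversal
# potential, a per-region maximal conductance density and a set of gates.
# Gate kinetics are given as closed-form expressions of v in a small
# arithmetic grammar (see parse_rate_expr), either as alpha/beta rates or as
# inf/tau pairs. Gates advance with the first-order Rush-Larsen exponential
# update; the membrane potential advances by forward Euler within the ODE
# substep (the coupling current I_m belongs to the PDE step of the
# splitting).

V_GRID <- seq(-120, 60, by = 1)  # validation grid, mV

#' Gating variable specification
#'
#' @param name Gate name (e.g. `"m"`).
#' @param exponent Exponent `p >= 0` of the gate in the channel open
#'   probability product.
#' @param alpha,beta Rate expressions (strings in the model grammar, 1/ms)
#'   for the alpha-beta formulation.
#' @param inf,tau Steady state and time constant (ms) expressions for the
#'   inf-tau formulation.
#'
#' Exactly one formulation must be given. At construction the expressions
#' are validated on a voltage grid covering -120..60 mV: `tau(v)` must be
#' positive and `0 <= inf(v) <= 1` throughout.
#' @return A `gate_spec`.
#' @export
gate_spec <- function(name, exponent = 1, alpha = NULL, beta = NULL,
                      inf = NULL, tau = NULL) {
  stopifnot(is.character(name), length(name) == 1L, exponent >= 0)
  ab <- !is.null(alpha) && !is.null(beta)
  it <- !is.null(inf) && !is.null(tau)
  if (ab == it) {
    stop("gate '", name, "': give either alpha+beta or inf+tau expressions")
  }
  g <- structure(list(name = name, exponent = exponent,
                      formulation = if (ab) "alpha-beta" else "inf-tau",
                      alpha = alpha, beta = beta, inf = inf, tau = tau),
                 class = "gate_spec")
  g$funs <- compile_gate(g)
  it_ <- gate_inf_tau(g, V_GRID)
  if (any(!is.finite(it_$tau)) || any(it_$tau <= 0)) {
    stop("gate '", name, "': tau(v) must be positive on [-120, 60] mV")
  }
  if (any(!is.finite(it_$inf)) || any(it_$inf < 0) || any(it_$inf > 1)) {
    stop("gate '", name, "': steady state must lie in [0, 1] on [-120, 60] mV")
  }
  g
}

compile_gate <- function(g) {
  if (g$formulation == "alpha-beta") {
    list(alpha = parse_rate_expr(g$alpha), beta = parse_rate_expr(g$beta))
  } else {
    list(inf = parse_rate_expr(g$inf), tau = parse_rate_expr(g$tau))
  }
}

# steady state and time constant of a gate at voltages v
gate_inf_tau <- function(gate, v) {
  f <- gate$funs
  if (gate$formulation == "alpha-beta") {
    a <- f$alpha(v); b <- f$beta(v)
    tau <- 1 / (a + b)
    list(inf = a * tau, tau = tau)
  } else {
    list(inf = f$inf(v), tau = f$tau(v))
  }
}

#' Ion channel specification
#'
#' @param name Channel name.
#' @param reversal_mV Reversal potential (mV). Ionic concentrations are
#'   treated as constant, so reversal potentials are fixed model constants.
#' @param g_mS_per_cm2 Named numeric vector of maximal conductance densities
#'   (mS/cm^2) per region label; the name `"default"` supplies the value for
#'   unlisted regions. Regions without a value (and MYELIN always) get 0.
#' @param gates List of [gate_spec()] objects (empty for an ohmic leak).
#' @return A `channel_spec`.
#' @export
channel_spec <- function(name, reversal_mV, g_mS_per_cm2, gates = list()) {
  stopifnot(is.character(name), is.numeric(reversal_mV),
            is.numeric(g_mS_per_cm2), !is.null(names(g_mS_per_cm2)))
  assert_region(setdiff(names(g_mS_per_cm2), "default"),
                "region label in conductance table")
  if (any(g_mS_per_cm2 < 0)) stop("channel '", name, "': conductances must be >= 0")
  if (isTRUE(g_mS_per_cm2[["MYELIN"]] > 0)) {
    stop("channel '", name, "': MYELIN must have zero conductance")
  }
  stopifnot(all(vapply(gates, inherits, TRUE, "gate_spec")))
  structure(list(name = name, reversal_mV = reversal_mV,
                 g_mS_per_cm2 = g_mS_per_cm2, gates = gates),
            class = "channel_spec")
}

#' Membrane model: channels plus capacitance map
#'
#' @param channels List of [channel_spec()] objects.
#' @param cm_uF_per_cm2 Named numeric vector of specific capacitance per
#'   region (`"default"` for unlisted regions). MYELIN is forced to 0: on
#'   myelinated membrane both the ionic current and the capacitance vanish
#'   and the facets become no-flux boundaries.
#' @param name Model name (used in file IO).
#' @param spontaneous Logical hint: `TRUE` marks models known to be
#'   autonomously active, for which [steady_state()] is expected not to
#'   converge.
#' @return A `membrane_model`.
#' @export
membrane_model <- function(channels, cm_uF_per_cm2 = c(default = 1, MYELIN = 0),
                           name = "model", spontaneous = FALSE) {
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_spec")))
  stopifnot(is.numeric(cm_uF_per_cm2), !is.null(names(cm_uF_per_cm2)))
  assert_region(setdiff(names(cm_uF_per_cm2), "default"),
                "region label in capacitance table")
  if (any(cm_uF_per_cm2 < 0)) stop("capacitance must be >= 0")
  if (!is.na(region_value(cm_uF_per_cm2, "MYELIN", default = NA)) &&
      cm_uF_per_cm2[["MYELIN"]] != 0) {
    stop("MYELIN must have zero capacitance")
  }
  nm <- unlist(lapply(channels, function(ch)
    if (length(ch$gates)) paste(ch$name, vapply(ch$gates, `[[`, "", "name"),
                                sep = ".") else character(0)))
  structure(list(name = name, channels = channels,
                 cm_uF_per_cm2 = cm_uF_per_cm2,
                 gate_names = nm, spontaneous = spontaneous),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("membrane_model '%s': %d channel(s), %d gate(s)%s\n", x$name,
              length(x$channels), length(x$gate_names),
              if (x$spontaneous) " [spontaneously active]" else ""))
  for (ch in x$channels) {
    gdesc <- if (length(ch$gates)) {
      paste(vapply(ch$gates, function(g) sprintf("%s^%g", g$name, g$exponent),
                   ""), collapse = " ")
    } else "(ohmic)"
    cat(sprintf("  %s: E = %g mV, g = {%s} mS/cm2, %s\n", ch$name,
                ch$reversal_mV,
                paste(sprintf("%s: %g", names(ch$g_mS_per_cm2),
                              ch$g_mS_per_cm2), collapse = ", "), gdesc))
  }
  invisible(x)
}

# region -> value lookup with "default" fallback; MYELIN falls back to 0,
# never to "default" (myelin carries no channels or capacitance).
region_value <- function(map, region, default = 0) {
  out <- numeric(length(region))
  for (i in seq_along(region)) {
    r <- region[i]
    out[i] <- if (r %in% names(map)) {
      map[[r]]
    } else if (r == "MYELIN") {
      0
    } else if ("default" %in% names(map)) {
      map[["default"]]
    } else {
      default
    }
  }
  out
}

#' Ionic current density of a membrane model
#'
#' Evaluates \eqn{I_{ion} = \sum_c g_c(region) \prod_j s_j^{p_j} (v - E_c)}
#' in uA/cm^2, outward positive.
#'
#' @param model A [membrane_model()].
#' @param v Membrane potential(s), mV.
#' @param s Gate values: a named vector (names `channel.gate`) for scalar
#'   `v`, or a matrix with one row per element of `v` and those column
#'   names.
#' @param region Region label at which to evaluate the densities.
#' @return Ionic current density, uA/cm^2.
#' @export
evaluate_iion <- function(model, v, s = NULL, region = "SOMA") {
  assert_region(region)
  if (region == "MYELIN") {
    stop("MYELIN carries no ionic model (Iion and Cm are zero there)")
  }
  if (is.null(s)) s <- matrix(numeric(0), nrow = length(v), ncol = 0)
  if (is.null(dim(s))) s <- matrix(s, nrow = length(v), ncol = length(s),
                                   byrow = TRUE, dimnames = list(NULL, names(s)))
  iion <- numeric(length(v))
  for (ch in model$channels) {
    g <- region_value(ch$g_mS_per_cm2, region)
    if (g == 0) next
    open <- rep(1, length(v))
    for (gt in ch$gates) {
      cn <- paste(ch$name, gt$name, sep = ".")
      if (!cn %in% colnames(s)) stop("missing gate state '", cn, "'")
      open <- open * s[, cn]^gt$exponent
    }
    iion <- iion + g * open * (v - ch$reversal_mV)
  }
  iion
}

#' Rush-Larsen update of a single gate
#'
#' For voltage held fixed over the substep the gate ODE
#' \eqn{ds/dt = (s_\infty(v) - s)/\tau(v)} is linear; the Rush-Larsen
#' scheme advances it exactly:
#' \eqn{s_1 = s_\infty + (s_0 - s_\infty) e^{-dt/\tau}}.
#'
#' @param gate A [gate_spec()].
#' @param s0 Current gate value(s).
#' @param v Membrane potential (mV), scalar or vector matching `s0`.
#' @param dt Substep (ms), > 0.
#' @return Updated gate value(s), clipped to [0, 1] only when outside by
#'   less than 1e-12 (pure floating-point excursions).
#' @export
rush_larsen_gate_update <- function(gate, s0, v, dt) {
  stopifnot(dt > 0)
  it <- gate_inf_tau(gate, v)
  if (any(!is.finite(it$tau)) || any(it$tau <= 0)) {
    stop("gate '", gate$name, "': tau(v) <= 0")
  }
  s1 <- it$inf + (s0 - it$inf) * exp(-dt / it$tau)
  clip01(s1)
}

clip01 <- function(s, slack = 1e-12) {
  s[s < 0 & s > -slack] <- 0
  s[s > 1 & s < 1 + slack] <- 1
  s
}

# --- vectorized runtime used by the ODE stepper and the solver --------------

# Per-vertex compiled model: region_w is an n x R matrix of membrane-area
# fractions per region (columns named by region). Conductances and
# capacitance are area-weighted across regions meeting at a vertex.
membrane_runtime <- function(model, region_w) {
  regs <- colnames(region_w)
  assert_region(regs)
  n <- nrow(region_w)
  cmv <- as.vector(region_w %*% region_value(model$cm_uF_per_cm2, regs))
  chans <- list()
  gate_cols <- character(0)
  funs <- list(); fgate <- character(0)
  for (ch in model$channels) {
    gv <- as.vector(region_w %*% region_value(ch$g_mS_per_cm2, regs))
    cols <- if (length(ch$gates)) paste(ch$name, vapply(ch$gates, `[[`, "", "name"),
                                        sep = ".") else character(0)
    chans[[ch$name]] <- list(g = gv, E = ch$reversal_mV, cols = cols,
                             p = vapply(ch$gates, `[[`, 0, "exponent"))
    for (k in seq_along(ch$gates)) {
      funs[[cols[k]]] <- ch$gates[[k]]
      fgate <- c(fgate, cols[k])
    }
    gate_cols <- c(gate_cols, cols)
  }
  list(n = n, cm = cmv, channels = chans, gates = funs,
       gate_cols = gate_cols, region_w = region_w)
}

rt_iion <- function(rt, v, S) {
  iion <- numeric(length(v))
  for (ch in rt$channels) {
    open <- if (length(ch$cols)) {
      o <- S[, ch$cols[1]]^ch$p[1]
      for (k in seq_along(ch$cols)[-1]) o <- o * S[, ch$cols[k]]^ch$p[k]
      o
    } else 1
    iion <- iion + ch$g * open * (v - ch$E)
  }
  iion
}

rt_gate_init <- function(rt, v) {
  S <- matrix(0, length(v), length(rt$gate_cols),
              dimnames = list(NULL, rt$gate_cols))
  for (cn in rt$gate_cols) S[, cn] <- gate_inf_tau(rt$gates[[cn]], v)$inf
  S
}

# One batch of n_sub Rush-Larsen + forward-Euler substeps. Gates are updated
# from the voltage at the start of each substep, then the voltage advances
# with the updated gates (first-order Rush-Larsen as generated by standard
# cell-model compilers). Returns list(v, S).
rt_ode_substeps <- function(rt, v, S, Is, dt, n_sub, t0 = 0) {
  cm <- rt$cm
  if (any(cm <= 0)) stop("ODE step on a vertex with Cm <= 0")
  for (k in seq_len(n_sub)) {
    for (cn in rt$gate_cols) {
      it <- gate_inf_tau(rt$gates[[cn]], v)
      S[, cn] <- it$inf + (S[, cn] - it$inf) * exp(-dt / it$tau)
    }
    S <- clip01(S)
    v <- v - dt * (rt_iion(rt, v, S) + Is) / cm
    if (any(!is.finite(v)) || any(!is.finite(S))) {
      bad <- which(!is.finite(v))[1]
      if (is.na(bad)) bad <- which(!is.finite(S), arr.ind = TRUE)[1, 1]
      stop(sprintf("non-finite membrane state at vertex %d, t = %.6g ms",
                   bad, t0 + k * dt))
    }
  }
  list(v = v, S = S)
}

#' Membrane state on a set of active membrane vertices
#'
#' @param model A [membrane_model()].
#' @param region Character vector of region labels, one per vertex (no
#'   MYELIN: myelinated membrane carries no state).
#' @param v Initial membrane potential (mV), recycled to the vertex count.
#' @param s Optional gate matrix; defaults to the steady state of each gate
#'   at `v`.
#' @param t Initial time (ms).
#' @return A `membrane_state` with elements `v`, `s`, `t`.
#' @export
membrane_state <- function(model, region, v = -65, s = NULL, t = 0,
                           region_w = NULL) {
  if (is.null(region_w)) {
    assert_region(region)
    if (any(region == "MYELIN")) stop("MYELIN vertices carry no membrane state")
    n <- length(region)
    region_w <- outer(region, sort(unique(region)), `==`) * 1
    colnames(region_w) <- sort(unique(region))
  } else {
    n <- nrow(region_w)
    region <- rep(colnames(region_w)[1], n)
  }
  rt <- membrane_runtime(model, region_w)
  v <- rep_len(v, n)
  if (is.null(s)) s <- rt_gate_init(rt, v)
  stopifnot(nrow(s) == n)
  structure(list(v = v, s = s, t = t, region = region, runtime = rt),
            class = "membrane_state")
}

#' Advance the membrane ODE sub-system
#'
#' Integrates gates (Rush-Larsen) and membrane potential (forward Euler on
#' \eqn{dv/dt = -(I_{ion} + I_s)/C_m}) over one global step split into
#' uniform substeps. The transmembrane coupling current \eqn{I_m} is not
#' included here; it enters through the PDE step of the operator splitting.
#'
#' @param model A [membrane_model()] (must be the one the state was built
#'   with).
#' @param state A [membrane_state()].
#' @param Is Stimulation current density (uA/cm^2), scalar, per-vertex
#'   vector, or named per-region vector.
#' @param dt_global Global step (ms).
#' @param dt_sub Substep (ms); must divide `dt_global` to within 1e-12
#'   relative.
#' @return The advanced `membrane_state`.
#' @export
membrane_ode_step <- function(model, state, Is = 0, dt_global,
                              dt_sub = dt_global) {
  stopifnot(inherits(state, "membrane_state"), dt_global > 0, dt_sub > 0)
  n_sub <- dt_global / dt_sub
  if (abs(n_sub - round(n_sub)) > 1e-12 * n_sub) {
    stop("dt_sub must divide dt_global")
  }
  n_sub <- as.integer(round(n_sub))
  if (!is.null(names(Is))) Is <- region_value(Is, state$region)
  Is <- rep_len(Is, length(state$v))
  out <- rt_ode_substeps(state$runtime, state$v, state$s, Is,
                         dt_sub, n_sub, t0 = state$t)
  state$v <- out$v
  state$s <- out$S
  state$t <- state$t + dt_global
  state
}

#' Resting state of a membrane model
#'
#' Relaxes the space-clamped ODE system (no coupling current, `Is = 0`)
#' from -65 mV with gates at their steady state, and reports the final
#' state. Spontaneously active models legitimately never converge; they
#' return `converged = FALSE` rather than an error.
#'
#' @param model A [membrane_model()].
#' @param region Region whose densities to use.
#' @param horizon_ms Relaxation horizon (default 2000 ms).
#' @param dt_ms Integration substep.
#' @param v0 Starting potential (mV).
#' @return `list(v, s, converged, dvdt)` where `converged` requires
#'   `|dv/dt| <= 1e-6` mV/ms at the end of the horizon.
#' @export
steady_state <- function(model, region = "SOMA", horizon_ms = 2000,
                         dt_ms = 0.01, v0 = -65) {
  st <- membrane_state(model, region, v = v0)
  n <- as.integer(round(horizon_ms / dt_ms))
  out <- rt_ode_substeps(st$runtime, st$v, st$s, 0, dt_ms, n)
  dvdt <- -rt_iion(st$runtime, out$v, out$S) / st$runtime$cm
  list(v = as.numeric(out$v), s = out$S,
       converged = abs(dvdt) <= 1e-6 && !isTRUE(model$spontaneous),
       dvdt = as.numeric(dvdt))
}

# Space-clamped trajectory under constant Is; used for limit-cycle
# initialization of phase-staggered cells and as a light-weight experiment
# design tool. Returns list(t, v, s = matrix), sampled every `stride` steps.
ode_trajectory <- function(model, region = "SOMA", Is = 0, T_ms, dt_ms = 0.01,
                           init = NULL, stride = 1L, region_w = NULL) {
  st <- membrane_state(model, region, v = if (is.null(init)) -65 else init$v,
                       s = if (is.null(init)) NULL else init$s,
                       region_w = region_w)
  n <- as.integer(round(T_ms / dt_ms))
  keep <- seq(0L, n, by = stride)
  V <- numeric(length(keep)); V[1] <- st$v
  Smat <- matrix(0, length(keep), ncol(st$s), dimnames = list(NULL, colnames(st$s)))
  Smat[1, ] <- st$s
  v <- st$v; S <- st$s; ki <- 2L
  for (k in seq_len(n)) {
    out <- rt_ode_substeps(st$runtime, v, S, Is, dt_ms, 1L, t0 = (k - 1) * dt_ms)
    v <- out$v; S <- out$S
    if (ki <= length(keep) && k == keep[ki]) {
      V[ki] <- v; Smat[ki, ] <- S; ki <- ki + 1L
    }
  }
  list(t = keep * dt_ms, v = V, s = Smat)
}

# States on the limit cycle of a tonically firing space-clamped model:
# burn-in, then return the state at the end and at `offset_ms` earlier.
# Used to start two-cell simulations with a controlled spike-time offset.
limit_cycle_states <- function(model, region = "SOMA", Is, burn_in_ms = 300,
                               offset_ms = 5, dt_ms = 0.01, region_w = NULL) {
  tr <- ode_trajectory(model, region, Is, T_ms = burn_in_ms, dt_ms = dt_ms,
                       region_w = region_w)
  n <- length(tr$t)
  k_off <- n - as.integer(round(offset_ms / dt_ms))
  if (k_off < 1L) stop("offset exceeds the burn-in horizon")
  list(lead = list(v = tr$v[n], s = tr$s[n, , drop = FALSE]),
       lag = list(v = tr$v[k_off], s = tr$s[k_off, , drop = FALSE]))
}

# --- bundled reference models ------------------------------------------------

#' Standard Hodgkin-Huxley membrane model
#'
#' The classical squid-axon model (gNa = 120, gK = 36, gL = 0.3 mS/cm^2;
#' ENa = 50, EK = -77, EL = -54.387 mV; Cm = 1 uF/cm^2) with uniform
#' densities over all active regions and zeros on MYELIN. Serves as the
#' excitable fixture model; cell-type-specific kinetics are loaded from
#' model files instead (see [load_model_spec()]).
#'
#' @return A [membrane_model()].
#' @export
hh_model <- function() {
  membrane_model(
    name = "hh",
    channels = list(
      channel_spec("Na", 50, c(default = 120, MYELIN = 0), list(
        gate_spec("m", 3,
                  alpha = "expm1_div(-(v + 40) / 10)",
                  beta = "4 * exp(-(v + 65) / 18)"),
        gate_spec("h", 1,
                  alpha = "0.07 * exp(-(v + 65) / 20)",
                  beta = "1 / (1 + exp(-(v + 35) / 10))"))),
      channel_spec("K", -77, c(default = 36, MYELIN = 0), list(
        gate_spec("n", 4,
                  alpha = "0.1 * expm1_div(-(v + 55) / 10)",
                  beta = "0.125 * exp(-(v + 65) / 80)"))),
      channel_spec("leak", -54.387, c(default = 0.3, MYELIN = 0))),
    cm_uF_per_cm2 = c(default = 1, MYELIN = 0))
}

#' Passive (leak-only) membrane model
#'
#' @param g_mS_per_cm2 Leak conductance density.
#' @param E_mV Leak reversal potential (= resting potential).
#' @param cm_uF_per_cm2 Specific capacitance.
#' @return A [membrane_model()].
#' @export
passive_model <- function(g_mS_per_cm2 = 0.1, E_mV = -70, cm_uF_per_cm2 = 1) {
  membrane_model(
    name = "passive",
    channels = list(channel_spec("leak", E_mV,
                                 c(default = g_mS_per_cm2, MYELIN = 0))),
    cm_uF_per_cm2 = c(default = cm_uF_per_cm2, MYELIN = 0))
}
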