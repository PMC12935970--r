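---
title: "Methods: the coupled EMI model, its discretization, and the desk-scale fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled EMI model, its discretization, and the desk-scale fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`emisim` solves the geometrically explicit EMI (Extracellular-Membrane-
Intracellular) formulation of neural electrodynamics. The intracellular
domain of each cell, $\Omega_i$, and the shared extracellular domain,
$\Omega_e$, each carry a quasi-static potential,

$$\nabla\cdot\sigma_i\nabla u_i = 0 \;\text{in } \Omega_i, \qquad
  \nabla\cdot\sigma_e\nabla u_e = 0 \;\text{in } \Omega_e,$$

coupled across the explicit membrane surface $\Gamma$ by conservation of
current, $n_e\cdot\sigma_e\nabla u_e = -n_i\cdot\sigma_i\nabla u_i = I_m$,
and by the membrane dynamics

$$C_m\frac{\partial v}{\partial t} = I_m - (I_{ion}(v, s) + I_s), \qquad
  \frac{ds}{dt} = F(v, s), \qquad v = u_i - u_e \;\text{on }\Gamma .$$

Myelinated membrane has $C_m = 0$ and no channels; it degenerates to a
no-flux condition on both sides. The outer boundary is grounded
($u_e = 0$), and a spherical stimulation electrode enters as a Neumann
condition on the surface of a cavity cut out of $\Omega_e$: constant
protocol $-I_e/A_e$, sinusoidal protocol $(I_e/A_e)\sin(2\pi f t)$ with
$t$ in seconds (simulation time is in ms; the unit conversion is isolated
in one function and unit-tested). Because both formulas divide by the
*measured* discrete cavity area $A_e$, the injected total current is exact
regardless of how coarsely the staircase cavity approximates a sphere.

Unlike cable-equation or open-loop ("MI+E") treatments, nothing here
assumes the extracellular potential is a passive readout: the membrane and
both volumes are solved together, which is what makes ephaptic coupling
between closely apposed cells, and the loading effect of the extracellular
medium on the membrane, representable.

Units form a closed system with no hidden constants: mV, ms, mS/cm,
uF/cm^2, uA/cm^2, uA, coordinates in cm (entered in um). In these units
uA/mS = mV and uF mV/(ms cm^2) = uA/cm^2.

## Discretization

Each global step $\Delta t$ (default 0.01 ms) applies first-order Godunov
splitting:

1. **Membrane ODE step.** Gating variables advance with the first-order
   Rush-Larsen scheme — exact integration of the linear gate ODE for
   voltage frozen over the substep — and $v$ advances by forward Euler on
   $-(I_{ion}+I_s)/C_m$, optionally with several substeps per global step.
   The coupling current $I_m$ is deliberately absent here; it belongs to
   the elliptic step.
2. **Coupled elliptic step.** Backward Euler on the membrane closure gives
   $(u_i-u_e)|_\Gamma = v^* + (\Delta t/C_m) I_m$ with
   $I_m = -n_i\cdot\sigma_i\nabla u_i$. Eliminating $v$ yields one
   symmetric positive definite system for all $u_i$ and $u_e$ degrees of
   freedom, assembled from P1 stiffness blocks plus a lumped (vertex-mass)
   membrane coupling $\beta_v = C_m A_v/\Delta t$. Membrane vertices carry
   one intracellular and one extracellular dof, so $v = u_i - u_e$ holds
   exactly at dofs. The matrix is time-independent; its sparse Cholesky
   factorization (CHOLMOD via `Matrix`) is computed once and reused every
   step, making each step a pair of triangular solves.

Consequences verified by the test-suite: per-cell area-weighted $I_m$ sums
to zero at every step to solver precision (divergence theorem on the
closed cell); the splitting self-converges at first order in $\Delta t$;
Rush-Larsen is exact for frozen voltage; the discrete potential of the
electrode matches the analytic $-I_e/(4\pi\sigma_e r)$ within 5% at probes
20-80 um from the source on the graded validation box.

The discrete membrane current is reported in its algebraically exact
closure form $I_m = (C_m/\Delta t)(v - v^*)$, which is the variationally
consistent and exactly conservative flux. The elementwise P1 gradient flux
is a different discretization of the same quantity; the two converge to
each other at O(h) on resolved isotropic meshes (checked at two
refinements) but disagree pointwise at box corners and inside thin
anisotropic features — the closure form is the one used everywhere.

## Meshes

Idealized box-union neurons (cuboid soma, optional dendrite stub, axon of
rectangular cross-section partitioned into labelled segments: AIS,
PARA_AIS, MYELIN, RANVIER, ...) are meshed on a rectilinear grid whose
planes are snapped to every geometric feature, each hexahedron split into
six tetrahedra with the Kuhn template (face-conforming across cells).
Snapping makes the discrete membrane area *exact* for box cells and
guarantees at least one element layer in thin features (2 um axons, 1 um
inter-cell gaps) regardless of the nominal mesh size `h_um`. The margin of
extracellular space must be at least `2 h` (two element layers). For
far-field work the margin can be meshed with geometrically growing
elements (`graded_margin`), pushing the grounded boundary hundreds of
micrometres out at logarithmic cost; the point-source validation box grades
from 2.5 um elements at the source to a boundary beyond 4 mm.

Two-cell meshes place mirror-image cells with their axon tips facing
across a gap of extracellular space; the x grid is built on one half and
reflected, so the mirror symmetry is exact to machine precision.

Meshes exchange as ASCII MSH 4.1 (coordinates in um) with the physical
group convention `extra`, `intra_cell<k>`, `outer`, `electrode`,
`membrane_cell<k>_<REGION>`; solution snapshots export as ASCII VTU.

## Membrane models

Models are declarative: channels with per-region maximal conductance
tables, fixed reversal potentials (ionic concentrations are treated as
constant), and gates specified as alpha/beta or inf/tau expressions in a
small validated grammar (`v`, arithmetic, `exp`, `log`, `pow`,
`expm1_div(x) = x/(e^x-1)` for removable singularities). Expressions are
checked on a -120..60 mV grid at load time ($\tau > 0$,
$0 \le s_\infty \le 1$). Cell-type-specific published channel inventories
are therefore user data files, not code; the bundled models are:

* `passive` — ohmic leak (0.1 mS/cm^2, -70 mV);
* `hh` — the classical squid-axon model, uniform densities;
* `hh-ais` — HH kinetics with sodium concentrated in the AIS
  (500 vs 50 mS/cm^2) and moderate potassium, making the AIS the spike
  initiation site. A *uniform* box cell is nearly space-clamped and emits
  almost no extracellular field (its membrane currents cancel pointwise);
  the density gradient is what produces the current dipole — AIS sink,
  somatic return — behind every extracellular signature in the package;
* `hh-pacemaker` — `hh-ais` with the leak reversal depolarized to -48 mV
  (leak 0.2 mS/cm^2), firing spontaneously at ~50 Hz with a slow
  subthreshold ramp. This stands in for the autonomously pacemaking cell
  class of the two-cell synchronization experiments; the slow approach to
  threshold is what makes spike timing sensitive to sub-millivolt cleft
  potentials. Strongly driven relaxation firing has a far smaller phase
  response and would mask the effect.

Initial conditions: quiescent models start from `steady_state()` (2000 ms
relaxation by default; shorter with a coarser substep where the fixture is
known to settle faster). Spontaneously active models never converge —
`steady_state()` returns a flag, not an error — and two-cell runs start
each cell from a checkpoint of its own space-clamped limit cycle, the
lagging cell from the state `offset_ms` (default 5 ms) earlier on the
cycle. The space-clamped surrogate uses area-weighted region densities and
the somatic drive diluted by the soma's membrane-area fraction, which is
the correct reduction for these nearly isopotential box cells.

## Desk-scale fixtures and what they do and do not show

The bundled experiments run on one idealized cell: 20 um cubic soma,
40 x 2 x 2 um AIS axon, 100 um margin, h = 10 um with feature-snapped
refinement; electrode of 5 um nominal radius on the axon axis with
center-to-AIS distance 20 um (distances follow the point-source
convention, measured to the electrode center). At 30 Hz and 100 nA this
yields ~1.1 mV extracellular oscillation amplitude at the AIS and exact
doubling with doubled current — subthreshold behavior is effectively
linear. Horizons are three stimulus periods (100 ms); amplitudes are
measured after discarding the first period, detrended with a
period-averaged slope estimate that leaves pure sinusoids untouched (and
degenerates gracefully to no detrending for windows under two periods,
where drift and oscillation are not separable).

The two-cell fixture uses a 16 x 16 um AIS cross-section and a 1 um gap
(0.5 um element layers inside it). The thicker AIS compensates for the
apposed membrane area that full-scale simulations obtain by bending
anatomically shaped axons toward each other; the tip-to-tip cleft
potential scales with the facing area, and without the compensation the
box fixture's ephaptic coupling would be an order of magnitude too weak to
study. With it, a firing cell produces -0.2 to -0.6 mV at its quiescent
neighbor's AIS at sigma_e = 3 mS/cm, doubling when sigma_e is halved
(the O(1/sigma_e) ephaptic scaling), and in-phase pairs double the
mid-gap spike amplitude.

Synchronization: two pacemaker cells started 5 ms apart pull together at
a rate that increases strongly as sigma_e decreases. The box pair locks
with ~1 ms of residual lag (full-scale cells at micrometre separations
show stable sub-millisecond to millisecond offsets), so at desk scale
"synchronized" is defined as the offset entering a 2 ms band and staying
there; with 900 ms horizons the sigma_e = 0.6 mS/cm pair locks while 1.5
and 3 mS/cm do not, and the residual offsets themselves are ordered in
sigma_e. Sub-millisecond tolerances (the 0.1 ms default of
`synchronization_time()`) are meaningful only for production-scale runs.

The open-loop comparison (`emi_mie_firing_delay()`) runs the same
electrode-driven problem fully coupled and open loop (membrane ODEs driven
by the analytic source field only). The fixture uses a 500 um graded
margin and rescales the electrode current with sigma_e so the open-loop
drive is identical across conductivities; the residual first-spike-time
difference then isolates the feedback term and grows as sigma_e falls. At
desk scale the absolute difference also contains a small constant bias
(~-0.03 ms) from the remaining domain truncation and the insulating-cell
obstacle effect, so it is the *growth* of the delay with 1/sigma_e, not
its absolute sign at bulk conductivity, that the desk fixtures establish.

What these fixtures do not show: absolute spike counts or timings of real
cell types (those require the published channel tables as model files and
anatomically sized meshes), dendritic filtering (the box dendrite is a
stub), and any effect of concentration dynamics (reversal potentials are
fixed; electrodiffusion is out of scope).

## Numerical choices

* Linear solver: sparse Cholesky, factor-once; the residual of the first
  solve is verified against the configured tolerance (default 1e-10).
* Lumped membrane quadrature; conductances and capacitance at a vertex are
  area-weighted over the facets meeting there, so region boundaries are
  handled without double counting.
* Spike detection: upward crossing of -20 mV with a 2 ms refractory
  period, one spike per crossing (a depolarization-block plateau counts
  once). Both parameters are exposed; the defaults are unambiguous for
  full-height action potentials and for the bundled fixtures.
* Offset pairing: each spike of the reference train matches its nearest
  neighbor in the other train; pairs further apart than half the median
  inter-spike interval are dropped and counted.
* Electrode sign conventions are taken literally from the two protocol
  formulas (constant: $-I_e/A_e$, giving a negative potential for positive
  $I_e$; sinusoidal: $+(I_e/A_e)\sin$), with an explicit
  `sign_convention` switch for users needing the opposite reading.
* Determinism: there is no randomness anywhere in the stack; identical
  configurations produce byte-identical traces (asserted in the tests).

## Problem sizes

The validation and test problems are sized for a laptop-class single core:
10-25 k potential dofs for the stimulation fixtures (117-380 k tets for the
graded far-field boxes), 3-5 k dofs for the two-cell fixtures, horizons of
tens of milliseconds for stimulation runs and 0.9 s for the
synchronization sweep, all at the default 0.01 ms step. A full sweep of
the bundled experiments completes in well under an hour; individual
validation checks in seconds to a few minutes.
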