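# emisim

Fully coupled finite-element simulation of neural electric fields: the
EMI (Extracellular–Membrane–Intracellular) model in R.

Most models of extracellular potentials around neurons are open loop: the
membrane is solved first under the assumption that the extracellular
potential is zero, and the field is reconstructed afterwards from the
membrane currents with point- or line-source formulas. That approximation
breaks down exactly where extracellular fields are interesting — in
micrometre clefts between cells, under strong stimulation electrodes, and
whenever the field feeds back on the membrane (ephaptic coupling). The EMI
model closes the loop: both the intracellular potential \(u_i\) and the
extracellular potential \(u_e\) satisfy
\(\nabla\cdot\sigma\nabla u = 0\) in their own subdomains and are coupled
across an explicit membrane surface \(\Gamma\) by current continuity and

\[ C_m \frac{\partial v}{\partial t} = I_m - (I_{ion} + I_s),
   \qquad v = u_i - u_e \ \text{on}\ \Gamma , \]

with Hodgkin–Huxley-type gating dynamics \(ds/dt = F(v, s)\) whose channel
densities vary over membrane regions (soma, AIS, myelin, nodes, ...).

The package provides, end to end:

* **geometry** — structured tetrahedral meshes for idealized box neurons
  with tagged membrane regions, spherical electrode cavities, two-cell
  mirror configurations with micrometre gaps; MSH 4.1 reading/writing and
  VTU export (`build_single_cell_mesh`, `build_two_cell_mesh`,
  `read_msh`, `write_vtu`);
* **membrane** — declarative region-dependent ionic models loaded from
  YAML files and integrated with the Rush–Larsen scheme
  (`load_model_spec`, `membrane_ode_step`, built-ins `hh`, `passive`,
  `hh-ais`, `hh-pacemaker`);
* **solver** — first-order operator splitting with a monolithic sparse
  SPD elliptic solve, factorized once per problem (`emi_problem`,
  `run_simulation`); somatic and constant/sinusoidal electrode
  stimulation protocols; an open-loop ("MI+E") mode for comparison;
* **analysis** — spike detection and counting, spike-timing offsets,
  synchronization times, subthreshold oscillation amplitudes, and
  point-source field reconstruction (`detect_spikes`,
  `spike_offset_series`, `synchronization_time`,
  `oscillation_amplitude`, `mie_extracellular_potential`,
  `emi_mie_firing_delay`);
* **configs** — YAML-driven reproducible runs and parameter sweeps with
  full provenance (`run_from_config`, `sweep`), bundled experiment
  presets under `inst/experiments/`, and a thin `exec/emisim` CLI.

## Worked example

A quiescent Hodgkin–Huxley cell 20 µm from a spherical electrode driven
with 100 nA at 30 Hz, in a medium with σₑ = 3 mS/cm:

```r
library(emisim)

problem <- fixture_electrode_problem(Ie_nA = 100, waveform = "sinusoidal",
                                     f_Hz = 30, T_end_ms = 100,
                                     model = "hh", sigma_e_mS_per_cm = 3)
result <- run_simulation(problem)
result
#> simulation_result (emi): 100 ms at dt = 0.01 ms, 2 probe(s), 10001 sample(s)

oscillation_amplitude(result, column = "ue_ais", period_ms = 1000 / 30)
#> [1] 1.108044
oscillation_amplitude(result, column = "v_ais", period_ms = 1000 / 30)
#> [1] 0.863156
```

The extracellular potential at the AIS membrane point oscillates at the
stimulus frequency with an amplitude of about ±1.1 mV (±0.55 mV at 50 nA —
the subthreshold response is linear in the stimulus), and the membrane
potential follows with a similar subthreshold modulation. The analytic
point-source field at that distance is
`analytic_point_source(0.1, 3, 20e-4)` = −1.33 mV; the finite domain and
the insulating cell account for the difference.

Two spontaneously pacemaking cells 1 µm apart synchronize through the
shared extracellular field alone — faster the lower the extracellular
conductivity:

```r
sweep(system.file("experiments", "two_cell_sync.yaml", package = "emisim"),
      list("conductivities.sigma_e_mS_per_cm" = c(3, 1.5, 0.6)))
```

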