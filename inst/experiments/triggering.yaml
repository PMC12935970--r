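# Ephaptic action-potential triggering: cell 1 pacemakes spontaneously,
# cell 2 is held quiescent by a positive (hyperpolarizing) somatic current.
# Sweep the extracellular conductivity downward,
#   sweep("triggering.yaml",
#         list("conductivities.sigma_e_mS_per_cm" = c(3, 0.3, 0.15, 0.06)))
# and check spike_count.v2_ais: direct triggering requires a large
# reduction of sigma_e below the bulk value.
experiment: triggering
geometry:
  kind: two_cell
  soma_um: [20, 20, 20]
  axon_cross_um: [16, 16]
  axon_segments:
    - {region: AIS, length_um: 40}
  gap_um: 1
  gap_h_um: 0.5
  margin_um: 50
  h_um: 10
membrane:
  model: hh-pacemaker
conductivities: {sigma_i_mS_per_cm: 5, sigma_e_mS_per_cm: 3}
stimuli:
  somatic:
    - {cell: 2, region: SOMA, Is_uA_per_cm2: 6}
solver: {dt_ms: 0.01, T_end_ms: 120}
init:
  kind: limit_cycle
  Is_uA_per_cm2: 0
  burn_in_ms: 300
  offsets_ms: [0, 0]
probes:
  - {name: v1_ais, kind: v, cell: 1, region: AIS, point_um: [50, 0, 0]}
  - {name: v2_ais, kind: v, cell: 2, region: AIS, point_um: [51, 0, 0]}
  - {name: ue_gap, kind: ue, point_um: [50.5, 0, 0]}
analysis:
  spike_threshold_mV: -20
  refractory_ms: 2
  count_window_ms: [0, 120]
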