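# Ephaptic synchronization of two spontaneously pacemaking cells whose AIS
# tips face each other across 1 um of extracellular space. Cell 2 starts
# 5 ms behind cell 1 (limit-cycle checkpoint). Sweep
#   sweep("two_cell_sync.yaml",
#         list("conductivities.sigma_e_mS_per_cm" = c(3, 1.5, 0.6)))
# to see synchronization accelerate as sigma_e decreases. The desk-scale
# synchronization band (sync.tol_ms) is 2 ms: the box fixture locks with
# about 1 ms of residual lag, analogous to the stable sub-millisecond to
# millisecond offsets of full-scale cells at micrometre separations.
experiment: two_cell_sync
geometry:
  kind: two_cell
  soma_um: [20, 20, 20]
  axon_cross_um: [16, 16]   # apposed-area compensation for the box fixture
  axon_segments:
    - {region: AIS, length_um: 40}
  gap_um: 1
  gap_h_um: 0.5
  margin_um: 50
  h_um: 10
membrane:
  model: hh-pacemaker
conductivities: {sigma_i_mS_per_cm: 5, sigma_e_mS_per_cm: 3}
solver: {dt_ms: 0.01, T_end_ms: 900}
init:
  kind: limit_cycle
  Is_uA_per_cm2: 0
  burn_in_ms: 300
  offsets_ms: [0, 5]
probes:
  - {name: v1_ais, kind: v, cell: 1, region: AIS, point_um: [50, 0, 0]}
  - {name: v2_ais, kind: v, cell: 2, region: AIS, point_um: [51, 0, 0]}
  - {name: ue_gap, kind: ue, point_um: [50.5, 0, 0]}
analysis:
  spike_threshold_mV: -20
  refractory_ms: 2
  sync: {tol_ms: 2.0, hold: 3, probeA: v1_ais, probeB: v2_ais}
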