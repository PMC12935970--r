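# Spike-count modulation by constant extracellular stimulation: sweep
# stimulation strength and electrode-to-AIS distance, e.g.
#   sweep("spike_count_grid.yaml",
#         list("stimuli.electrode.Ie_nA" = c(200, 500, 1000),
#              "geometry.electrode.offset_um" = c(10, 20, 40)))
experiment: spike_count_grid
geometry:
  kind: single_cell
  soma_um: [20, 20, 20]
  axon_cross_um: [2, 2]
  axon_segments:
    - {region: AIS, length_um: 40}
  margin_um: 100
  h_um: 10
  electrode: {radius_um: 5, offset_um: 20}
membrane:
  model: hh-ais            # region-heterogeneous excitable fixture
conductivities: {sigma_i_mS_per_cm: 5, sigma_e_mS_per_cm: 3}
stimuli:
  somatic:
    - {cell: 1, region: SOMA, Is_uA_per_cm2: 0}
  electrode: {Ie_nA: 500, waveform: constant}
solver: {dt_ms: 0.01, T_end_ms: 200}
probes:
  - {name: v_soma, kind: v, cell: 1, region: SOMA}
  - {name: v_ais, kind: v, cell: 1, region: AIS, point_um: [50, 0, 0]}
analysis:
  spike_threshold_mV: -20
  refractory_ms: 2
  count_window_ms: [0, 200]
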