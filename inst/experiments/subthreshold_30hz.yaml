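# Subthreshold frequency following: quiescent cell 20 um from a sinusoidal
# electrode (30 Hz, 100 nA), extracellular and membrane potential recorded
# at an AIS membrane point. Halve Ie_nA to check amplitude linearity.
experiment: subthreshold_30hz
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
  model: hh
conductivities: {sigma_i_mS_per_cm: 5, sigma_e_mS_per_cm: 3}
stimuli:
  electrode: {Ie_nA: 100, waveform: sinusoidal, f_Hz: 30}
solver: {dt_ms: 0.01, T_end_ms: 100}
probes:
  - {name: v_ais, kind: v, cell: 1, region: AIS, point_um: [50, 0, 0]}
  - {name: ue_ais, kind: ue, cell: 1, region: AIS, point_um: [50, 0, 0]}
analysis:
  amplitude_period_ms: 33.333333
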