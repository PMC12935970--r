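schema_version: 1
name: passive
spontaneous: no
capacitance_uF_per_cm2:
  default: 1.0
  MYELIN: 0.0
channels:
- name: leak
  reversal_mV: -70.0
  conductance_mS_per_cm2:
    default: 0.1
    MYELIN: 0.0
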