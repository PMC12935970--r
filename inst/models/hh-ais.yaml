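schema_version: 1
name: hh-ais
spontaneous: no
capacitance_uF_per_cm2:
  default: 1.0
  MYELIN: 0.0
channels:
- name: Na
  reversal_mV: 50.0
  conductance_mS_per_cm2:
    default: 50.0
    AIS: 500.0
    MYELIN: 0.0
  gates:
  - name: m
    exponent: 3.0
    alpha: expm1_div(-(v + 40) / 10)
    beta: 4 * exp(-(v + 65) / 18)
  - name: h
    exponent: 1.0
    alpha: 0.07 * exp(-(v + 65) / 20)
    beta: 1 / (1 + exp(-(v + 35) / 10))
- name: K
  reversal_mV: -77.0
  conductance_mS_per_cm2:
    default: 30.0
    AIS: 60.0
    MYELIN: 0.0
  gates:
  - name: 'n'
    exponent: 4.0
    alpha: 0.1 * expm1_div(-(v + 55) / 10)
    beta: 0.125 * exp(-(v + 65) / 80)
- name: leak
  reversal_mV: -54.387
  conductance_mS_per_cm2:
    default: 0.3
    MYELIN: 0.0
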