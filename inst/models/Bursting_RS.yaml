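# Bursting excitatory (regular-spiking-type) neuron: persistent-Na-driven
# burster with slow M-type K+ termination. Also produces mixed-mode firing
# (bursts alternating with single spikes) at the documented intensity.
name: Bursting_RS
citation: >
  Adapted transcription after Golomb, Yue & Yaari (2006) CA1 pyramidal-cell
  burster: transient Na (instantaneous m_inf^3, h), delayed rectifier
  (n^4), persistent Na (p_inf, instantaneous) and a slow M-type K+ current
  (z, tau 75 ms). Conductances tuned by simulation to give intrinsic
  bursting across the constant range and mixed-mode firing at
  extra.mixed_mode_intensity; not an exact reprint of the source.
C_m: 1.0
leak: {g: 0.05, E: -70.0}
V_rest_hint: -70.2
spike_threshold: -10.0
constant_range: [0.5, 2.5]
doc_intensity: 1.0
extra: {mixed_mode_intensity: 2.5}
channels:
  - name: Na
    g_max: 35.0
    E: 55.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: steady
          instantaneous: true
          f1: {form: logistic, params: [1.0, -30.0, 9.5]}   # m_inf
          f2: {form: constant, params: [1.0]}               # unused
      - symbol: "h"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -45.0, -7.0]}  # h_inf
          f2: {form: sigtau, params: [0.1, 0.75, -40.5, -6.0]}  # tau_h
  - name: Kdr
    g_max: 6.0
    E: -90.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -35.0, 10.0]}  # n_inf
          f2: {form: sigtau, params: [0.1, 0.5, -27.0, 15.0]}   # tau_n
  - name: NaP
    g_max: 0.3
    E: 55.0
    gates:
      - symbol: "p"
        exponent: 1
        kinetics:
          type: steady
          instantaneous: true
          f1: {form: logistic, params: [1.0, -47.0, 3.0]}   # p_inf
          f2: {form: constant, params: [1.0]}
  - name: M
    g_max: 1.0
    E: -90.0
    gates:
      - symbol: "z"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -39.0, 5.0]}   # z_inf
          f2: {form: constant, params: [75.0]}              # tau_z
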