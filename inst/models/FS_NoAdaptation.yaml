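# Wang-Buzsaki hippocampal fast-spiking interneuron: non-adapting,
# high-frequency firing; instantaneous Na activation, phi = 5 on h and n.
name: FS_NoAdaptation
citation: >
  Wang & Buzsaki (1996) fast-spiking interneuron; exact transcription
  (m = m_inf(V), phi = 5 temperature-like factor on h and n).
C_m: 1.0
leak: {g: 0.1, E: -65.0}
V_rest_hint: -64.0
spike_threshold: -10.0
constant_range: [0.5, 3.0]
doc_intensity: 1.0
channels:
  - name: Na
    g_max: 35.0
    E: 55.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          instantaneous: true
          f1: {form: linoid, params: [0.1, -35.0, 10.0]}    # alpha_m
          f2: {form: expo, params: [4.0, -60.0, -18.0]}     # beta_m
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          phi: 5.0
          f1: {form: expo, params: [0.07, -58.0, -20.0]}    # alpha_h
          f2: {form: logistic, params: [1.0, -28.0, 10.0]}  # beta_h
  - name: K
    g_max: 9.0
    E: -90.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          phi: 5.0
          f1: {form: linoid, params: [0.01, -34.0, 10.0]}   # alpha_n
          f2: {form: expo, params: [0.125, -44.0, -80.0]}   # beta_n
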