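# Classical Hodgkin-Huxley squid-axon model (Class II excitability).
# Exact transcription, modern convention (rest near -65 mV).
name: ClassII_excitable
citation: >
  Hodgkin & Huxley (1952) squid giant axon; exact transcription in the
  shifted (-65 mV rest) convention. Class II: firing onset at a finite rate.
C_m: 1.0
leak: {g: 0.3, E: -54.4}
V_rest_hint: -65.0
spike_threshold: -10.0
constant_range: [7.0, 15.0]
doc_intensity: 10.0
channels:
  - name: Na
    g_max: 120.0
    E: 50.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.1, -40.0, 10.0]}    # alpha_m
          f2: {form: expo, params: [4.0, -65.0, -18.0]}     # beta_m
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.07, -65.0, -20.0]}    # alpha_h
          f2: {form: logistic, params: [1.0, -35.0, 10.0]}  # beta_h
  - name: K
    g_max: 36.0
    E: -77.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.01, -55.0, 10.0]}   # alpha_n
          f2: {form: expo, params: [0.125, -65.0, -80.0]}   # beta_n
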