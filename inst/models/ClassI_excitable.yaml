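# Traub-Miles hippocampal pyramidal-cell model (reduced single-compartment
# form), Class I excitability: arbitrarily low firing rates at rheobase.
name: ClassI_excitable
citation: >
  Traub & Miles (1991) CA3 pyramidal cell, reduced single-compartment (RTM)
  form; exact transcription. Class I: continuous f-I onset from ~0 Hz.
C_m: 1.0
leak: {g: 0.1, E: -67.0}
V_rest_hint: -67.0
spike_threshold: -10.0
constant_range: [0.5, 3.0]
doc_intensity: 1.0
channels:
  - name: Na
    g_max: 100.0
    E: 50.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.32, -54.0, 4.0]}    # alpha_m
          f2: {form: linoid, params: [-0.28, -27.0, -5.0]}  # beta_m
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.128, -50.0, -18.0]}   # alpha_h
          f2: {form: logistic, params: [4.0, -27.0, 5.0]}   # beta_h
  - name: K
    g_max: 80.0
    E: -100.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.032, -52.0, 5.0]}   # alpha_n
          f2: {form: expo, params: [0.5, -57.0, -40.0]}     # beta_n
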