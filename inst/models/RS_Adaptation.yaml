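# Regular-spiking pyramidal cell WITH spike-frequency adaptation:
# Traub-Miles spiking currents plus an M-type slow potassium current.
name: RS_Adaptation
citation: >
  Adapted transcription after Ermentrout (1998): Traub-Miles Na/K spiking
  currents with an M-type slow K+ adaptation current (w gate, tau ~ 100 ms
  bell). Parameters verified by simulation to give regular spiking with
  clear spike-frequency adaptation; not an exact reprint of the source.
C_m: 1.0
leak: {g: 0.1, E: -67.0}
V_rest_hint: -72.9
spike_threshold: -10.0
constant_range: [3.0, 6.0]
doc_intensity: 3.0
channels:
  - name: Na
    g_max: 100.0
    E: 50.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.32, -54.0, 4.0]}
          f2: {form: linoid, params: [-0.28, -27.0, -5.0]}
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.128, -50.0, -18.0]}
          f2: {form: logistic, params: [4.0, -27.0, 5.0]}
  - name: K
    g_max: 80.0
    E: -100.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.032, -52.0, 5.0]}
          f2: {form: expo, params: [0.5, -57.0, -40.0]}
  - name: M
    g_max: 1.0
    E: -100.0
    gates:
      - symbol: "w"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -35.0, 10.0]}         # w_inf
          f2: {form: biexp_inv, params: [400.0, 3.3, -35.0, 20.0, 1.0, 20.0]}  # tau_w
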