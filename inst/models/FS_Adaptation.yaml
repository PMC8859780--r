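# Fast-spiking interneuron WITH adaptation: Wang-Buzsaki spiking currents
# plus a weak M-type slow K+ current producing mild rate adaptation.
name: FS_Adaptation
citation: >
  Adapted transcription after Gouwens et al. (2014) fast-spiking fits:
  Wang-Buzsaki Na/K spiking backbone plus a slow M-type K+ current
  (tau ~ 100 ms) giving spike-frequency adaptation. Verified by simulation;
  not an exact reprint of the source.
C_m: 1.0
leak: {g: 0.1, E: -65.0}
V_rest_hint: -68.9
spike_threshold: -10.0
constant_range: [2.5, 6.0]
doc_intensity: 3.0
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
          f1: {form: linoid, params: [0.1, -35.0, 10.0]}
          f2: {form: expo, params: [4.0, -60.0, -18.0]}
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          phi: 5.0
          f1: {form: expo, params: [0.07, -58.0, -20.0]}
          f2: {form: logistic, params: [1.0, -28.0, 10.0]}
  - name: K
    g_max: 9.0
    E: -90.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          phi: 5.0
          f1: {form: linoid, params: [0.01, -34.0, 10.0]}
          f2: {form: expo, params: [0.125, -44.0, -80.0]}
  - name: M
    g_max: 0.6
    E: -90.0
    gates:
      - symbol: "w"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -35.0, 10.0]}
          f2: {form: biexp_inv, params: [400.0, 3.3, -35.0, 20.0, 1.0, 20.0]}
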