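# Regular-spiking neuron WITHOUT adaptation: retinal-ganglion-cell-type
# spiking currents (Na, delayed-rectifier K, inactivating A-type K).
name: RS_NoAdaptation
citation: >
  Adapted transcription after Fohlmeister & Miller (1997) retinal ganglion
  cell: Na (m3 h), delayed rectifier (n4) and A-type K+ (a3 hA) currents.
  The Ca2+ and Ca2+-gated K+ currents of the source (which produce
  adaptation there) are omitted, yielding non-adapting regular spiking;
  leak adjusted to hold rest near -65 mV. Verified by simulation.
C_m: 1.0
leak: {g: 0.05, E: -65.0}
V_rest_hint: -65.0
spike_threshold: -10.0
constant_range: [2.0, 8.0]
doc_intensity: 4.0
channels:
  - name: Na
    g_max: 50.0
    E: 35.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.6, -30.0, 10.0]}
          f2: {form: expo, params: [20.0, -55.0, -18.0]}
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.4, -50.0, -20.0]}
          f2: {form: logistic, params: [6.0, -20.0, 10.0]}
  - name: K
    g_max: 12.0
    E: -75.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.02, -40.0, 10.0]}
          f2: {form: expo, params: [0.4, -50.0, -80.0]}
  - name: KA
    g_max: 36.0
    E: -75.0
    gates:
      - symbol: "a"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.006, -90.0, 10.0]}
          f2: {form: expo, params: [0.1, -30.0, -10.0]}
      - symbol: "hA"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.04, -70.0, -20.0]}
          f2: {form: logistic, params: [0.6, -40.0, 10.0]}
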