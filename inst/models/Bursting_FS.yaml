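# Bursting inhibitory (fast-spiking-type) neuron: Kv3-based fast spiking
# with a slowly inactivating d-type K+ current producing stuttering bursts.
name: Bursting_FS
citation: >
  Adapted transcription after Golomb et al. (2007) fast-spiking cortical
  interneuron: Na (instantaneous m_inf^3, h), Kv3 delayed rectifier (n^2)
  and slowly inactivating d-type K+ (a^3 b). Conductances tuned by
  simulation for stuttering/bursting in the constant range; not an exact
  reprint of the source.
C_m: 1.0
leak: {g: 0.25, E: -70.0}
V_rest_hint: -71.1
spike_threshold: -10.0
constant_range: [4.0, 8.0]
doc_intensity: 4.5
channels:
  - name: Na
    g_max: 112.5
    E: 50.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: steady
          instantaneous: true
          f1: {form: logistic, params: [1.0, -24.0, 11.5]}
          f2: {form: constant, params: [1.0]}
      - symbol: "h"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -58.3, -6.7]}
          f2: {form: sigtau, params: [0.5, 14.0, -60.0, 12.0]}
  - name: Kv3
    g_max: 225.0
    E: -90.0
    gates:
      - symbol: "n"
        exponent: 2
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -12.4, 6.8]}
          f2: {form: prodsigtau, params: [0.087, 11.4, -14.6, 8.6, 0.087, 11.4, 1.3, 18.7]}
  - name: Kd
    g_max: 1.8
    E: -90.0
    gates:
      - symbol: "a"
        exponent: 3
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -50.0, 20.0]}
          f2: {form: constant, params: [2.0]}
      - symbol: "b"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -70.0, -6.0]}
          f2: {form: constant, params: [150.0]}
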