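# Phasic (onset) spiking neuron: spikes only at stimulus onset, silenced by
# a low-threshold K+ current, as in ventral cochlear nucleus models.
name: Phasic_Spiking
citation: >
  Adapted transcription after Rothman & Manis (2003) type-II ventral
  cochlear nucleus neuron (cf. Gai et al.): classical Na/K spiking currents
  plus a low-threshold K+ current (w^4) that enforces phasic onset firing.
  Conductance tuned by simulation; not an exact reprint of the source.
C_m: 1.0
leak: {g: 0.3, E: -54.4}
V_rest_hint: -69.5
spike_threshold: -10.0
constant_range: [14.0, 40.0]
doc_intensity: 20.0
channels:
  - name: Na
    g_max: 120.0
    E: 50.0
    gates:
      - symbol: "m"
        exponent: 3
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.1, -40.0, 10.0]}
          f2: {form: expo, params: [4.0, -65.0, -18.0]}
      - symbol: "h"
        exponent: 1
        kinetics:
          type: rate
          f1: {form: expo, params: [0.07, -65.0, -20.0]}
          f2: {form: logistic, params: [1.0, -35.0, 10.0]}
  - name: K
    g_max: 36.0
    E: -77.0
    gates:
      - symbol: "n"
        exponent: 4
        kinetics:
          type: rate
          f1: {form: linoid, params: [0.01, -55.0, 10.0]}
          f2: {form: expo, params: [0.125, -65.0, -80.0]}
  - name: KLT
    g_max: 6.0
    E: -77.0
    gates:
      - symbol: "w"
        exponent: 1
        kinetics:
          type: steady
          f1: {form: logistic, params: [1.0, -55.0, 6.0]}   # w_inf
          f2: {form: sigtau, params: [1.0, 5.0, -50.0, 10.0]}   # tau_w
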