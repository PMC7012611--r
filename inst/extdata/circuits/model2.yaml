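name: model2
populations: [E, I, S, X]
polarity:
  E: 1
  I: -1
  S: -1
  X: -1
J0:
  E: 48.0
  I: 29.0
  S: 0.0
  X: 24.0
J:
  E: {E: 20.0, I: 30.0, S: 32.0, X: 36.0}
  I: {E: 40.0, I: 28.0, S: 16.0, X: 32.0}
  S: {E: 26.0, I: 12.0}
  X: {E: 24.0, S: 36.0, X: 22.0}
tau:
  E: {E: 4.0, I: 2.0, S: 2.0, X: 4.0}
  I: {E: 2.0, I: 2.0, S: 4.0, X: 4.0}
  S: {E: 2.0, I: 2.0}
  X: {E: 2.0, S: 4.0, X: 2.0}
neuron:
  C_M: 1.0
  V_th: -50.0
  V_R: -70.0
  g_leak: {E: 0.05, I: 0.1, S: 0.05, X: 0.05}
r0: 5.0
sizes:
  counts: {E: 57600, I: 6400, S: 6400, X: 6400}
  K: 500
opto:
  targets: [I]
  I0: 8.0
  Gamma0: 0.5
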