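# Kinetics set "grc2017": gating kinetics for the granule-cell channel
# complement, normalized to 30 C (no run-time Q10 scaling).
#
# The rate constants below are configuration data of this package, authored in
# the functional forms used by the granule-cell model family (sigmoid
# steady-state / bell time constant, alpha-beta exp/sigmoid/linoid rates, a
# calcium-and-voltage-dependent BK-type gate, and a 13-state Markov resurgent
# sodium scheme) and calibrated so that the mid-range reference models
# reproduce the published canonical granule-cell behaviors (feature table,
# input resistance, theta-band resonance, axonal conduction).
name: grc2017
temp_C: 30
calcium:
  cao: 2.0
  carest: 1.0e-4
  beta: 1.5       # "Calc" decay rate, 1/ms (mono-compartment default)
  beta_multi: 0.1 # dendritic-shell decay used by the multi-compartment model
  depth: 0.2      # shell depth, um
  floor: 1.0e-6
channels:
  Na:             # transient sodium, m^3 h
    kind: hh
    gates:
      - {name: m, p: 3, kind: inf_tau, vhalf: -37, k: 4.5, tau_min: 0.008, tau_amp: 0.06, vt: -38, k1: 8, k2: 8}
      - {name: h, p: 1, kind: inf_tau, vhalf: -46, k: -4.5, tau_min: 0.2, tau_amp: 5, vt: -55, k1: 9, k2: 9}
  Nap:            # persistent sodium, m
    kind: hh
    gates:
      - {name: m, p: 1, kind: inf_tau, vhalf: -44, k: 4.2, tau_min: 3, tau_amp: 3, vt: -42, k1: 10, k2: 10}
  Nar:            # resurgent-like sodium, s (activation) * f (inactivation)
    kind: hh
    gates:
      - {name: s, p: 1, kind: inf_tau, vhalf: -32, k: 5, tau_min: 0.3, tau_amp: 4.5, vt: -55, k1: 12, k2: 12}
      - {name: f, p: 1, kind: inf_tau, vhalf: -59, k: -5, tau_min: 4, tau_amp: 12, vt: -65, k1: 15, k2: 15}
  KV:             # delayed rectifier, n^4
    kind: hh
    gates:
      - {name: "n", p: 4, kind: inf_tau, vhalf: -30, k: 7, tau_min: 0.2, tau_amp: 1.2, vt: -38, k1: 12, k2: 12}
  KA:             # A-type, a^3 b
    kind: hh
    gates:
      - {name: a, p: 3, kind: inf_tau, vhalf: -50, k: 12, tau_min: 0.4, tau_amp: 1.2, vt: -50, k1: 20, k2: 20}
      - {name: b, p: 1, kind: inf_tau, vhalf: -74, k: -7, tau_min: 6, tau_amp: 12, vt: -70, k1: 15, k2: 15}
  Kslow:          # M-like slow potassium, n
    kind: hh
    gates:
      - {name: "n", p: 1, kind: inf_tau, vhalf: -33, k: 5, tau_min: 55, tau_amp: 20, vt: -40, k1: 18, k2: 18}
  Kir:            # inward rectifier, d (opens with hyperpolarization)
    kind: hh
    gates:
      - {name: d, p: 1, kind: inf_tau, vhalf: -102, k: -10, tau_min: 5, tau_amp: 15, vt: -90, k1: 20, k2: 20}
  KCa:            # calcium-dependent potassium (BK-like), c
    kind: hh
    gates:
      - {name: c, p: 1, kind: kca, Aa: 2.5, Ba: 11.765, Ka: 1.5e-3, Ab: 1.5, Bb: 11.765, Kb: 1.5e-4}
  CaHVA:          # high-voltage-activated calcium, s^2 u; dynamic Nernst reversal
    kind: hh
    carries_ca: true
    gates:
      - {name: s, p: 2, kind: inf_tau, vhalf: -20, k: 7, tau_min: 0.3, tau_amp: 1.2, vt: -25, k1: 12, k2: 12}
      - {name: u, p: 1, kind: inf_tau, vhalf: -50, k: -6, tau_min: 20, tau_amp: 60, vt: -40, k1: 15, k2: 15}
  Lkg:            # ohmic leak
    kind: hh
    gates: []
  NaM:            # 13-state Markov resurgent sodium (multi-compartment model)
    kind: markov
    params:
      alpha0: 150
      va: 20
      beta0: 3
      vb: 20
      gamma: 150
      delta: 40
      epsilon: 1.75
      zeta0: 0.03
      vz: 25
      Con: 0.005
      Coff: 0.5
      Oon: 0.75
      Ooff: 0.005
      scale: 2.75
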