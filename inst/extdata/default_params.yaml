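# Canonical hJSMC model parameter document.
# Loading this file with load_parameters() reproduces default_parameters()
# exactly; any field may be overridden. Units: mV, ms, pA, nS, pF, mM, K, L.
#
# Provenance key:
#   [whole-cell] value printed in the source whole-cell characterisations
#     (C_m = 50 pF; G_CaL 1.44, G_CaT 0.0425, G_Kv 1.0217, G_BK 80,
#      G_Na 25.1 nS; total leak at least 45-fold below G_Kv, 0 mV reversal;
#      ICC rest -57 mV, amplitude 23.5 mV, upstroke 300 ms, plateau 9700 ms)
#   [homeostasis-fit] scale chosen so the cell holds its ionic steady state
#     (P_NaK, k_NCX, alpha_NCX, leak split, initial Na_i/K_i/Ca_total)
#   [kinetics-fit] rate-coefficient tables fitted so the assembled cell
#     reproduces the recorded slow-wave phenotype (gate and Markov tables,
#     gap-junction coupling, waveform shape constants, buffers, V_c)
#   [physical] physical constant or standard physiological bath value

membrane:
  C_m: 50.0
conductances:
  G_CaL: 1.43999999999999995
  G_CaT: 0.0425
  G_Kv: 1.02170000000000005
  G_BK: 80.0
  G_Na: 25.10000000000000142
  G_NaLeak: 0.0007
  G_KLeak: 0.0215
pumps:
  P_NaK: 4.24000000000000021
  K_mK: 1.0
  K_mNa: 40.0
  k_NCX: 70000.0
  gamma_NCX: 0.34999999999999998
  K_mNai: 87.5
  K_mCa: 1.37999999999999989
  k_sat: 0.10000000000000001
  alpha_NCX: 0.83999999999999997
physical:
  F: 96.48669999999999902
  R: 8.31400000000000006
  T: 310.0
  V_c: 3.50000000000000003e-12
external:
  Na_o: 140.0
  K_o: 5.40000000000000036
  Ca_o: 2.0
initial:
  V0: -60.0
  Na_i: 9.72000000000000064
  K_i: 150.0
  Ca_total: 0.0012
buffers:
  CaM:
    B_total: 0.008
    K_d: 0.001
  CRT:
    B_total: 0.027
    K_d: 0.005
gates:
  m_CaT:
    type: act
    v_half: -44.0
    slope: 5.5
    tau_min: 1.19999999999999996
    tau_amp: 3.0
    tau_v: -60.0
    tau_w: 25.0
  h_CaT:
    type: inact
    v_half: -68.0
    slope: 5.0
    tau_min: 80.0
    tau_amp: 150.0
    tau_v: -65.0
    tau_w: 20.0
  x_Kv:
    type: act
    v_half: -13.0
    slope: 14.5
    tau_min: 1500.0
    tau_amp: 0.0
    tau_v: -50.0
    tau_w: 30.0
  y_Kv:
    type: inact
    v_half: 60.0
    slope: 20.0
    tau_min: 500.0
    tau_amp: 0.0
    tau_v: 0.0
    tau_w: 30.0
markov:
  CaL:
    act_a: 0.46500000000000002
    act_k: 25.0
    deact_a: 0.05
    deact_k: 75.0
    inact_a: 0.04
    inact_k: 25.0
    rec_a: 0.005
    rec_k: 50.0
    ca_on: 2.5
    ca_off: 6.00000000000000015e-05
    mode_ca_act_scale: 0.25
  BK:
    k_on: 1000.0
    k_off_c: 2.5
    k_off_o: 0.25
    open_a: 0.0026
    open_k: 25.0
    close_a: 4.0
    close_k: 60.0
  Na:
    act_a: 8.0
    act_k: 14.0
    deact_a: 0.29999999999999999
    deact_k: 16.0
    inact_o_a: 1.0
    inact_o_k: 50.0
    rec_o_a: 0.0001
    rec_o_k: 30.0
    inact_c_a: 25.0
    inact_c_k: 12.0
    rec_c_a: 0.0001
    rec_c_k: 12.0
    slow_a: 0.0008
    slow_rec_a: 0.003
    slow_rec_k: 60.0
stimulus:
  V_ICCrest: -57.0
  V_ICCamp: 23.5
  t_up: 300.0
  t_plat: 9700.0
  s_up: 3.5
  plateau_frac: 0.69999999999999996
  tau_plat: 6000.0
  w_fall: 200.0
  t_fall: 1500.0
  G_couple: 0.34999999999999998
  t_start: 0.0
  hwang_rest: -61.0
  hwang_amp: 31.5
flags:
  ca_free: no

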