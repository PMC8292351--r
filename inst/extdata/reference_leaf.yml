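# Reference parameterization (25 C). Values equal the package defaults;
# the file doubles as a template for the CLI's --config option.
env:
  Q: 0
  T_leaf: 25
  C: 200        # chloroplast CO2, ubar
  O: 209        # chloroplast O2, mbar
  P: 1          # bar
leaf:
  alpha_total: 0.85
  alpha_1: 0.41
  alpha_2: 0.44
  V_max_cb6f: 350     # umol e- m-2 s-1
  V_max_rubc: 100     # umol CO2 m-2 s-1
  R_d: 1              # umol CO2 m-2 s-1
  g_m: 0.084          # mol m-2 s-1 bar-1
  state_transitions: no
  cef_mode: minimal
photochemical_constants:
  K_P1: 14.5
  K_D1: 0.55
  K_F1: 0.05
  K_P2: 4.5
  K_D2: 0.55
  K_F2: 0.05
  K_U2: 0
biochemical_constants:
  k_c: 3.6
  K_c: 260
  k_o: 0.9
  K_o: 179
  q_cycle_on: yes
  ndh_pump_on: yes
  h_per_atp: 4
detector:
  S_det: 1
  eps_F2: 1
  eps_F1: 0
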