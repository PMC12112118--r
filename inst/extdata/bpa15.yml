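name: bpa15
species: [BPA, P_tr, P_or, CO2]
c0_mol_per_L: 1.31e-4
rates_1_per_M_s: [1.002e10, 3.92e10, 1.387e10]
b_coeffs: [3.09e-2, 3.39e-4, -3.10e-8, 8.81e-13]
t_max_s: 18000
duration_s: 18000
grid_step_s: 3600
k_prop: 1.0e-10
law:
  slope_cm2_per_mA: 6.48e-12
  intercept: 8.55e-12
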