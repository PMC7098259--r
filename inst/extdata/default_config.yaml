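# Default forward-simulation scenario: segmented head phantom, 2-mm firing
# spot in the grey-matter shell calibrated to a 100 V/m peak field, default
# MEN/MN particles, 0.1 mmol/kg dose for a 50 kg subject, 500 Oe operating
# point with a -500 +/- 50 Oe selection field.
phantom:
  shape: [64, 64, 64]
  voxel_size_mm: 1.0
  radii_mm: [20.0, 25.0, 28.0]       # WM / GM / CSF ellipsoid semi-axes
  conductivities: {WM: 0.14, GM: 0.33, CSF: 1.79}   # S/m
source:
  diameter_mm: 2.0
  rate_pA_per_pF: 70.0
  capacitance_density_pF_mm3: 1.0e+4  # nominal; rescaled by the calibration below
  target_peak_E_Vm: 100.0            # top of the 5-100 V/m working range
particles:
  men: {diameter_nm: 50, Ms_emu_cc: 10, alpha_G_cm_V: 0.1, Hc_Oe: 100,
        mass_density_g_cc: 5, temperature_K: 300}
  mn:  {diameter_nm: 50, Ms_emu_cc: 100, alpha_G_cm_V: 0, Hc_Oe: 100,
        mass_density_g_cc: 5, temperature_K: 300}
dose:
  dose_mmol_kg: 0.1
  bodyweight_kg: 50
  molar_mass_g_mol: 467.8            # one BaTiO3 + CoFe2O4 formula-unit pair
  frequency_Hz: 1.0e+4
  loop_model: rectangular
  safety_limit_W: 50
scan:
  background_Oe: 500
  selection_Oe: -500
  linear_halfwidth_Oe: 50
  gradient_Oe_mm: 25                 # 2.5 T/m
  drive_frequency_Hz: 1.0e+4
  noise_sd: 0
study:
  densities_cm3: [1.0e+12, 1.0e+13, 1.0e+14, 1.0e+15, 1.0e+16, 1.0e+17]
seed: 1
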