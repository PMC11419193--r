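# Default run configuration: physical constants of the 1D
# thermoembolization model. A run started from this file uses the standard
# parameter set; edit a copy to override.
flow:
  p_map: 100        # mean arterial (root) pressure, mmHg
  p_cvp: 5          # central venous (sink) pressure, mmHg
  mu: 8.9e-4        # blood dynamic viscosity, Pa s
  gamma_a: 1.0e-10  # terminal conductance parameter, m^3 (usually calibrated)
bolus:
  gamma_t: 13       # hydrolysis time constant, 1/s (usually calibrated)
  rho_dcacl: 1532   # DCACl density, kg/m^3
  rho_o: 1280       # bolus density, kg/m^3
  cp_o: 1970        # bolus specific heat, J/(kg K)
  mu_o: 7.0e-4      # bolus viscosity, Pa s (recorded; flow uses blood mu)
  h: 1.38e+05       # exothermic energy release, J/mol
  molar_mass: 0.147 # DCACl molar mass, kg/mol
  molarity: 2       # DCACl molarity in the bolus, mol/L
  rho_b: 1045       # blood density, kg/m^3
  cp_b: 3600        # blood specific heat, J/(kg K)
  v_dcacl_ul: 200   # injected bolus volume, uL
delta: 0.01         # damage threshold for embolization tagging
seed: 1
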