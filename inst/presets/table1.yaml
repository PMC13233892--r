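# Verification and squeeze-benchmark constants (SI units)
study: mms
params:
  rho_s_true: 1000.0     # kg/m^3, pure solid density
  rho_f_true: 1000.0     # kg/m^3, pure fluid density
  mu_f: 1.0e-3           # Pa.s, fluid viscosity
  kappa_bar: 1.0e-9      # m^2, saturation permeability
  phi_fc: 0.1            # critical porosity
  mu_s: 5000.0           # Pa, solid shear modulus
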