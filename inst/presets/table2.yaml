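# Perivascular-space peristalsis constants (SI units)
study: pvs
params:
  rho_s_true: 1000.0
  rho_f_true: 1000.0
  mu_f: 9.0e-4           # Pa.s, CSF viscosity
  kappa_bar: 1.8e-14     # m^2, tissue permeability
  phi_fc: 0.1
  mu_s: 14000.0          # Pa, solid shear modulus
peristalsis:
  lambda: 0.2            # m, wavelength (heart rate f = 5 Hz -> c = 1 m/s)
  f: 5.0                 # Hz
  h: 1.0e-5              # m, base inner radius of the PVS annulus
  R_o: 1.1e-5            # m, outer radius
  b: 2.5e-7              # m, wall wave amplitude
  Dp: 0.0                # Pa, imposed axial pressure difference per wavelength
  phi_Rf: 0.2            # referential porosity
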