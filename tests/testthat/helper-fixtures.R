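## Shared fixtures for the test suite: small parameter sets, meshes and a
## transient context with no loads.

mp_verif <- function() material_params(1e3, 1e3, 1e-3, 1e-9, 0.1, 5e3)
mp_pvs <- function() material_params(1e3, 1e3, 9e-4, 1.8e-14, 0.1, 14e3)

tiny_mesh <- function(nr = 2L, nz = 4L)
  build_structured_mesh(0, 5e-3, 0, 1e-2, nr = nr, nz = nz)

## transient context on the tiny mesh with zero loads and simple bcs
tiny_ctx <- function(mesh = tiny_mesh(), phiRf = 0.5,
                     bcs = list(bottom = list(u = list(0, 0), p = 0),
                                axis = list(u = list(0, NA)))) {
  lay <- build_spaces(mesh)
  ctx <- porozero:::build_context(mesh, lay, mp_verif(),
                                  referential_porosity(phiRf), "transient",
                                  bcs = bcs,
                                  fd_scales = list(u = 1e-4, v = 1e-2, p = 100))
  porozero:::update_step_data(ctx, 0, hist = list(c0 = 0,
                                                  uh = numeric(lay$ndof),
                                                  vh = numeric(lay$ndof),
                                                  vfh = numeric(lay$ndof)))
  ctx
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
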