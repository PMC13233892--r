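test_that("the wall profile follows the traveling wave", {
  cfg <- peristalsis_config(lambda = 150e-6, n_r = 4L, n_z = 8L)
  expect_equal(wall_profile(0, cfg), 10e-6)
  expect_equal(wall_profile(cfg$lambda / 4, cfg), 10.25e-6)
  cfg0 <- peristalsis_config(lambda = 150e-6, b = 0, n_r = 4L, n_z = 8L)
  zp <- seq(0, cfg0$lambda, length.out = 7)
  expect_equal(wall_profile(zp, cfg0), rep(10e-6, 7))
  ## c = lambda f invariant
  expect_equal(cfg$c, 150e-6 * 5)
})

test_that("the zero-amplitude state is an exact solution (rigid drift)", {
  cfg <- peristalsis_config(lambda = 150e-6, b = 0, n_r = 6L, n_z = 12L)
  ctx <- porozero:::peristalsis_context(cfg, amp = 0)
  porozero:::update_step_data(ctx, 0)
  U0 <- porozero:::peristalsis_base_state(ctx)
  s <- porozero:::assemble_system(U0, ctx)
  expect_lt(max(abs(s$res)), 1e-25)
  res <- run_peristalsis_case(cfg)
  expect_lt(abs(res$summary$Q_m3_s),
            1e-6 * abs(cfg$c) * pi * (cfg$R_o^2 - cfg$h^2))
  expect_equal(res$summary$peak_p_mmHg, 0, tolerance = 1e-10)
  expect_equal(res$summary$min_phi, 0.2, tolerance = 1e-9)
})

test_that("the flow-rate functional reduces to a cross-section integral", {
  cfg <- peristalsis_config(lambda = 150e-6, b = 0, n_r = 6L, n_z = 12L)
  ctx <- porozero:::peristalsis_context(cfg, amp = 0)
  ctx$wave_c <- 0                       # undeformed, stationary frame
  lay <- ctx$layout
  U <- numeric(lay$ndof)
  V <- 1e-3
  U[porozero:::dof_v_node(lay, seq_len(lay$nnode), 2L)] <- V
  Q <- volume_flow_rate(U, ctx, cfg)
  ## phi V pi (R_o^2 - h^2): uniform axial fluid velocity, solid at rest
  expect_equal(Q, 0.2 * V * pi * (cfg$R_o^2 - cfg$h^2), tolerance = 1e-10)
})

test_that("moving-frame and transient solvers agree at moderate amplitude", {
  b <- 0.05e-6
  cfg <- peristalsis_config(lambda = 150e-6, b = b, n_r = 10L, n_z = 16L)
  resm <- run_peristalsis_case(cfg)
  expect_gt(resm$summary$Q_um3_s, 0)
  ## independent route: transient run with a traveling wall Dirichlet on
  ## the same mesh, ramped over one period
  mesh <- build_structured_mesh(cfg$h, cfg$R_o, 0, cfg$lambda, nz = cfg$n_z,
                                periodic_z = TRUE,
                                Rgrid = porozero:::peristalsis_radial_grid(cfg))
  lay <- build_spaces(mesh, with_mult = TRUE)
  Tper <- 1 / cfg$f
  bcs <- list(
    left = list(u = list(function(R, Z, t)
      b * min(t / Tper, 1) * sin(2 * pi * (Z - cfg$c * t) / cfg$lambda), 0),
      flux = TRUE),
    right = list(u = list(0, 0), flux = TRUE))
  ctx <- porozero:::build_context(mesh, lay, cfg$params, cfg$phiR, "transient",
                                  bcs = bcs,
                                  fd_scales = list(u = b, v = cfg$c, p = 100))
  run <- advance_transient(ctx, numeric(lay$ndof), dt = Tper / 48,
                           nsteps = 2 * 48, order = 2L,
                           newton = newton_config(rtol = 1e-7, maxit = 40))
  expect_true(run$converged)
  fl <- porozero:::filtration_diagnostics(run$U, run$Vs, ctx)
  ## flow rates agree within a few percent (different discretizations of
  ## the same traveling-wave state)
  geo <- ctx$geo
  Qt <- 0
  loc <- porozero:::gather_loc(run$U, ctx)
  vsl <- matrix(run$Vs[lay$iu], lay$nelem, 8L)
  for (q in seq_len(geo$nq)) {
    N <- geo$L[q, ]; Nb <- geo$Nb[q]; u <- loc$u
    durR <- geo$b[, 1] * u[, 1] + geo$b[, 2] * u[, 2] + geo$b[, 3] * u[, 3] +
      geo$dNbR[, q] * u[, 7]
    durZ <- geo$c[, 1] * u[, 1] + geo$c[, 2] * u[, 2] + geo$c[, 3] * u[, 3] +
      geo$dNbZ[, q] * u[, 7]
    duzR <- geo$b[, 1] * u[, 4] + geo$b[, 2] * u[, 5] + geo$b[, 3] * u[, 6] +
      geo$dNbR[, q] * u[, 8]
    duzZ <- geo$c[, 1] * u[, 4] + geo$c[, 2] * u[, 5] + geo$c[, 3] * u[, 6] +
      geo$dNbZ[, q] * u[, 8]
    urq <- N[1] * u[, 1] + N[2] * u[, 2] + N[3] * u[, 3] + Nb * u[, 7]
    J <- ((1 + durR) * (1 + duzZ) - durZ * duzR) * (1 + urq / geo$Rq[, q])
    phi <- pmin(pmax(1 - (1 - ctx$phiRf[, q]) / J, 0), 1)
    vfz <- N[1] * loc$v[, 4] + N[2] * loc$v[, 5] + N[3] * loc$v[, 6]
    vsz <- N[1] * vsl[, 4] + N[2] * vsl[, 5] + N[3] * vsl[, 6] + Nb * vsl[, 8]
    meas <- 2 * pi * geo$A * geo$w[q] * geo$Rq[, q]
    Qt <- Qt + sum(meas * phi * (vfz - vsz) * J)
  }
  Qt <- Qt / cfg$lambda
  expect_lt(abs(Qt - resm$summary$Q_m3_s) / abs(resm$summary$Q_m3_s), 0.05)
})

test_that("reversing the wave direction flips the pumping direction", {
  b <- 0.05e-6
  cfgp <- peristalsis_config(lambda = 150e-6, b = b, n_r = 8L, n_z = 16L)
  cfgm <- peristalsis_config(lambda = 150e-6, b = b, n_r = 8L, n_z = 16L,
                             direction = -1)
  Qp <- run_peristalsis_case(cfgp)$summary$Q_m3_s
  Qm <- run_peristalsis_case(cfgm)$summary$Q_m3_s
  expect_lt(abs(Qp + Qm) / abs(Qp), 1e-3)
})

test_that("periodic and zero-mean-pressure invariants hold on a converged case", {
  cfg <- peristalsis_config(lambda = 150e-6, b = 0.05e-6, n_r = 8L, n_z = 16L)
  res <- run_peristalsis_case(cfg)
  lay <- res$ctx$layout
  p <- res$U[porozero:::dof_p_node(lay, seq_len(lay$nnode))]
  expect_lt(abs(sum(res$ctx$Wp * p)) / (sum(res$ctx$Wp) * max(abs(p))), 1e-10)
  ## periodicity is built into the dof identification: fields at z = 0 and
  ## z = lambda literally share dofs
  expect_equal(nrow(res$ctx$mesh$nodes), (cfg$n_r + 1L) * cfg$n_z)
})

test_that("pumping scales quadratically at small amplitude", {
  gap <- 1e-6
  cfg1 <- peristalsis_config(lambda = 150e-6, b = 0.01 * gap, n_r = 8L, n_z = 16L)
  cfg2 <- peristalsis_config(lambda = 150e-6, b = 0.02 * gap, n_r = 8L, n_z = 16L)
  Q1 <- run_peristalsis_case(cfg1)$summary$Q_m3_s
  Q2 <- run_peristalsis_case(cfg2)$summary$Q_m3_s
  expect_lt(abs(Q2 / Q1 - 4), 0.4)     # within 10 % of quadratic scaling
})
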