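test_that("residuals vanish for the unloaded reference state", {
  ctx <- tiny_ctx()
  U <- numeric(ctx$layout$ndof)
  s <- porozero:::assemble_system(U, ctx)
  expect_equal(max(abs(s$res)), 0)
})

test_that("hydrostatic pore pressure with matching boundary traction is an equilibrium", {
  p0 <- 100
  mesh <- tiny_mesh()
  bcs <- list(bottom = list(u = list(0, 0), p = p0),
              right = list(traction = list(type = "total_ref",
                             fun = function(R, Z, t) cbind(-p0 + 0 * R, 0 * R)),
                           flux = TRUE),
              top = list(p = p0,
                         traction = list(type = "total_ref",
                           fun = function(R, Z, t) cbind(0 * R, -p0 + 0 * R))),
              axis = list(u = list(0, NA)))
  ctx <- tiny_ctx(mesh, bcs = bcs)
  lay <- ctx$layout
  U <- numeric(lay$ndof)
  U[lay$off_p + seq_len(lay$nnode)] <- p0
  s <- porozero:::assemble_system(U, ctx)
  bn <- porozero:::block_norms(s$res, lay)
  expect_lt(max(bn), 1e-12)
})

test_that("assembled Jacobian matches directional finite differences", {
  set.seed(1)
  ctx <- tiny_ctx()
  lay <- ctx$layout
  porozero:::update_step_data(ctx, 0, hist = list(
    c0 = 100, uh = rnorm(lay$ndof, 0, 1e-4), vh = rnorm(lay$ndof, 0, 1e-2),
    vfh = rnorm(lay$ndof, 0, 1e-2)))
  U <- numeric(lay$ndof)
  U[seq_len(lay$off_v)] <- rnorm(lay$off_v, 0, 1e-4)
  U[(lay$off_v + 1):lay$off_p] <- rnorm(2 * lay$nnode, 0, 1e-3)
  U[(lay$off_p + 1):lay$ndof] <- rnorm(lay$nnode, 0, 10)
  s <- porozero:::assemble_system(U, ctx, want_jac = TRUE)
  ## block-scaled direction to keep the FD step well conditioned per field
  d <- numeric(lay$ndof)
  d[seq_len(lay$off_v)] <- rnorm(lay$off_v) * 1e-4
  d[(lay$off_v + 1):lay$off_p] <- rnorm(2 * lay$nnode) * 1e-3
  d[(lay$off_p + 1):lay$ndof] <- rnorm(lay$nnode) * 10
  h <- 1e-4
  rp <- porozero:::assemble_system(U + h * d, ctx)$res
  rm <- porozero:::assemble_system(U - h * d, ctx)$res
  fd <- (rp - rm) / (2 * h)
  jd <- as.numeric(s$jac %*% d)
  expect_lt(sqrt(sum((fd - jd)^2)) / sqrt(sum(jd^2)), 1e-6)
})

test_that("a zero-load quiescent run stays identically zero and Dirichlet data are exact", {
  mesh <- tiny_mesh()
  g <- function(R, Z, t) 1e-6 * t * (Z / 1e-2)
  bcs <- list(bottom = list(u = list(0, 0), p = 0),
              right = list(u = list(0, function(R, Z, t) g(R, Z, t))),
              axis = list(u = list(0, NA)))
  lay <- build_spaces(mesh)
  ctx <- porozero:::build_context(mesh, lay, mp_verif(),
                                  referential_porosity(0.5), "transient",
                                  bcs = bcs,
                                  fd_scales = list(u = 1e-6, v = 1e-4, p = 10))
  run <- advance_transient(ctx, numeric(lay$ndof), dt = 0.1, nsteps = 3,
                           newton = newton_config(rtol = 1e-10))
  expect_true(run$converged)
  ## constrained dofs carry their data exactly
  expect_equal(run$U[ctx$dir_idx], ctx$dir_val)
  ## a fully unloaded variant stays exactly zero
  ctx0 <- tiny_ctx()
  run0 <- advance_transient(ctx0, numeric(ctx0$layout$ndof), dt = 0.1,
                            nsteps = 2, newton = newton_config())
  expect_true(run0$converged)
  expect_equal(max(abs(run0$U)), 0)
})

test_that("Newton converges quadratically on a single implicit step", {
  ms <- manufactured_solution("phi05")
  mesh <- build_structured_mesh(0, ms$Rdom, 0, ms$L, nr = 2L, nz = 4L)
  ctx <- porozero:::mms_context(ms, mesh)
  lay <- ctx$layout
  dt <- 2e-3
  porozero:::update_step_data(ctx, dt, hist = list(
    c0 = 1 / dt, uh = numeric(lay$ndof), vh = numeric(lay$ndof),
    vfh = numeric(lay$ndof)))
  sol <- porozero:::solve_newton(numeric(lay$ndof), ctx,
                                 newton_config(rtol = 1e-12, maxit = 12,
                                               jac_reuse = FALSE))
  expect_true(sol$converged)
  expect_lte(sol$iters, 6L)
  ## superlinear signature: a single full Newton step collapses the
  ## residual by several orders of magnitude on this mildly nonlinear step
  h <- sol$res_history
  expect_lt(h[2] / h[1], 1e-3)
})
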