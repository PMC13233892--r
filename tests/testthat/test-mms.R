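test_that("manufactured fields honor their defining values", {
  ms <- manufactured_solution("phi05")
  ## displacement vanishes at t = 0
  R <- c(1e-3, 3e-3); Z <- c(2e-3, 8e-3)
  expect_equal(max(abs(ms$u(R, Z, 0))), 0)
  ## p = p_o at the (current) corner r = z = L at t = t_o: invert the
  ## separable map numerically for the reference preimage of (L, L)
  Rstar <- uniroot(function(R) R + ms$uR(R, 0, ms$t_o) - ms$L,
                   c(0, ms$L), tol = 1e-14)$root
  Zstar <- uniroot(function(Z) Z + ms$uZ(0, Z, ms$t_o) - ms$L,
                   c(0, ms$L), tol = 1e-14)$root
  expect_equal(ms$p(Rstar, Zstar, ms$t_o), ms$p_o, tolerance = 1e-9)
  ## zero-porosity case: fluid velocity identical to the solid's
  ms0 <- manufactured_solution("phi0")
  for (t in c(0.01, 0.3, 1)) {
    expect_equal(ms0$vf(R, Z, t), ms0$vs(R, Z, t))
  }
  expect_equal(ms0$phi(R, Z, 0.5), c(0, 0))
})

test_that("symbolically derived sources agree with numerical differentiation", {
  ms <- manufactured_solution("phi05")
  R <- c(0.8e-3, 2.9e-3, 4.6e-3); Z <- c(1.5e-3, 5.5e-3, 9.1e-3); t <- 0.03
  h <- 1e-8
  ## referential pressure gradient
  gp <- ms$grad_p(R, Z, t)
  fdR <- (ms$p(R + h, Z, t) - ms$p(R - h, Z, t)) / (2 * h)
  expect_lt(max(rel_diff(gp[, 1], fdR)), 1e-6)
  ## continuity source against an independent finite-difference divergence
  l1 <- 1 + (ms$uR(R + h, Z, t) - ms$uR(R - h, Z, t)) / (2 * h)
  l3 <- 1 + (ms$uZ(R, Z + h, t) - ms$uZ(R, Z - h, t)) / (2 * h)
  compr <- function(R, Z, t) {
    ph <- ms$phi(R, Z, t); vs <- ms$vs(R, Z, t); vf <- ms$vf(R, Z, t)
    vs[, 1] + ph * (vf[, 1] - vs[, 1])
  }
  compz <- function(R, Z, t) {
    ph <- ms$phi(R, Z, t); vs <- ms$vs(R, Z, t); vf <- ms$vf(R, Z, t)
    vs[, 2] + ph * (vf[, 2] - vs[, 2])
  }
  qn <- (compr(R + h, Z, t) - compr(R - h, Z, t)) / (2 * h) / l1 +
    compr(R, Z, t) / (R + ms$uR(R, Z, t)) +
    (compz(R, Z + h, t) - compz(R, Z - h, t)) / (2 * h) / l3
  expect_lt(max(rel_diff(ms$sources$q(R, Z, t), qn)), 1e-5)
  ## at t = 0 the fields vanish but the acceleration does not: the
  ## continuity source is zero and b_s reduces to the initial acceleration
  expect_lt(max(abs(ms$sources$q(R, Z, 0))), 1e-12)
  h2 <- 1e-6
  as0 <- (ms$vs(R, Z, h2) - ms$vs(R, Z, -h2)) / (2 * h2)
  expect_lt(max(abs(ms$sources$bs(R, Z, 0) - as0)), 1e-6 * max(abs(as0)))
})

test_that("the mixture momentum source closes the strong equation (independent path)", {
  for (case in c("phi05", "phi0")) {
    ms <- manufactured_solution(case)
    mp <- ms$params; phiRf <- ms$phiRf
    t <- 0.03; h <- 1e-7
    R <- c(1e-3, 3e-3); Z <- c(2e-3, 5.5e-3)
    l1 <- 1 + (ms$uR(R + h, Z, t) - ms$uR(R - h, Z, t)) / (2 * h)
    l3 <- 1 + (ms$uZ(R, Z + h, t) - ms$uZ(R, Z - h, t)) / (2 * h)
    Tfun <- function(R, Z) {
      l1 <- 1 + (ms$uR(R + h, Z, t) - ms$uR(R - h, Z, t)) / (2 * h)
      l2 <- 1 + ms$uR(R, Z, t) / R
      l3 <- 1 + (ms$uZ(R, Z + h, t) - ms$uZ(R, Z - h, t)) / (2 * h)
      vapply(seq_along(R), function(i) {
        st <- solid_stresses(diag(c(l1[i], l2[i], l3[i])), 0, 1 - phiRf, mp)
        c(st$T_e_s[1, 1], st$T_e_s[2, 2], st$T_e_s[3, 3], st$J_s)
      }, numeric(4))
    }
    T0 <- Tfun(R, Z)
    divT_r <- (Tfun(R + h, Z)[1, ] - Tfun(R - h, Z)[1, ]) / (2 * h) / l1 +
      (T0[1, ] - T0[2, ]) / (R + ms$uR(R, Z, t))
    divT_z <- (Tfun(R, Z + h)[3, ] - Tfun(R, Z - h)[3, ]) / (2 * h) / l3
    phif <- ms$phi(R, Z, t)
    rho_s <- (1 - phif) * mp$rho_s_true
    as_ <- (ms$vs(R, Z, t + h) - ms$vs(R, Z, t - h)) / (2 * h)
    dp_r <- (ms$p(R + h, Z, t) - ms$p(R - h, Z, t)) / (2 * h) / l1
    dp_z <- (ms$p(R, Z + h, t) - ms$p(R, Z - h, t)) / (2 * h) / l3
    bs <- ms$sources$bs(R, Z, t)
    ## rho_f (a_f - b_f) has the closed form -phi grad p - mu phi^3 w / kappa
    w_r <- if (case == "phi05")
      (ms$vf(R, Z, t)[, 1] - ms$vs(R, Z, t)[, 1]) / phif else 0
    w_z <- if (case == "phi05")
      (ms$vf(R, Z, t)[, 2] - ms$vs(R, Z, t)[, 2]) / phif else 0
    rfa_r <- -phif * dp_r - mp$mu_f * phif^3 * w_r / mp$kappa_bar
    rfa_z <- -phif * dp_z - mp$mu_f * phif^3 * w_z / mp$kappa_bar
    res_r <- rho_s * (as_[, 1] - bs[, 1]) + rfa_r + dp_r - divT_r
    res_z <- rho_s * (as_[, 2] - bs[, 2]) + rfa_z + dp_z - divT_z
    sc <- abs(dp_r) + abs(divT_r) + abs(rho_s * bs[, 1]) + 1e-300
    expect_lt(max(abs(res_r) / sc), 1e-5)
    sc_z <- abs(dp_z) + abs(divT_z) + abs(rho_s * bs[, 2]) + 1e-300
    expect_lt(max(abs(res_z) / sc_z), 1e-5)
  }
})

test_that("assembled residual at the interpolated manufactured state converges away", {
  ms <- manufactured_solution("phi05")
  t <- 0.03
  norms <- vapply(1:2, function(lev) {
    hm <- 2.5e-3 / 2^(lev - 1)
    mesh <- build_structured_mesh(0, ms$Rdom, 0, ms$L,
                                  nr = round(ms$Rdom / hm),
                                  nz = round(ms$L / hm))
    ctx <- porozero:::mms_context(ms, mesh)
    lay <- ctx$layout
    nd <- mesh$nodes
    U <- numeric(lay$ndof)
    U[porozero:::dof_u_node(lay, 1:lay$nnode, 1)] <- ms$uR(nd[, 1], nd[, 2], t)
    U[porozero:::dof_u_node(lay, 1:lay$nnode, 2)] <- ms$uZ(nd[, 1], nd[, 2], t)
    vf <- ms$vf(nd[, 1], nd[, 2], t)
    U[porozero:::dof_v_node(lay, 1:lay$nnode, 1)] <- vf[, 1]
    U[porozero:::dof_v_node(lay, 1:lay$nnode, 2)] <- vf[, 2]
    U[porozero:::dof_p_node(lay, 1:lay$nnode)] <- ms$p(nd[, 1], nd[, 2], t)
    h <- 1e-6
    vs <- ms$vs(nd[, 1], nd[, 2], t)
    as_ <- (ms$vs(nd[, 1], nd[, 2], t + h) - ms$vs(nd[, 1], nd[, 2], t - h)) / (2 * h)
    vfd <- (ms$vf(nd[, 1], nd[, 2], t + h) - ms$vf(nd[, 1], nd[, 2], t - h)) / (2 * h)
    uh <- numeric(lay$ndof); vh <- numeric(lay$ndof); vfh <- numeric(lay$ndof)
    uh[porozero:::dof_u_node(lay, 1:lay$nnode, 1)] <- vs[, 1]
    uh[porozero:::dof_u_node(lay, 1:lay$nnode, 2)] <- vs[, 2]
    vh[porozero:::dof_u_node(lay, 1:lay$nnode, 1)] <- as_[, 1]
    vh[porozero:::dof_u_node(lay, 1:lay$nnode, 2)] <- as_[, 2]
    vfh[porozero:::dof_v_node(lay, 1:lay$nnode, 1)] <- vfd[, 1]
    vfh[porozero:::dof_v_node(lay, 1:lay$nnode, 2)] <- vfd[, 2]
    porozero:::update_step_data(ctx, t, hist = list(c0 = 0, uh = uh, vh = vh,
                                                    vfh = vfh))
    sqrt(sum(porozero:::assemble_system(U, ctx)$res^2))
  }, 0)
  expect_lt(norms[2], 0.55 * norms[1])
})

test_that("a short coarse convergence study shows second-order fields", {
  rep1 <- run_convergence_study("phi05", levels = 3L, dt = 2e-3,
                                T_final = 1e-2, quiet = TRUE)
  expect_true(all(rep1$errors$u_L2 > 0))
  expect_true(all(diff(log(rep1$errors$u_L2)) < 0))
  expect_gt(rep1$rates["u_L2"], 1.5)
  expect_gt(rep1$rates["p_L2"], 1.5)
  expect_gt(rep1$rates["vf_L2"], 1.5)
  ## synthetic rate fitting sanity
  tab <- data.frame(h_e = c(1, 0.5, 0.25), e = c(4, 1, 0.25))
  expect_equal(unname(fit_rates(tab)["e"]), 2, tolerance = 1e-12)
  tab2 <- data.frame(h_e = c(1, 0.5, 0.25), e = c(1, 1, 1))
  expect_equal(unname(fit_rates(tab2)["e"]), 0, tolerance = 1e-12)
})

test_that("the zero-porosity study keeps the fluid glued to the solid", {
  rep0 <- run_convergence_study("phi0", levels = 2L, dt = 2e-3,
                                T_final = 1e-2, quiet = TRUE)
  ## discrete |v_f - v_s| stays within a small factor of the u_s error
  expect_lt(rep0$vf_vs[2], 10 * rep0$errors$u_L2[2])
})
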