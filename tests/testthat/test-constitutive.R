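test_that("permeability law reproduces its closed-form values", {
  mp <- material_params(1e3, 1e3, 1e-3, 1e-9, 0.1, 5e3)
  expect_equal(permeability(0.1, mp), 1e-9)                 # continuity at phi_fc
  expect_equal(permeability(0, mp), 0)
  expect_equal(permeability(0.05, mp), 3.125e-10)           # (4-1.5)*0.5^3
  mp2 <- material_params(1e3, 1e3, 9e-4, 1.8e-14, 0.1, 14e3)
  expect_equal(permeability(0.2, mp2), 1.8e-14)             # saturated branch
  expect_error(permeability(1.2, mp), "outside")
})

test_that("permeability is continuous, C1 at phi_fc and o(phi_f) near zero", {
  for (phi_fc in c(0.05, 0.1, 0.3)) {
    mp <- material_params(1e3, 1e3, 1e-3, 1e-9, phi_fc, 5e3)
    d <- 1e-9
    expect_lt(abs(permeability(phi_fc - d, mp) - permeability(phi_fc + d, mp)),
              1e-6 * mp$kappa_bar)
    ## one-sided derivatives match (both ~ 0) at machine precision scale
    dl <- (permeability(phi_fc, mp) - permeability(phi_fc - d, mp)) / d
    dr <- (permeability(phi_fc + d, mp) - permeability(phi_fc, mp)) / d
    expect_lt(abs(dl - dr), 1e-4 * mp$kappa_bar / phi_fc)
    ## kappa = o(phi): kappa/phi decreasing to zero
    phis <- 10^seq(-2, -8, by = -1) * phi_fc
    ratio <- permeability(phis, mp) / phis
    expect_true(all(diff(ratio) < 0))
    expect_lt(ratio[length(ratio)], 1e-12 * mp$kappa_bar / phi_fc)
  }
})

test_that("eta and the division-free mobilities agree where both exist", {
  mp <- material_params(1e3, 1e3, 1e-3, 1e-9, 0.1, 5e3)
  expect_equal(drag_coefficient_eta(0.1, mp), 1e4)
  mp2 <- material_params(1e3, 1e3, 9e-4, 1.8e-14, 0.1, 14e3)
  expect_equal(drag_coefficient_eta(0.2, mp2), 9e-4 * 0.04 / 1.8e-14)
  expect_error(drag_coefficient_eta(0, mp), "undefined")
  ## derived example values
  expect_equal(mobilities(0.05, mp)$pressure,
               permeability(0.05, mp) / (mp$mu_f * 0.05))   # 6.25e-6
  expect_equal(mobilities(0.05, mp)$pressure, 6.25e-6)
  expect_equal(mobilities(0.2, mp2)$pressure, 1.8e-14 / (9e-4 * 0.2))
  ## limits at phi = 0
  m0 <- mobilities(0, mp)
  expect_identical(m0$pressure, 0)
  expect_identical(m0$inertial, 0)
  ## pressure mobility equals phi/eta for phi >= 1e-6
  phis <- 10^seq(-6, 0, length.out = 40)
  phis <- phis[phis <= 1]
  expect_lt(max(rel_diff(mobilities(phis, mp)$pressure,
                         phis / drag_coefficient_eta(phis, mp))), 1e-12)
  ## phi/eta -> 0 monotonically as phi -> 0
  small <- 10^seq(-3, -10, by = -1)
  expect_true(all(diff(mobilities(small, mp)$pressure) < 0))
})

test_that("porosity follows the deformation with saturation", {
  r <- porosity_from_deformation(1, 0.2)
  expect_equal(r$phi_f, 0.2)
  expect_equal(r$phi_s + r$phi_f, 1)
  expect_equal(porosity_from_deformation(0.8, 0.2)$phi_f, 0)   # full compaction
  expect_equal(porosity_from_deformation(2, 0.5)$phi_f, 0.75)
  over <- porosity_from_deformation(0.7, 0.2)
  expect_true(over$overcompacted)
  expect_equal(over$phi_f, 0)                                  # clamped
  expect_error(porosity_from_deformation(-1, 0.2), "invalid deformation")
  ## saturation exact for random states
  set.seed(42)
  J <- exp(rnorm(100, 0, 0.3)); phiR <- runif(100)
  rr <- porosity_from_deformation(J, phiR)
  expect_equal(rr$phi_s + rr$phi_f, rep(1, 100))
})

test_that("neo-Hookean stresses: reference state, hydrostatic, frame indifference", {
  mp <- mp_verif()
  s0 <- solid_stresses(diag(3), 0, 0.5, mp)
  expect_equal(max(abs(s0$S_e_star)), 0)
  expect_equal(max(abs(s0$P_total)), 0)
  sh <- solid_stresses(diag(3), 50, 0.5, mp)
  expect_equal(sh$P_total, -50 * diag(3))
  th <- pi / 5
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(max(abs(solid_stresses(Rot, 0, 0.5, mp)$S_e_star)), 1e-12 * mp$mu_s)
  ## elastic Cauchy stress is deviatoric
  Fs <- diag(c(1.2, 1, 1 / 1.2))
  expect_lt(abs(sum(diag(solid_stresses(Fs, 0, 1, mp)$T_e_s))), 1e-10 * mp$mu_s)
})

test_that("second Piola-Kirchhoff stress matches the energy finite-difference oracle", {
  mp <- mp_verif()
  psi <- function(C) {
    J <- sqrt(det(C))
    0.5 * mp$mu_s * (J^(-2 / 3) * sum(diag(C)) - 3)
  }
  set.seed(7)
  for (k in 1:4) {
    A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    Fs <- A
    if (det(Fs) < 0) Fs[, 1] <- -Fs[, 1]
    C <- t(Fs) %*% Fs
    S_fd <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      dC <- matrix(0, 3, 3); dC[i, j] <- h / 2; dC[j, i] <- dC[j, i] + h / 2
      S_fd[i, j] <- 2 * (psi(C + dC) - psi(C - dC)) / (2 * h)
    }
    S <- solid_stresses(Fs, 0, 1, mp)$S_e_star
    expect_lt(max(abs(S - S_fd)) / max(abs(S)), 1e-6)
  }
})

test_that("stress push-forward identity holds for random admissible states", {
  mp <- mp_verif()
  set.seed(11)
  for (k in 1:5) {
    Fs <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(Fs) <= 0.2) next
    p <- rnorm(1, 0, 100)
    st <- solid_stresses(Fs, p, 0.6, mp)
    lhs <- st$P_total %*% t(Fs) / st$J_s
    rhs <- -p * diag(3) + st$T_e_s
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(1, max(abs(rhs))))
    ## S and T_e symmetric
    expect_lt(max(abs(st$S_e_star - t(st$S_e_star))), 1e-10 * max(abs(st$S_e_star)))
    expect_lt(max(abs(st$T_e_s - t(st$T_e_s))), 1e-10 * max(1, max(abs(st$T_e_s))))
  }
})

test_that("solid + fluid momentum densities sum to the mixture density", {
  ## the mixture equation of motion is the sum of the per-phase equations:
  ## the drag terms cancel and the phi-weighted pressure gradients combine
  mp <- mp_verif()
  set.seed(3)
  for (k in 1:5) {
    phi <- runif(1, 0.05, 0.95)
    as_ <- rnorm(3); af <- rnorm(3); bs <- rnorm(3); bf <- rnorm(3)
    gp <- rnorm(3); divT <- rnorm(3); vrel <- rnorm(3)
    drag <- phi^2 * mp$mu_f / permeability(phi, mp)
    rho_s <- (1 - phi) * mp$rho_s_true; rho_f <- phi * mp$rho_f_true
    solid <- rho_s * (as_ - bs) + (1 - phi) * gp - drag * vrel - divT
    fluid <- rho_f * (af - bf) + phi * gp + drag * vrel
    mixture <- rho_s * (as_ - bs) + rho_f * (af - bf) + gp - divT
    expect_equal(solid + fluid, mixture, tolerance = 1e-12)
  }
})

test_that("filtration velocity is phi-weighted relative velocity", {
  expect_equal(filtration_velocity(0.3, c(1, 0), c(1, 0)), c(0, 0))
  expect_equal(filtration_velocity(0, c(5, 2), c(0, 0)), c(0, 0))
  expect_equal(filtration_velocity(0.2, c(1, 0), c(0, 0)), c(0.2, 0))
})

test_that("radial porosity profile blends as specified", {
  h <- 10e-6; Rb <- 12e-6
  expect_equal(referential_porosity_profile(h, 0.8, 0.2, Rb, h), 0.8)
  expect_equal(referential_porosity_profile(Rb, 0.8, 0.2, Rb, h), 0.2)
  expect_equal(referential_porosity_profile((h + Rb) / 2, 0.8, 0.2, Rb, h), 0.5)
  expect_equal(referential_porosity_profile(5 * Rb, 0.8, 0.2, Rb, h), 0.2)
  ## continuity and C1 at R_bar: one-sided slopes right at the blend
  ## radius are small compared with the interior slope scale
  d <- 1e-9
  vals <- referential_porosity_profile(c(Rb - d, Rb + d), 0.8, 0.2, Rb, h)
  ## the value gap across the knot is quadratic: |f''| d^2 with
  ## f'' = 0.3 (pi/(Rb-h))^2
  expect_lt(abs(vals[1] - vals[2]), 2 * 0.3 * (pi / (Rb - h))^2 * d^2)
  slope_scale <- 0.3 * pi / (Rb - h)
  dl <- diff(referential_porosity_profile(c(Rb - d, Rb), 0.8, 0.2, Rb, h)) / d
  dr <- diff(referential_porosity_profile(c(Rb, Rb + d), 0.8, 0.2, Rb, h)) / d
  expect_lt(abs(dl - dr), 0.01 * slope_scale)
  expect_error(referential_porosity_profile(h / 2, 0.8, 0.2, Rb, h), "R < h")
})
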