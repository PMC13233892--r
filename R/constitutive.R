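#' Porosity-dependent permeability law
#'
#' Permeability of the solid skeleton as a function of the current fluid
#' volume fraction. Above the critical porosity `phi_fc` the permeability
#' saturates at `kappa_bar`; below it, it follows the cubic blending law
#' kappa = kappa_bar * (4 - 3 x) * x^3 with x = phi_f / phi_fc, which is C1
#' at the junction and behaves as o(phi_f) near zero porosity, the property
#' that lets the rescaled fluid-momentum equation degenerate gracefully to
#' v_f = v_s.
#'
#' @param phi_f Fluid volume fraction(s) in [0, 1]. Vectorized.
#' @param params A [material_params()] object.
#' @return Permeability value(s) in m^2, in [0, kappa_bar].
#' @export
permeability <- function(phi_f, params) {
  .check_phi(phi_f)
  phi_f <- pmin(pmax(phi_f, 0), 1)
  x <- phi_f / params$phi_fc
  ifelse(x < 1, params$kappa_bar * (4 - 3 * x) * x^3, params$kappa_bar)
}

#' Drag coefficient eta of the fluid-solid interaction
#'
#' eta(phi_f) = mu_f phi_f^2 / kappa_s(phi_f), the coefficient by which the
#' fluid momentum balance is rescaled. Only meaningful for strictly positive
#' porosity: at phi_f = 0 the quotient is undefined and callers must use the
#' division-free [mobilities()] instead.
#'
#' @inheritParams permeability
#' @return eta in Pa.s/m^2.
#' @export
drag_coefficient_eta <- function(phi_f, params) {
  .check_phi(phi_f)
  if (any(phi_f <= 0))
    stop("eta is undefined at phi_f = 0; use mobilities() in assembled forms")
  params$mu_f * phi_f^2 / permeability(phi_f, params)
}

#' Division-free mobilities of the rescaled fluid momentum equation
#'
#' The coefficients phi_f / eta (pressure mobility, m^2/(Pa.s)) and
#' phi_f rho_f* / eta (inertial mobility, s) evaluated in closed algebraic
#' form so that phi_f = 0 is an ordinary evaluation point: on the blended
#' permeability branch phi_f/eta = kappa_bar (4 - 3x) x^2 / (mu_f phi_fc),
#' and on the saturated branch kappa_bar / (mu_f phi_f). Both mobilities are
#' continuous, nonnegative on [0, 1] and vanish at phi_f = 0.
#'
#' @inheritParams permeability
#' @return A list with components `pressure` and `inertial`, each vectorized
#'   like `phi_f`.
#' @export
mobilities <- function(phi_f, params) {
  .check_phi(phi_f)
  .mobilities_unchecked(pmin(pmax(phi_f, 0), 1), params)
}

## kernel-facing variant: no domain check, so non-finite porosities from
## inadmissible Newton iterates propagate into the residual (where the
## line search rejects them) instead of raising an error
.mobilities_unchecked <- function(phi_f, params) {
  x <- phi_f / params$phi_fc
  m_p <- ifelse(x < 1,
                params$kappa_bar * (4 - 3 * x) * x^2 / (params$mu_f * params$phi_fc),
                params$kappa_bar / (params$mu_f * phi_f))
  list(pressure = m_p, inertial = params$rho_f_true * m_p)
}

#' Current volume fractions from the solid deformation
#'
#' With incompressible constituents the solid volume fraction transforms as
#' phi_s = phi_Rs / J_s; saturation gives phi_f = 1 - phi_s. Over-compaction
#' (J_s < phi_Rs, i.e. phi_f < 0) is flagged and the returned fractions are
#' clamped to [0, 1] so constitutive evaluation stays defined during
#' transient Newton iterates; converged solutions are required to satisfy
#' phi_f >= -tol.
#'
#' @param J_s Determinant(s) of the solid deformation gradient, > 0.
#' @param phi_Rf Referential fluid volume fraction(s).
#' @param tol Tolerance below which negative phi_f is flagged as
#'   non-physical over-compaction.
#' @return List with `phi_s`, `phi_f` (clamped), `phi_f_raw` (unclamped) and
#'   logical `overcompacted`.
#' @export
porosity_from_deformation <- function(J_s, phi_Rf, tol = 1e-10) {
  if (any(!is.finite(J_s)) || any(J_s <= 0))
    stop("invalid deformation: J_s must be positive and finite")
  phi_Rs <- 1 - phi_Rf
  phi_s_raw <- phi_Rs / J_s
  phi_f_raw <- 1 - phi_s_raw
  over <- phi_f_raw < -tol
  phi_s <- pmin(pmax(phi_s_raw, 0), 1)
  phi_f <- 1 - phi_s
  list(phi_s = phi_s, phi_f = phi_f, phi_f_raw = phi_f_raw,
       overcompacted = over)
}

#' Solid stress measures of the neo-Hookean skeleton
#'
#' Computes, for one deformation state, the second Piola-Kirchhoff stress of
#' the pure solid S_e* = 2 dPsi/dC with Psi = (mu_s/2)(Ibar1 - 3), the
#' elastic first Piola-Kirchhoff stress P_e = phi_Rs F S_e*, the total first
#' Piola-Kirchhoff stress P = -p J F^{-T} + P_e, and the elastic Cauchy
#' stress T_e = J^{-1} P_e F^T. Tensors are full 3x3 objects (the hoop
#' component carries the axisymmetric kinematics).
#'
#' @param F_s Deformation gradient, 3x3 matrix with positive determinant.
#' @param p Pore pressure (Pa).
#' @param phi_Rs Referential solid volume fraction.
#' @param params A [material_params()] object.
#' @return List with matrices `S_e_star`, `P_e_s`, `P_total`, `T_e_s` and
#'   scalar `J_s`.
#' @export
solid_stresses <- function(F_s, p, phi_Rs, params) {
  stopifnot(is.matrix(F_s), all(dim(F_s) == c(3L, 3L)))
  J <- det(F_s)
  if (!is.finite(J) || J <= 0) stop("invalid deformation: det(F_s) <= 0")
  C <- crossprod(F_s)                       # F^T F
  Cinv <- solve(C)
  trCbar <- J^(-2 / 3) * sum(diag(C))
  S <- params$mu_s * J^(-2 / 3) * (diag(3) - (trCbar / 3) * J^(2 / 3) * Cinv)
  ## note: (tr Cbar / 3) * Cs^{-1} with Cbar = J^{-2/3} C  ==>
  ## S = mu_s J^{-2/3} (I - (tr C / 3) C^{-1})
  P_e <- phi_Rs * F_s %*% S
  Finv_t <- t(solve(F_s))
  P_tot <- -p * J * Finv_t + P_e
  T_e <- (P_e %*% t(F_s)) / J
  list(S_e_star = S, P_e_s = P_e, P_total = P_tot, T_e_s = T_e, J_s = J)
}

#' Filtration velocity
#'
#' The flux-carrying velocity of porous flow, v_flt = phi_f (v_f - v_s). It
#' vanishes wherever the porosity vanishes, which is what makes it the right
#' quantity for flux boundary conditions and flow-rate reporting.
#'
#' @param phi_f Fluid volume fraction(s).
#' @param v_f,v_s Fluid and solid velocities; vectors or conforming arrays.
#' @return phi_f * (v_f - v_s).
#' @export
filtration_velocity <- function(phi_f, v_f, v_s) {
  .check_phi(phi_f)
  phi_f * (v_f - v_s)
}

.check_phi <- function(phi_f, tol = 1e-9) {
  if (any(!is.finite(phi_f)) || any(phi_f < -tol) || any(phi_f > 1 + tol))
    stop("phi_f outside [0, 1]")
  invisible(TRUE)
}
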