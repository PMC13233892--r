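#' Material parameters of the biphasic mixture
#'
#' Bundles the constitutive constants of the solid-fluid mixture: true (pure
#' phase) mass densities, fluid viscosity, the saturation permeability and
#' critical porosity of the porosity-dependent permeability law, and the
#' neo-Hookean shear modulus of the solid skeleton. All values are SI.
#'
#' @param rho_s_true Mass density of the pure solid (kg/m^3).
#' @param rho_f_true Mass density of the pure fluid (kg/m^3).
#' @param mu_f Fluid dynamic viscosity (Pa.s). Treated as a material constant
#'   even where the porosity vanishes.
#' @param kappa_bar Saturation permeability (m^2): the permeability attained
#'   for porosities at or above the critical porosity.
#' @param phi_fc Critical porosity (dimensionless, in (0, 1]) below which the
#'   permeability follows the cubic blending law.
#' @param mu_s Shear modulus of the solid skeleton (Pa).
#' @return An object of class `material_params`.
#' @examples
#' mp <- material_params(1e3, 1e3, 1e-3, 1e-9, 0.1, 5e3)
#' permeability(0.05, mp)
#' @export
material_params <- function(rho_s_true, rho_f_true, mu_f, kappa_bar,
                            phi_fc, mu_s) {
  vals <- c(rho_s_true = rho_s_true, rho_f_true = rho_f_true, mu_f = mu_f,
            kappa_bar = kappa_bar, phi_fc = phi_fc, mu_s = mu_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material parameters must be strictly positive and finite")
  if (phi_fc > 1) stop("phi_fc must lie in (0, 1]")
  structure(as.list(vals), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Biphasic material parameters (SI units)\n")
  cat(sprintf("  rho_s* = %g kg/m^3, rho_f* = %g kg/m^3\n",
              x$rho_s_true, x$rho_f_true))
  cat(sprintf("  mu_f = %g Pa.s, kappa_bar = %g m^2, phi_fc = %g\n",
              x$mu_f, x$kappa_bar, x$phi_fc))
  cat(sprintf("  mu_s = %g Pa\n", x$mu_s))
  invisible(x)
}

#' Referential porosity field
#'
#' The referential fluid volume fraction phi_Rf, defined over the solid's
#' reference configuration. Either spatially uniform, or the cosine-blend
#' radial profile used to emulate a fluid-rich perivascular lumen inside
#' brain parenchyma: phi_Rf falls smoothly from `phi_f0` at the inner radius
#' `h` to `phi_f_inf` at the blend radius `R_bar`, and is constant beyond.
#'
#' @param value Uniform value of phi_Rf in [0, 1] (used when `type =
#'   "uniform"`).
#' @param type `"uniform"` or `"profile"`.
#' @param phi_f0,phi_f_inf Porosities at `R = h` and beyond `R = R_bar`.
#' @param h Inner radius (m) where the profile starts.
#' @param R_bar Blend radius (m), `R_bar > h`.
#' @return An object of class `referential_porosity`; evaluate it with
#'   [eval_porosity()].
#' @export
referential_porosity <- function(value = NULL, type = c("uniform", "profile"),
                                 phi_f0 = NULL, phi_f_inf = NULL,
                                 h = NULL, R_bar = NULL) {
  type <- match.arg(type)
  if (type == "uniform") {
    stopifnot(is.numeric(value), length(value) == 1L, value >= 0, value <= 1)
    obj <- list(type = "uniform", value = value)
  } else {
    stopifnot(phi_f0 >= 0, phi_f0 <= 1, phi_f_inf >= 0, phi_f_inf <= 1,
              R_bar > h, h > 0)
    obj <- list(type = "profile", phi_f0 = phi_f0, phi_f_inf = phi_f_inf,
                h = h, R_bar = R_bar)
  }
  structure(obj, class = "referential_porosity")
}

#' Evaluate a referential porosity field at radial coordinates
#'
#' @param phiR A [referential_porosity()] object.
#' @param R Reference radial coordinates (m).
#' @return Vector of phi_Rf values in [0, 1].
#' @export
eval_porosity <- function(phiR, R) {
  stopifnot(inherits(phiR, "referential_porosity"))
  if (phiR$type == "uniform") return(rep_len(phiR$value, length(R)))
  referential_porosity_profile(R, phiR$phi_f0, phiR$phi_f_inf,
                               phiR$R_bar, phiR$h)
}

#' Radial cosine-blend referential porosity profile
#'
#' phi_Rf(R) equals `phi_f0` at `R = h`, blends through a half cosine to
#' `phi_f_inf` at `R = R_bar`, and is constant for `R > R_bar`. The blend is
#' continuous and C1 at `R = R_bar`.
#'
#' @param R Reference radial coordinate (m), `R >= h`.
#' @param phi_f0 Porosity at the inner radius.
#' @param phi_f_inf Far-field porosity.
#' @param R_bar Blend radius (m).
#' @param h Inner radius (m).
#' @return phi_Rf values.
#' @export
referential_porosity_profile <- function(R, phi_f0, phi_f_inf, R_bar, h) {
  if (any(R < h - 1e-12 * max(h, 1)))
    stop("referential porosity profile evaluated at R < h")
  out <- rep_len(phi_f_inf, length(R))
  inb <- R <= R_bar
  out[inb] <- 0.5 * (phi_f_inf + phi_f0) -
    0.5 * (phi_f_inf - phi_f0) * cos(pi * (R[inb] - h) / (R_bar - h))
  out
}
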