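## Method-of-manufactured-solutions harness.
##
## The manufactured fields are prescribed analytically; the body forces
## b_s, b_f and the continuity source q that make them an exact solution of
## the strong system are derived symbolically (base R expression calculus,
## stats::D). Because the manufactured map is separable (u_R depends on R
## and t only, u_Z on Z and t only) the deformation gradient is diagonal
## and every spatial operator has a closed referential form:
## d/dr = (1/lambda_1) d/dR and d/dz = (1/lambda_3) d/dZ.

esub <- function(e, env) do.call(substitute, list(e, env))

## tiny expression algebra helpers
e_ <- function(a) if (is.numeric(a)) a else a
emul <- function(a, b) bquote((.(a)) * (.(b)))
eadd <- function(a, b) bquote((.(a)) + (.(b)))
esubtr <- function(a, b) bquote((.(a)) - (.(b)))
ediv <- function(a, b) bquote((.(a)) / (.(b)))

mms_fn <- function(e) {
  force(e)
  function(R, Z, t) {
    v <- eval(e, list(R = R, Z = Z, t = t))
    if (length(v) == 1L) rep(v, length(R)) else v
  }
}
mms_fn2 <- function(er, ez) {
  fr <- mms_fn(er); fz <- mms_fn(ez)
  function(R, Z, t) cbind(fr(R, Z, t), fz(R, Z, t))
}

#' Manufactured solution for the verification study
#'
#' Analytic pressure, solid displacement and fluid velocity on the
#' axisymmetric rectangle R in [0, 5 mm], Z in [0, 10 mm] (L = 10 mm):
#' p = p_o sin(pi t / 2 t_o) (r/L)^3 (z/L)^3 in current coordinates,
#' u_R = u_o (1 - cos(pi t / 2 t_o)) (R/L)^3,
#' u_Z = u_o (1 - cos(pi t / 2 t_o)) (Z/L)^3, with p_o = 100 Pa,
#' u_o = 0.1 mm, t_o = 1 s. Two cases of uniform referential porosity are
#' covered: phi_Rf = 0.5, where the manufactured fluid velocity is
#' v_f = v_s + phi_f w with the smooth perturbation
#' w = (u_o/t_o) sin(pi t / 2 t_o) ((r/L)^2, (z/L)^2); and phi_Rf = 0,
#' where v_f = v_s identically (the fluid moves with the solid wherever
#' there is no fluid), and where the porosity 1 - 1/J_s touches zero on the
#' symmetry axis so the study genuinely exercises the vanishing-porosity
#' regularization.
#'
#' @param case `"phi05"` or `"phi0"`.
#' @param params [material_params()]; Table-style verification constants by
#'   default.
#' @return An object of class `manufactured_solution`: compiled field,
#'   gradient, source, traction and flux functions of (R, Z, t), plus the
#'   geometry constants.
#' @export
manufactured_solution <- function(case = c("phi05", "phi0"),
                                  params = material_params(1e3, 1e3, 1e-3,
                                                           1e-9, 0.1, 5e3)) {
  case <- match.arg(case)
  p_o <- 100; u_o <- 1e-4; t_o <- 1; L <- 1e-2; Rdom <- 5e-3
  phiRf <- if (case == "phi05") 0.5 else 0
  ## perturbation amplitude on the Darcy velocity scale kappa grad(p) / mu
  V0 <- params$kappa_bar * p_o / (params$mu_f * L)
  cst <- list(p_o = p_o, u_o = u_o, t_o = t_o, L = L, V0 = V0,
              phiRf = phiRf, mu_s = params$mu_s, mu_f = params$mu_f,
              kb = params$kappa_bar, rsf = params$rho_f_true,
              rss = params$rho_s_true)

  uR <- esub(quote(u_o * (1 - cos(pi * t / (2 * t_o))) * (R / L)^3), cst)
  uZ <- esub(quote(u_o * (1 - cos(pi * t / (2 * t_o))) * (Z / L)^3), cst)
  l1 <- eadd(1, D(uR, "R"))
  l2 <- esub(quote(1 + u_o * (1 - cos(pi * t / (2 * t_o))) * R^2 / L^3), cst)
  l3 <- eadd(1, D(uZ, "Z"))
  Jx <- emul(emul(l1, l2), l3)
  rmap <- eadd(quote(R), uR)
  zmap <- eadd(quote(Z), uZ)
  comp <- function(e) esub(e, list(r = rmap, z = zmap))

  vsr <- D(uR, "t"); vsz <- D(uZ, "t")
  asr <- D(vsr, "t"); asz <- D(vsz, "t")

  psp <- esub(quote(p_o * sin(pi * t / (2 * t_o)) * (r / L)^3 * (z / L)^3), cst)
  pref <- comp(psp)
  dp_r <- comp(D(psp, "r"))
  dp_z <- comp(D(psp, "z"))

  ## the two verification cases hold the porosity frozen at a constant
  ## current value (the coupled porosity-deformation law is exercised by
  ## the benchmark problems, not by the manufactured studies)
  phi <- phiRf
  if (case == "phi05") {
    wr <- comp(esub(quote(V0 * sin(pi * t / (2 * t_o)) * (r / L)^2), cst))
    wz <- comp(esub(quote(V0 * sin(pi * t / (2 * t_o)) * (z / L)^2), cst))
    vfr <- eadd(vsr, emul(phi, wr))
    vfz <- eadd(vsz, emul(phi, wz))
  } else {
    wr <- 0; wz <- 0
    vfr <- vsr; vfz <- vsz
  }

  ## fluid acceleration in ALE form: total t-derivative of the referential
  ## expression plus convection by (v_f - v_s)
  cfr <- esubtr(vfr, vsr); cfz <- esubtr(vfz, vsz)
  afr <- eadd(D(vfr, "t"),
              eadd(emul(ediv(D(vfr, "R"), l1), cfr),
                   emul(ediv(D(vfr, "Z"), l3), cfz)))
  afz <- eadd(D(vfz, "t"),
              eadd(emul(ediv(D(vfz, "R"), l1), cfr),
                   emul(ediv(D(vfz, "Z"), l3), cfz)))

  ## rescaled fluid momentum:  b_f = a_f + grad p / rho_f* + w eta / rho_f*
  ## (on the manufactured states phi stays on the saturated permeability
  ## branch whenever w is nonzero, so eta = mu_f phi^2 / kappa_bar)
  drag_r <- if (case == "phi05")
    esub(emul(wr, quote(mu_f * (PHI)^2 / (kb * rsf))), c(cst, list(PHI = phi))) else 0
  drag_z <- if (case == "phi05")
    esub(emul(wz, quote(mu_f * (PHI)^2 / (kb * rsf))), c(cst, list(PHI = phi))) else 0
  bfr <- eadd(afr, eadd(esub(ediv(dp_r, quote(rsf)), cst), drag_r))
  bfz <- eadd(afz, eadd(esub(ediv(dp_z, quote(rsf)), cst), drag_z))

  ## rho_f (a_f - b_f) = -phi grad p - mu_f phi^3 w / kappa_bar
  rfa_r <- esub(esubtr(emul(-1, emul(phi, dp_r)),
                       if (case == "phi05")
                         emul(quote(mu_f / kb), emul(bquote((.(phi))^3), wr))
                       else 0), cst)
  rfa_z <- esub(esubtr(emul(-1, emul(phi, dp_z)),
                       if (case == "phi05")
                         emul(quote(mu_f / kb), emul(bquote((.(phi))^3), wz))
                       else 0), cst)

  ## elastic Cauchy stress (diagonal): T_ii = phi_Rs mu_s J^(-5/3) (l_i^2 - trC/3)
  trC <- eadd(bquote((.(l1))^2), eadd(bquote((.(l2))^2), bquote((.(l3))^2)))
  phis <- 1 - phiRf
  Tfac <- esub(emul(quote(mu_s), emul(phis, bquote((.(Jx))^(-5 / 3)))), cst)
  Trr <- emul(Tfac, esubtr(bquote((.(l1))^2), ediv(trC, 3)))
  Ttt <- emul(Tfac, esubtr(bquote((.(l2))^2), ediv(trC, 3)))
  Tzz <- emul(Tfac, esubtr(bquote((.(l3))^2), ediv(trC, 3)))
  divT_r <- eadd(ediv(D(Trr, "R"), l1), ediv(esubtr(Trr, Ttt), rmap))
  divT_z <- ediv(D(Tzz, "Z"), l3)

  ## mixture momentum: b_s = a_s + (grad p - div T_e + rho_f(a_f - b_f))/rho_s
  rho_s <- params$rho_s_true * (1 - phiRf)
  bsr <- eadd(asr, ediv(eadd(esubtr(dp_r, divT_r), rfa_r), rho_s))
  bsz <- eadd(asz, ediv(eadd(esubtr(dp_z, divT_z), rfa_z), rho_s))

  ## continuity source: q = div(v_s + phi^2 w) in current coordinates
  comp_r <- eadd(vsr, emul(bquote((.(phi))^2), wr))
  comp_z <- eadd(vsz, emul(bquote((.(phi))^2), wz))
  qsrc <- eadd(eadd(ediv(D(comp_r, "R"), l1), ediv(comp_r, rmap)),
               ediv(D(comp_z, "Z"), l3))

  ## boundary data -------------------------------------------------------
  vflt_r <- emul(bquote((.(phi))^2), wr)     # filtration velocity phi^2 w
  vflt_z <- emul(bquote((.(phi))^2), wz)
  ## referential TOTAL traction density on the top edge (normal e_z):
  ## (T_e - p I) n, area-scaled: (0, (T_zz - p) l1 l2). Prescribing the
  ## total traction (with the discrete pressure trace appearing in the
  ## boundary term) keeps the pressure controlled on the free edge in the
  ## incompressible limit; with the elastic-only datum the zero-porosity
  ## case exhibits a weakly controlled pressure/dilation boundary mode.
  trac_top_z <- emul(esubtr(Tzz, pref), emul(l1, l2))

  structure(list(
    case = case, params = params, phiRf = phiRf,
    L = L, Rdom = Rdom, p_o = p_o, u_o = u_o, t_o = t_o,
    expr = list(uR = uR, uZ = uZ, p = pref, vfr = vfr, vfz = vfz,
                J = Jx, phi = phi, q = qsrc, bsr = bsr, bfr = bfr),
    u = mms_fn2(uR, uZ),
    uR = mms_fn(uR), uZ = mms_fn(uZ),
    p = mms_fn(pref),
    vf = mms_fn2(vfr, vfz),
    vs = mms_fn2(vsr, vsz),
    J = mms_fn(Jx), phi = mms_fn(phi),
    grad_u = list(RR = mms_fn(D(uR, "R")), RZ = mms_fn(0),
                  ZR = mms_fn(0), ZZ = mms_fn(D(uZ, "Z")),
                  hoop = mms_fn(esub(
                    quote(u_o * (1 - cos(pi * t / (2 * t_o))) * R^2 / L^3), cst))),
    grad_p = mms_fn2(D(pref, "R"), D(pref, "Z")),
    div_vf = mms_fn(eadd(eadd(D(vfr, "R"),
                              ediv(vfr, quote(R))), D(vfz, "Z"))),
    sources = list(bs = mms_fn2(bsr, bsz), bf = mms_fn2(bfr, bfz),
                   q = mms_fn(qsrc)),
    flux = list(right = mms_fn(vflt_r), top = mms_fn(vflt_z),
                bottom = mms_fn(emul(-1, vflt_z))),
    traction_top = mms_fn2(0, trac_top_z)
  ), class = "manufactured_solution")
}

#' @export
print.manufactured_solution <- function(x, ...) {
  cat(sprintf(
    "Manufactured solution, case %s (phi_Rf = %g), domain %g x %g mm\n",
    x$case, x$phiRf, 1e3 * x$Rdom, 1e3 * x$L))
  invisible(x)
}

#' Derive the manufactured-solution source terms
#'
#' Returns the body forces and continuity source that make the manufactured
#' fields an exact solution of the strong system, as callable coefficient
#' functions of the reference coordinates and time. The derivation is
#' symbolic; `q` participates only in verification runs and is zero in all
#' physical problems.
#'
#' @param ms A [manufactured_solution()].
#' @return List of functions `bs(R,Z,t)`, `bf(R,Z,t)` (two-column) and
#'   `q(R,Z,t)`.
#' @export
derive_mms_sources <- function(ms) ms$sources

## -------------------------------------------------------------------------

mms_bcs <- function(ms) {
  uRf <- ms$uR; uZf <- ms$uZ
  list(
    axis = list(u = list(0, function(R, Z, t) uZf(R, Z, t))),
    bottom = list(u = list(function(R, Z, t) uRf(R, Z, t),
                           function(R, Z, t) uZf(R, Z, t)),
                  flux = function(R, Z, t) ms$flux$bottom(R, Z, t)),
    right = list(u = list(function(R, Z, t) uRf(R, Z, t),
                          function(R, Z, t) uZf(R, Z, t)),
                 flux = function(R, Z, t) ms$flux$right(R, Z, t)),
    top = list(traction = list(type = "total_ref",
                               fun = ms$traction_top),
               flux = function(R, Z, t) ms$flux$top(R, Z, t))
  )
}

mms_context <- function(ms, mesh, quad = tri_quadrature(5L)) {
  layout <- build_spaces(mesh, with_mult = TRUE)
  phiR <- referential_porosity(ms$phiRf)
  ctx <- build_context(mesh, layout, ms$params, phiR, "transient",
                       bcs = mms_bcs(ms), sources = ms$sources,
                       quad = quad,
                       fd_scales = list(
                         u = ms$u_o,
                         v = max(ms$u_o / ms$t_o,
                                 ms$params$kappa_bar * ms$p_o /
                                   (ms$params$mu_f * ms$L)),
                         p = ms$p_o))
  ctx$phi_frozen <- TRUE
  pn <- function(t) sum(ctx$Wp * ms$p(mesh$nodes[, 1L], mesh$nodes[, 2L], t))
  ctx$mult_target_fun <- pn
  ctx
}

## Relative error norms of a discrete state against the manufactured
## fields, evaluated by quadrature on the reference domain.
mms_errors <- function(U, ctx, ms, t) {
  lay <- ctx$layout; geo <- ctx$geo
  loc <- gather_loc(U, ctx)
  u <- loc$u; v <- loc$v; p <- loc$p
  b <- geo$b; cc <- geo$c
  acc <- numeric(12)   # err/ref pairs: uL2, pL2, vL2, uH1, pH1, vHdiv
  for (q in seq_len(geo$nq)) {
    N <- geo$L[q, ]; Nb <- geo$Nb[q]
    Rq <- geo$Rq[, q]; Zq <- geo$Zq[, q]
    dNbR <- geo$dNbR[, q]; dNbZ <- geo$dNbZ[, q]
    meas <- (2 * pi) * geo$A * geo$w[q] * Rq
    urh <- N[1] * u[, 1] + N[2] * u[, 2] + N[3] * u[, 3] + Nb * u[, 7]
    uzh <- N[1] * u[, 4] + N[2] * u[, 5] + N[3] * u[, 6] + Nb * u[, 8]
    durR <- b[, 1] * u[, 1] + b[, 2] * u[, 2] + b[, 3] * u[, 3] + dNbR * u[, 7]
    durZ <- cc[, 1] * u[, 1] + cc[, 2] * u[, 2] + cc[, 3] * u[, 3] + dNbZ * u[, 7]
    duzR <- b[, 1] * u[, 4] + b[, 2] * u[, 5] + b[, 3] * u[, 6] + dNbR * u[, 8]
    duzZ <- cc[, 1] * u[, 4] + cc[, 2] * u[, 5] + cc[, 3] * u[, 6] + dNbZ * u[, 8]
    ph <- N[1] * p[, 1] + N[2] * p[, 2] + N[3] * p[, 3]
    dpR <- b[, 1] * p[, 1] + b[, 2] * p[, 2] + b[, 3] * p[, 3]
    dpZ <- cc[, 1] * p[, 1] + cc[, 2] * p[, 2] + cc[, 3] * p[, 3]
    vrh <- N[1] * v[, 1] + N[2] * v[, 2] + N[3] * v[, 3]
    vzh <- N[1] * v[, 4] + N[2] * v[, 5] + N[3] * v[, 6]
    divvh <- b[, 1] * v[, 1] + b[, 2] * v[, 2] + b[, 3] * v[, 3] +
      vrh / Rq +
      cc[, 1] * v[, 4] + cc[, 2] * v[, 5] + cc[, 3] * v[, 6]

    uex_r <- ms$uR(Rq, Zq, t); uex_z <- ms$uZ(Rq, Zq, t)
    gu <- list(RR = ms$grad_u$RR(Rq, Zq, t), ZZ = ms$grad_u$ZZ(Rq, Zq, t))
    pex <- ms$p(Rq, Zq, t); gp <- ms$grad_p(Rq, Zq, t)
    vex <- ms$vf(Rq, Zq, t); dvex <- ms$div_vf(Rq, Zq, t)

    acc[1] <- acc[1] + sum(meas * ((urh - uex_r)^2 + (uzh - uex_z)^2))
    acc[2] <- acc[2] + sum(meas * (uex_r^2 + uex_z^2))
    acc[3] <- acc[3] + sum(meas * (ph - pex)^2)
    acc[4] <- acc[4] + sum(meas * pex^2)
    acc[5] <- acc[5] + sum(meas * ((vrh - vex[, 1])^2 + (vzh - vex[, 2])^2))
    acc[6] <- acc[6] + sum(meas * (vex[, 1]^2 + vex[, 2]^2))
    acc[7] <- acc[7] + sum(meas * ((durR - gu$RR)^2 + durZ^2 + duzR^2 +
                                   (duzZ - gu$ZZ)^2))
    acc[8] <- acc[8] + sum(meas * (gu$RR^2 + gu$ZZ^2))
    acc[9] <- acc[9] + sum(meas * ((dpR - gp[, 1])^2 + (dpZ - gp[, 2])^2))
    acc[10] <- acc[10] + sum(meas * (gp[, 1]^2 + gp[, 2]^2))
    acc[11] <- acc[11] + sum(meas * (divvh - dvex)^2)
    acc[12] <- acc[12] + sum(meas * dvex^2)
  }
  c(u_L2 = sqrt(acc[1] / acc[2]),
    p_L2 = sqrt(acc[3] / acc[4]),
    vf_L2 = sqrt(acc[5] / acc[6]),
    u_H1 = sqrt(acc[7] / acc[8]),
    p_H1 = sqrt(acc[9] / acc[10]),
    vf_Hdiv = sqrt(acc[11] / acc[12]))
}

## L2 norm of v_f - v_s of a discrete transient state (zero-porosity check)
vf_minus_vs_norm <- function(U, Vs, ctx) {
  lay <- ctx$layout; geo <- ctx$geo
  loc <- gather_loc(U, ctx)
  vsl <- matrix(Vs[lay$iu], lay$nelem, 8L)
  num <- 0; den <- 0
  for (q in seq_len(geo$nq)) {
    N <- geo$L[q, ]; Nb <- geo$Nb[q]
    meas <- (2 * pi) * geo$A * geo$w[q] * geo$Rq[, q]
    vfr <- N[1] * loc$v[, 1] + N[2] * loc$v[, 2] + N[3] * loc$v[, 3]
    vfz <- N[1] * loc$v[, 4] + N[2] * loc$v[, 5] + N[3] * loc$v[, 6]
    vsr <- N[1] * vsl[, 1] + N[2] * vsl[, 2] + N[3] * vsl[, 3] + Nb * vsl[, 7]
    vsz <- N[1] * vsl[, 4] + N[2] * vsl[, 5] + N[3] * vsl[, 6] + Nb * vsl[, 8]
    num <- num + sum(meas * ((vfr - vsr)^2 + (vfz - vsz)^2))
    den <- den + sum(meas * (vsr^2 + vsz^2))
  }
  sqrt(num) / max(sqrt(den), 1e-300)
}

#' Run the manufactured-solution convergence study
#'
#' Solves the transient problem on a sequence of uniformly refined meshes
#' (starting size 2.5 mm), computes relative error norms at the final time
#' and fits convergence rates by log-log least squares.
#'
#' @param case `"phi05"` or `"phi0"`.
#' @param levels Number of refinement levels (>= 3 for a meaningful fit).
#' @param dt Time step (s).
#' @param T_final Final time (s).
#' @param params Material parameters.
#' @param newton Newton configuration.
#' @param quiet Suppress progress messages.
#' @return A `convergence_report`: data frame of per-level errors, fitted
#'   `rates`, and run metadata.
#' @export
run_convergence_study <- function(case = "phi05", levels = 4L, dt = 5e-4,
                                  T_final = 5e-2,
                                  params = material_params(1e3, 1e3, 1e-3,
                                                           1e-9, 0.1, 5e3),
                                  newton = newton_config(rtol = 1e-9),
                                  quiet = FALSE) {
  stopifnot(levels >= 2L)
  ms <- manufactured_solution(case, params)
  nsteps <- round(T_final / dt)
  rows <- list()
  extra <- list()
  for (lev in seq_len(levels)) {
    h <- 2.5e-3 / 2^(lev - 1)
    mesh <- build_structured_mesh(0, ms$Rdom, 0, ms$L,
                                  nr = as.integer(ms$Rdom / h),
                                  nz = as.integer(ms$L / h))
    ctx <- mms_context(ms, mesh)
    U0 <- numeric(ctx$layout$ndof)
    run <- advance_transient(ctx, U0, dt = dt, nsteps = nsteps,
                             order = 2L, newton = newton)
    if (!run$converged)
      stop("solver failed at level ", lev, ", t = ", run$failure$t)
    err <- mms_errors(run$U, ctx, ms, nsteps * dt)
    rows[[lev]] <- c(h_e = h, err)
    extra[[lev]] <- list(vf_vs = vf_minus_vs_norm(run$U, run$Vs, ctx),
                         min_phi = run$min_phi_run)
    if (!quiet)
      message(sprintf("level %d (h = %.4g mm): u_L2 %.3e, p_L2 %.3e, vf_L2 %.3e",
                      lev, 1e3 * h, err["u_L2"], err["p_L2"], err["vf_L2"]))
  }
  tab <- as.data.frame(do.call(rbind, rows))
  rates <- fit_rates(tab)
  ntail <- min(3L, nrow(tab))
  rates_tail <- fit_rates(tab[(nrow(tab) - ntail + 1L):nrow(tab), ])
  structure(list(case = case, errors = tab, rates = rates,
                 rates_tail = rates_tail,
                 vf_vs = vapply(extra, `[[`, 0, "vf_vs"),
                 min_phi = vapply(extra, `[[`, 0, "min_phi"),
                 dt = dt, T_final = T_final),
            class = "convergence_report")
}

#' Fit convergence rates from an error table
#'
#' Least-squares slope of log(error) against log(h) for each error column.
#'
#' @param tab Data frame with column `h_e` and one column per error norm.
#' @return Named vector of fitted rates.
#' @export
fit_rates <- function(tab) {
  stopifnot("h_e" %in% names(tab))
  lh <- log(tab$h_e)
  vapply(setdiff(names(tab), "h_e"), function(cn) {
    le <- log(tab[[cn]])
    if (any(!is.finite(le))) return(NA_real_)
    unname(stats::coef(stats::lm(le ~ lh))[2])
  }, 0)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence study, case %s (%d levels, dt = %g s, T = %g s)\n",
              x$case, nrow(x$errors), x$dt, x$T_final))
  print(cbind(x$errors), digits = 4)
  cat("fitted rates (all levels):\n")
  print(round(x$rates, 3))
  cat("fitted rates (asymptotic tail):\n")
  print(round(x$rates_tail, 3))
  invisible(x)
}
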