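#' Twice continuously differentiable rectangular window
#'
#' Weight function used to confine the squeezing traction to a band: zero
#' outside [0, 1], exactly one on [0.2, 0.8], with C2 (quintic smoothstep)
#' transitions on [0, 0.2] and [0.8, 1].
#'
#' @param s Dimensionless coordinate(s).
#' @return Weight(s) in [0, 1].
#' @export
smooth_rect <- function(s) {
  ramp <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    x^3 * (10 - 15 * x + 6 * x^2)
  }
  ramp(s / 0.2) * ramp((1 - s) / 0.2)
}

#' Configuration of the locally squeezed porous cylinder benchmark
#'
#' A fluid-saturated cylinder (radius `R`, height `L`) is squeezed by a
#' time-harmonic radial traction confined to the band `Z0 < Z < Z1` of the
#' lateral surface. The load drives complete local fluid expulsion, which
#' is what the vanishing-porosity reformulation is built to survive; the
#' `"traditional"` formulation selector reproduces the unscaled fluid
#' momentum equation and its failure as the porosity collapses.
#'
#' @param R,L Cylinder radius and height (m).
#' @param Z0,Z1 Axial extent of the squeezing band (m).
#' @param p_o Traction amplitude (Pa).
#' @param t_o Load period (s).
#' @param h_e Mesh size (m).
#' @param dt Time step (s).
#' @param T_final Final time (s).
#' @param params Material parameters (verification constants by default).
#' @param phi_Rf Initial (referential) porosity, uniform.
#' @param formulation `"modified"` (rescaled, division-free) or
#'   `"traditional"`.
#' @param pressure_bc `"open"` (p = 0 on top and bottom, the benchmark
#'   boundary conditions) or `"sealed"` (all boundaries impermeable and the
#'   pressure pinned by a zero-mean constraint; used for the fluid-content
#'   conservation check).
#' @return A `squeeze_config` list.
#' @export
squeeze_config <- function(R = 0.5e-3, L = 10e-3, Z0 = 2e-3, Z1 = 3e-3,
                           p_o = 100, t_o = 0.4, h_e = 1e-4, dt = 1e-3,
                           T_final = 2,
                           params = material_params(1e3, 1e3, 1e-3, 1e-9,
                                                    0.1, 5e3),
                           phi_Rf = 0.5,
                           formulation = c("modified", "traditional"),
                           pressure_bc = c("open", "sealed")) {
  stopifnot(Z0 < Z1, Z1 < L, p_o >= 0, t_o > 0, h_e > 0, dt > 0)
  structure(list(R = R, L = L, Z0 = Z0, Z1 = Z1, p_o = p_o, t_o = t_o,
                 h_e = h_e, dt = dt, T_final = T_final, params = params,
                 phi_Rf = phi_Rf, formulation = match.arg(formulation),
                 pressure_bc = match.arg(pressure_bc)),
            class = "squeeze_config")
}

squeeze_context <- function(cfg) {
  mesh <- build_structured_mesh(0, cfg$R, 0, cfg$L, h_e = cfg$h_e)
  sealed <- cfg$pressure_bc == "sealed"
  ## even without pressure Dirichlet data the pressure level is pinned by
  ## the total-traction boundary terms (the pressure trace enters them),
  ## so no mean-pressure constraint is needed in the sealed variant
  layout <- build_spaces(mesh, with_mult = FALSE)
  trac_fun <- function(R, Z, t) {
    g <- -cfg$p_o * smooth_rect((Z - cfg$Z0) / (cfg$Z1 - cfg$Z0)) *
      (1 - cos(2 * pi * t / cfg$t_o))
    cbind(g, 0 * Z)
  }
  zero_trac <- function(R, Z, t) cbind(0 * R, 0 * R)
  bcs <- list(
    bottom = list(u = list(0, 0),
                  p = if (!sealed) 0 else NULL,
                  flux = if (sealed) TRUE else NULL),
    top = list(p = if (!sealed) 0 else NULL,
               traction = list(type = "total_ref", fun = zero_trac),
               flux = if (sealed) TRUE else NULL),
    right = list(traction = list(type = "total_ref", fun = trac_fun),
                 flux = TRUE),
    axis = list(u = list(0, NA))
  )
  u_scale <- max(cfg$p_o / cfg$params$mu_s * cfg$R, 1e-9)
  v_scale <- max(cfg$params$kappa_bar * cfg$p_o /
                   (cfg$params$mu_f * (cfg$Z1 - cfg$Z0)), 1e-9)
  ctx <- build_context(mesh, layout, cfg$params,
                       referential_porosity(cfg$phi_Rf), "transient",
                       bcs = bcs, formulation = cfg$formulation,
                       fd_scales = list(u = u_scale, v = v_scale,
                                        p = max(cfg$p_o, 1)))
  ctx
}

#' Run the squeezed-cylinder benchmark
#'
#' Advances the transient problem under the band-confined radial traction,
#' recording the porosity at the monitor point (0, (Z0+Z1)/2), its average
#' over the radial line through that point, and the minimum porosity seen
#' at quadrature points. With `formulation = "traditional"` the solver is
#' expected to fail once the porosity becomes very small; the failure is
#' returned, not raised.
#'
#' @param cfg A [squeeze_config()].
#' @param newton Newton configuration.
#' @param keep_every Keep full solution vectors every this many steps.
#' @param quiet Suppress progress output.
#' @return List with `probe` (data frame: t, phi_point, phi_line_avg,
#'   min_phi), `converged`, `failure` (if any), final `U`, `Vs`, kept
#'   `states`, and the assembly context `ctx` for post-processing.
#' @export
run_squeeze_benchmark <- function(cfg, newton = newton_config(rtol = 1e-7),
                                  keep_every = 0L, quiet = TRUE) {
  ctx <- squeeze_context(cfg)
  lay <- ctx$layout
  zmid <- 0.5 * (cfg$Z0 + cfg$Z1)
  line_pts <- cbind(seq(0, cfg$R, length.out = 21)[-21] + cfg$R / 42, zmid)
  point <- cbind(1e-9 * cfg$R, zmid)
  probe_rows <- list()
  mon <- function(step, t, U, Vs, info) {
    fp <- eval_state_fields(U, ctx, point)
    fl <- eval_state_fields(U, ctx, line_pts)
    row <- c(t = t, phi_point = fp$phi_f, phi_line_avg = mean(fl$phi_f),
             min_phi = info$min_phi, iters = info$iters)
    probe_rows[[length(probe_rows) + 1L]] <<- row
    if (!quiet && step %% 50 == 0)
      message(sprintf("  t = %.3f s: phi_point = %.4f, min_phi = %.4f",
                      t, fp$phi_f, info$min_phi))
    NULL
  }
  nsteps <- round(cfg$T_final / cfg$dt)
  run <- advance_transient(ctx, numeric(lay$ndof), dt = cfg$dt,
                           nsteps = nsteps, order = 2L, newton = newton,
                           monitor = mon, keep_every = keep_every)
  probe <- if (length(probe_rows)) as.data.frame(do.call(rbind, probe_rows))
    else data.frame(t = numeric(0), phi_point = numeric(0),
                    phi_line_avg = numeric(0), min_phi = numeric(0),
                    iters = numeric(0))
  list(probe = probe, converged = run$converged, failure = run$failure,
       U = run$U, Vs = run$Vs, states = run$states,
       min_phi_run = if (run$converged) run$min_phi_run else
         min(c(Inf, probe$min_phi)),
       cfg = cfg, ctx = ctx)
}

#' Porosity probe series of a benchmark run
#'
#' @param run Result of [run_squeeze_benchmark()].
#' @return Data frame with columns `t`, `phi_point` (porosity at the
#'   monitor point on the axis at the band center) and `phi_line_avg`
#'   (average over the radial line through it).
#' @export
probe_porosity <- function(run) {
  run$probe[, c("t", "phi_point", "phi_line_avg")]
}

## Filtration-velocity field diagnostics at a converged state: returns
## per-quadrature-point magnitudes of v_flt and v_f - v_s together with the
## local porosity (used to verify that both vanish in depleted regions).
filtration_diagnostics <- function(U, Vs, ctx) {
  lay <- ctx$layout; geo <- ctx$geo
  loc <- gather_loc(U, ctx)
  vsl <- matrix(Vs[lay$iu], lay$nelem, 8L)
  out <- list()
  for (q in seq_len(geo$nq)) {
    N <- geo$L[q, ]; Nb <- geo$Nb[q]
    u <- loc$u
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
    phiRf <- ctx$phiRf[, q]
    phi <- pmin(pmax(1 - (1 - phiRf) / J, 0), 1)
    vfr <- N[1] * loc$v[, 1] + N[2] * loc$v[, 2] + N[3] * loc$v[, 3]
    vfz <- N[1] * loc$v[, 4] + N[2] * loc$v[, 5] + N[3] * loc$v[, 6]
    vsr <- N[1] * vsl[, 1] + N[2] * vsl[, 2] + N[3] * vsl[, 3] + Nb * vsl[, 7]
    vsz <- N[1] * vsl[, 4] + N[2] * vsl[, 5] + N[3] * vsl[, 6] + Nb * vsl[, 8]
    rel <- sqrt((vfr - vsr)^2 + (vfz - vsz)^2)
    out[[q]] <- cbind(phi = phi, vflt = phi * rel, vrel = rel, J = J)
  }
  as.data.frame(do.call(rbind, out))
}

## Current-configuration fluid volume int phi_f J dV and reference fluid
## content int phi_Rf dV (conservation check for sealed runs).
fluid_content <- function(U, ctx) {
  geo <- ctx$geo; lay <- ctx$layout
  loc <- gather_loc(U, ctx)
  cur <- 0; ref <- 0
  for (q in seq_len(geo$nq)) {
    N <- geo$L[q, ]; Nb <- geo$Nb[q]
    u <- loc$u
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
    phiRf <- ctx$phiRf[, q]
    phi <- 1 - (1 - phiRf) / J
    meas <- 2 * pi * geo$A * geo$w[q] * geo$Rq[, q]
    cur <- cur + sum(meas * phi * J)
    ref <- ref + sum(meas * phiRf)
  }
  c(current = cur, reference = ref)
}
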