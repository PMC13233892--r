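#' Configuration of the traveling-wave perivascular peristalsis problem
#'
#' Steady poroelastic flow in the annular perivascular space (PVS) around a
#' penetrating arteriole, driven by a peristaltic wall wave
#' r_i(z, t) = h + b sin(2 pi (z - c t) / lambda), formulated in the frame
#' moving with the wave so the problem is steady and lambda-periodic. The
#' wave speed satisfies c = lambda * f with the heart-rate frequency f held
#' fixed across wavelength sweeps.
#'
#' @param lambda Wavelength (m).
#' @param f Wave frequency (Hz); the wave speed is `c = lambda * f`.
#' @param h Mean inner (arterial wall) radius (m).
#' @param R_o Outer (glia limitans) radius (m).
#' @param b Wall wave amplitude (m), `b < R_o - h`.
#' @param Dp Prescribed axial pressure difference per wavelength (Pa);
#'   zero for pure peristaltic pumping.
#' @param direction +1 for a wave traveling toward positive z, -1 for the
#'   reversed wave (used by the reversal-antisymmetry checks).
#' @param params Material parameters (CSF/tissue values by default:
#'   mu_f = 9e-4 Pa.s, kappa_bar = 1.8e-14 m^2, phi_fc = 0.1,
#'   mu_s = 14 kPa, densities 1e3 kg/m^3).
#' @param phiR Referential porosity: a [referential_porosity()] object
#'   (uniform 0.2 by default, or the radial blend profile for the
#'   PVS-plus-parenchyma studies).
#' @param n_r Radial cell count.
#' @param n_z Axial cell count per wavelength.
#' @param grade_r Geometric grading factor for the radial grid (> 1
#'   concentrates cells at the inner wall; 1 = uniform).
#' @param continuation Amplitude continuation fractions ending at 1.
#' @return A `peristalsis_config` list.
#' @export
peristalsis_config <- function(lambda = 0.2, f = 5, h = 10e-6, R_o = 11e-6,
                               b = 0.25e-6, Dp = 0, direction = 1,
                               params = material_params(1e3, 1e3, 9e-4,
                                                        1.8e-14, 0.1, 14e3),
                               phiR = referential_porosity(0.2),
                               n_r = 50L, n_z = 96L, grade_r = 1,
                               continuation = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(lambda > 0, f > 0, h > 0, R_o > h, b >= 0, b < R_o - h,
            n_r >= 2L, n_z >= 8L, grade_r >= 1, direction %in% c(-1, 1))
  stopifnot(abs(tail(continuation, 1L) - 1) < 1e-12, all(diff(continuation) > 0))
  structure(list(lambda = lambda, f = f, c = direction * lambda * f,
                 direction = direction, h = h, R_o = R_o,
                 b = b, Dp = Dp, params = params, phiR = phiR,
                 n_r = as.integer(n_r), n_z = as.integer(n_z),
                 grade_r = grade_r, continuation = continuation),
            class = "peristalsis_config")
}

#' @export
print.peristalsis_config <- function(x, ...) {
  cat(sprintf(
    "Peristalsis: lambda = %g m, c = %g m/s, annulus [%g, %g] um, b = %g um\n",
    x$lambda, x$c, 1e6 * x$h, 1e6 * x$R_o, 1e6 * x$b))
  cat(sprintf("  mesh %d x %d%s, Dp = %g Pa\n", x$n_r, x$n_z,
              if (x$grade_r > 1) sprintf(" (graded %.2f)", x$grade_r) else "",
              x$Dp))
  invisible(x)
}

#' Inner wall profile in the moving frame
#'
#' @param zp Moving-frame axial coordinate(s) (m).
#' @param cfg A [peristalsis_config()].
#' @return Inner radius r_i'(z') = h + b sin(2 pi z' / lambda) (m).
#' @export
wall_profile <- function(zp, cfg) {
  cfg$h + cfg$b * sin(2 * pi * zp / cfg$lambda)
}

peristalsis_radial_grid <- function(cfg) {
  n <- cfg$n_r
  if (cfg$grade_r <= 1 + 1e-12) return(seq(cfg$h, cfg$R_o, length.out = n + 1L))
  w <- cfg$grade_r^(0:(n - 1L))
  cfg$h + (cfg$R_o - cfg$h) * c(0, cumsum(w)) / sum(w)
}

peristalsis_context <- function(cfg, amp = cfg$b) {
  mesh <- build_structured_mesh(cfg$h, cfg$R_o, 0, cfg$lambda,
                                nz = cfg$n_z, periodic_z = TRUE,
                                Rgrid = peristalsis_radial_grid(cfg))
  layout <- build_spaces(mesh, with_vs = TRUE, with_mult = TRUE)
  amp_env <- new.env(parent = emptyenv()); amp_env$amp <- amp
  ## the walls are impermeable; with the exact substitution
  ## v_s' = -c F e_z the wall flux v_s'.n vanishes identically, so no
  ## continuity boundary terms are needed on the lateral surfaces
  bcs <- list(
    left = list(u = list(function(R, Z, t)
      amp_env$amp * sin(2 * pi * Z / cfg$lambda), 0)),
    right = list(u = list(0, 0))
  )
  gap <- cfg$R_o - cfg$h
  p_scale <- max(cfg$params$mu_f * cfg$c * cfg$lambda * max(cfg$b, 0.01 * gap) /
                   (cfg$params$kappa_bar * gap * 2 * pi), 1)
  ctx <- build_context(mesh, layout, cfg$params, cfg$phiR, "moving",
                       bcs = bcs,
                       fd_scales = list(u = max(cfg$b, 1e-3 * gap),
                                        v = max(cfg$c, 1e-6),
                                        p = p_scale),
                       wave_c = cfg$c,
                       dp_over_lambda = cfg$Dp / cfg$lambda,
                       mult_target = 0)
  ctx$amp_env <- amp_env
  ctx
}

## exact solution of the zero-amplitude problem: rigid axial drift -c e_z
peristalsis_base_state <- function(ctx) {
  lay <- ctx$layout
  U <- numeric(lay$ndof)
  U[dof_v_node(lay, seq_len(lay$nnode), 2L)] <- -ctx$wave_c
  U[dof_vs_node(lay, seq_len(lay$nnode), 2L)] <- -ctx$wave_c
  U
}

#' Solve one peristalsis case
#'
#' Newton solve of the steady moving-frame system with amplitude
#' continuation from the analytic zero-amplitude state (rigid drift at the
#' wave speed). Summary statistics follow the study conventions: peak
#' pressure is max |p'| over the domain in mmHg; the average axial pressure
#' gradient is the peak-to-peak pressure along the inner wall divided by
#' the wavelength, in mmHg/m; the volume flow rate is the
#' wavelength-averaged axial filtration flux.
#'
#' @param cfg A [peristalsis_config()].
#' @param newton Newton configuration (constant damping factor 1 with
#'   Jacobian reuse by default, refreshed on slow contraction).
#' @param quiet Suppress continuation progress.
#' @return List of class `peristalsis_result` with `summary` (Q_bar in
#'   m^3/s and um^3/s, peak pressure in mmHg, average gradient in mmHg/m,
#'   min phi_f), the converged coefficient vector `U`, and `ctx`.
#' @export
run_peristalsis_case <- function(cfg, newton = newton_config(rtol = 1e-8,
                                                             maxit = 40),
                                 quiet = TRUE) {
  ctx <- peristalsis_context(cfg, amp = 0)
  U <- peristalsis_base_state(ctx)
  lay <- ctx$layout
  ## smooth predictor for an amplitude increment: the wall displacement is
  ## extended into the annulus with a linear radial ramp, which keeps the
  ## first iterate free of inverted cells at fine radial resolution
  nd <- ctx$mesh$nodes
  ramp <- (cfg$R_o - nd[, 1L]) / (cfg$R_o - cfg$h)
  predict_u <- ramp * sin(2 * pi * nd[, 2L] / cfg$lambda)
  iur <- dof_u_node(lay, seq_len(lay$nnode), 1L)
  targets <- cfg$continuation * cfg$b
  a0 <- 0
  sol <- NULL
  limited <- FALSE
  for (tg in targets) {
    repeat {
      da <- tg - a0
      ok <- FALSE
      while (!ok) {
        amp <- a0 + da
        ctx$amp_env$amp <- amp
        update_step_data(ctx, 0)
        Utry <- U
        Utry[iur] <- Utry[iur] + da * predict_u
        soln <- solve_newton(Utry, ctx, newton)
        if (soln$converged) {
          ok <- TRUE
          U <- soln$U; a0 <- amp; sol <- soln
          if (!quiet)
            message(sprintf("  amplitude %5.1f%%: %d iterations, min phi %.4f",
                            100 * amp / cfg$b, soln$iters, soln$min_phi))
        } else {
          da <- da / 2
          if (da < (tg - a0) / 64 || da <= 0) {
            ## the solution branch has terminated (the porosity floor has
            ## reached zero and the steady traveling-wave state ceases to
            ## exist at larger amplitude in this discretization): return
            ## the largest-amplitude converged state, flagged
            limited <- TRUE
            break
          }
        }
      }
      if (limited || a0 >= tg - 1e-15 * cfg$b) break
    }
    if (limited) break
  }
  if (is.null(sol))
    stop("peristalsis continuation failed before any amplitude converged")
  if (limited && !quiet)
    message(sprintf(
      "  amplitude continuation terminated at %.1f%% of the target", 
      100 * a0 / cfg$b))
  ## restore the context to the achieved amplitude for post-processing
  ctx$amp_env$amp <- a0
  update_step_data(ctx, 0)
  summ <- peristalsis_summary(U, ctx, cfg, sol$min_phi)
  summ$amp_achieved <- a0 / cfg$b
  summ$depletion_limited <- limited
  structure(list(U = U, cfg = cfg, ctx = ctx,
                 min_phi = sol$min_phi,
                 amp_achieved = a0 / cfg$b,
                 depletion_limited = limited,
                 summary = summ),
            class = "peristalsis_result")
}

#' @export
print.peristalsis_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Peristalsis result (lambda = %g m, R_o = %g um):\n",
              x$cfg$lambda, 1e6 * x$cfg$R_o))
  cat(sprintf("  Q_bar = %.4g um^3/s, peak |p| = %.4g mmHg\n",
              s$Q_um3_s, s$peak_p_mmHg))
  cat(sprintf("  avg dp/dz = %.4g mmHg/m, min phi_f = %.4g\n",
              s$grad_mmHg_m, s$min_phi))
  if (isTRUE(x$depletion_limited))
    cat(sprintf("  (amplitude continuation depletion-limited at %.1f%%)\n",
                100 * x$amp_achieved))
  invisible(x)
}

MMHG_PA <- 133.322

#' Volume flow rate of a moving-frame solution
#'
#' Q_bar = (1/lambda) * int v_flt_z J dOmega over the computational
#' annulus, with the filtration velocity phi_f (v_f - v_s) (frame
#' invariant).
#'
#' @param U Converged coefficient vector.
#' @param ctx Assembly context of the solve.
#' @param cfg The configuration.
#' @return Flow rate in m^3/s.
#' @export
volume_flow_rate <- function(U, ctx, cfg) {
  geo <- ctx$geo; lay <- ctx$layout
  loc <- gather_loc(U, ctx)
  Q <- 0
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
    phi <- pmin(pmax(1 - (1 - ctx$phiRf[, q]) / J, 0), 1)
    vfz <- N[1] * loc$v[, 4] + N[2] * loc$v[, 5] + N[3] * loc$v[, 6]
    vsz <- -ctx$wave_c * (1 + duzZ)
    meas <- 2 * pi * geo$A * geo$w[q] * geo$Rq[, q]
    Q <- Q + sum(meas * phi * (vfz - vsz) * J)
  }
  Q / ctx$mesh$Zlen
}

peristalsis_summary <- function(U, ctx, cfg, min_phi = NA_real_) {
  lay <- ctx$layout; mesh <- ctx$mesh
  Q <- volume_flow_rate(U, ctx, cfg)
  ptot <- U[dof_p_node(lay, seq_len(lay$nnode))] +
    (cfg$Dp / cfg$lambda) * mesh$nodes[, 2L]
  peak <- max(abs(ptot))
  inner <- which(abs(mesh$nodes[, 1L] - cfg$h) < 1e-12 * cfg$R_o)
  grad <- (max(ptot[inner]) - min(ptot[inner])) / cfg$lambda
  list(Q_m3_s = Q, Q_um3_s = Q * 1e18,
       peak_p_Pa = peak, peak_p_mmHg = peak / MMHG_PA,
       grad_Pa_m = grad, grad_mmHg_m = grad / MMHG_PA,
       min_phi = min_phi)
}

#' Sweep a geometry parameter of the peristalsis study
#'
#' For `axis = "domain-length"` the wavelength is swept with the frequency
#' f held fixed (so c = lambda f changes accordingly); for
#' `axis = "outer-radius"` the outer radius is swept with everything else
#' fixed. Each row is solved by [run_peristalsis_case()]; failures are
#' recorded and the sweep continues.
#'
#' @param axis `"domain-length"` or `"outer-radius"`.
#' @param values Sorted parameter values (m).
#' @param cfg Base configuration.
#' @param newton Newton configuration.
#' @param quiet Suppress progress.
#' @return Data frame with one row per value: parameter, Q_bar (um^3/s),
#'   peak pressure (mmHg), average gradient (mmHg/m), min phi_f, ok flag.
#' @export
run_parameter_sweep <- function(axis = c("domain-length", "outer-radius"),
                                values, cfg = peristalsis_config(),
                                newton = newton_config(rtol = 1e-8,
                                                       maxit = 40),
                                quiet = TRUE) {
  axis <- match.arg(axis)
  stopifnot(all(diff(values) > 0))
  rows <- list()
  for (v in values) {
    ci <- cfg
    if (axis == "domain-length") { ci$lambda <- v; ci$c <- ci$direction * v * ci$f }
    else ci$R_o <- v
    class(ci) <- class(cfg)
    res <- tryCatch(run_peristalsis_case(ci, newton, quiet = quiet),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        value_m = v, Q_um3_s = NA, peak_p_mmHg = NA, grad_mmHg_m = NA,
        min_phi = NA, ok = FALSE)
    } else {
      s <- res$summary
      rows[[length(rows) + 1L]] <- data.frame(
        value_m = v, Q_um3_s = s$Q_um3_s, peak_p_mmHg = s$peak_p_mmHg,
        grad_mmHg_m = s$grad_mmHg_m, min_phi = s$min_phi, ok = TRUE)
    }
    if (!quiet) message(sprintf("sweep %s = %g done", axis, v))
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- if (axis == "domain-length") "lambda_m" else "Ro_m"
  out
}
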