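#' Backward-differentiation time-derivative stencil
#'
#' Discrete time derivative of a history of coefficient vectors at constant
#' step size. `history` is ordered newest first: `history[[1]]` is the
#' current vector x^n, `history[[2]]` is x^(n-1), and so on.
#'
#' @param history List of numeric vectors, newest first (length >= order + 1).
#' @param dt Constant time step (s).
#' @param order 1 (backward Euler) or 2.
#' @return The derivative vector: BDF1 `(x^n - x^(n-1))/dt`; BDF2
#'   `(3 x^n - 4 x^(n-1) + x^(n-2))/(2 dt)`.
#' @export
bdf_derivative <- function(history, dt, order = 2L) {
  stopifnot(dt > 0, order %in% c(1L, 2L))
  if (length(history) < order + 1L)
    stop("insufficient history for BDF order ", order)
  if (order == 1L) (history[[1]] - history[[2]]) / dt
  else (3 * history[[1]] - 4 * history[[2]] + history[[3]]) / (2 * dt)
}

## Leading coefficient and history combination of the BDF stencil:
## dx/dt ~ c0 * x^n + hist_combo.
bdf_coeffs <- function(prev, prev2, dt, order) {
  if (order == 1L) list(c0 = 1 / dt, h = -prev / dt)
  else list(c0 = 1.5 / dt, h = (-4 * prev + prev2) / (2 * dt))
}

#' Advance the coupled transient problem
#'
#' Steps the monolithic system with constant time step: solid velocity and
#' acceleration and the referential fluid-velocity rate are discretized by
#' BDF (second order by default, with a first-order startup step), and each
#' step is solved by damped Newton. The fluid acceleration is evaluated in
#' ALE form: referential rate plus convection by `v_f - v_s`.
#'
#' @param ctx Assembly context (mode `"transient"`).
#' @param U0 Initial coefficient vector (u_s, v_f, p blocks).
#' @param Vs0 Initial solid velocity in the u-block layout (full-length
#'   vector; only the displacement slots are read).
#' @param dt Time step (s).
#' @param nsteps Number of steps.
#' @param t0 Initial time.
#' @param order BDF order (1 or 2; 2 uses a BDF1 first step).
#' @param newton A [newton_config()].
#' @param monitor Optional `function(step, t, U, Vs, info)` called after
#'   every accepted step; its returned values are collected in `$probe`.
#' @param keep_every Keep full solution vectors every this many steps
#'   (0 keeps only the final state).
#' @return List with `U` (final), `Vs`, `times`, `states` (kept vectors),
#'   `probe`, `converged`, and `failure` info if the run stopped early.
#' @export
advance_transient <- function(ctx, U0, Vs0 = NULL, dt, nsteps,
                              t0 = 0, order = 2L,
                              newton = newton_config(),
                              monitor = NULL, keep_every = 0L) {
  lay <- ctx$layout
  U <- U0
  Vs <- if (is.null(Vs0)) numeric(lay$ndof) else Vs0
  Uprev <- U; Uprev2 <- NULL
  Vsprev <- Vs; Vsprev2 <- NULL
  times <- numeric(0)
  states <- list(); probe <- list()
  min_phi_run <- Inf
  for (n in seq_len(nsteps)) {
    t <- t0 + n * dt
    ord <- if (n == 1L || order == 1L) 1L else 2L
    cu <- bdf_coeffs(Uprev, Uprev2, dt, ord)
    cv <- bdf_coeffs(Vsprev, Vsprev2, dt, ord)
    update_step_data(ctx, t, hist = list(c0 = cu$c0, uh = cu$h,
                                         vh = cv$h, vfh = cu$h))
    ## predictor: linear extrapolation once history exists
    Ug <- if (!is.null(Uprev2)) 2 * Uprev - Uprev2 else Uprev
    sol <- solve_newton(Ug, ctx, newton)
    if (sol$converged) {
      U <- sol$U
      Vs <- cu$c0 * U + cu$h
    } else {
      ## robustness fallback: redo the failed step as first-order substeps
      ## (sharp porosity fronts entering or leaving quadrature points can
      ## defeat a full-size step), then resume the nominal grid with a
      ## first-order restart
      done <- FALSE
      for (nsub in c(2L, 4L, 8L)) {
        dts <- dt / nsub
        Us <- Uprev; Vss <- Vsprev
        ok <- TRUE
        for (k in seq_len(nsub)) {
          tk <- t - dt + k * dts
          cs <- bdf_coeffs(Us, NULL, dts, 1L)
          cvs <- bdf_coeffs(Vss, NULL, dts, 1L)
          update_step_data(ctx, tk, hist = list(c0 = cs$c0, uh = cs$h,
                                                vh = cvs$h, vfh = cs$h))
          ctx$force_jac <- TRUE
          ss <- solve_newton(Us, ctx, newton)
          if (!ss$converged) { ok <- FALSE; break }
          Vss <- cs$c0 * ss$U + cs$h
          Us <- ss$U
        }
        if (ok) {
          U <- Us; Vs <- Vss; sol <- ss
          Uprev2 <- NULL; Vsprev2 <- NULL    # BDF1 restart next step
          done <- TRUE
          break
        }
      }
      if (!done)
        return(list(U = U, Vs = Vs, times = times, states = states,
                    probe = probe, converged = FALSE,
                    failure = list(step = n, t = t,
                                   reason = sol$reason %||% "no convergence",
                                   res_history = sol$res_history,
                                   min_phi = sol$min_phi)))
    }
    if (is.finite(sol$min_phi)) min_phi_run <- min(min_phi_run, sol$min_phi)
    Uprev2 <- Uprev; Uprev <- U
    Vsprev2 <- Vsprev; Vsprev <- Vs
    times <- c(times, t)
    if (keep_every > 0L && (n %% keep_every == 0L || n == nsteps))
      states[[length(states) + 1L]] <- list(step = n, t = t, U = U, Vs = Vs)
    if (!is.null(monitor))
      probe[[length(probe) + 1L]] <-
        monitor(n, t, U, Vs, list(iters = sol$iters, min_phi = sol$min_phi))
  }
  list(U = U, Vs = Vs, times = times, states = states, probe = probe,
       converged = TRUE, min_phi_run = min_phi_run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
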