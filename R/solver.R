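## Problem context construction and the monolithic Newton solver.

#' Newton solver configuration
#'
#' @param rtol Relative residual tolerance (per residual block, against the
#'   largest starting residual seen so far in the run).
#' @param maxit Maximum Newton iterations per solve.
#' @param damping `"auto"` for backtracking line search, `"fixed"` for a
#'   constant damping factor.
#' @param damp_factor Constant factor used when `damping = "fixed"`.
#' @param jac_reuse Reuse the factorized Jacobian across iterations (and
#'   time steps) while the residual contracts fast enough.
#' @param alpha_min Smallest backtracking line-search factor before the
#'   step is declared stalled.
#' @param verbose Print per-iteration diagnostics.
#' @return A `newton_config` list.
#' @export
newton_config <- function(rtol = 1e-8, maxit = 30L,
                          damping = c("auto", "fixed"), damp_factor = 1,
                          jac_reuse = TRUE, alpha_min = 1 / 64,
                          verbose = FALSE) {
  damping <- match.arg(damping)
  stopifnot(rtol > 0, maxit >= 1, alpha_min > 0, alpha_min <= 1)
  list(rtol = rtol, maxit = as.integer(maxit), damping = damping,
       damp_factor = damp_factor, jac_reuse = jac_reuse,
       alpha_min = alpha_min, verbose = verbose)
}

## Boundary-condition specification is a named list over boundary tags.
## Each tag entry may contain:
##   u        : length-2 list/vector (r, z); each entry a constant, a
##              function(R, Z, t), or NA for an unconstrained component
##   p        : constant or function(R, Z, t) -> Dirichlet pressure
##   traction : list(type = "elastic_ref" | "total_ref",
##                   fun = function(R, Z, t) -> cbind(r, z) referential
##                   traction density per unit reference area)
##   flux     : TRUE (impermeable, v_flt.n = 0) or function(R, Z, t) ->
##              prescribed outward normal filtration flux per unit current
##              area. Presence of `flux` adds the continuity boundary term.
## The `axis` tag needs no entries beyond u_r = 0; its edge integrals carry
## zero measure.
build_context <- function(mesh, layout, params, phiR,
                          mode = c("transient", "moving"),
                          bcs = list(), sources = NULL,
                          formulation = c("modified", "traditional"),
                          quad = tri_quadrature(5L),
                          fd_scales = list(u = 1e-4, v = 1e-3, p = 1),
                          wave_c = 0, dp_over_lambda = 0,
                          mult_target = 0) {
  mode <- match.arg(mode)
  formulation <- match.arg(formulation)
  ctx <- new.env(parent = emptyenv())
  ctx$mesh <- mesh; ctx$layout <- layout; ctx$params <- params
  ctx$mode <- mode; ctx$formulation <- formulation
  ctx$geo <- precompute_geometry(mesh, quad)
  ctx$wave_c <- wave_c; ctx$dp_over_lambda <- dp_over_lambda
  ctx$sources <- sources; ctx$src <- NULL
  ctx$bcs <- bcs
  ctx$c0 <- 0
  ctx$t <- 0
  ctx$phi_smooth <- 1e-4
  ctx$pen_k <- 0
  ctx$mult_target <- mult_target
  fd_rel <- 6e-6
  ctx$fd_h <- list(u = fd_rel * fd_scales$u, v = fd_rel * fd_scales$v,
                   p = fd_rel * fd_scales$p, vs = fd_rel * fd_scales$v)
  ctx$jac_ii <- NULL; ctx$jac_jj <- NULL
  ctx$fac <- NULL
  ctx$force_jac <- FALSE
  ctx$newton_scale0 <- NULL
  ctx$min_phi_last <- NA_real_
  ctx$min_phi_raw <- NA_real_

  ## porosity at quadrature points
  ctx$phiR_obj <- phiR
  ctx$phiRf <- matrix(eval_porosity(phiR, as.vector(ctx$geo$Rq)),
                      layout$nelem, ctx$geo$nq)

  ## mean-pressure weights (computational measure)
  if (layout$with_mult) {
    W <- numeric(layout$nnode)
    for (q in seq_len(ctx$geo$nq)) {
      for (a in 1:3) {
        contrib <- 2 * pi * ctx$geo$A * ctx$geo$w[q] * ctx$geo$L[q, a] *
          ctx$geo$Rq[, q]
        agg <- rowsum(contrib, mesh$tri[, a])
        iw <- as.integer(rownames(agg))
        W[iw] <- W[iw] + agg[, 1]
      }
    }
    ctx$Wp <- W
  }

  ctx$egroups <- build_edge_groups(mesh, layout, ctx$geo, bcs)
  dir <- build_dirichlet(mesh, layout, bcs)
  ctx$dir_idx <- dir$idx
  ctx$dir_fun <- dir$fun
  ctx$dir_val <- if (length(dir$idx)) dir$fun(0) else numeric(0)
  ctx$dir_scale <- 1
  ## zero-length histories by default (steady problems)
  nu <- layout$nelem
  ctx$uh <- matrix(0, nu, 8L); ctx$vh <- matrix(0, nu, 8L)
  ctx$vfh <- matrix(0, nu, 6L)
  ctx
}

build_edge_groups <- function(mesh, layout, geo, bcs) {
  qe <- edge_quadrature()
  groups <- list()
  normals <- list(left = c(-1, 0), right = c(1, 0),
                  bottom = c(0, -1), top = c(0, 1), axis = c(-1, 0))
  for (tag in unique(mesh$edges$tag)) {
    if (tag == "axis") next                    # zero measure; skip entirely
    spec <- bcs[[tag]]
    has_trac <- !is.null(spec$traction)
    has_flux <- !is.null(spec$flux)
    if (!has_trac && !has_flux) next
    ed <- mesh$edges[mesh$edges$tag == tag, ]
    loc1 <- unique(ed$loc1); loc2 <- unique(ed$loc2)
    stopifnot(length(loc1) == 1L, length(loc2) == 1L)
    nqe <- length(qe$s)
    Ledge <- matrix(0, nqe, 3L)
    Ledge[, loc1] <- 1 - qe$s
    Ledge[, loc2] <- qe$s
    el <- ed$elem
    Rc <- mesh$Rc[el, , drop = FALSE]; Zc <- mesh$Zc[el, , drop = FALSE]
    Rq <- Rc %*% t(Ledge); Zq <- Zc %*% t(Ledge)
    len <- sqrt((Rc[, loc2] - Rc[, loc1])^2 + (Zc[, loc2] - Zc[, loc1])^2)
    ne <- nrow(ed)
    dNbR <- matrix(0, ne, nqe); dNbZ <- matrix(0, ne, nqe)
    bb <- geo$b[el, , drop = FALSE]; cb <- geo$c[el, , drop = FALSE]
    for (q in seq_len(nqe)) {
      L <- Ledge[q, ]
      dNbR[, q] <- 27 * (L[2] * L[3] * bb[, 1] + L[1] * L[3] * bb[, 2] +
                         L[1] * L[2] * bb[, 3])
      dNbZ[, q] <- 27 * (L[2] * L[3] * cb[, 1] + L[1] * L[3] * cb[, 2] +
                         L[1] * L[2] * cb[, 3])
    }
    eg <- new.env(parent = emptyenv())
    eg$tag <- tag; eg$elem <- el; eg$n1 <- ed$n1; eg$n2 <- ed$n2
    eg$b <- bb; eg$c <- cb; eg$dNbR <- dNbR; eg$dNbZ <- dNbZ
    eg$sq <- qe$s; eg$wq <- qe$w; eg$len <- len
    eg$Rq <- Rq; eg$Zq <- Zq; eg$Ledge <- Ledge
    eg$p1 <- Ledge[, 1]; eg$p2 <- Ledge[, 2]; eg$p3 <- Ledge[, 3]
    eg$Nref <- normals[[tag]]
    eg$traction_fun <- if (has_trac) spec$traction$fun else NULL
    eg$traction_type <- if (has_trac) spec$traction$type else NULL
    eg$traction <- NULL
    eg$has_flux <- has_flux
    eg$flux_fun <- if (has_flux && is.function(spec$flux)) spec$flux else NULL
    eg$fluxdata <- NULL
    eg$uh <- matrix(0, ne, 8L)
    groups[[length(groups) + 1L]] <- eg
  }
  groups
}

build_dirichlet <- function(mesh, layout, bcs) {
  idx <- integer(0)
  parts <- list()       # list of (dofs, coords, fun/values)
  for (tag in names(bcs)) {
    spec <- bcs[[tag]]
    ed <- mesh$edges[mesh$edges$tag == tag, ]
    if (!nrow(ed)) next
    nodes <- sort(unique(c(ed$n1, ed$n2)))
    Rn <- mesh$nodes[nodes, 1L]; Zn <- mesh$nodes[nodes, 2L]
    if (!is.null(spec$u)) {
      for (comp in 1:2) {
        g <- spec$u[[comp]]
        if (is.null(g) || (!is.function(g) && length(g) == 1L && is.na(g))) next
        parts[[length(parts) + 1L]] <- list(
          dofs = dof_u_node(layout, nodes, comp), R = Rn, Z = Zn, g = g)
      }
    }
    if (!is.null(spec$p)) {
      parts[[length(parts) + 1L]] <- list(
        dofs = dof_p_node(layout, nodes), R = Rn, Z = Zn, g = spec$p)
    }
  }
  if (!length(parts)) return(list(idx = integer(0), fun = NULL))
  idx <- unlist(lapply(parts, `[[`, "dofs"), use.names = FALSE)
  fun <- function(t) {
    unlist(lapply(parts, function(pp) {
      v <- if (is.function(pp$g)) pp$g(pp$R, pp$Z, t) else pp$g
      rep_len(v, length(pp$dofs))
    }), use.names = FALSE)
  }
  ## de-duplicate (corner nodes may appear under two tags); keep first
  keep <- !duplicated(idx)
  list(idx = idx[keep],
       fun = function(t) fun(t)[keep])
}

## Refresh all time-dependent data (Dirichlet values, traction/flux data,
## manufactured sources) and the element-local BDF histories.
update_step_data <- function(ctx, t, hist = NULL) {
  ctx$t <- t
  lay <- ctx$layout
  if (length(ctx$dir_idx)) ctx$dir_val <- ctx$dir_fun(t)
  if (!is.null(ctx$mult_target_fun)) ctx$mult_target <- ctx$mult_target_fun(t)
  if (!is.null(ctx$sources)) {
    src <- vector("list", ctx$geo$nq)
    for (q in seq_len(ctx$geo$nq)) {
      R <- ctx$geo$Rq[, q]; Z <- ctx$geo$Zq[, q]
      bs <- ctx$sources$bs(R, Z, t)
      bf <- ctx$sources$bf(R, Z, t)
      qq <- ctx$sources$q(R, Z, t)
      src[[q]] <- list(bsr = bs[, 1], bsz = bs[, 2],
                       bfr = bf[, 1], bfz = bf[, 2], q = qq)
    }
    ctx$src <- src
  }
  for (eg in ctx$egroups) {
    if (!is.null(eg$traction_fun))
      eg$traction <- lapply(seq_along(eg$sq), function(q)
        eg$traction_fun(eg$Rq[, q], eg$Zq[, q], t))
    if (!is.null(eg$flux_fun))
      eg$fluxdata <- lapply(seq_along(eg$sq), function(q)
        eg$flux_fun(eg$Rq[, q], eg$Zq[, q], t))
  }
  if (!is.null(hist)) {
    ctx$c0 <- hist$c0
    ctx$uh <- matrix(hist$uh[lay$iu], lay$nelem, 8L)
    ctx$vh <- matrix(hist$vh[lay$iu], lay$nelem, 8L)
    ctx$vfh <- matrix(hist$vfh[lay$iv], lay$nelem, 6L)
    for (eg in ctx$egroups)
      eg$uh <- matrix(hist$uh[lay$iu[eg$elem, , drop = FALSE]],
                      length(eg$elem), 8L)
  }
  invisible(ctx)
}

block_norms <- function(res, lay) {
  nu <- lay$off_v
  c(u = sqrt(sum(res[seq_len(nu)]^2)),
    v = sqrt(sum(res[(lay$off_v + 1L):lay$off_p]^2)),
    p = sqrt(sum(res[(lay$off_p + 1L):(lay$off_p + lay$nnode)]^2)),
    rest = if (lay$ndof > lay$off_p + lay$nnode)
      sqrt(sum(res[(lay$off_p + lay$nnode + 1L):lay$ndof]^2)) else 0)
}

#' Monolithic Newton solve of the assembled nonlinear system
#'
#' Damped Newton iteration on the coupled residual, with sparse-direct
#' factorization of the finite-difference-assembled Jacobian, optional
#' Jacobian reuse across iterations, and backtracking line search.
#'
#' @param U0 Initial iterate (Dirichlet rows are overwritten with their
#'   data).
#' @param ctx Assembly context from the problem drivers.
#' @param cfg A [newton_config()].
#' @return List with the converged vector `U`, `converged`, `iters`,
#'   `res_history` (scaled block-norm maxima) and `min_phi` (smallest raw
#'   porosity seen at the converged state).
#' @export
solve_newton <- function(U0, ctx, cfg = newton_config()) {
  lay <- ctx$layout
  typ <- c(rep(ctx$fd_h$u, lay$off_v), rep(ctx$fd_h$v, lay$off_p - lay$off_v),
           rep(ctx$fd_h$p, lay$nnode),
           rep(ctx$fd_h$v, lay$ndof - lay$off_p - lay$nnode)) / 6e-6
  new_jac <- function(U) {
    sysj <- assemble_system(U, ctx, want_jac = TRUE)
    ## column scaling by typical dof magnitudes, row equilibration on top:
    ## keeps the mixed-units saddle point well conditioned for the sparse LU
    As <- sysj$jac %*% Matrix::Diagonal(x = typ)
    rs <- 1 / pmax(Matrix::rowSums(abs(As)), 1e-300)
    ctx$fac <- tryCatch(Matrix::lu(Matrix::Diagonal(x = rs) %*% As),
                        error = function(e) NULL)
    ctx$rowscale <- rs
    ctx$force_jac <- FALSE
    list(res = sysj$res)
  }
  U <- U0
  if (length(ctx$dir_idx)) U[ctx$dir_idx] <- ctx$dir_val
  fresh_jac <- FALSE
  if (is.null(ctx$fac) || isTRUE(ctx$force_jac)) {
    res <- new_jac(U)$res
    fresh_jac <- TRUE
  } else res <- assemble_system(U, ctx)$res
  nrm <- sqrt(sum((ctx$rowscale * res)^2))
  if (!is.finite(nrm))
    return(list(U = U, converged = FALSE, iters = 0L, res_history = nrm,
                min_phi = ctx$min_phi_last,
                reason = "non-finite residual at initial iterate"))
  nrm0 <- nrm
  hist <- nrm
  iter <- 0L
  converged <- nrm <= cfg$rtol * nrm0   # covers the quiescent nrm0 = 0 case
  while (!converged && iter < cfg$maxit) {
    iter <- iter + 1L
    d <- if (is.null(ctx$fac)) NULL else
      tryCatch(typ * -as.numeric(Matrix::solve(ctx$fac, ctx$rowscale * res)),
               error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) {
      if (!fresh_jac) { new_jac(U); fresh_jac <- TRUE; iter <- iter - 1L; next }
      return(list(U = U, converged = FALSE, iters = iter,
                  res_history = hist, min_phi = ctx$min_phi_last,
                  reason = "singular linear system"))
    }
    stepnorm <- max(abs(d) / typ)
    alpha <- if (cfg$damping == "fixed") cfg$damp_factor else 1
    repeat {
      Un <- U + alpha * d
      resn <- assemble_system(Un, ctx)$res
      nrmn <- sqrt(sum((ctx$rowscale * resn)^2))
      ok <- is.finite(nrmn) &&
        (cfg$damping == "fixed" || nrmn <= (1 - 1e-4 * alpha) * nrm ||
         stepnorm <= cfg$rtol)
      if (ok) break
      alpha <- alpha / 2
      if (alpha < cfg$alpha_min) break
    }
    if (!is.finite(nrmn) || (cfg$damping == "auto" && nrmn > nrm &&
                             stepnorm > cfg$rtol)) {
      if (fresh_jac)
        return(list(U = U, converged = FALSE, iters = iter,
                    res_history = hist, min_phi = ctx$min_phi_last,
                    reason = if (is.finite(nrmn)) "line search stalled"
                             else "non-finite residual"))
      ## stale Jacobian could not produce descent: refresh and retry
      new_jac(U); fresh_jac <- TRUE
      iter <- iter - 1L
      next
    }
    contraction <- nrmn / max(nrm, 1e-300)
    U <- Un; res <- resn; nrm <- nrmn
    hist <- c(hist, nrm)
    if (cfg$verbose)
      message(sprintf("  newton %2d: |res| %.3e step %.3e (alpha %.3g%s)",
                      iter, nrm, stepnorm, alpha,
                      if (fresh_jac) ", new J" else ""))
    converged <- nrm <= cfg$rtol * nrm0 ||
      (alpha == 1 && stepnorm <= cfg$rtol)
    if (!converged && (!cfg$jac_reuse || contraction > 0.2)) {
      res <- new_jac(U)$res
      fresh_jac <- TRUE
      nrm <- sqrt(sum((ctx$rowscale * res)^2))
    } else fresh_jac <- FALSE
  }
  list(U = U, converged = converged, iters = iter,
       res_history = hist, min_phi = ctx$min_phi_last)
}
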