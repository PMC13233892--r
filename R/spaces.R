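#' Mixed finite-element space layout
#'
#' Degree-of-freedom layout for the mixed discretization: MINI displacement
#' (piecewise-linear vector field enriched with one interior cubic bubble
#' per triangle), piecewise-linear vector fluid velocity, piecewise-linear
#' scalar pressure; optionally a piecewise-linear vector solid velocity (the
#' traveling-wave-frame solver carries it as a primary unknown) and one
#' scalar multiplier row enforcing a mean-pressure constraint.
#'
#' Global ordering: displacement nodal dofs (interleaved r, z per node),
#' displacement bubble dofs (r, z per element), fluid-velocity nodal dofs,
#' pressure nodal dofs, solid-velocity nodal dofs (if present), multiplier
#' (if present).
#'
#' @param mesh An [build_structured_mesh()] mesh.
#' @param with_vs Carry the solid velocity as a primary P1 unknown.
#' @param with_mult Append a scalar mean-pressure multiplier dof.
#' @return An object of class `fe_layout` with dof counts, block offsets
#'   and gather index matrices `iu` (M x 8), `iv` (M x 6), `ip` (M x 3)
#'   (and `ivs` when present) giving the global dof of each element-local
#'   dof. Local ordering within a block: r-components of the three
#'   vertices, then z-components, then (for `iu`) bubble r and z.
#' @export
build_spaces <- function(mesh, with_vs = FALSE, with_mult = FALSE) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$tri)
  off_ub <- 2L * N
  off_v <- off_ub + 2L * M
  off_p <- off_v + 2L * N
  off_vs <- if (with_vs) off_p + N else NA_integer_
  ndof <- off_p + N + (if (with_vs) 2L * N else 0L) + (if (with_mult) 1L else 0L)
  i_mult <- if (with_mult) ndof else NA_integer_

  t1 <- mesh$tri[, 1L]; t2 <- mesh$tri[, 2L]; t3 <- mesh$tri[, 3L]
  el <- seq_len(M)
  iu <- cbind(2L * t1 - 1L, 2L * t2 - 1L, 2L * t3 - 1L,
              2L * t1, 2L * t2, 2L * t3,
              off_ub + 2L * el - 1L, off_ub + 2L * el)
  iv <- cbind(off_v + 2L * t1 - 1L, off_v + 2L * t2 - 1L, off_v + 2L * t3 - 1L,
              off_v + 2L * t1, off_v + 2L * t2, off_v + 2L * t3)
  ip <- cbind(off_p + t1, off_p + t2, off_p + t3)
  ivs <- if (with_vs)
    cbind(off_vs + 2L * t1 - 1L, off_vs + 2L * t2 - 1L, off_vs + 2L * t3 - 1L,
          off_vs + 2L * t1, off_vs + 2L * t2, off_vs + 2L * t3) else NULL

  structure(list(nnode = N, nelem = M, ndof = ndof,
                 off_ub = off_ub, off_v = off_v, off_p = off_p,
                 off_vs = off_vs, i_mult = i_mult,
                 with_vs = with_vs, with_mult = with_mult,
                 iu = iu, iv = iv, ip = ip, ivs = ivs),
            class = "fe_layout")
}

#' @export
print.fe_layout <- function(x, ...) {
  cat(sprintf(paste0("MINI/P1/P1 layout: %d dofs (%d nodes, %d bubbles", "%s%s)\n"),
              x$ndof, x$nnode, x$nelem,
              if (x$with_vs) ", +vs" else "",
              if (x$with_mult) ", +multiplier" else ""))
  invisible(x)
}

## dof index helpers -------------------------------------------------------

dof_u_node <- function(layout, nodes, comp) 2L * (nodes - 1L) + comp
dof_v_node <- function(layout, nodes, comp) layout$off_v + 2L * (nodes - 1L) + comp
dof_p_node <- function(layout, nodes) layout$off_p + nodes
dof_vs_node <- function(layout, nodes, comp) layout$off_vs + 2L * (nodes - 1L) + comp
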