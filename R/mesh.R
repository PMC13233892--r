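#' Structured axisymmetric triangle mesh on a rectangle
#'
#' Builds a uniform structured mesh of the reference rectangle
#' `[R0, R1] x [Z0, Z1]` in the (R, Z) half-plane, splitting each grid
#' rectangle into two consistently oriented triangles. Boundary facets are
#' tagged `left`, `right`, `bottom`, `top`; a `left` boundary at R = 0 is
#' tagged `axis` instead. With `periodic_z = TRUE` the top and bottom rows
#' of nodes are identified (the mesh becomes a tube in Z), which is how the
#' traveling-wave peristalsis problem imposes wavelength periodicity.
#'
#' @param R0,R1 Radial extent (m), `0 <= R0 < R1`.
#' @param Z0,Z1 Axial extent (m).
#' @param nr,nz Number of cells radially / axially. Alternatively give
#'   `h_e` and the counts are chosen as `round(extent / h_e)` (at least 1).
#' @param h_e Target cell size (m), used when `nr`/`nz` are missing.
#' @param periodic_z Identify Z = Z1 with Z = Z0.
#' @return An object of class `axisym_mesh` with fields `nodes` (N x 2),
#'   `tri` (M x 3 node indices), per-element coordinate matrices `Rc`, `Zc`
#'   (M x 3; for periodic meshes wrapped elements carry the unshifted
#'   coordinates), boundary `edges` (data frame: n1, n2, elem, tag) and
#'   `h_e`.
#' @export
build_structured_mesh <- function(R0, R1, Z0, Z1, nr = NULL, nz = NULL,
                                  h_e = NULL, periodic_z = FALSE,
                                  Rgrid = NULL) {
  stopifnot(R0 >= 0, R1 > R0, Z1 > Z0)
  if (!is.null(Rgrid)) {
    stopifnot(abs(Rgrid[1] - R0) < 1e-15 + 1e-12 * R1,
              all(diff(Rgrid) > 0))
    nr <- length(Rgrid) - 1L
  }
  if (is.null(nr)) nr <- max(1L, as.integer(round((R1 - R0) / h_e)))
  if (is.null(nz)) nz <- max(1L, as.integer(round((Z1 - Z0) / h_e)))
  if (periodic_z && nz < 3L) stop("periodic mesh needs nz >= 3")
  Rg <- if (!is.null(Rgrid)) Rgrid else seq(R0, R1, length.out = nr + 1L)
  nzn <- if (periodic_z) nz else nz + 1L     # axial node rows
  Zg <- Z0 + (Z1 - Z0) * (seq_len(nzn) - 1L) / nz
  nid <- function(i, j) (j - 1L) * (nr + 1L) + i   # i radial 1..nr+1
  nodes <- cbind(R = rep(Rg, times = nzn), Z = rep(Zg, each = nr + 1L))

  ii <- rep(seq_len(nr), times = nz)
  jj <- rep(seq_len(nz), each = nr)
  jp <- if (periodic_z) ifelse(jj + 1L > nz, 1L, jj + 1L) else jj + 1L
  n00 <- nid(ii, jj); n10 <- nid(ii + 1L, jj)
  n11 <- nid(ii + 1L, jp); n01 <- nid(ii, jp)
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  M <- nrow(tri)

  ## per-element coordinates; wrapped nodes get Z + (Z1 - Z0)
  Rc <- matrix(nodes[tri, 1L], M, 3L)
  Zc <- matrix(nodes[tri, 2L], M, 3L)
  if (periodic_z) {
    wrapped <- rep(jj + 1L > nz, times = 2L)     # both triangles of the cell
    for (k in 2L:3L) {
      fix <- wrapped & (Zc[, k] < Zc[, 1L])
      Zc[fix, k] <- Zc[fix, k] + (Z1 - Z0)
    }
  }

  ## boundary edges (radial boundaries always; axial only if not periodic)
  edges <- list()
  jseq <- seq_len(nz)
  jpseq <- if (periodic_z) ifelse(jseq + 1L > nz, 1L, jseq + 1L) else jseq + 1L
  ## left boundary: nodes (1, j)-(1, j+1), element = second triangle of cell (1, j)
  e_left <- (jseq - 1L) * nr + 1L + M / 2L
  edges$left <- data.frame(n1 = nid(1L, jseq), n2 = nid(1L, jpseq),
                           elem = e_left,
                           tag = if (R0 == 0) "axis" else "left")
  ## right boundary: nodes (nr+1, j)-(nr+1, j+1), element = first triangle of cell (nr, j)
  e_right <- (jseq - 1L) * nr + nr
  edges$right <- data.frame(n1 = nid(nr + 1L, jseq), n2 = nid(nr + 1L, jpseq),
                            elem = e_right, tag = "right")
  if (!periodic_z) {
    iseq <- seq_len(nr)
    edges$bottom <- data.frame(n1 = nid(iseq, 1L), n2 = nid(iseq + 1L, 1L),
                               elem = iseq, tag = "bottom")
    edges$top <- data.frame(n1 = nid(iseq, nz + 1L), n2 = nid(iseq + 1L, nz + 1L),
                            elem = (nz - 1L) * nr + iseq + M / 2L, tag = "top")
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  ## local (within-element) node positions of each edge endpoint
  loc1 <- integer(nrow(edges)); loc2 <- integer(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    tv <- tri[edges$elem[k], ]
    loc1[k] <- match(edges$n1[k], tv)
    loc2[k] <- match(edges$n2[k], tv)
  }
  if (anyNA(loc1) || anyNA(loc2)) stop("internal error: edge-element mismatch")
  edges$loc1 <- loc1; edges$loc2 <- loc2

  structure(list(nodes = nodes, tri = tri, Rc = Rc, Zc = Zc,
                 edges = edges, nr = nr, nz = nz, Rgrid = Rg,
                 periodic_z = periodic_z, Zlen = Z1 - Z0,
                 h_e = max((R1 - R0) / nr, (Z1 - Z0) / nz)),
            class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d nodes, %d triangles (%d x %d cells)%s\n",
              nrow(x$nodes), nrow(x$tri), x$nr, x$nz,
              if (x$periodic_z) ", Z-periodic" else ""))
  invisible(x)
}

#' Uniform refinement by cell-count doubling
#'
#' @param mesh An `axisym_mesh` built by [build_structured_mesh()].
#' @return A structured mesh with twice the cell count in each direction.
#' @export
refine_mesh <- function(mesh) {
  R0 <- min(mesh$nodes[, 1L]); R1 <- max(mesh$nodes[, 1L])
  Z0 <- min(mesh$nodes[, 2L])
  Z1 <- if (mesh$periodic_z) Z0 + mesh$Zlen else max(mesh$nodes[, 2L])
  Rg <- mesh$Rgrid
  Rg2 <- sort(c(Rg, 0.5 * (Rg[-1L] + Rg[-length(Rg)])))
  build_structured_mesh(R0, R1, Z0, Z1, nz = 2L * mesh$nz,
                        periodic_z = mesh$periodic_z, Rgrid = Rg2)
}
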