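## Point evaluation of discrete fields on a structured mesh.

## Locate reference points in a structured axisymmetric mesh and return
## element indices plus barycentric coordinates. Points must lie inside the
## mesh rectangle (points on the boundary are nudged inside).
locate_points <- function(mesh, pts) {
  R0 <- min(mesh$nodes[, 1]); R1 <- max(mesh$nodes[, 1])
  Z0 <- min(mesh$nodes[, 2])
  Z1 <- if (mesh$periodic_z) Z0 + mesh$Zlen else max(mesh$nodes[, 2])
  nr <- mesh$nr; nz <- mesh$nz
  dr <- (R1 - R0) / nr; dz <- (Z1 - Z0) / nz
  eps <- 1e-12
  R <- pmin(pmax(pts[, 1], R0 + eps * dr), R1 - eps * dr)
  Z <- pts[, 2]
  if (mesh$periodic_z) Z <- Z0 + (Z - Z0) %% (Z1 - Z0)
  Z <- pmin(pmax(Z, Z0 + eps * dz), Z1 - eps * dz)
  Rg <- mesh$Rgrid
  i <- pmin(pmax(findInterval(R, Rg, rightmost.closed = TRUE) - 1L, 0), nr - 1)
  j <- pmin(pmax(floor((Z - Z0) / dz), 0), nz - 1)
  xi <- (R - Rg[i + 1L]) / (Rg[i + 2L] - Rg[i + 1L])
  et <- (Z - Z0) / dz - j
  cell <- j * nr + i + 1
  M2 <- nrow(mesh$tri) / 2
  ## first triangle (n00,n10,n11) covers xi >= eta
  lower <- xi >= et
  elem <- ifelse(lower, cell, cell + M2)
  ## barycentric coords w.r.t. local vertices
  L <- matrix(0, length(R), 3)
  L[lower, ] <- cbind(1 - xi[lower], xi[lower] - et[lower], et[lower])
  L[!lower, ] <- cbind(1 - et[!lower], xi[!lower], et[!lower] - xi[!lower])
  list(elem = as.integer(elem), L = L)
}

## Evaluate displacement-derived quantities (u, F, J, phi_f) and nodal
## fields (v_f, p) of a coefficient vector at reference points.
eval_state_fields <- function(U, ctx, pts) {
  mesh <- ctx$mesh; lay <- ctx$layout
  lc <- locate_points(mesh, pts)
  el <- lc$elem; L <- lc$L
  u <- matrix(U[lay$iu[el, , drop = FALSE]], length(el), 8L)
  v <- matrix(U[lay$iv[el, , drop = FALSE]], length(el), 6L)
  p <- matrix(U[lay$ip[el, , drop = FALSE]], length(el), 3L)
  geo <- ctx$geo
  b <- geo$b[el, , drop = FALSE]; cc <- geo$c[el, , drop = FALSE]
  Nb <- 27 * L[, 1] * L[, 2] * L[, 3]
  dNbR <- 27 * (L[, 2] * L[, 3] * b[, 1] + L[, 1] * L[, 3] * b[, 2] +
                L[, 1] * L[, 2] * b[, 3])
  dNbZ <- 27 * (L[, 2] * L[, 3] * cc[, 1] + L[, 1] * L[, 3] * cc[, 2] +
                L[, 1] * L[, 2] * cc[, 3])
  ur <- rowSums(L * u[, 1:3]) + Nb * u[, 7]
  uz <- rowSums(L * u[, 4:6]) + Nb * u[, 8]
  durR <- rowSums(b * u[, 1:3]) + dNbR * u[, 7]
  durZ <- rowSums(cc * u[, 1:3]) + dNbZ * u[, 7]
  duzR <- rowSums(b * u[, 4:6]) + dNbR * u[, 8]
  duzZ <- rowSums(cc * u[, 4:6]) + dNbZ * u[, 8]
  R <- pts[, 1]
  hoop <- ifelse(R > 1e-12 * max(mesh$nodes[, 1]), 1 + ur / R, 1 + durR)
  J <- ((1 + durR) * (1 + duzZ) - durZ * duzR) * hoop
  phiRf <- eval_porosity(ctx$phiR_obj, R)
  phi_raw <- 1 - (1 - phiRf) / J
  list(u = cbind(ur, uz), J = J,
       phi_f = pmin(pmax(phi_raw, 0), 1), phi_raw = phi_raw,
       v_f = cbind(rowSums(L * v[, 1:3]), rowSums(L * v[, 4:6])),
       p = rowSums(L * p),
       F = cbind(Frr = 1 + durR, Frz = durZ, Fzr = duzR, Fzz = 1 + duzZ,
                 Ftt = hoop))
}
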