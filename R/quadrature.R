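#' Quadrature rules used by the assembler
#'
#' Triangle rules are given in barycentric coordinates with weights summing
#' to one (so the integral over a triangle of area A is A * sum(w * f)).
#' The degree-5 seven-point rule is the assembler default: the integrands
#' mix the cubic displacement bubble with stress and mobility coefficients,
#' and degree 5 keeps the quadrature-consistency error well below the
#' discretization error on all the meshes used here.
#'
#' @param degree Polynomial degree to integrate exactly (2 or 5).
#' @return List with matrix `L` (nq x 3 barycentric coordinates) and
#'   weights `w` (summing to 1).
#' @export
tri_quadrature <- function(degree = 5L) {
  if (degree <= 2L) {
    L <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 4, 3L, 3L, byrow = TRUE) * 2 / 3
    ## midpoint rule (degree 2): points (1/2,1/2,0) cyclic
    L <- matrix(c(0.5, 0.5, 0, 0, 0.5, 0.5, 0.5, 0, 0.5), 3L, 3L, byrow = TRUE)
    return(list(L = L, w = rep(1 / 3, 3L)))
  }
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  L <- rbind(c(1 / 3, 1 / 3, 1 / 3),
             c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
             c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225,
         rep(0.1323941527885062, 3L),
         rep(0.1259391805448271, 3L))
  list(L = L, w = w)
}

#' Gauss rule on the unit interval (for boundary edges)
#'
#' @param n Number of points (3, exact to degree 5).
#' @return List with points `s` in (0, 1) and weights `w` summing to 1.
#' @export
edge_quadrature <- function(n = 3L) {
  g <- sqrt(3 / 5)
  list(s = c(0.5 * (1 - g), 0.5, 0.5 * (1 + g)),
       w = c(5, 8, 5) / 18)
}
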