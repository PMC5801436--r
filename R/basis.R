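# Reference-element tools shared by the assembly routines, the Raviart-Thomas
# evaluator and the test oracles. Local corner j (1-based) of a hexahedron has
# offset bits (dx, dy, dz) with j = 1 + dx + 2 dy + 4 dz, matching the
# element connectivity built by build_hex_mesh().

corner_offsets <- function() {
  cbind(dx = rep(0:1, 4),
        dy = rep(rep(0:1, each = 2), 2),
        dz = rep(0:1, each = 4))
}

#' Gauss-Legendre quadrature on the unit interval
#'
#' @param n number of points (1 to 5).
#' @return list with `points` and `weights` on \[0, 1\].
#' @export
gauss_rule <- function(n) {
  gl <- switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(0.6), 0, sqrt(0.6)), w = c(5, 8, 5) / 9),
    "4" = list(
      x = c(-0.8611363115940526, -0.3399810435848563,
            0.3399810435848563, 0.8611363115940526),
      w = c(0.3478548451374538, 0.6521451548625461,
            0.6521451548625461, 0.3478548451374538)),
    "5" = list(
      x = c(-0.9061798459386640, -0.5384693101056831, 0,
            0.5384693101056831, 0.9061798459386640),
      w = c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891)),
    stop("unsupported quadrature order: ", n))
  list(points = (1 + gl$x) / 2, weights = gl$w / 2)
}

#' Trilinear shape function values on the unit cube
#'
#' @param xi matrix (or length-3 vector) of local coordinates in \[0, 1\]^3.
#' @return matrix `nrow(xi)` x 8 of shape function values.
#' @export
trilinear_basis <- function(xi) {
  xi <- rbind(xi)
  off <- corner_offsets()
  out <- matrix(0, nrow(xi), 8)
  for (j in 1:8) {
    fx <- if (off[j, 1] == 1) xi[, 1] else 1 - xi[, 1]
    fy <- if (off[j, 2] == 1) xi[, 2] else 1 - xi[, 2]
    fz <- if (off[j, 3] == 1) xi[, 3] else 1 - xi[, 3]
    out[, j] <- fx * fy * fz
  }
  out
}

#' Trilinear shape function gradients on the unit cube
#'
#' Gradients are with respect to the local coordinates; divide by the mesh
#' width to obtain physical gradients.
#'
#' @param xi length-3 vector of local coordinates.
#' @return 8 x 3 matrix of local gradients.
#' @export
trilinear_grad <- function(xi) {
  off <- corner_offsets()
  out <- matrix(0, 8, 3)
  for (j in 1:8) {
    f <- vapply(1:3, function(a)
      if (off[j, a] == 1) xi[a] else 1 - xi[a], numeric(1))
    s <- ifelse(off[j, ] == 1, 1, -1)
    out[j, 1] <- s[1] * f[2] * f[3]
    out[j, 2] <- s[2] * f[1] * f[3]
    out[j, 3] <- s[3] * f[1] * f[2]
  }
  out
}

# tensor-product quadrature over the unit cube: data.frame-free list with
# points (nq x 3) and weights (nq)
cube_quadrature <- function(n) {
  g <- gauss_rule(n)
  grid <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  list(points = cbind(g$points[grid$x], g$points[grid$y], g$points[grid$z]),
       weights = g$weights[grid$x] * g$weights[grid$y] * g$weights[grid$z])
}
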