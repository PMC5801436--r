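# Closed-form reference solutions. All positions are in meters, dipole
# moments in A m, magnetic fields in Tesla, potentials in Volt.

MU0 <- 4 * pi * 1e-7

#' Current dipole
#'
#' A mathematical point dipole j^p(r) = M delta(r - r0) with moment `M`
#' \[A m\] at position `r0` \[m\].
#'
#' @param position length-3 numeric, dipole location in meters.
#' @param moment length-3 numeric, dipole moment in A m.
#' @return object of class `dipole`.
#' @export
dipole <- function(position, moment) {
  position <- as.numeric(position); moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3)
  if (sqrt(sum(moment^2)) <= 0)
    stop("dipole moment must be nonzero")
  structure(list(position = position, moment = moment), class = "dipole")
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf("dipole at (%.4g, %.4g, %.4g) mm, moment (%.3g, %.3g, %.3g) A m\n",
              x$position[1] * 1e3, x$position[2] * 1e3, x$position[3] * 1e3,
              x$moment[1], x$moment[2], x$moment[3]))
  invisible(x)
}

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1) b <- b[rep(1, n), , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Primary magnetic field of a point dipole
#'
#' B^p(r) = mu0 / (4 pi) M x (r - r0) / |r - r0|^3, the field the source
#' current alone would generate in free space.
#'
#' @param dip a [dipole()].
#' @param r n x 3 matrix of field points (meters).
#' @return n x 3 matrix of fields in Tesla.
#' @export
primary_b_field <- function(dip, r) {
  r <- rbind(r)
  a <- sweep(r, 2, dip$position)
  an <- sqrt(rowSums(a^2))
  if (any(an == 0)) stop("field point coincides with the dipole position")
  (MU0 / (4 * pi)) * cross3(dip$moment, a) / an^3
}

#' Sarvas solution: magnetic field outside a spherical conductor
#'
#' Closed-form total magnetic field outside a spherically symmetric volume
#' conductor centered at the origin,
#' B(r) = mu0 / (4 pi F^2) (F M x r0 - (M x r0 . r) grad F),
#' with a = r - r0, F = a (r a + r^2 - r0 . r). The result is independent of
#' the (radial) conductivity profile, and vanishes identically for radial
#' sources; accordingly the function takes no conductivity argument.
#'
#' @param dip a [dipole()] strictly inside the conductor.
#' @param r n x 3 matrix of field points outside the conductor (meters).
#' @return n x 3 matrix of fields in Tesla.
#' @export
sarvas_b_field <- function(dip, r) {
  r <- rbind(r)
  r0 <- dip$position; m <- dip$moment
  a <- sweep(r, 2, r0)
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  rr0 <- as.vector(r %*% r0)
  F <- an * (rn * an + rn^2 - rr0)
  if (any(abs(F) < 1e-30))
    stop("numerical degeneracy: F = 0 (field point on the dipole ray)")
  cF1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  cF2 <- an + 2 * rn + ar / an
  gF <- r * cF1 - matrix(r0, nrow(r), 3, byrow = TRUE) * cF2
  mxr0 <- cross3(m, r0)[1, ]
  q <- as.vector(r %*% mxr0)   # (M x r0) . r
  (MU0 / (4 * pi)) * (F * matrix(mxr0, nrow(r), 3, byrow = TRUE) - q * gF) / F^2
}

#' Singularity potential of the subtraction approach
#'
#' Potential of a point dipole in an unbounded homogeneous conductor of
#' conductivity `sigma_inf`:
#' u_inf(r) = M . (r - r0) / (4 pi sigma_inf |r - r0|^3).
#'
#' @param dip a [dipole()].
#' @param sigma_inf homogeneous conductivity in S/m.
#' @param r n x 3 matrix of evaluation points (meters).
#' @return numeric vector of potentials in Volt.
#' @export
singularity_potential <- function(dip, sigma_inf, r) {
  stopifnot(sigma_inf > 0)
  r <- rbind(r)
  a <- sweep(r, 2, dip$position)
  an <- sqrt(rowSums(a^2))
  if (any(an == 0)) stop("evaluation point coincides with the dipole position")
  as.vector(a %*% dip$moment) / (4 * pi * sigma_inf * an^3)
}

#' Gradient of the singularity potential
#'
#' Exact analytic gradient of [singularity_potential()]:
#' grad u_inf = (M / |a|^3 - 3 (M . a) a / |a|^5) / (4 pi sigma_inf).
#'
#' @inheritParams singularity_potential
#' @return n x 3 matrix in V/m.
#' @export
grad_singularity_potential <- function(dip, sigma_inf, r) {
  stopifnot(sigma_inf > 0)
  r <- rbind(r)
  a <- sweep(r, 2, dip$position)
  an2 <- rowSums(a^2)
  if (any(an2 == 0)) stop("evaluation point coincides with the dipole position")
  an <- sqrt(an2)
  ma <- as.vector(a %*% dip$moment)
  (matrix(dip$moment, nrow(r), 3, byrow = TRUE) / an^3 -
     3 * ma * a / an^5) / (4 * pi * sigma_inf)
}
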