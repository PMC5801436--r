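# Continuous Galerkin (trilinear nodal) discretization of the subtraction
# correction-potential problem
#   -div(sigma grad u_corr) = div(sigma_corr grad u_inf)   in Omega
#    sigma grad u_corr . n  = -sigma grad u_inf . n        on the boundary
# with sigma = sigma_inf + sigma_corr and sigma_corr = 0 around the source.

#' Resolve the source environment of a dipole in a mesh
#'
#' Locates the element containing the dipole (half-open ownership
#' `[x, x + h)` per axis) and returns the homogeneous conductivity
#' `sigma_inf` of the subtraction split, taken from that element. A dipole
#' that coincides with a mesh vertex is perturbed by `1e-9 h` along each
#' axis, with a warning, since the nodal interpolant of the singularity
#' potential would otherwise be evaluated at its pole.
#'
#' @param mesh a `hex_mesh`.
#' @param dip a [dipole()].
#' @return list with the (possibly perturbed) `dipole`, containing `element`
#'   id and `sigma_inf`.
#' @export
source_environment <- function(mesh, dip) {
  pos <- dip$position
  on_lattice <- abs(pos / mesh$h - round(pos / mesh$h)) < 1e-12
  if (all(on_lattice)) {
    warning("dipole coincides with a mesh vertex; perturbing by 1e-9 h")
    pos <- pos + 1e-9 * mesh$h
    dip <- dipole(pos, dip$moment)
  }
  el <- locate_element(mesh, pos)
  if (el == 0L)
    stop("dipole position lies outside the mesh")
  list(dipole = dip, element = el, sigma_inf = mesh$sigma[el])
}

#' Assemble the CG stiffness matrix
#'
#' K_ij = int sigma grad(phi_i) . grad(phi_j) over all elements, with
#' trilinear nodal hat functions and 2x2x2 Gauss quadrature per element
#' (exact for this basis on axis-aligned cubes). The matrix is symmetric
#' positive semi-definite with the constants in its kernel (pure Neumann
#' problem).
#'
#' @param mesh a `hex_mesh` with positive conductivities.
#' @return object of class `cg_system` holding the sparse matrix `K`
#'   (dgCMatrix, vertices x vertices) and the mesh.
#' @export
assemble_cg_stiffness <- function(mesh) {
  stopifnot(all(mesh$sigma > 0))
  Kref <- cpp_ref_stiffness(2L)
  A <- mesh$elements
  ai <- rep(1:8, times = 8)
  bi <- rep(1:8, each = 8)
  nvert <- nrow(mesh$vertices)
  # assemble in element chunks to keep the triplet transients moderate on
  # the finer meshes
  chunk <- 100000L
  starts <- seq(1L, nrow(A), by = chunk)
  K <- NULL
  for (s in starts) {
    e <- s:min(s + chunk - 1L, nrow(A))
    Kc <- Matrix::sparseMatrix(
      i = as.vector(A[e, ai]), j = as.vector(A[e, bi]),
      x = as.vector(outer(mesh$sigma[e] * mesh$h, as.vector(Kref))),
      dims = c(nvert, nvert))
    K <- if (is.null(K)) Kc else K + Kc
  }
  structure(list(K = K, mesh = mesh, env = new.env(parent = emptyenv())),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("CG system: %d nodal dofs, %d nonzeros\n",
              nrow(x$K), Matrix::nnzero(x$K)))
  invisible(x)
}

#' Assemble the CG subtraction right-hand side
#'
#' j_i = -int_Omega sigma_corr grad(u_inf) . grad(phi_i)
#'       - int_boundary sigma_inf grad(u_inf) . n phi_i,
#' with the analytic gradient of the singularity potential evaluated at the
#' quadrature points. The volume term only visits elements where
#' sigma_corr = sigma - sigma_inf is nonzero.
#'
#' @param mesh a `hex_mesh`.
#' @param dip a [dipole()] inside the mesh.
#' @param sigma_inf homogeneous source conductivity; default: conductivity
#'   of the element containing the dipole.
#' @param quad_order volume quadrature order per axis (default 2).
#' @return numeric right-hand-side vector over mesh vertices.
#' @export
assemble_cg_rhs <- function(mesh, dip, sigma_inf = NULL, quad_order = 2) {
  se <- source_environment(mesh, dip)
  if (is.null(sigma_inf)) sigma_inf <- se$sigma_inf
  dip <- se$dipole
  bf <- boundary_faces(mesh)
  cpp_cg_rhs(mesh$elem_origin, mesh$elements - 1L, mesh$sigma, mesh$h,
             sigma_inf, dip$position, dip$moment, bf, as.integer(quad_order),
             2L, nrow(mesh$vertices))
}

# boundary faces as an integer matrix (e0, axis0, sign) for the C++ kernels
boundary_faces <- function(mesh) {
  nb <- mesh$neighbors
  bl <- which(nb == 0L, arr.ind = TRUE)
  d <- bl[, 2]
  out <- cbind(bl[, 1] - 1L, as.integer((d + 1) %/% 2) - 1L,
               ifelse(d %% 2 == 0L, 1L, -1L))
  storage.mode(out) <- "integer"
  out
}

#' Solve the singular Neumann system
#'
#' Solves K u = j for the correction potential in the zero-mean gauge. The
#' right-hand side is projected onto the compatible subspace (orthogonal to
#' constants); the system is grounded at one node, factorized with a sparse
#' Cholesky decomposition (cached on the system object for reuse across
#' sources), and the mean of the solution is removed. The magnetic field
#' depends only on the gradient of the potential, so the gauge is
#' immaterial.
#'
#' @param system a `cg_system`.
#' @param rhs right-hand side vector.
#' @param tol relative residual tolerance (default 1e-8).
#' @return object of class `potential_field` with `basis = "cg"`.
#' @export
solve_neumann <- function(system, rhs, tol = 1e-8) {
  stopifnot(inherits(system, "cg_system"))
  K <- system$K
  n <- nrow(K)
  rhs <- rhs - mean(rhs)
  if (all(rhs == 0))
    return(potential_field("cg", numeric(n), system$mesh,
                           info = list(solver = "cholesky", residual = 0)))
  if (n > CG_DIRECT_LIMIT) {
    # direct factorization fill becomes prohibitive; geometric two-level PCG
    if (is.null(system$env$prec))
      system$env$prec <- cg_two_level_precond(K, system$mesh$vertices,
                                              system$mesh$h)
    sol <- pcg_zero_mean(K, rhs, system$env$prec, tol, max_iter = 500L)
    return(potential_field("cg", sol$x, system$mesh,
                           info = list(solver = "pcg",
                                       residual = sol$residual,
                                       iterations = sol$iterations)))
  }
  if (is.null(system$env$chol))
    system$env$chol <- Matrix::Cholesky(
      Matrix::forceSymmetric(K[-1, -1, drop = FALSE]), LDL = FALSE,
      perm = TRUE, super = TRUE)
  x <- c(0, as.vector(Matrix::solve(system$env$chol, rhs[-1])))
  x <- x - mean(x)
  res <- sqrt(sum((as.vector(K %*% x) - rhs)^2)) / sqrt(sum(rhs^2))
  if (res > tol)
    stop(sprintf("Neumann solve did not reach tolerance: residual %.3g", res))
  potential_field("cg", x, system$mesh,
                  info = list(solver = "cholesky", residual = res))
}

# potential field container shared by CG and DG solvers
potential_field <- function(basis, coefficients, mesh, info = list()) {
  structure(list(basis = basis, coefficients = coefficients, mesh = mesh,
                 info = info),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential field (%s basis): %d dofs", x$basis,
              length(x$coefficients)))
  if (!is.null(x$info$residual))
    cat(sprintf(", solver residual %.2g", x$info$residual))
  cat("\n")
  invisible(x)
}

#' Nodal coefficients of the singularity potential
#'
#' Interpolates u_inf into the discrete space: vertex values for the CG
#' basis, element-corner values (identical at shared vertices) for the DG
#' basis. Used to integrate the u_inf part of the secondary magnetic field
#' with the same discretization as the correction potential.
#'
#' @param mesh a `hex_mesh`.
#' @param dip a [dipole()].
#' @param sigma_inf homogeneous source conductivity.
#' @param basis `"cg"` or `"dg"`.
#' @return coefficient vector (vertices, or 8 x elements).
#' @export
uinf_coefficients <- function(mesh, dip, sigma_inf, basis = c("cg", "dg")) {
  basis <- match.arg(basis)
  uv <- singularity_potential(dip, sigma_inf, mesh$vertices)
  if (basis == "cg") uv else uv[as.vector(t(mesh$elements))]
}
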