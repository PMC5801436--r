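# Symmetric interior-penalty discontinuous Galerkin (SIPG) discretization of
# the subtraction correction-potential problem, with element-wise trilinear
# basis (8 dofs per hexahedron, dof 8(e-1)+j for corner j of element e).
#
# On an internal face between elements e and f the scheme uses the
# conductivity-weighted average {q} = w_e q_e + w_f q_f with
# w_e = sigma_f / (sigma_e + sigma_f) (and vice versa), so that
# w_e sigma_e = w_f sigma_f = sigma_e sigma_f / (sigma_e + sigma_f), and the
# penalty is eta sigma_hat / h_gamma with sigma_hat the harmonic mean
# 2 sigma_e sigma_f / (sigma_e + sigma_f) - the companion of the weighted
# average that keeps the penalty on the scale of the smaller conductivity,
# the regime that matters at the skull.

#' Assemble the SIPG stiffness matrix
#'
#' Bilinear form: volume term int sigma grad(u) . grad(v) per element;
#' consistency and symmetry terms -int {sigma grad u} . \[\[v\]\]
#' - int {sigma grad v} . \[\[u\]\] over internal faces with
#' conductivity-weighted averages; penalty
#' eta int (sigma_hat / h_gamma) \[\[u\]\] . \[\[v\]\]. Face quadrature is
#' 2 x 2 Gauss (exact for trilinear traces). The matrix is symmetric with
#' constants in its kernel; it is positive semi-definite for sufficiently
#' large `eta`.
#'
#' @param mesh a `hex_mesh`.
#' @param eta penalty parameter (> 0), default 4 for trilinear elements.
#' @return object of class `dg_system` with the sparse matrix `K`
#'   (8 elements x 8 elements dofs), the mesh and `eta`.
#' @export
assemble_dg_stiffness <- function(mesh, eta = 4) {
  if (eta <= 0) stop("invalid penalty: eta must be positive")
  raw <- cpp_dg_stiffness(mesh$sigma, mesh$h, eta, mesh$neighbors - 1L)
  # slots are already valid CSC (sorted, 0-based); bypass sparseMatrix() to
  # avoid duplicating the (potentially multi-GB) value vector
  K <- methods::new(methods::getClassDef("dgCMatrix",
                                         package = "Matrix"),
                    p = raw$p, i = raw$i, x = raw$x,
                    Dim = c(raw$ndof, raw$ndof))
  structure(list(K = K, mesh = mesh, eta = eta,
                 env = new.env(parent = emptyenv())),
            class = "dg_system")
}

#' @export
print.dg_system <- function(x, ...) {
  cat(sprintf("SIPG system: %d dofs (8 x %d elements), eta = %g, %d nonzeros\n",
              nrow(x$K), nrow(x$K) / 8, x$eta, Matrix::nnzero(x$K)))
  invisible(x)
}

#' Per-face trace data of the SIPG scheme
#'
#' Weighted-average weights, penalty conductivity sigma_hat (harmonic mean)
#' and local mesh width per internal face; mainly a diagnostic surface.
#'
#' @param mesh a `hex_mesh`; @param skeleton its `skeleton`.
#' @return data.frame with one row per internal face.
#' @export
dg_face_data <- function(mesh, skeleton) {
  se <- mesh$sigma[skeleton$ifaces[, 1]]
  sf <- mesh$sigma[skeleton$ifaces[, 2]]
  data.frame(e = skeleton$ifaces[, 1], f = skeleton$ifaces[, 2],
             axis = skeleton$ifaces[, 3],
             w_e = sf / (se + sf), w_f = se / (se + sf),
             sigma_hat = 2 * se * sf / (se + sf),
             h_gamma = mesh$h)
}

#' Assemble the SIPG subtraction right-hand side
#'
#' l(v) = -int_Omega sigma_corr grad(u_inf) . grad(v)
#'        - int_boundary sigma_inf grad(u_inf) . n v
#'        + int_skeleton {sigma_corr grad(u_inf)} . \[\[v\]\],
#' with analytic grad(u_inf) at the quadrature points; the skeleton term is
#' restricted to faces where sigma_corr does not vanish on both sides.
#'
#' @param mesh a `hex_mesh`; @param skeleton its `skeleton`.
#' @param dip a [dipole()] inside the mesh.
#' @param sigma_inf homogeneous source conductivity; default from the
#'   element containing the dipole.
#' @param quad_order volume quadrature order per axis (default 2).
#' @return right-hand-side vector of length 8 x elements.
#' @export
assemble_dg_rhs <- function(mesh, skeleton, dip, sigma_inf = NULL,
                            quad_order = 2) {
  se <- source_environment(mesh, dip)
  if (is.null(sigma_inf)) sigma_inf <- se$sigma_inf
  dip <- se$dipole
  ifc <- skeleton$ifaces
  ifc[, 1:2] <- ifc[, 1:2] - 1L
  ifc[, 3] <- ifc[, 3] - 1L
  cpp_dg_rhs(mesh$elem_origin, mesh$sigma, mesh$h, sigma_inf,
             dip$position, dip$moment, boundary_faces(mesh), ifc,
             as.integer(quad_order), 2L)
}

# prolongation from the CG (vertex) space into the DG space: each element
# corner dof takes the value of its vertex; P^T K_dg P equals the CG
# stiffness because all face jumps vanish on continuous functions
dg_prolongation <- function(mesh) {
  nd <- 8L * nrow(mesh$elements)
  Matrix::sparseMatrix(i = seq_len(nd), j = as.vector(t(mesh$elements)),
                       x = 1, dims = c(nd, nrow(mesh$vertices)))
}

# two-level preconditioner setup: damped element-block Jacobi smoother plus
# a coarse correction in the conforming (CG) subspace, solved by a grounded
# sparse Cholesky factorization
dg_precond_setup <- function(system) {
  env <- system$env
  if (!is.null(env$prec)) return(invisible(env$prec))
  mesh <- system$mesh
  K <- system$K
  nelem <- nrow(mesh$elements)
  cg <- assemble_cg_stiffness(mesh)
  nvert <- nrow(cg$K)
  coarse_solve <- if (nvert > CG_DIRECT_LIMIT) {
    # fine meshes: the conforming level itself is solved approximately by a
    # geometric V-cycle (Jacobi + 2h-lattice Galerkin coarse factorization);
    # a fixed linear symmetric operator, so outer PCG remains valid
    cg_two_level_precond(cg$K, mesh$vertices, mesh$h)
  } else {
    fac <- Matrix::Cholesky(
      Matrix::forceSymmetric(cg$K[-1, -1, drop = FALSE]),
      LDL = FALSE, perm = TRUE, super = TRUE)
    function(rc) c(0, as.vector(Matrix::solve(fac, rc[-1])))
  }
  P <- dg_prolongation(mesh)
  Pt <- Matrix::t(P)
  # block-diagonal inverse of the element 8x8 blocks (block Jacobi); the
  # blocks are positive definite whenever the element has at least one face
  # in the skeleton; a single isolated element falls back to point Jacobi
  smooth <- if (nelem > 1) {
    binv <- cpp_dg_block_inverse(K@p, K@i, K@x, nelem)
    # block-diagonal CSC slots written directly: column 8(e-1)+c holds rows
    # 8(e-1)+1..8(e-1)+8, matching the column-major block inverses
    ndof <- 8L * nelem
    B <- methods::new(methods::getClassDef("dgCMatrix", package = "Matrix"),
                      p = 8L * (0:ndof),
                      i = rep(8L * (seq_len(nelem) - 1L), each = 64L) +
                        rep_len(0:7, 64L * nelem),
                      x = binv$x, Dim = c(ndof, ndof))
    rm(binv)   # closures capture this frame; drop transients
    function(r) as.vector(B %*% r)
  } else {
    D <- Matrix::diag(K)
    function(r) r / D
  }
  rm(cg)
  invisible(gc(FALSE))
  # damp below 1/lambda_max(B^-1 K) (power iteration) so the symmetric
  # V-cycle stays positive definite
  v <- rep_len(c(1, -1, 0.5, -0.25), nrow(K))
  lmax <- 1
  for (i in 1:16) {
    v <- smooth(as.vector(K %*% v))
    lmax <- sqrt(sum(v^2))
    v <- v / lmax
    if (i %% 4L == 0L) invisible(gc(FALSE))
  }
  omega <- 0.9 / lmax
  prec <- function(r) {
    z1 <- omega * smooth(r)
    r1 <- r - as.vector(K %*% z1)
    zc <- coarse_solve(as.vector(Pt %*% r1))
    z2 <- z1 + as.vector(P %*% zc)
    r2 <- r - as.vector(K %*% z2)
    z2 + omega * smooth(r2)
  }
  env$prec <- prec
  invisible(prec)
}

#' Solve the SIPG system
#'
#' Preconditioned conjugate gradients in the zero-mean gauge. The
#' preconditioner is a symmetric two-level V-cycle: damped Jacobi smoothing
#' around a coarse correction in the conforming trilinear subspace (whose
#' Galerkin matrix is exactly the CG stiffness), solved by a cached sparse
#' Cholesky factorization. This keeps memory linear in the mesh size, which
#' matters for the finer sphere models where a direct factorization of the
#' DG matrix is not practical.
#'
#' @param system a `dg_system`.
#' @param rhs right-hand side (length 8 x elements), compatible (summing
#'   to zero) up to roundoff.
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return object of class `potential_field` with `basis = "dg"`.
#' @export
solve_dg <- function(system, rhs, tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(system, "dg_system"))
  prec <- dg_precond_setup(system)
  sol <- pcg_zero_mean(system$K, rhs, prec, tol, max_iter)
  potential_field("dg", sol$x, system$mesh,
                  info = list(solver = "pcg", residual = sol$residual,
                              iterations = sol$iterations))
}

#' Element-wise charge balance of a DG solution
#'
#' For every element K integrates the chosen discrete flux over its faces
#' and subtracts the prescribed boundary inflow:
#' sum over internal faces of int( j_hat . n_K + {sigma_corr grad u_inf} . n_K )
#' minus sum over boundary faces of int( sigma_inf grad u_inf . n ).
#' With the conservative skeleton flux
#' j_hat = {sigma grad u_corr} - eta (sigma_hat / h) \[\[u_corr\]\]
#' this balance vanishes for every element up to the solver tolerance
#' (discrete conservation of charge); the one-sided nodal flux
#' sigma_K grad u_corr|_K has no such guarantee and violates the balance,
#' most visibly across the high-contrast skull interfaces.
#'
#' @param potential a DG `potential_field`.
#' @param system the `dg_system` it was solved on.
#' @param dip the source [dipole()] (possibly perturbed; use the one from
#'   [source_environment()]).
#' @param sigma_inf homogeneous source conductivity.
#' @param flux `"conservative"` or `"nodal"`.
#' @return numeric vector of per-element balances \[A\].
#' @export
element_balance <- function(potential, system, dip, sigma_inf,
                            flux = c("conservative", "nodal")) {
  flux <- match.arg(flux)
  stopifnot(potential$basis == "dg")
  mesh <- system$mesh
  cpp_dg_balance(mesh$elem_origin, mesh$sigma, mesh$h, system$eta,
                 mesh$neighbors - 1L, potential$coefficients, sigma_inf,
                 dip$position, dip$moment, 2L, flux == "conservative")
}

#' Evaluate a DG potential and its face jumps
#'
#' Maximum absolute inter-element jump of a DG field over internal face
#' centroids; a diagnostic for the consistency of the discrete solution
#' (jumps vanish as the mesh is refined).
#'
#' @param potential a DG `potential_field`.
#' @param skeleton the mesh `skeleton`.
#' @return numeric vector of jump values (e-side minus f-side) per face.
#' @export
face_jumps <- function(potential, skeleton) {
  stopifnot(potential$basis == "dg")
  u <- potential$coefficients
  ifc <- skeleton$ifaces
  n <- nrow(ifc)
  jumps <- numeric(n)
  for (a in 1:3) {
    sela <- which(ifc[, 3] == a)
    if (!length(sela)) next
    xe <- c(0.5, 0.5, 0.5); xe[a] <- 1
    xf <- c(0.5, 0.5, 0.5); xf[a] <- 0
    Ne <- trilinear_basis(xe)[1, ]
    Nf <- trilinear_basis(xf)[1, ]
    Ue <- matrix(u[rep(8 * (ifc[sela, 1] - 1L), each = 8) + 1:8], 8)
    Uf <- matrix(u[rep(8 * (ifc[sela, 2] - 1L), each = 8) + 1:8], 8)
    jumps[sela] <- as.vector(Ne %*% Ue) - as.vector(Nf %*% Uf)
  }
  jumps
}
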