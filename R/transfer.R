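# MEG transfer matrices: B_MEG = S K^-1, computed row-wise from K B^t = S^t
# using the symmetry of K, so that each additional source costs one
# matrix-vector product instead of one EEG solve.

#' Compute an MEG transfer matrix
#'
#' Solves K x = (S^t column r) for every row r of the integration matrix S
#' (each column mean-removed for the pure-Neumann nullspace) and stacks the
#' solutions into B_MEG. Rows are solved sequentially in a fixed order, so
#' the result is deterministic given the solver settings.
#'
#' @param system a `cg_system` or `dg_system`.
#' @param S integration matrix (rows = 3 x sensors, columns = dofs of the
#'   system).
#' @param tol solver tolerance per row.
#' @return object of class `transfer_matrix` with the dense matrix `B` and
#'   provenance (discretization, tolerance, eta if DG).
#' @export
compute_transfer <- function(system, S, tol = 1e-8) {
  ndof <- nrow(system$K)
  if (ncol(S) != ndof)
    stop("integration matrix does not match the system dofs")
  B <- matrix(0, nrow(S), ndof)
  for (r in seq_len(nrow(S))) {
    rhs <- S[r, ]
    sol <- tryCatch(
      if (inherits(system, "cg_system")) solve_neumann(system, rhs, tol)
      else solve_dg(system, rhs, tol),
      error = function(e)
        stop(sprintf("transfer solve failed for row %d: %s", r,
                     conditionMessage(e))))
    B[r, ] <- sol$coefficients
  }
  structure(list(
    B = B,
    provenance = list(discretization = class(system)[1], tol = tol,
                      eta = system$eta, ndof = ndof)),
    class = "transfer_matrix")
}

#' Apply a transfer matrix to a source right-hand side
#'
#' @param transfer a `transfer_matrix`.
#' @param rhs EEG right-hand-side vector (compatible with the system the
#'   transfer matrix was computed from).
#' @return sensors x 3 matrix of secondary-field values \[T\].
#' @export
apply_transfer <- function(transfer, rhs) {
  if (length(rhs) != ncol(transfer$B))
    stop("right-hand side length does not match the transfer matrix")
  matrix(transfer$B %*% (rhs - mean(rhs)), ncol = 3, byrow = TRUE)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("MEG transfer matrix: %d field components x %d dofs (%s)\n",
              nrow(x$B), ncol(x$B), x$provenance$discretization))
  invisible(x)
}
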