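# Geometric two-level machinery for the conforming (vertex) systems on fine
# meshes. Direct sparse factorization of the 3D nodal Laplacian stops being
# practical somewhere below half a million unknowns (supernodal fill), so
# beyond a size threshold the grounded Cholesky solve is replaced by
# conjugate gradients preconditioned with a symmetric V-cycle: damped Jacobi
# smoothing around a coarse correction on the 2h vertex lattice, with the
# Galerkin coarse operator factorized directly. The same V-cycle serves as
# the (approximate, linear, symmetric) coarse solver inside the DG
# preconditioner on fine meshes.

CG_DIRECT_LIMIT <- 200000L

# trilinear interpolation from the 2h vertex lattice into the fine vertex
# set, built purely from integer lattice arithmetic: fine vertex i gets
# weights (1, 1/2) from the surrounding even-lattice points that exist in
# the fine vertex set (rows renormalized near the staircase boundary)
cg_coarse_interpolation <- function(vertices, h) {
  iv <- round(vertices / h)
  nfine <- nrow(iv)
  fine_keys <- lattice_key(iv[, 1], iv[, 2], iv[, 3])
  base <- 2L * floor(iv / 2)
  off <- corner_offsets() * 2L
  ii <- jj <- ww <- vector("list", 8)
  cand_keys <- vector("list", 8)
  for (c in 1:8) {
    pt <- sweep(base, 2, off[c, ], "+")
    w <- (1 - abs(iv[, 1] - pt[, 1]) / 2) *
      (1 - abs(iv[, 2] - pt[, 2]) / 2) *
      (1 - abs(iv[, 3] - pt[, 3]) / 2)
    k <- lattice_key(pt[, 1], pt[, 2], pt[, 3])
    sel <- which(w > 0 & !is.na(match(k, fine_keys)))
    ii[[c]] <- sel
    cand_keys[[c]] <- k[sel]
    ww[[c]] <- w[sel]
  }
  all_keys <- sort(unique(unlist(cand_keys)))
  P <- Matrix::sparseMatrix(
    i = unlist(ii),
    j = match(unlist(cand_keys), all_keys),
    x = unlist(ww),
    dims = c(nfine, length(all_keys)))
  rs <- Matrix::rowSums(P)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% P
}

# symmetric two-level V-cycle preconditioner for a conforming vertex system
cg_two_level_precond <- function(K, vertices, h) {
  P <- cg_coarse_interpolation(vertices, h)
  Ac <- Matrix::forceSymmetric(Matrix::t(P) %*% K %*% P)
  fac <- Matrix::Cholesky(Ac[-1, -1, drop = FALSE], LDL = FALSE,
                          perm = TRUE, super = TRUE)
  Pt <- Matrix::t(P)
  rm(Ac)   # the returned closure captures this frame
  invisible(gc(FALSE))
  D <- Matrix::diag(K)
  v <- rep_len(c(1, -1, 0.5, -0.25), nrow(K))
  lmax <- 1
  for (i in 1:16) {
    v <- as.vector(K %*% v) / D
    lmax <- sqrt(sum(v^2))
    v <- v / lmax
    if (i %% 4L == 0L) invisible(gc(FALSE))
  }
  omega <- 0.9 / lmax
  function(r) {
    z1 <- omega * r / D
    r1 <- r - as.vector(K %*% z1)
    rc <- as.vector(Pt %*% r1)
    zc <- c(0, as.vector(Matrix::solve(fac, rc[-1])))
    z2 <- z1 + as.vector(P %*% zc)
    r2 <- r - as.vector(K %*% z2)
    z2 + omega * r2 / D
  }
}

# preconditioned conjugate gradients in the zero-mean gauge (shared by the
# large-mesh CG solve and, with a different preconditioner, the DG solve)
pcg_zero_mean <- function(K, b, prec, tol, max_iter) {
  n <- nrow(K)
  b <- b - mean(b)
  bn <- sqrt(sum(b^2))
  if (bn == 0)
    return(list(x = numeric(n), iterations = 0L, residual = 0))
  x <- numeric(n)
  r <- b
  z <- prec(r); z <- z - mean(z)
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Kp <- as.vector(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    rn <- sqrt(sum(r^2))
    if (rn <= tol * bn) break
    if (it >= max_iter)
      stop(sprintf(
        "iterative solve failed to converge: residual %.3g after %d iterations",
        rn / bn, it))
    if (n > 2e6) invisible(gc(FALSE))
    else if (n > 5e5 && it %% 10L == 0L) invisible(gc(FALSE))
    z <- prec(r); z <- z - mean(z)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x - mean(x), iterations = it, residual = rn / bn)
}
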