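# Shared fixtures and independent reference (oracle) implementations.
# Oracles are deliberately written in plain R, independently of the compiled
# assembly kernels, so that both routes can be compared on small meshes.

# structured block mesh: nx x ny x nz unit voxels of width h_mm, with an
# optional label array and compartment table
test_block_mesh <- function(nx, ny, nz, h_mm = 1, sigma = 1, labels = NULL,
                            compartments = NULL) {
  if (is.null(labels)) labels <- array(1L, c(nx, ny, nz))
  if (is.null(compartments))
    compartments <- compartment_table(paste0("c", seq_along(sigma)),
                                      100 + seq_along(sigma), sigma)
  seg <- structure(list(labels = labels, dims = dim(labels),
                        voxel_size = h_mm * 1e-3, origin = rep(0, 3),
                        index0 = 0, compartments = compartments,
                        convention = "test"),
                   class = "voxel_segmentation")
  build_hex_mesh(seg)
}

# small four-layer sphere (quarter-scale radii) shared across tests
local_sphere_cache <- new.env(parent = emptyenv())
test_small_sphere <- function(h_mm = 2) {
  key <- paste0("s", h_mm)
  if (is.null(local_sphere_cache[[key]])) {
    comp <- compartment_table(outer_radius_mm = c(19.5, 20, 21.5, 23))
    mesh <- sphere_mesh(h_mm, comp)
    local_sphere_cache[[key]] <- list(mesh = mesh,
                                      skeleton = build_skeleton(mesh))
  }
  local_sphere_cache[[key]]
}

# independent single-element trilinear stiffness via high-order R quadrature
ref_element_stiffness <- function(h, sigma, q = 4) {
  quad <- megfem:::cube_quadrature(q)
  K <- matrix(0, 8, 8)
  for (p in seq_len(nrow(quad$points))) {
    G <- trilinear_grad(quad$points[p, ]) / h
    K <- K + quad$weights[p] * h^3 * sigma * (G %*% t(G))
  }
  K
}

# independent R implementation of the CG subtraction right-hand side
ref_cg_rhs <- function(mesh, dip, sigma_inf, qvol = 2, qface = 2) {
  rhs <- numeric(nrow(mesh$vertices))
  quad <- megfem:::cube_quadrature(qvol)
  h <- mesh$h
  for (e in seq_len(nrow(mesh$elements))) {
    sc <- mesh$sigma[e] - sigma_inf
    if (sc == 0) next
    for (p in seq_len(nrow(quad$points))) {
      x <- mesh$elem_origin[e, ] + h * quad$points[p, ]
      g <- grad_singularity_potential(dip, sigma_inf, x)[1, ]
      G <- trilinear_grad(quad$points[p, ]) / h
      rhs[mesh$elements[e, ]] <- rhs[mesh$elements[e, ]] -
        quad$weights[p] * h^3 * sc * as.vector(G %*% g)
    }
  }
  skel <- build_skeleton(mesh)
  g2 <- gauss_rule(qface)
  for (b in seq_len(skel$n_bnd)) {
    e <- skel$bfaces[b, 1]; a <- skel$bfaces[b, 2]; s <- skel$bfaces[b, 3]
    ta <- setdiff(1:3, a)
    for (i in seq_len(qface)) for (j in seq_len(qface)) {
      xi <- numeric(3)
      xi[a] <- if (s > 0) 1 else 0
      xi[ta[1]] <- g2$points[i]; xi[ta[2]] <- g2$points[j]
      x <- mesh$elem_origin[e, ] + h * xi
      g <- grad_singularity_potential(dip, sigma_inf, x)[1, ]
      N <- trilinear_basis(xi)[1, ]
      w <- g2$weights[i] * g2$weights[j] * h^2
      rhs[mesh$elements[e, ]] <- rhs[mesh$elements[e, ]] -
        w * sigma_inf * (s * g[a]) * N
    }
  }
  rhs
}

# independent R implementation of the SIPG bilinear form (dense, tiny meshes)
ref_dg_stiffness <- function(mesh, eta, qface = 2) {
  ne <- nrow(mesh$elements)
  n <- 8 * ne
  K <- matrix(0, n, n)
  h <- mesh$h
  Kel <- ref_element_stiffness(h, 1, q = 2)
  for (e in seq_len(ne)) {
    idx <- 8 * (e - 1) + 1:8
    K[idx, idx] <- K[idx, idx] + mesh$sigma[e] * Kel
  }
  skel <- build_skeleton(mesh)
  g2 <- gauss_rule(qface)
  for (k in seq_len(skel$n_int)) {
    e <- skel$ifaces[k, 1]; f <- skel$ifaces[k, 2]; a <- skel$ifaces[k, 3]
    se <- mesh$sigma[e]; sf <- mesh$sigma[f]
    we <- sf / (se + sf); wf <- se / (se + sf)
    shat <- 2 * se * sf / (se + sf)
    ie <- 8 * (e - 1) + 1:8; jf <- 8 * (f - 1) + 1:8
    ta <- setdiff(1:3, a)
    for (i in seq_len(qface)) for (j in seq_len(qface)) {
      xe <- numeric(3); xe[a] <- 1
      xe[ta[1]] <- g2$points[i]; xe[ta[2]] <- g2$points[j]
      xf <- xe; xf[a] <- 0
      Ne <- trilinear_basis(xe)[1, ]; Nf <- trilinear_basis(xf)[1, ]
      dNe <- trilinear_grad(xe)[, a] / h
      dNf <- trilinear_grad(xf)[, a] / h
      w <- g2$weights[i] * g2$weights[j] * h^2
      # jump [[v]] . n_e = v_e - v_f; {sigma grad u} . n_e
      jmp <- c(Ne, -Nf)
      avg <- c(we * se * dNe, wf * sf * dNf)
      full <- c(ie, jf)
      K[full, full] <- K[full, full] -
        w * (outer(jmp, avg) + outer(avg, jmp)) +
        w * eta * shat / h * outer(jmp, jmp)
    }
  }
  K
}

# Monte-Carlo Biot-Savart integral of sigma grad(phi_b) over one element
mc_element_bs <- function(mesh, e, b, sensor, n = 1e6, seed = 99) {
  h <- mesh$h
  set.seed(seed)
  xi <- matrix(runif(3 * n), n, 3)
  x <- sweep(xi * h, 2, mesh$elem_origin[e, ], "+")
  # local gradient of basis b at each point
  off <- megfem:::corner_offsets()
  gx <- (if (off[b, 1] == 1) 1 else -1) *
    (if (off[b, 2] == 1) xi[, 2] else 1 - xi[, 2]) *
    (if (off[b, 3] == 1) xi[, 3] else 1 - xi[, 3])
  gy <- (if (off[b, 2] == 1) 1 else -1) *
    (if (off[b, 1] == 1) xi[, 1] else 1 - xi[, 1]) *
    (if (off[b, 3] == 1) xi[, 3] else 1 - xi[, 3])
  gz <- (if (off[b, 3] == 1) 1 else -1) *
    (if (off[b, 1] == 1) xi[, 1] else 1 - xi[, 1]) *
    (if (off[b, 2] == 1) xi[, 2] else 1 - xi[, 2])
  G <- cbind(gx, gy, gz) / h
  d <- -sweep(x, 2, sensor)
  r3 <- (rowSums(d^2))^1.5
  kern <- d / r3
  cr <- cbind(G[, 2] * kern[, 3] - G[, 3] * kern[, 2],
              G[, 3] * kern[, 1] - G[, 1] * kern[, 3],
              G[, 1] * kern[, 2] - G[, 2] * kern[, 1])
  -1e-7 * mesh$sigma[e] * h^3 * colMeans(cr)
}

# Monte-Carlo Biot-Savart integral of an RT0 basis over its support
mc_rt0_bs <- function(mesh, skel, k, sensor, n = 1e6, seed = 98) {
  h <- mesh$h
  e <- skel$ifaces[k, 1]; f <- skel$ifaces[k, 2]; a <- skel$ifaces[k, 3]
  cent <- face_centroids(mesh, skel, "internal")[k, ]
  set.seed(seed)
  out <- 0
  for (el in c(e, f)) {
    xi <- matrix(runif(3 * n), n, 3)
    x <- sweep(xi * h, 2, mesh$elem_origin[el, ], "+")
    tent <- 1 - abs(x[, a] - cent[a]) / h
    psi <- matrix(0, n, 3); psi[, a] <- tent
    d <- -sweep(x, 2, sensor)
    r3 <- (rowSums(d^2))^1.5
    kern <- d / r3
    cr <- cbind(psi[, 2] * kern[, 3] - psi[, 3] * kern[, 2],
                psi[, 3] * kern[, 1] - psi[, 1] * kern[, 3],
                psi[, 1] * kern[, 2] - psi[, 2] * kern[, 1])
    out <- out - 1e-7 * h^3 * colMeans(cr)
  }
  out
}
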