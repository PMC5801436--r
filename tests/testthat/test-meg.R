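test_that("nodal integration of constant potentials is a null field", {
  sm <- test_small_sphere(4)
  sens <- generate_magnetometers(8, 30)
  S <- assemble_S_nodal(sm$mesh, sens, basis = "cg", quad_order = 2)
  Bc <- S %*% rep(1, ncol(S))
  expect_lt(max(abs(Bc)), 1e-10 * max(abs(S)))
})

test_that("single-element Biot-Savart entries match Monte-Carlo quadrature", {
  mesh <- test_block_mesh(1, 1, 1, h_mm = 5, sigma = 0.8)
  sensor <- c(0.03, 0.02, 0.04)
  S <- assemble_S_nodal(mesh, matrix(sensor, 1), basis = "cg")
  for (b in c(1, 6)) {
    mc <- mc_element_bs(mesh, 1, b, sensor, n = 1e6)
    expect_equal(S[, b], mc, tolerance = 5e-3, ignore_attr = TRUE)
  }
})

test_that("matrix and matrix-free nodal integration agree exactly", {
  sm <- test_small_sphere(4)
  sens <- generate_magnetometers(6, 30)
  set.seed(21)
  u <- rnorm(nrow(sm$mesh$vertices))
  S <- assemble_S_nodal(sm$mesh, sens, basis = "cg")
  B1 <- matrix(S %*% u, ncol = 3, byrow = TRUE)
  B2 <- bs_nodal_field(sm$mesh, sens, u, basis = "cg")
  expect_equal(B1, B2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(assemble_S_nodal(sm$mesh, matrix(c(0, 0, 0.01), 1)),
               "outside")
})

test_that("conservative flux of a continuous linear field is sigma grad u . n", {
  mesh <- test_block_mesh(3, 2, 2, h_mm = 2, sigma = 0.9)
  skel <- build_skeleton(mesh)
  grad <- c(2, -1, 0.5)
  # interpolate u(x) = grad . x into the DG space
  verts <- mesh$vertices[as.vector(t(mesh$elements)), ]
  u <- as.vector(verts %*% grad)
  pot <- megfem:::potential_field("dg", u, mesh)
  dip <- dipole(c(1, 1, 1) * 1e-3, c(1, 0, 0))
  fl <- conservative_flux(pot, skel, eta = 4, dip, 0.9, boundary = "zero")
  nrm <- matrix(0, skel$n_int, 3)
  nrm[cbind(seq_len(skel$n_int), skel$ifaces[, 3])] <- 1
  expect_equal(fl$internal, 0.9 * as.vector(nrm %*% grad), tolerance = 1e-12)
  # zero potential, no source: zero flux
  fl0 <- conservative_flux(megfem:::potential_field("dg", 0 * u, mesh), skel,
                           4, dip, 0.9, boundary = "zero")
  expect_identical(max(abs(fl0$internal)), 0)
})

test_that("RT0 interpolation honors its degrees of freedom and constants", {
  mesh <- test_block_mesh(3, 3, 3, h_mm = 2)
  skel <- build_skeleton(mesh)
  v0 <- c(1.5, -2, 0.75)
  nrm_i <- matrix(0, skel$n_int, 3)
  nrm_i[cbind(seq_len(skel$n_int), skel$ifaces[, 3])] <- 1
  nrm_b <- matrix(0, skel$n_bnd, 3)
  nrm_b[cbind(seq_len(skel$n_bnd), skel$bfaces[, 2])] <- skel$bfaces[, 3]
  fl <- structure(list(internal = as.vector(nrm_i %*% v0),
                       boundary = as.vector(nrm_b %*% v0), skeleton = skel),
                  class = "face_flux_field")
  rt <- rt0_project(fl, mesh)
  # dof interpolation at a face centroid: normal component equals alpha
  cent <- face_centroids(mesh, skel, "internal")
  k <- 5L
  val <- evaluate_rt0(rt, cent[k, , drop = FALSE])[1, ]
  expect_equal(val[skel$ifaces[k, 3]], fl$internal[k], tolerance = 1e-12)
  # a constant field assigned via its normal fluxes is reproduced everywhere
  set.seed(31)
  pts <- matrix(runif(300, 0.2e-3, 5.8e-3), 100, 3)
  vals <- evaluate_rt0(rt, pts)
  expect_equal(vals, matrix(v0, 100, 3, byrow = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("element-wise RT0 divergence is the net outflux over the volume", {
  mesh <- test_block_mesh(2, 2, 2, h_mm = 3)
  skel <- build_skeleton(mesh)
  set.seed(32)
  fl <- structure(list(internal = rnorm(skel$n_int),
                       boundary = rnorm(skel$n_bnd), skeleton = skel),
                  class = "face_flux_field")
  rt <- rt0_project(fl, mesh)
  h <- mesh$h
  alpha <- c(fl$internal, fl$boundary)
  for (e in c(1L, 8L)) {
    # net outflux: +faces minus -faces (canonical internal normals are +axis)
    sgn <- c(-1, 1, -1, 1, -1, 1)
    ids <- skel$face_of[e, ]
    bnd <- ids > skel$n_int
    sgn[bnd] <- 1  # boundary normals are already outward
    out <- sum(sgn * alpha[ids]) * h^2
    # divergence by central differencing inside the element (it is constant)
    x0 <- mesh$elem_origin[e, ] + h / 2
    d <- 0.2 * h
    div <- sum(vapply(1:3, function(a) {
      dx <- numeric(3); dx[a] <- d
      (evaluate_rt0(rt, matrix(x0 + dx, 1))[1, a] -
         evaluate_rt0(rt, matrix(x0 - dx, 1))[1, a]) / (2 * d)
    }, numeric(1)))
    expect_equal(div, out / h^3, tolerance = 1e-10)
  }
})

test_that("RT0 basis moments match Monte-Carlo quadrature", {
  mesh <- test_block_mesh(2, 1, 1, h_mm = 5)
  skel <- build_skeleton(mesh)
  sensor <- c(0.04, 0.03, 0.025)
  M <- assemble_rt0_moments(mesh, skel, matrix(sensor, 1))
  mc <- mc_rt0_bs(mesh, skel, 1, sensor, n = 1e6)
  expect_equal(M[, 1], mc, tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("conservative and nodal DG integrators coincide for linear potentials", {
  # uniform conductivity and a continuous linear potential: the skeleton
  # flux has no jumps, its RT0 extension reproduces the constant current
  # sigma grad(u), and both integrators see the same volume field
  mesh <- test_block_mesh(3, 3, 2, h_mm = 2, sigma = 1.1)
  skel <- build_skeleton(mesh)
  sens <- matrix(c(0.05, 0.04, 0.06), 1)
  grad <- c(0.8, -0.4, 1.2) * 1e-3
  u <- as.vector(mesh$vertices[as.vector(t(mesh$elements)), ] %*% grad)
  pot <- megfem:::potential_field("dg", u, mesh)
  B_nodal <- bs_nodal_field(mesh, sens, u, basis = "dg")
  dip <- dipole(c(1, 1, 1) * 1e-3, c(1, 0, 0))
  fl <- conservative_flux(pot, skel, eta = 4, dip, 1.1, boundary = "zero")
  # boundary RT0 dofs must carry the same current for constant reproduction
  nrm_b <- matrix(0, skel$n_bnd, 3)
  nrm_b[cbind(seq_len(skel$n_bnd), skel$bfaces[, 2])] <- skel$bfaces[, 3]
  fl$boundary <- 1.1 * as.vector(nrm_b %*% grad)
  B_rt0 <- megfem:::bs_rt0_field(mesh, skel, sens, fl)
  expect_equal(B_rt0, B_nodal, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("integration matrices are linear and the DG matrix matches the apply route", {
  mesh <- test_block_mesh(2, 2, 1, h_mm = 3, sigma = 0.6)
  skel <- build_skeleton(mesh)
  sens <- matrix(c(0.04, -0.03, 0.05), 1)
  S <- assemble_S_corr_DG(mesh, skel, sens, eta = 4)
  set.seed(34)
  u <- rnorm(8 * nrow(mesh$elements))
  v <- rnorm(8 * nrow(mesh$elements))
  expect_equal(as.vector(S %*% (2 * u - 3 * v)),
               as.vector(2 * (S %*% u) - 3 * (S %*% v)), tolerance = 1e-12)
  # matrix route equals flux-then-moments route (zero boundary datum)
  pot <- megfem:::potential_field("dg", u, mesh)
  dip <- dipole(c(1, 1, 1) * 1e-3, c(1, 0, 0))
  fl <- conservative_flux(pot, skel, 4, dip, 0.6, boundary = "zero")
  B1 <- megfem:::bs_rt0_field(mesh, skel, sens, fl)
  B2 <- matrix(S %*% u, ncol = 3, byrow = TRUE)
  expect_equal(B1, B2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("full field assembly is the exact sum of its parts", {
  sm <- test_small_sphere(4)
  sens <- generate_magnetometers(8, 30)
  dip <- dipole(c(0.0011, 0.0014, 0.0088), c(1, -0.3, 0))
  se <- source_environment(sm$mesh, dip)
  sys <- assemble_dg_stiffness(sm$mesh, eta = 4)
  sol <- solve_dg(sys, assemble_dg_rhs(sm$mesh, sm$skeleton, se$dipole))
  bf <- full_b_field(se$dipole, sens, sol, skeleton = sm$skeleton,
                     flux = "conservative", sigma_inf = se$sigma_inf, eta = 4)
  expect_identical(bf$B, bf$Bp + bf$Bs)
  expect_identical(bf$Bs, bf$Bs_inf + bf$Bs_corr)
})

test_that("a radial source leaves only numerical cancellation residue", {
  sm <- test_small_sphere()
  sens <- generate_magnetometers(16, 30)
  pos <- c(0.0003, 0.0007, 0.0101)
  dip <- dipole(pos, pos / sqrt(sum(pos^2)))  # radial: analytic B vanishes
  se <- source_environment(sm$mesh, dip)
  sys <- assemble_dg_stiffness(sm$mesh, eta = 4)
  sol <- solve_dg(sys, assemble_dg_rhs(sm$mesh, sm$skeleton, se$dipole))
  bf <- full_b_field(se$dipole, sens, sol, skeleton = sm$skeleton,
                     flux = "conservative", sigma_inf = se$sigma_inf, eta = 4)
  expect_lt(sqrt(sum(bf$B^2)) / sqrt(sum(bf$Bp^2)), 0.2)
})
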