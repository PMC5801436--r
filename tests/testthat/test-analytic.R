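test_that("primary field matches an independently coded cross product", {
  dip <- dipole(c(0.01, -0.02, 0.03), c(0.5, -1, 2))
  r <- matrix(c(0.08, 0.05, -0.11), 1)
  B <- primary_b_field(dip, r)[1, ]
  # scalar re-derivation, component by component
  a <- r[1, ] - dip$position
  m <- dip$moment
  cx <- c(m[2] * a[3] - m[3] * a[2], m[3] * a[1] - m[1] * a[3],
          m[1] * a[2] - m[2] * a[1])
  d <- sqrt(sum(a^2))
  expect_equal(B, 1e-7 * cx / d^3, tolerance = 1e-14)
})

test_that("primary field obeys the closed-form special cases", {
  r0 <- c(0, 0, 0.02)
  # moment parallel to the separation: zero field
  dip <- dipole(r0, c(0, 0, 3))
  expect_equal(primary_b_field(dip, matrix(c(0, 0, 0.1), 1))[1, ], rep(0, 3))
  # perpendicular moment at distance d: magnitude mu0 |M| / (4 pi d^2)
  dipp <- dipole(r0, c(2, 0, 0))
  d <- 0.08
  B <- primary_b_field(dipp, matrix(c(0, 0, 0.02 + d), 1))[1, ]
  expect_equal(sqrt(sum(B^2)), 1e-7 * 2 / d^2, tolerance = 1e-12)
  expect_error(primary_b_field(dipp, matrix(r0, 1)), "coincides")
})

test_that("Sarvas field vanishes for radial sources and takes no conductivity", {
  for (pos in list(c(0, 0, 0.05), c(0.03, 0.01, -0.02))) {
    dip <- dipole(pos, 2.5 * pos)  # radial moment
    r <- matrix(rnorm(30), 10)
    r <- 0.12 * r / sqrt(rowSums(r^2))
    expect_equal(max(abs(sarvas_b_field(dip, r))), 0)
  }
  expect_false("sigma" %in% names(formals(sarvas_b_field)))
  expect_false(any(grepl("conduct", names(formals(sarvas_b_field)))))
})

test_that("secondary Sarvas field is purely tangential at external points", {
  set.seed(3)
  dip <- dipole(c(0.011, -0.024, 0.04), c(1, 2, -0.5))
  r <- matrix(rnorm(60), 20)
  r <- 0.11 * r / sqrt(rowSums(r^2))
  B <- sarvas_b_field(dip, r)
  Bp <- primary_b_field(dip, r)
  radial <- rowSums((B - Bp) * r / 0.11)
  expect_lt(max(abs(radial)) / max(abs(B)), 1e-12)
})

test_that("Sarvas field is linear in the dipole moment", {
  r <- matrix(c(0.09, -0.03, 0.06), 1)
  p <- c(0.02, 0.015, -0.03)
  m1 <- c(1, 0, 2); m2 <- c(-0.5, 1, 0)
  B12 <- sarvas_b_field(dipole(p, m1 + 2 * m2), r)
  expect_equal(B12, sarvas_b_field(dipole(p, m1), r) +
                 2 * sarvas_b_field(dipole(p, m2), r), tolerance = 1e-12)
})

test_that("Sarvas field is divergence- and curl-free outside the conductor", {
  dip <- dipole(c(0.01, 0.02, 0.035), c(1, -1, 0.5))
  eps <- 1e-6
  pts <- rbind(c(0.1, 0.02, -0.04), c(-0.07, 0.08, 0.05))
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    J <- matrix(0, 3, 3)  # J[a, b] = d B_a / d x_b
    for (b in 1:3) {
      dx <- numeric(3); dx[b] <- eps
      J[, b] <- (sarvas_b_field(dip, matrix(x + dx, 1)) -
                   sarvas_b_field(dip, matrix(x - dx, 1))) / (2 * eps)
    }
    scale <- max(abs(J))
    expect_lt(abs(sum(diag(J))) / scale, 1e-5)              # div B = 0
    curl <- c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
    expect_lt(max(abs(curl)) / scale, 1e-5)                 # curl B = 0
  }
})

test_that("singularity potential has dipole antisymmetry and 1/r^2 decay", {
  dip <- dipole(c(0.001, 0.002, -0.001), c(1, 2, 3))
  d <- c(0.004, -0.003, 0.005)
  up <- singularity_potential(dip, 0.33, matrix(dip$position + d, 1))
  um <- singularity_potential(dip, 0.33, matrix(dip$position - d, 1))
  expect_equal(up, -um, tolerance = 1e-12)
  u1 <- singularity_potential(dip, 0.33, matrix(dip$position + 10 * d, 1))
  u2 <- singularity_potential(dip, 0.33, matrix(dip$position + 100 * d, 1))
  expect_equal(u1 / u2, 100, tolerance = 1e-6)
  expect_error(singularity_potential(dip, 0.33, matrix(dip$position, 1)),
               "coincides")
})

test_that("analytic gradient matches central finite differences", {
  dip <- dipole(c(0.005, -0.002, 0.001), c(0.3, -1.2, 0.8))
  sinf <- 0.33
  set.seed(11)
  for (k in 1:5) {
    x <- rnorm(3, sd = 0.02)
    d <- sqrt(sum((x - dip$position)^2))
    eps <- 1e-6 * d
    g <- grad_singularity_potential(dip, sinf, matrix(x, 1))[1, ]
    gfd <- vapply(1:3, function(a) {
      dx <- numeric(3); dx[a] <- eps
      (singularity_potential(dip, sinf, matrix(x + dx, 1)) -
         singularity_potential(dip, sinf, matrix(x - dx, 1))) / (2 * eps)
    }, numeric(1))
    expect_equal(g, gfd, tolerance = 1e-5)
  }
})

test_that("the singularity potential is harmonic away from the source", {
  dip <- dipole(c(0, 0, 0), c(1, 0.5, -2))
  sinf <- 1
  set.seed(12)
  for (k in 1:5) {
    x <- rnorm(3, sd = 0.05)
    h <- 1e-4 * sqrt(sum(x^2))
    lap <- 0
    for (a in 1:3) {
      dx <- numeric(3); dx[a] <- h
      lap <- lap +
        (singularity_potential(dip, sinf, matrix(x + dx, 1)) -
           2 * singularity_potential(dip, sinf, matrix(x, 1)) +
           singularity_potential(dip, sinf, matrix(x - dx, 1))) / h^2
    }
    # scale by the potential's own second-derivative magnitude
    scale <- abs(singularity_potential(dip, sinf, matrix(x, 1))) /
      sum(x^2)
    expect_lt(abs(lap) / scale, 1e-4)
  }
})
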