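test_that("dipole ensembles have the stated size, tangency and determinism", {
  ecc <- eccentricity_table()$eccentricity
  ens <- generate_dipoles(1000, ecc, seed = 6)
  expect_identical(nrow(ens$positions), 8000L)
  r0n <- sqrt(rowSums(ens$positions^2))
  tang <- abs(rowSums(ens$positions * ens$moments))
  expect_lt(max(tang / r0n), 1e-12)
  expect_equal(sqrt(rowSums(ens$moments^2)), rep(1, 8000), tolerance = 1e-12)
  # shell radii are eccentricity times the brain radius
  expect_equal(r0n, rep(ecc, each = 1000) * 0.078, tolerance = 1e-12)
  ens2 <- generate_dipoles(1000, ecc, seed = 6)
  expect_identical(ens$positions, ens2$positions)
  expect_identical(ens$moments, ens2$moments)
  expect_error(generate_dipoles(5, c(0.5, 1)), "between 0 and 1")
})

test_that("the eccentricity table ties shells to distances from the CSF", {
  tab <- eccentricity_table()
  expect_identical(nrow(tab), 8L)
  expect_equal(tab$distance_mm[tab$eccentricity == 0.9873], 0.99)
  expect_equal(tab$distance_mm[tab$eccentricity == 0.9796], 1.59)
  expect_equal(tab$distance_mm, round((1 - tab$eccentricity) * 78, 2))
})

test_that("brain filtering equals an exhaustive label lookup", {
  sm <- test_small_sphere()
  mesh <- sm$mesh
  # deep sources are always kept
  deep <- generate_dipoles(50, 0.1, brain_radius_mm = 19.5, seed = 13)
  expect_identical(nrow(filter_brain_dipoles(deep, mesh)$positions), 50L)
  # shallow shell: some excluded, matching the brute-force check
  shallow <- generate_dipoles(200, 0.97, brain_radius_mm = 19.5, seed = 14)
  kept <- filter_brain_dipoles(shallow, mesh)
  bid <- match("brain", mesh$compartments$name)
  manual <- vapply(seq_len(200), function(i) {
    e <- locate_element(mesh, shallow$positions[i, , drop = FALSE])
    e != 0L && mesh$labels[e] == bid
  }, logical(1))
  expect_identical(nrow(kept$positions), sum(manual))
  expect_identical(kept$n_excluded, sum(!manual))
  # a dipole placed in a CSF element is excluded
  csf_el <- which(mesh$labels == match("csf", mesh$compartments$name))[1]
  pos <- mesh$elem_origin[csf_el, ] + mesh$h / 2
  one <- list(positions = matrix(pos, 1), moments = matrix(c(1, 0, 0), 1),
              eccentricity = 0.9, n_excluded = 0L)
  class(one) <- "dipole_ensemble"
  expect_identical(nrow(filter_brain_dipoles(one, mesh)$positions), 0L)
})

test_that("magnetometer arrays sit on the sphere with orthonormal frames", {
  sens <- generate_magnetometers(256, 110)
  expect_identical(nrow(sens$positions), 256L)
  expect_equal(sqrt(rowSums(sens$positions^2)), rep(0.110, 256),
               tolerance = 1e-12)
  expect_equal(rowSums(sens$normal * sens$t1), rep(0, 256), tolerance = 1e-12)
  expect_equal(rowSums(sens$normal * sens$t2), rep(0, 256), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(sens$t1^2)), rep(1, 256), tolerance = 1e-12)
  # all sensors distinct (positive minimal angular separation)
  g <- tcrossprod(sens$normal)
  diag(g) <- -2
  expect_lt(max(g), 1 - 1e-4)
})

test_that("RDM%/MAG% reproduce their defining identities", {
  set.seed(15)
  f <- matrix(rnorm(96), 32, 3)
  expect_equal(rdm_percent(f, f), 0, tolerance = 1e-12)
  expect_equal(mag_percent(f, f), 0, tolerance = 1e-12)
  expect_equal(rdm_percent(-f, f), 100, tolerance = 1e-12)
  expect_equal(mag_percent(-f, f), 0, tolerance = 1e-12)
  expect_equal(rdm_percent(2 * f, f), 0, tolerance = 1e-12)
  expect_equal(mag_percent(2 * f, f), 100, tolerance = 1e-12)
  # scale invariance of RDM%, joint-rotation invariance of MAG%
  g <- matrix(rnorm(96), 32, 3)
  expect_equal(rdm_percent(5 * g, f), rdm_percent(g, f), tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(mag_percent(g %*% R, f %*% R), mag_percent(g, f),
               tolerance = 1e-12)
  expect_error(rdm_percent(f, 0 * f), "radial")
  expect_error(mag_percent(f, 0 * f), "radial")
})

test_that("summaries match sort-based brute-force statistics", {
  s <- summarize_errors(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$total_range, 4)
  sc <- summarize_errors(rep(7, 10))
  expect_equal(sc$iqr, 0)
  expect_equal(sc$total_range, 0)
  set.seed(16)
  x <- rnorm(101)
  s2 <- summarize_errors(x)
  xs <- sort(x)
  expect_equal(s2$median, xs[51])
  expect_equal(s2$q1, xs[26])              # type-7 on n = 101 hits order stats
  expect_equal(s2$q3, xs[76])
  expect_equal(s2$total_range, xs[101] - xs[1])
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("a miniature study runs deterministically end to end", {
  # quarter-scale sphere keeps this fast; CG only
  comp <- compartment_table(outer_radius_mm = c(19.5, 20, 21.5, 23))
  mesh <- sphere_mesh(4, comp)
  skel <- build_skeleton(mesh)
  sens <- generate_magnetometers(16, 30)
  ens <- filter_brain_dipoles(
    generate_dipoles(3, c(0.5, 0.8), brain_radius_mm = 19.5, seed = 17),
    mesh)
  s1 <- forward_error_samples(mesh, sens, ens, method = "cg",
                              fluxes = "nodal", fields = c("Bs", "B"),
                              skeleton = skel)
  s2 <- forward_error_samples(mesh, sens, ens, method = "cg",
                              fluxes = "nodal", fields = c("Bs", "B"),
                              skeleton = skel)
  expect_identical(s1$rdm, s2$rdm)
  expect_identical(s1$mag, s2$mag)
  expect_true(all(s1$rdm >= 0 & s1$rdm <= 100))
  expect_true(all(s1$mag > -100))
  expect_identical(nrow(s1), 6L * 2L)
  # summaries recomputable from the samples
  sb <- s1[s1$field == "Bs", ]
  expect_equal(summarize_errors(sb$rdm)$mean, mean(sb$rdm))
})
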