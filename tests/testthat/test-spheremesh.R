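test_that("voxelization labels voxels by the innermost enclosing shell", {
  comp <- compartment_table(c("in", "out"), c(6, 10), c(1, 2))
  seg <- voxelize_sphere(comp, 2)
  # brute-force re-count over all voxel centers
  n <- ceiling(10 / 2)
  cc <- (seq(-n, n - 1) + 0.5) * 2
  g <- as.matrix(expand.grid(cc, cc, cc))
  d <- sqrt(rowSums(g^2))
  expect_identical(sum(seg$labels == 1L), sum(d <= 6))
  expect_identical(sum(seg$labels == 2L), sum(d > 6 & d <= 10))
  expect_identical(sum(seg$labels == 0L), sum(d > 10))
})

test_that("single-compartment element count matches brute-force enumeration", {
  comp <- compartment_table("ball", 10, 1)
  mesh <- build_hex_mesh(voxelize_sphere(comp, 4))
  n <- ceiling(10 / 4)
  cc <- (seq(-n, n - 1) + 0.5) * 4
  g <- as.matrix(expand.grid(cc, cc, cc))
  expect_identical(nrow(mesh$elements), sum(sqrt(rowSums(g^2)) <= 10))
  expect_identical(nrow(mesh$elements), sum(mesh$labels == 1L))
})

test_that("degenerate resolutions are rejected", {
  comp <- compartment_table("ball", 10, 1)
  expect_error(voxelize_sphere(comp, 12), "invalid resolution")
  expect_error(voxelize_sphere(comp, 0), "positive")
  expect_error(compartment_table("ball", 0, 1), "positive")
})

test_that("vertex deduplication is exact on small blocks", {
  m1 <- test_block_mesh(1, 1, 1)
  expect_identical(dim(m1$elements), c(1L, 8L))
  expect_identical(nrow(m1$vertices), 8L)
  m2 <- test_block_mesh(2, 1, 1)
  expect_identical(nrow(m2$elements), 2L)
  expect_identical(nrow(m2$vertices), 12L)  # shared face dedups 4 vertices
  # all elements are exact cubes of edge h with volume h^3
  for (e in 1:2) {
    v <- m2$vertices[m2$elements[e, ], ]
    expect_equal(max(v[, 1]) - min(v[, 1]), m2$h)
    expect_equal(apply(v, 2, function(x) length(unique(x))), rep(2, 3),
                 ignore_attr = TRUE)
  }
})

test_that("skeleton faces partition element faces (internal xor boundary)", {
  m2 <- test_block_mesh(2, 1, 1)
  sk2 <- build_skeleton(m2)
  expect_identical(sk2$n_int, 1L)
  expect_identical(sk2$n_bnd, 10L)
  m1 <- test_block_mesh(1, 1, 1)
  sk1 <- build_skeleton(m1)
  expect_identical(sk1$n_int, 0L)
  expect_identical(sk1$n_bnd, 6L)

  sm <- test_small_sphere()
  sk <- sm$skeleton
  expect_identical(6L * nrow(sm$mesh$elements), 2L * sk$n_int + sk$n_bnd)
  # canonical orientation: normal from lower to higher element index
  expect_true(all(sk$ifaces[, 1] < sk$ifaces[, 2]))
})

test_that("internal face count matches brute-force face matching", {
  comp <- compartment_table("ball", 8, 1)
  mesh <- build_hex_mesh(voxelize_sphere(comp, 2))
  skel <- build_skeleton(mesh)
  # hash-join: each face keyed by its 4 sorted vertex ids
  faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 5, 6),
                c(3, 4, 7, 8), c(1, 3, 5, 7), c(2, 4, 6, 8))
  keys <- unlist(lapply(faces, function(f)
    apply(mesh$elements[, f, drop = FALSE], 1, function(v)
      paste(sort(v), collapse = "-"))))
  expect_identical(skel$n_int, sum(table(keys) == 2L))
  # both elements of an internal face agree on the 4 shared vertices
  k <- skel$ifaces[1, ]
  shared <- intersect(mesh$elements[k[1], ], mesh$elements[k[2], ])
  expect_identical(length(shared), 4L)
})

test_that("leaky-point detection finds exactly the shared vertices", {
  labels <- array(0L, c(2, 1, 1)); labels[1, 1, 1] <- 2L; labels[2, 1, 1] <- 4L
  comp <- compartment_table(c("brain", "csf", "skull", "skin"),
                            c(5, 6, 7, 8), c(0.33, 1.79, 0.01, 0.43))
  mesh <- test_block_mesh(2, 1, 1, labels = labels,
                          compartments = comp)
  lp <- find_leaky_points(mesh)
  expect_identical(length(lp), 4L)
  expect_setequal(lp, intersect(mesh$elements[1, ], mesh$elements[2, ]))
  # symmetric under swapping brain and CSF in the inner set
  labels2 <- labels; labels2[1, 1, 1] <- 1L
  mesh2 <- test_block_mesh(2, 1, 1, labels = labels2, compartments = comp)
  expect_identical(find_leaky_points(mesh2), lp)
})

test_that("mesh generation is deterministic", {
  comp <- compartment_table()
  m1 <- build_hex_mesh(voxelize_sphere(comp, 8))
  m2 <- build_hex_mesh(voxelize_sphere(comp, 8))
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$labels, m2$labels)
})

test_that("element lookup honors half-open ownership", {
  mesh <- test_block_mesh(2, 2, 2, h_mm = 1)
  h <- mesh$h
  # interior point
  e <- locate_element(mesh, matrix(c(0.5, 0.5, 0.5) * h, 1))
  expect_identical(mesh$vox_index[e, ], c(0, 0, 0), ignore_attr = TRUE)
  # point on the shared face belongs to the +side element
  e2 <- locate_element(mesh, matrix(c(1, 0.5, 0.5) * h, 1))
  expect_identical(mesh$vox_index[e2, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_identical(locate_element(mesh, matrix(c(10, 0, 0), 1)), 0L)
})

test_that("VTK export writes a readable legacy unstructured grid", {
  mesh <- test_block_mesh(2, 1, 1)
  f <- tempfile(fileext = ".vtk")
  write_vtk_mesh(mesh, f)
  txt <- readLines(f)
  expect_identical(txt[4], "DATASET UNSTRUCTURED_GRID")
  expect_identical(sum(txt == "12"), 2L)  # two hexahedron cell types
  expect_true(any(grepl("^CELL_DATA 2$", txt)))
  unlink(f)
})
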